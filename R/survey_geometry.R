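## Survey-area construction: respondent buffers, pocket integration, overall
## survey area.

new_coverage <- function(geometry, class2 = "coverage_area") {
  structure(list(geometry = geometry,
                 area_km2 = polyset_area_m2(geometry) * 1e-6),
            class = c(class2, "coverage_area"))
}

#' @export
print.coverage_area <- function(x, ...) {
  cat(sprintf("<%s: %d ring(s), %.4f km2>\n", class(x)[1], length(x$geometry),
              x$area_km2))
  invisible(x)
}

#' Respondent coverage: union of detection buffers around valid returns
#'
#' Each respondent return is buffered by `r` meters (default 50 m — the
#' distance within which a householder is assumed aware of fox-cub or
#' badger-sett activity, roughly two gardens in semi-detached housing) and
#' the discs are unioned into the ground effectively surveyed.
#'
#' @param respondents a validated `site_survey`, or a data.frame with `x`,`y`
#'   columns of valid respondent locations (meters).
#' @param r buffer radius in meters (> 0).
#' @param quad_segs circle-approximation fineness (segments per quarter
#'   circle; default 16 i.e. 64 segments per disc).
#' @return a `coverage_area`: list with `geometry` ([polyset()]) and
#'   `area_km2`.
#' @export
respondent_coverage <- function(respondents, r = 50, quad_segs = 16) {
  if (inherits(respondents, "site_survey")) {
    respondents <- valid_respondents(respondents)
  }
  stopifnot(r > 0)
  respondents <- respondents[is.finite(respondents$x) & is.finite(respondents$y), ,
                             drop = FALSE]
  if (nrow(respondents) == 0L) degenerate_error("no valid respondents to buffer")
  geom <- discs_union(respondents$x, respondents$y, r, quad_segs = quad_segs)
  new_coverage(geom)
}

as_surveyed_polyset <- function(greenspaces) {
  if (is.null(greenspaces)) return(polyset())
  if (inherits(greenspaces, "polyset")) return(greenspaces)
  if (is.list(greenspaces) && !is.null(greenspaces$surveyed)) {
    return(greenspaces$surveyed)
  }
  polyset(greenspaces)
}

#' Integrate qualifying concavities ("pockets") into the coverage
#'
#' The buffer union around respondents is typically concave, with cavities
#' partly surrounded by surveyed gardens. Because fox territories are convex,
#' excluding such a cavity would understate the area surveyed and overstate
#' density; a cavity is therefore merged into the survey area when at least
#' `edge_fraction` (default 75%) of its edge borders respondent coverage or
#' surveyed greenspace.
#'
#' Candidates are (a) interior holes of the coverage (edge fraction 1 by
#' construction) and (b) connected components of the morphological closing
#' (dilate then erode by `closing_radius`) minus the coverage. The edge
#' fraction of a candidate is the share of its perimeter lying within `tol`
#' meters of the coverage/greenspace boundary. Every candidate decision is
#' recorded in the `pockets` attribute of the result.
#'
#' @param coverage a `coverage_area` from [respondent_coverage()].
#' @param greenspaces surveyed greenspace polygons ([read_greenspaces()]
#'   output, a [polyset()], or NULL).
#' @param edge_fraction minimum covered-edge share in (0, 1].
#' @param closing_radius morphological closing radius, meters; defaults to
#'   200 m, the scale of territory geometry.
#' @param tol boundary-adjacency tolerance in meters (absorbs segmentization
#'   error).
#' @param min_area_m2 candidates smaller than this are ignored as numeric
#'   slivers.
#' @return a `coverage_area` whose geometry includes surveyed greenspace and
#'   all accepted pockets; attribute `pockets` is a data.frame
#'   (kind, area_m2, perimeter_m, fraction, accepted).
#' @export
integrate_pockets <- function(coverage, greenspaces = NULL,
                              edge_fraction = 0.75, closing_radius = 200,
                              tol = 1, min_area_m2 = 1) {
  stopifnot(inherits(coverage, "coverage_area"),
            edge_fraction > 0, edge_fraction <= 1, closing_radius > 0)
  gs <- as_surveyed_polyset(greenspaces)
  base <- ps_union(coverage$geometry, gs)

  decisions <- data.frame(kind = character(0), area_m2 = numeric(0),
                          perimeter_m = numeric(0), fraction = numeric(0),
                          accepted = logical(0))
  fills <- list()

  ## (a) interior holes: fully bounded by surveyed ground
  comps <- group_rings(base)
  for (cp in comps) {
    for (h in cp$holes) {
      a <- abs(ring_signed_area(h))
      if (a < min_area_m2) next
      acc <- 1 >= edge_fraction
      decisions <- rbind(decisions, data.frame(
        kind = "hole", area_m2 = a, perimeter_m = ring_perimeter(h),
        fraction = 1, accepted = acc))
      if (acc) fills <- c(fills, list(list(x = rev(h$x), y = rev(h$y))))
    }
  }

  ## (b) boundary pockets from morphological closing
  closed <- ps_offset(ps_offset(base, closing_radius), -closing_radius)
  pockets <- ps_minus(closed, base)
  base_edges_all <- polyset_edges(base)
  filter_edges <- function(e, bbox, pad) {
    keep <- pmax(e$x1, e$x2) >= bbox[1] - pad & pmin(e$x1, e$x2) <= bbox[2] + pad &
            pmax(e$y1, e$y2) >= bbox[3] - pad & pmin(e$y1, e$y2) <= bbox[4] + pad
    list(x1 = e$x1[keep], y1 = e$y1[keep], x2 = e$x2[keep], y2 = e$y2[keep])
  }
  pcomps <- group_rings(pockets)
  for (cp in pcomps) {
    a <- abs(ring_signed_area(cp$outer))
    if (a < min_area_m2) next
    bb <- ring_bbox(cp$outer)
    be <- filter_edges(base_edges_all, bb, pad = 2 * tol)
    if (length(be$x1) == 0L) be <- base_edges_all
    dens <- densify_ring(cp$outer, step = max(tol, 0.5))
    d <- point_segment_dist(dens$x, dens$y, be$x1, be$y1, be$x2, be$y2)
    frac <- sum(dens$len[d <= tol]) / sum(dens$len)
    acc <- frac >= edge_fraction
    decisions <- rbind(decisions, data.frame(
      kind = "pocket", area_m2 = a, perimeter_m = ring_perimeter(cp$outer),
      fraction = frac, accepted = acc))
    if (acc) fills <- c(fills, list(cp$outer))
  }

  out <- if (length(fills)) ps_union(base, polyset(fills)) else base
  res <- new_coverage(out)
  attr(res, "pockets") <- decisions
  res
}

#' Overall survey area: coverage plus buffers around group centroids
#'
#' A further `r`-meter buffer (default 200 m, the record-integration
#' distance) is added around each social-group centroid and merged with the
#' survey boundary; its area is the denominator of group density.
#'
#' @param coverage a `coverage_area` (normally pocket-integrated).
#' @param centroids data.frame/matrix of centroid coordinates (`x`, `y`), a
#'   `group_clusters` object, or NULL/empty for none.
#' @param r centroid buffer radius, meters.
#' @param quad_segs circle-approximation fineness.
#' @return a `survey_area` (subclass of `coverage_area`).
#' @export
overall_survey_area <- function(coverage, centroids, r = 200, quad_segs = 16) {
  stopifnot(inherits(coverage, "coverage_area"), r > 0)
  if (inherits(centroids, "group_clusters")) centroids <- centroids$summary
  cents <- if (is.null(centroids)) NULL else as.data.frame(centroids)
  geom <- coverage$geometry
  if (!is.null(cents) && nrow(cents) > 0L) {
    discs <- discs_union(cents$x, cents$y, r, quad_segs = quad_segs)
    geom <- ps_union(geom, discs)
  }
  new_coverage(geom, class2 = "survey_area")
}

#' Export the survey-geometry layers of one site to GeoJSON
#'
#' Writes coverage, candidate pockets (with their accept/reject decision and
#' edge fraction) and the final survey area.
#' @param coverage pocket-integrated `coverage_area`.
#' @param survey `survey_area`.
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. the site id).
#' @return invisibly, the vector of files written.
#' @export
export_geometry_geojson <- function(coverage, survey, dir, prefix = "site") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_coverage.geojson"))
  write_geojson(list(list(geometry = coverage$geometry,
                          properties = list(layer = "coverage",
                                            area_km2 = coverage$area_km2))), f1)
  f2 <- file.path(dir, paste0(prefix, "_survey_area.geojson"))
  write_geojson(list(list(geometry = survey$geometry,
                          properties = list(layer = "survey_area",
                                            area_km2 = survey$area_km2))), f2)
  invisible(c(f1, f2))
}
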