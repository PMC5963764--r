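## GeoJSON in/out for planar polygon layers (via jsonlite). Coordinates are
## carried verbatim (projected meters), i.e. the files are GeoJSON-dialect
## with a local planar CRS, matching the rest of the pipeline.

geojson_ring_to_list <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  ## GeoJSON rings are closed; drop the repeated last vertex
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  list(x = m[, 1], y = m[, 2])
}

polygon_coords_to_rings <- function(coords) {
  rings <- lapply(coords, geojson_ring_to_list)
  ## normalise orientation: first ring outer (positive), rest holes (negative)
  for (i in seq_along(rings)) {
    a <- ring_signed_area(rings[[i]])
    want_pos <- i == 1L
    if ((a > 0) != want_pos) {
      rings[[i]] <- list(x = rev(rings[[i]]$x), y = rev(rings[[i]]$y))
    }
  }
  rings
}

#' Read a greenspace polygon layer from GeoJSON
#'
#' Features must be Polygon or MultiPolygon with planar (metric) coordinates;
#' a boolean `surveyed` property marks ground actually covered by field
#' surveys (unmarked features default to unsurveyed).
#'
#' @param path GeoJSON file.
#' @return list with elements `surveyed` and `unsurveyed`, each a [polyset()].
#' @export
read_greenspaces <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(g$type, "FeatureCollection")) g$features else list(g)
  surveyed <- list(); unsurveyed <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    rings <- switch(geom$type,
      Polygon = polygon_coords_to_rings(geom$coordinates),
      MultiPolygon = do.call(c, lapply(geom$coordinates, polygon_coords_to_rings)),
      format_error(sprintf("unsupported GeoJSON geometry type '%s'", geom$type))
    )
    if (isTRUE(f$properties$surveyed)) {
      surveyed <- c(surveyed, rings)
    } else {
      unsurveyed <- c(unsurveyed, rings)
    }
  }
  list(surveyed = polyset(surveyed), unsurveyed = polyset(unsurveyed))
}

## Group the rings of a polyset into outer-with-holes components (holes have
## opposite orientation sign and lie inside their outer ring).
group_rings <- function(ps) {
  if (length(ps) == 0L) return(list())
  areas <- vapply(ps, ring_signed_area, numeric(1))
  dominant <- sign(sum(areas[abs(areas) == max(abs(areas))][1]))
  outers <- which(sign(areas) == dominant)
  holes <- setdiff(seq_along(ps), outers)
  comps <- lapply(outers, function(i) list(outer = ps[[i]], holes = list()))
  for (h in holes) {
    px <- ps[[h]]$x[1]; py <- ps[[h]]$y[1]
    for (k in seq_along(comps)) {
      if (point_in_ring(px, py, comps[[k]]$outer)) {
        comps[[k]]$holes <- c(comps[[k]]$holes, list(ps[[h]]))
        break
      }
    }
  }
  comps
}

ring_to_geojson <- function(r, close = TRUE) {
  x <- r$x; y <- r$y
  if (close) { x <- c(x, x[1]); y <- c(y, y[1]) }
  lapply(seq_along(x), function(i) c(x[i], y[i]))
}

polyset_to_geojson_geom <- function(ps) {
  comps <- group_rings(ps)
  polys <- lapply(comps, function(cp) {
    c(list(ring_to_geojson(cp$outer)), lapply(cp$holes, ring_to_geojson))
  })
  list(type = "MultiPolygon", coordinates = polys)
}

#' Write polygon features to GeoJSON
#'
#' @param features list of features, each `list(geometry = <polyset>,
#'   properties = <named list>)`.
#' @param path output file.
#' @export
write_geojson <- function(features, path) {
  fc <- list(
    type = "FeatureCollection",
    features = lapply(features, function(f) list(
      type = "Feature",
      properties = f$properties %||% structure(list(), names = character(0)),
      geometry = polyset_to_geojson_geom(f$geometry)
    ))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write point features to GeoJSON
#' @param df data.frame with `x`, `y` and any property columns.
#' @param path output file.
#' @export
write_points_geojson <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  fc <- list(
    type = "FeatureCollection",
    features = lapply(seq_len(nrow(df)), function(i) list(
      type = "Feature",
      properties = as.list(df[i, props, drop = FALSE]),
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i]))
    ))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
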