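## End-to-end orchestration: io -> geometry -> integration -> density
## (-> summaries), with per-site audit logging.

#' Pipeline run configuration
#'
#' All method constants live here, never hard-coded in the operations.
#'
#' @param sites list of per-site input specs, each
#'   `list(points = <csv path or data.frame>, polygons = <geojson path or
#'   NULL>, config = <site config list or yaml path>)`.
#' @param species species to analyse (`"fox"` or `"badger"`).
#' @param buffer_respondent_m respondent buffer radius (50 m).
#' @param buffer_centroid_m centroid buffer radius (200 m).
#' @param integration_threshold_m record-integration distance (200 m).
#' @param edge_fraction pocket edge-coverage rule (0.75).
#' @param closing_radius_m pocket-detection closing radius (200 m).
#' @param pockets apply the pocket rule (per-species switch, default on).
#' @param group_size animals per group for individual density (fox 3.4,
#'   badger 5.5 when NULL).
#' @param suburban_land_km2 national suburban land cover (9,116.4 km^2).
#' @param outdir output directory, or NULL for no file output.
#' @param seed RNG seed (only simulation subcommands use randomness).
#' @return a `run_config` list.
#' @export
run_config <- function(sites, species = "fox", buffer_respondent_m = 50,
                       buffer_centroid_m = 200, integration_threshold_m = 200,
                       edge_fraction = 0.75, closing_radius_m = 200,
                       pockets = TRUE, group_size = NULL,
                       suburban_land_km2 = 9116.4, outdir = NULL, seed = 1) {
  stopifnot(buffer_respondent_m > 0, buffer_centroid_m > 0,
            integration_threshold_m > 0,
            edge_fraction > 0, edge_fraction <= 1)
  if (is.null(group_size)) group_size <- if (species == "fox") 3.4 else 5.5
  structure(list(sites = sites, species = species,
                 buffer_respondent_m = buffer_respondent_m,
                 buffer_centroid_m = buffer_centroid_m,
                 integration_threshold_m = integration_threshold_m,
                 edge_fraction = edge_fraction,
                 closing_radius_m = closing_radius_m, pockets = pockets,
                 group_size = group_size,
                 suburban_land_km2 = suburban_land_km2,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

run_one_site <- function(spec, cfg, log) {
  site <- load_site_survey(spec$points, spec$polygons, spec$config %||% list())
  site <- validate_returns(site)
  log(sprintf("site %s: %d respondents (%d valid, %d geometry points), %d records (%d after de-duplication)",
              site$site_id, nrow(site$respondents), sum(site$respondents$valid),
              sum(site$respondents$geom_use), nrow(site$records),
              nrow(site_records(site))))
  cov <- respondent_coverage(site, r = cfg$buffer_respondent_m)
  log(sprintf("site %s: respondent coverage %.4f km2", site$site_id, cov$area_km2))
  if (isTRUE(cfg$pockets)) {
    cov <- integrate_pockets(cov, site$greenspaces,
                             edge_fraction = cfg$edge_fraction,
                             closing_radius = cfg$closing_radius_m)
    pk <- attr(cov, "pockets")
    for (i in seq_len(nrow(pk))) {
      log(sprintf("site %s: %s area %.0f m2 edge fraction %.3f -> %s",
                  site$site_id, pk$kind[i], pk$area_m2[i], pk$fraction[i],
                  if (pk$accepted[i]) "integrated" else "kept out"))
    }
    log(sprintf("site %s: coverage after pocket integration %.4f km2",
                site$site_id, cov$area_km2))
  }
  rec <- site_records(site, species = cfg$species)
  if (nrow(rec) == 0L) {
    warning(sprintf("site %s: no %s records; density is 0",
                    site$site_id, cfg$species))
  }
  cl <- cluster_records(rec, threshold = cfg$integration_threshold_m)
  for (i in seq_len(nrow(cl$summary))) {
    log(sprintf("site %s: cluster %d: %d member(s), centroid (%.1f, %.1f), diameter %.0f m",
                site$site_id, i, cl$summary$n_members[i], cl$summary$x[i],
                cl$summary$y[i], cl$summary$diameter_m[i]))
  }
  sa <- overall_survey_area(cov, cl$summary, r = cfg$buffer_centroid_m)
  log(sprintf("site %s: %d group(s), overall survey area %.4f km2",
              site$site_id, count_groups(cl), sa$area_km2))
  est <- site_density(count_groups(cl), sa, site_id = site$site_id,
                      species = cfg$species,
                      group_size = site$group_size %||% cfg$group_size,
                      hd = site$landscape$HD %||% NA_real_)
  attr(est, "city") <- site$city
  if (!is.null(cfg$outdir)) {
    export_geometry_geojson(cov, sa, cfg$outdir, prefix = site$site_id)
    export_clusters(cl,
                    csv = file.path(cfg$outdir, paste0(site$site_id, "_clusters.csv")),
                    geojson = file.path(cfg$outdir, paste0(site$site_id, "_centroids.geojson")))
  }
  est
}

#' Run the full estimation pipeline
#'
#' Executes load -> validate -> coverage -> pocket integration -> record
#' integration -> survey area -> density for every configured site, then
#' city aggregation and (when more than one site succeeds) the national
#' extrapolation. Failing sites do not abort a multi-site run; they are
#' returned as failure records.
#'
#' @param cfg a [run_config()].
#' @return list(estimates = data.frame per successful site, city_summary,
#'   national (`national_extrapolation` or NULL), failures = data.frame,
#'   log = character vector of audit lines).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$outdir)) dir.create(cfg$outdir, showWarnings = FALSE,
                                       recursive = TRUE)
  lines <- character(0)
  log <- function(msg) lines[[length(lines) + 1L]] <<- msg

  ests <- list(); fails <- list()
  for (spec in cfg$sites) {
    res <- tryCatch(run_one_site(spec, cfg, log),
                    carnidens_error = function(e) e)
    if (inherits(res, "carnidens_error")) {
      id <- spec$config$site_id %||% "?"
      log(sprintf("site %s: FAILED (%s): %s", id, class(res)[1],
                  conditionMessage(res)))
      fails[[length(fails) + 1L]] <- data.frame(
        site_id = id, error = class(res)[1],
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      ests[[length(ests) + 1L]] <- res
    }
  }
  if (length(ests) == 0L && length(fails) > 0L) {
    degenerate_error(paste0("no site could be analysed: ",
                            fails[[1]]$message))
  }

  edf <- as_estimates_df(ests)
  city <- if (!anyNA(edf$city)) aggregate_city(edf) else NULL
  national <- NULL
  if (!is.null(city) && nrow(city) >= 2L) {
    s <- summarize_mean_se(city$mean_group_density)
    national <- national_extrapolation(s$mean, s$se, cfg$suburban_land_km2)
  }
  if (!is.null(cfg$outdir)) {
    write.csv(edf, file.path(cfg$outdir, "site_estimates.csv"),
              row.names = FALSE)
    if (!is.null(city)) write.csv(city, file.path(cfg$outdir, "city_summary.csv"),
                                  row.names = FALSE)
    if (!is.null(national)) jsonlite::write_json(
      unclass(national), file.path(cfg$outdir, "national_summary.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(lines, file.path(cfg$outdir, "run.log"))
  }
  list(estimates = edf, city_summary = city, national = national,
       failures = if (length(fails)) do.call(rbind, fails) else NULL,
       log = lines)
}
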