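## Integration-distance sensitivity analysis: rerun clustering, survey-area
## construction and density across a sweep of thresholds. Because
## rendezvous-site spacing and inter-sett distances vary between cities, the
## robustness of the density estimate to the integration distance should be
## examined wherever the method is applied.

#' Sweep the record-integration distance
#'
#' Re-runs [cluster_records()], [overall_survey_area()] and [site_density()]
#' at each threshold. By default the survey area is recomputed per threshold
#' (centroid buffers move with the clustering, as in the full method);
#' `freeze_area` keeps the area fixed at the reference threshold's value to
#' isolate the pure clustering effect.
#'
#' @param site a validated `site_survey` (or data.frame of records when
#'   `coverage` is supplied directly).
#' @param thresholds ascending positive integration distances, meters.
#' @param coverage optional precomputed pocket-integrated `coverage_area`
#'   (computed once from the site otherwise).
#' @param centroid_buffer_m buffer radius added around centroids.
#' @param freeze_area if TRUE, use the survey area at `reference_threshold`
#'   for every row.
#' @param reference_threshold threshold whose area is used when freezing.
#' @param species optional species filter for the site's records.
#' @return data.frame (`sweep_table`): threshold, n_groups, survey_area_km2,
#'   group_density; one row per threshold.
#' @export
integration_sweep <- function(site, thresholds = seq(50, 400, by = 25),
                              coverage = NULL, centroid_buffer_m = 200,
                              freeze_area = FALSE, reference_threshold = 200,
                              species = NULL) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  if (inherits(site, "site_survey")) {
    if (is.null(coverage)) {
      cov <- respondent_coverage(site)
      coverage <- integrate_pockets(cov, site$greenspaces)
    }
    records <- site_records(site, species = species)
  } else {
    if (is.null(coverage)) validation_error("supply a coverage when 'site' is a bare record table")
    records <- as.data.frame(site)
  }

  frozen_area <- NULL
  if (freeze_area) {
    cl <- cluster_records(records, threshold = reference_threshold)
    frozen_area <- overall_survey_area(coverage, cl$summary,
                                       r = centroid_buffer_m)$area_km2
  }

  rows <- lapply(thresholds, function(th) {
    cl <- cluster_records(records, threshold = th)
    area <- if (freeze_area) frozen_area else
      overall_survey_area(coverage, cl$summary, r = centroid_buffer_m)$area_km2
    data.frame(threshold = th, n_groups = count_groups(cl),
               survey_area_km2 = area,
               group_density = count_groups(cl) / area)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}
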