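## Density estimation: group counts + survey areas -> relative group density
## (FGD/BGD), individual density, houses per group, city summaries and the
## national suburban extrapolation.

#' Per-site group density
#'
#' Relative group density is the number of independent social-group
#' centroids divided by the overall survey area.
#'
#' @param n_groups integer group count (>= 0).
#' @param area a `survey_area`/`coverage_area`, or a positive area in km^2.
#' @param site_id,species,group_size,hd optional metadata: site label,
#'   species, mean social-group size (animals per group; fox 3.4, badger 5.5
#'   are the conventional values) and housing density (houses km^-2). When
#'   supplied, individual density and houses per group are filled in.
#' @return a `density_estimate`: site_id, species, n_groups,
#'   survey_area_km2, group_density (groups km^-2, full precision),
#'   individual_density, houses_per_group.
#' @export
site_density <- function(n_groups, area, site_id = NA_character_,
                         species = NA_character_, group_size = NA_real_,
                         hd = NA_real_) {
  area_km2 <- if (inherits(area, "coverage_area")) area$area_km2 else as.numeric(area)
  if (!is.finite(area_km2) || area_km2 <= 0) {
    degenerate_error("survey area must be positive to form a density")
  }
  stopifnot(n_groups >= 0)
  gd <- n_groups / area_km2
  structure(list(
    site_id = site_id, species = species, n_groups = as.integer(n_groups),
    survey_area_km2 = area_km2, group_density = gd,
    individual_density = if (is.na(group_size)) NA_real_ else individual_density(gd, group_size),
    houses_per_group = if (is.na(hd) || n_groups == 0) NA_real_ else
      houses_per_group(hd, area_km2, n_groups)
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate %s [%s]: %d groups / %.2f km2 = %.2f km-2>\n",
              x$site_id, x$species, x$n_groups, x$survey_area_km2,
              x$group_density))
  invisible(x)
}

#' Individual (total population) density from group density
#'
#' @param group_density groups km^-2.
#' @param group_size mean animals per social group.
#' @return animals km^-2 (full precision; report to 1 dp).
#' @export
individual_density <- function(group_density, group_size) {
  stopifnot(group_density >= 0, group_size >= 0)
  group_density * group_size
}

#' Houses per social group
#'
#' @param hd housing density, houses km^-2.
#' @param area_km2 survey area, km^2.
#' @param n_groups number of groups (>= 1; 0 groups -> NA).
#' @return houses per group.
#' @export
houses_per_group <- function(hd, area_km2, n_groups) {
  if (n_groups < 1) return(NA_real_)
  (hd * area_km2) / n_groups
}

#' Mean, standard error and normal-approximation 95% CI
#'
#' SE uses the sample SD (n-1 denominator) over sqrt(n); with a single value
#' the SE and CI are reported missing. The CI is a plain normal
#' approximation (mean +/- 1.96 SE) and labelled as such.
#'
#' @param values numeric vector (NAs dropped).
#' @return list(mean, se, ci95 = c(lo, hi), n).
#' @export
summarize_mean_se <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 1L) validation_error("no values to summarize")
  m <- mean(v)
  se <- if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else m + c(-1.96, 1.96) * se
  list(mean = m, se = se, ci95 = ci, n = length(v))
}

as_estimates_df <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(site_id = e$site_id, species = e$species,
               n_groups = e$n_groups, survey_area_km2 = e$survey_area_km2,
               group_density = e$group_density,
               individual_density = e$individual_density,
               houses_per_group = e$houses_per_group,
               city = attr(e, "city") %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' City-level summaries of site group densities
#'
#' @param estimates a list of `density_estimate`s (each carrying a `city`
#'   attribute) or a data.frame with columns `city` and `group_density`.
#' @return data.frame: city, n_sites, mean_group_density, se_group_density
#'   (SE missing for single-site cities), ordered by first appearance.
#' @export
aggregate_city <- function(estimates) {
  df <- as_estimates_df(estimates)
  stopifnot(all(c("city", "group_density") %in% names(df)))
  if (anyNA(df$city)) validation_error("every estimate must be tagged with a city")
  cities <- unique(df$city)
  out <- do.call(rbind, lapply(cities, function(ct) {
    v <- df$group_density[df$city == ct]
    s <- summarize_mean_se(v)
    data.frame(city = ct, n_sites = s$n, mean_group_density = s$mean,
               se_group_density = s$se, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' National extrapolation over suburban land cover
#'
#' Multiplies mean group density by the suburban land area of England
#' (default 9,116.4 km^2, i.e. 7% of 130,279 km^2). Following the printed
#' arithmetic convention, the mean density is rounded to 2 decimal places
#' before multiplication and the resulting group count to the nearest whole
#' group; the SE scales the same way.
#'
#' @param mean_density groups km^-2.
#' @param se_density its standard error (NA allowed).
#' @param land_km2 suburban land cover, km^2.
#' @return a `national_extrapolation`: list(mean_density, se_density,
#'   land_km2, n_groups_est, se_est).
#' @export
national_extrapolation <- function(mean_density, se_density = NA_real_,
                                   land_km2 = 9116.4) {
  stopifnot(mean_density >= 0, land_km2 >= 0)
  md <- round(mean_density, 2)
  se <- if (is.na(se_density)) NA_real_ else round(se_density, 2)
  structure(list(
    mean_density = md, se_density = se, land_km2 = land_km2,
    n_groups_est = round(md * land_km2),
    se_est = if (is.na(se)) NA_real_ else round(se * land_km2)
  ), class = "national_extrapolation")
}

#' @export
print.national_extrapolation <- function(x, ...) {
  cat(sprintf("<national extrapolation: %.2f km-2 x %.1f km2 = %d groups (SE %s)>\n",
              x$mean_density, x$land_km2, x$n_groups_est,
              ifelse(is.na(x$se_est), "NA", format(x$se_est))))
  invisible(x)
}
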