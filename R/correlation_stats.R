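## Correlation and collinearity screens: Spearman rank correlation between
## sightings density and group density, and the sequential VIF elimination
## used before mixed-model fitting.

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] (`method = "spearman"`, average ranks for
#' ties) that also reports sample size and degrees of freedom. Two df
#' conventions are emitted: `df_reported = n - 1` (the convention used in
#' the sightings-density comparison this package accompanies) and the
#' textbook `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list(rho, n, df_reported, df).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) validation_error("spearman_rho needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    validation_error("spearman_rho undefined for a constant vector")
  }
  list(rho = cor(x, y, method = "spearman"), n = n,
       df_reported = n - 1L, df = n - 2L)
}

vif_of <- function(j, dat) {
  r2 <- summary(lm(stats::reformulate(setdiff(names(dat), j), response = j),
                   data = dat))$r.squared
  if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Sequential variance-inflation-factor elimination
#'
#' For each remaining variable j, VIF_j = 1/(1 - R^2_j) where R^2_j comes
#' from the OLS regression (with intercept) of j on all other remaining
#' variables. The largest VIF at or above `threshold` is removed, and the
#' procedure repeats until all remaining VIFs are below it. Exactly
#' collinear variables get an infinite VIF and are removed first. Ties are
#' broken by column order (with a warning).
#'
#' @param design data.frame of candidate numeric predictors (columns are
#'   variables, rows are sites); needs >= 2 variables and more rows than
#'   variables at every step.
#' @param threshold acceptable-VIF bound (default 2.5).
#' @return a `vif_trace`: list with `steps` (data.frame variable, vif, in
#'   removal order) and `retained` (data.frame variable, vif — final VIFs,
#'   all below threshold).
#' @export
vif_eliminate <- function(design, threshold = 2.5) {
  dat <- as.data.frame(design)
  stopifnot(ncol(dat) >= 2L)
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    validation_error("all design columns must be numeric")
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  steps <- data.frame(variable = character(0), vif = numeric(0))
  repeat {
    if (ncol(dat) < 2L) break
    if (nrow(dat) <= ncol(dat)) {
      validation_error("need more rows than variables at each VIF step")
    }
    vifs <- vapply(names(dat), vif_of, numeric(1), dat = dat)
    if (all(vifs < threshold)) break
    top <- max(vifs)
    cand <- names(vifs)[vifs == top]
    if (length(cand) > 1L) {
      warning(sprintf("VIF tie (%s = %.4g); removing '%s' (column order)",
                      paste(cand, collapse = ", "), top, cand[1]))
    }
    drop <- cand[1]
    steps <- rbind(steps, data.frame(variable = drop, vif = unname(vifs[drop])))
    dat <- dat[, setdiff(names(dat), drop), drop = FALSE]
  }
  final <- if (ncol(dat) >= 2L) {
    vapply(names(dat), vif_of, numeric(1), dat = dat)
  } else setNames(rep(NA_real_, ncol(dat)), names(dat))
  structure(list(
    steps = steps,
    retained = data.frame(variable = names(final), vif = unname(final)),
    threshold = threshold
  ), class = "vif_trace")
}

#' @export
print.vif_trace <- function(x, ...) {
  cat(sprintf("<vif_trace: removed %d, retained %d (threshold %g)>\n",
              nrow(x$steps), nrow(x$retained), x$threshold))
  if (nrow(x$steps)) {
    cat("removed:", paste(sprintf("%s (%.3g)", x$steps$variable, x$steps$vif),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a mixed-model-ready site table
#'
#' One row per site with square-root-transformed group density and the
#' landscape covariates (green space GS, housing density HD, industrial IND,
#' made ground MG), colonisation status and city — ready for an external
#' GLMM fit with CITY as a random factor. Garden area (GA) is excluded by
#' default: it is eliminated by the VIF screen. Rows with missing metrics
#' are flagged, not dropped.
#'
#' @param sites data.frame with one row per site: columns `site_id`, `city`,
#'   `colonisation`, `group_density` (or `fgd`), and the landscape metrics
#'   `GS`, `GA`, `HD`, `IND`, `MG` where available.
#' @param exclude metric columns to leave out (default `"GA"`).
#' @param path optional CSV output path.
#' @return data.frame: site_id, sqrt_fgd, GS, HD, IND, MG, COLON, CITY,
#'   missing_metrics flag.
#' @export
export_model_table <- function(sites, exclude = "GA", path = NULL) {
  df <- as.data.frame(sites)
  gd <- df$group_density %||% df$fgd
  if (is.null(gd)) validation_error("sites need a group_density (or fgd) column")
  metrics <- setdiff(c("GS", "HD", "IND", "MG"), exclude)
  out <- data.frame(site_id = df$site_id, sqrt_fgd = sqrt(gd),
                    stringsAsFactors = FALSE)
  for (m in metrics) out[[m]] <- if (m %in% names(df)) df[[m]] else NA_real_
  out$COLON <- df$colonisation %||% NA_character_
  out$CITY <- df$city %||% NA_character_
  out$missing_metrics <- !complete.cases(out[, metrics, drop = FALSE])
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
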