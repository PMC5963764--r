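## Input model: site surveys, respondent returns, sighting records.

RECORD_TYPES <- c("fox_cub", "badger_sett_main", "badger_sett_other",
                  "badger_sighting")
SPECIES_OF_TYPE <- c(fox_cub = "fox", badger_sett_main = "badger",
                     badger_sett_other = "badger", badger_sighting = "badger")

#' Load a site survey from a point table, optional greenspace polygons and a
#' site configuration
#'
#' The point table holds one row per geocoded location with columns
#' `site_id`, `role` (`respondent` or `record`), `species`, `record_type`,
#' `x`, `y`, `year`, `source`. Coordinates must be projected meters
#' (e.g. a national grid); values that all lie within longitude/latitude
#' ranges are rejected with a CRS error, since every buffer distance in the
#' method is metric. Records from all years are pooled by default
#' (restrict with `config$years`); records at exactly identical coordinates
#' are de-duplicated (flagged, first kept).
#'
#' @param points path to a CSV file, or a data.frame, with the columns above.
#' @param polygons optional path to a GeoJSON FeatureCollection of greenspace
#'   polygons in the same planar system, each feature carrying a boolean
#'   `surveyed` property; or a list as returned by [read_greenspaces()].
#' @param config list (or path to a YAML file) of site metadata: `site_id`,
#'   `city`, `colonisation` (`recent`/`long_term`), `fsd`, `group_size`,
#'   `landscape` (named list `GS`, `GA`, `MG`, `IND`, `HD`), `years`
#'   (optional year filter).
#' @return a `site_survey` object.
#' @seealso [validate_returns()]
#' @export
load_site_survey <- function(points, polygons = NULL, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  df <- if (is.character(points)) {
    read.csv(points, stringsAsFactors = FALSE)
  } else as.data.frame(points)

  if (!all(c("x", "y") %in% names(df))) {
    format_error("point table must have coordinate columns 'x' and 'y'")
  }
  if (!"role" %in% names(df)) {
    format_error("point table must have a 'role' column (respondent/record)")
  }
  for (col in c("id", "species", "record_type", "year", "source")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (!"site_id" %in% names(df)) df$site_id <- config$site_id %||% "site"
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)

  bad_role <- !df$role %in% c("respondent", "record")
  if (any(bad_role)) {
    validation_error(sprintf("unknown role value(s): %s",
                             paste(unique(df$role[bad_role]), collapse = ", ")))
  }

  ## metric-CRS guard: a full table inside lon/lat ranges is almost surely
  ## unprojected
  fin <- is.finite(df$x) & is.finite(df$y)
  if (any(fin) && all(abs(df$x[fin]) <= 360) && all(abs(df$y[fin]) <= 90)) {
    crs_error(paste0("coordinates look like longitude/latitude; ",
                     "projected meters are required"))
  }

  resp <- df[df$role == "respondent", , drop = FALSE]
  rec <- df[df$role == "record", , drop = FALSE]

  if (nrow(resp) == 0L) {
    degenerate_error("site has no respondents")
  }
  if (nrow(rec) > 0L) {
    unknown <- !rec$record_type %in% RECORD_TYPES
    if (any(unknown)) {
      validation_error(sprintf("unknown record_type(s): %s",
                               paste(unique(rec$record_type[unknown]),
                                     collapse = ", ")))
    }
    implied <- SPECIES_OF_TYPE[rec$record_type]
    mism <- !is.na(rec$species) & rec$species != implied
    if (any(mism)) {
      validation_error(sprintf(
        "species/record_type mismatch in record(s): %s",
        paste(utils::head(rec$id[mism], 5), collapse = ", ")))
    }
    rec$species <- unname(implied)
    if (!is.null(config$years)) {
      rec <- rec[rec$year %in% config$years, , drop = FALSE]
    }
    ## pool years; de-duplicate exact coordinate matches within species
    key <- paste(rec$species, rec$x, rec$y)
    rec$dup <- duplicated(key)
  } else {
    rec$dup <- logical(0)
  }

  if (is.character(polygons)) polygons <- read_greenspaces(polygons)

  respondents <- data.frame(
    id = if (all(is.na(resp$id))) paste0("r", seq_len(nrow(resp))) else as.character(resp$id),
    x = resp$x, y = resp$y,
    valid = TRUE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    id = if (nrow(rec) == 0L) character(0) else if (all(is.na(rec$id)))
      paste0("s", seq_len(nrow(rec))) else as.character(rec$id),
    species = as.character(rec$species), record_type = as.character(rec$record_type),
    x = rec$x, y = rec$y, year = rec$year,
    source = as.character(rec$source), dup = rec$dup,
    stringsAsFactors = FALSE
  )

  structure(list(
    site_id = config$site_id %||% as.character(df$site_id[1]),
    city = config$city %||% NA_character_,
    colonisation = config$colonisation %||% NA_character_,
    respondents = respondents,
    records = records,
    greenspaces = polygons,
    fsd = config$fsd %||% NA_real_,
    landscape = config$landscape %||% NULL,
    group_size = config$group_size %||% NA_real_,
    validated = FALSE
  ), class = "site_survey")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.site_survey <- function(x, ...) {
  cat(sprintf("<site_survey '%s'%s: %d respondents (%d valid), %d records>\n",
              x$site_id,
              if (is.na(x$city)) "" else paste0(" [", x$city, "]"),
              nrow(x$respondents), sum(x$respondents$valid),
              nrow(x$records)))
  invisible(x)
}

#' Validate respondent returns
#'
#' Flags and excludes from geometry: returns with non-finite coordinates and
#' duplicated respondent ids (first kept). Respondents at identical
#' coordinates (e.g. flats at one address) are all retained for response-rate
#' reporting but only one enters the coverage geometry (`geom_use`).
#' Idempotent; errors if no valid respondent remains.
#'
#' @param site a `site_survey`.
#' @return the site with `respondents$valid`, `respondents$reason` and
#'   `respondents$geom_use` populated and `validated = TRUE`.
#' @export
validate_returns <- function(site) {
  stopifnot(inherits(site, "site_survey"))
  r <- site$respondents
  r$valid <- TRUE; r$reason <- NA_character_
  bad <- !(is.finite(r$x) & is.finite(r$y))
  r$valid[bad] <- FALSE; r$reason[bad] <- "nonfinite_coord"
  dup <- duplicated(r$id)
  r$valid[dup] <- FALSE; r$reason[dup & !bad] <- "duplicate_id"
  if (!any(r$valid)) degenerate_error("all respondent returns invalid")
  r$geom_use <- r$valid & !duplicated(paste(r$x, r$y)) & !is.na(r$x)
  n_excl <- sum(!r$valid)
  if (n_excl > 0) {
    message(sprintf("validate_returns: %d of %d returns excluded", n_excl, nrow(r)))
  }
  site$respondents <- r
  site$validated <- TRUE
  site
}

#' Valid respondent locations of a site
#' @param site a validated `site_survey`.
#' @param geometry if TRUE (default) return only one respondent per distinct
#'   coordinate, as used for coverage geometry.
#' @return data.frame with columns id, x, y.
#' @export
valid_respondents <- function(site, geometry = TRUE) {
  if (!isTRUE(site$validated)) site <- validate_returns(site)
  r <- site$respondents
  r[if (geometry) r$geom_use else r$valid, c("id", "x", "y"), drop = FALSE]
}

#' Pooled, de-duplicated sighting records of a site
#' @param site a `site_survey`.
#' @param species optional filter (`"fox"` or `"badger"`).
#' @return data.frame of records (exact-coordinate duplicates removed).
#' @export
site_records <- function(site, species = NULL) {
  rec <- site$records[!site$records$dup, , drop = FALSE]
  if (!is.null(species)) rec <- rec[rec$species == species, , drop = FALSE]
  rec
}

#' Write a site's point table back to CSV
#'
#' Inverse of [load_site_survey()] for valid rows; coordinates round-trip
#' to better than 1e-6 m.
#' @param site a `site_survey`.
#' @param path output CSV path.
#' @export
write_points_csv <- function(site, path) {
  r <- site$respondents
  resp <- data.frame(site_id = site$site_id, role = "respondent", id = r$id,
                     species = NA, record_type = NA, x = r$x, y = r$y,
                     year = NA, source = NA, stringsAsFactors = FALSE)
  k <- site$records
  rec <- data.frame(site_id = site$site_id, role = "record", id = k$id,
                    species = k$species, record_type = k$record_type,
                    x = k$x, y = k$y, year = k$year, source = k$source,
                    stringsAsFactors = FALSE)
  write.csv(rbind(resp, rec), path, row.names = FALSE)
  invisible(path)
}
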