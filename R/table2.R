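## Bundled study-site results table.

#' Study-site results table (14 suburban fox sites, 8 towns/cities)
#'
#' Per-site survey area, questionnaire response, landscape composition,
#' relative fox group density (FGD) and, for the three Brighton badger
#' sites, badger group density (BGD), as published for the 2013-2015
#' suburban surveys. The `n_fox_groups` column is back-derived
#' (`fgd * area_km2` rounds to an exact integer at every site) and lets the
#' density operations re-derive the printed densities; per-site industrial
#' (IND) and made-ground (MG) metrics were not published and are NA.
#'
#' @return data.frame with one row per site; see the fixture header for
#'   column definitions.
#' @export
table2_sites <- function() {
  path <- system.file("extdata", "table2_sites.csv", package = "carnidens",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Nominal number of questionnaires distributed across all fox sites
#' @return integer (about 30,000).
#' @export
questionnaires_distributed <- function() 30000L

#' City-level (FSD, mean FGD) pairs
#'
#' One row per town/city: the national fox-sightings density (FSD, sightings
#' per 1000 people km^-2) and the city mean FGD, computed from the site
#' table with [aggregate_city()] and rounded to the 2 dp reporting
#' precision.
#'
#' @return data.frame: city, fsd, mean_fgd.
#' @export
table2_city_pairs <- function() {
  t2 <- table2_sites()
  cs <- aggregate_city(data.frame(city = t2$city, group_density = t2$fgd))
  fsd <- vapply(cs$city, function(ct) t2$fsd[t2$city == ct][1], numeric(1))
  data.frame(city = cs$city, fsd = unname(fsd),
             mean_fgd = round(cs$mean_group_density, 2),
             stringsAsFactors = FALSE)
}
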