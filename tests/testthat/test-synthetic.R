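test_that("fixed-count generation honours the spacing contract", {
  cfg <- simulation_config(n_groups = 4, min_spacing = 300, seed = 3)
  tr <- generate_territories(cfg)
  expect_equal(tr$n_groups, 4)
  expect_gte(min(dist(tr$centers)), 300)
  expect_equal(tr$true_density, 4)
})

test_that("generation is deterministic in the seed", {
  cfg <- simulation_config(seed = 99)
  a <- generate_territories(cfg)
  b <- generate_territories(cfg)
  expect_identical(a$centers, b$centers)
  expect_identical(a$activity_sites, b$activity_sites)
  expect_identical(a$households, b$households)
  sa <- suppressMessages(simulate_survey(a))
  sb <- suppressMessages(simulate_survey(b))
  expect_identical(sa$respondents, sb$respondents)
  c2 <- generate_territories(simulation_config(seed = 100))
  expect_false(identical(a$centers, c2$centers))
})

test_that("voronoi territories partition the window", {
  cfg <- simulation_config(n_groups = 6, min_spacing = 250, seed = 12)
  tr <- generate_territories(cfg)
  areas <- vapply(tr$territories, function(t)
    abs(carnidens:::ring_signed_area(t)), numeric(1))
  expect_equal(sum(areas), 1e6, tolerance = 1e-6)
  expect_length(tr$territories, 6)
})

test_that("activity sites stay within the scatter radius; badger mode marks the main sett", {
  cfg <- simulation_config(n_groups = 5, min_spacing = 250, species = "badger",
                           seed = 6)
  tr <- generate_territories(cfg)
  expect_equal(cfg$site_scatter, 150)
  as <- tr$activity_sites
  d <- sqrt((as$x - tr$centers$x[as$group])^2 + (as$y - tr$centers$y[as$group])^2)
  expect_true(all(d <= 150 + 1e-9))
  firsts <- as[as$site == 1, ]
  expect_true(all(firsts$record_type == "badger_sett_main"))
  expect_true(all(as$record_type[as$site > 1] == "badger_sett_other"))
})

test_that("infeasible spacing raises a generation error", {
  cfg <- simulation_config(n_groups = 50, min_spacing = 400, seed = 1)
  expect_error(generate_territories(cfg), class = "carnidens_generation_error")
})

test_that("zero response surfaces the degenerate-site error", {
  cfg <- simulation_config(n_groups = 3, response_rate = 0, seed = 4)
  tr <- generate_territories(cfg)
  expect_error(simulate_survey(tr), class = "carnidens_degenerate_error")
})

test_that("full response and global detection report every activity site", {
  cfg <- simulation_config(window = c(0, 800, 0, 800), n_groups = 2,
                           min_spacing = 250, site_scatter = 100,
                           housing_density = 500,
                           response_rate = 1, detection_radius = 2000, seed = 8)
  tr <- generate_territories(cfg)
  svy <- suppressMessages(simulate_survey(tr))
  expect_equal(nrow(svy$respondents), nrow(tr$households))
  expect_equal(nrow(svy$records), nrow(tr$activity_sites))
})

test_that("respondent counts are binomial in the response rate", {
  cfg <- simulation_config(window = c(0, 500, 0, 500), n_groups = 1,
                           housing_density = 800, response_rate = 0.19)
  tr <- generate_territories(cfg)
  nh <- nrow(tr$households)
  counts <- vapply(1:200, function(s) {
    c2 <- cfg; c2$seed <- 1000L + s
    t2 <- generate_territories(c2)
    attr(suppressMessages(simulate_survey(t2, c2)), "n_respondents")
  }, numeric(1))
  mu <- nh * 0.19
  sd3 <- 3 * sqrt(nh * 0.19 * 0.81 / 200)
  expect_lt(abs(mean(counts) - mu), sd3)
})

test_that("no merging occurs when spacing exceeds twice the scatter plus the threshold", {
  ## provable condition: inter-record distance across groups is at least
  ## min_spacing - 2*scatter > threshold, so single linkage cannot chain
  ok <- vapply(1:50, function(s) {
    cfg <- simulation_config(n_groups = 3, min_spacing = 450,
                             site_scatter = 100, response_rate = 1,
                             housing_density = 1500, seed = 3000L + s)
    tr <- generate_territories(cfg)
    svy <- suppressMessages(simulate_survey(tr, cfg))
    est <- suppressMessages(estimate_from_survey(svy, threshold = 200,
                                                 pockets = FALSE))
    est$n_groups == tr$n_groups
  }, logical(1))
  expect_true(all(ok))
})

test_that("a truth without groups estimates zero density", {
  cfg <- simulation_config(n_groups = 0, response_rate = 0.3, seed = 2)
  r <- suppressMessages(recovery_experiment(cfg, n_reps = 3))
  expect_true(all(r$est_density == 0))
  expect_true(all(r$est_n == 0))
})

test_that("count recovery does not degrade as response rate rises", {
  frac <- vapply(c(0.05, 0.4), function(rate) {
    cfg <- simulation_config(n_groups = 3, min_spacing = 450,
                             site_scatter = 100, response_rate = rate,
                             housing_density = 2000, seed = 77)
    attr(suppressMessages(recovery_experiment(cfg, n_reps = 30,
                                              pockets = FALSE)),
         "exact_fraction")
  }, numeric(1))
  expect_gte(frac[2], frac[1])
  expect_gte(frac[2], 0.9)
})

test_that("synthetic fixtures re-run identically through the file pipeline", {
  cfg <- simulation_config(n_groups = 3, min_spacing = 400, seed = 31,
                           response_rate = 0.35)
  tr <- generate_territories(cfg)
  svy <- suppressMessages(simulate_survey(tr, cfg))
  dir <- withr::local_tempdir()
  write_synthetic_fixture(tr, svy, dir, prefix = "fx")
  direct <- suppressMessages(estimate_from_survey(svy))
  s2 <- validate_returns(load_site_survey(file.path(dir, "fx_points.csv")))
  refiled <- suppressMessages(estimate_from_survey(s2))
  expect_equal(refiled$n_groups, direct$n_groups)
  expect_equal(refiled$group_density, direct$group_density, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "fx_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$n_groups, tr$n_groups)
})
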