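test_that("spearman_rho matches the exact rank formula on the city pairs", {
  fsd <- c(703.1, 37.8, 72.4, 13.2, 51.2, 14.6, 36.6, 4.0)
  fgd <- c(3.11, 3.53, 4.35, 3.91, 3.24, 4.15, 4.73, 2.76)
  s <- spearman_rho(fsd, fgd)
  d2 <- sum((rank(fsd) - rank(fgd))^2)
  expect_equal(d2, 80)
  expect_equal(s$rho, 1 - 6 * d2 / (8 * (64 - 1)))
  expect_equal(round(s$rho, 3), 0.048)
  expect_equal(s$n, 8)
  expect_equal(s$df_reported, 7)
  expect_equal(s$df, 6)
})

test_that("spearman_rho hits the exact limits and rejects degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x)$rho, 1.0)
  expect_equal(spearman_rho(x, -x)$rho, -1.0)
  expect_error(spearman_rho(rep(1, 5), x[1:5]),
               class = "carnidens_validation_error")
  expect_error(spearman_rho(1:2, 2:1), class = "carnidens_validation_error")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rlnorm(20); y <- runif(20)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base)
  expect_equal(spearman_rho(x, y^3 + 2 * y)$rho, base)
  expect_equal(spearman_rho(log(x), rank(y))$rho, base)
})

test_that("vif_eliminate leaves orthogonal designs alone", {
  x <- c(1, 1, -1, -1, 0, 0)
  y <- c(1, -1, 0, 0, 1, -1)
  tr <- vif_eliminate(data.frame(a = x, b = y))
  expect_equal(nrow(tr$steps), 0)
  expect_equal(tr$retained$vif, c(1, 1))
})

test_that("an exactly duplicated variable has infinite VIF and goes first", {
  set.seed(8)
  d <- data.frame(a = rnorm(12), b = rnorm(12))
  d$c <- d$a
  tr <- suppressWarnings(vif_eliminate(d))
  expect_equal(tr$steps$variable[1], "a")  # tie with c, column order
  expect_true(is.infinite(tr$steps$vif[1]))
  expect_true(all(tr$retained$vif < 2.5))
})

test_that("near-collinear variables are removed and VIFs match the car oracle", {
  skip_if_not_installed("car")
  set.seed(42)
  n <- 30
  d <- data.frame(x = rnorm(n), y = rnorm(n))
  d$z <- d$x + d$y + rnorm(n, sd = 0.05)
  own <- vapply(names(d), carnidens:::vif_of, numeric(1), dat = d)
  resp <- rnorm(n)
  oracle <- car::vif(lm(resp ~ x + y + z, data = d))
  expect_equal(unname(own[c("x", "y", "z")]),
               unname(oracle[c("x", "y", "z")]), tolerance = 1e-8)
  tr <- vif_eliminate(d)
  expect_equal(tr$steps$variable[1], names(which.max(own)))
  expect_true(all(tr$retained$vif < 2.5))
  expect_lte(nrow(tr$steps), ncol(d) - 1)
})

test_that("retained set is unchanged by column order (no ties)", {
  set.seed(9)
  n <- 40
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$c <- 2 * d$a - d$b + rnorm(n, sd = 0.1)
  d$e <- rnorm(n)
  r1 <- vif_eliminate(d)
  r2 <- vif_eliminate(d[, c("e", "c", "a", "b")])
  expect_setequal(r1$retained$variable, r2$retained$variable)
})

test_that("export_model_table prepares the GLMM input with GA excluded", {
  t2 <- table2_sites()
  sites <- data.frame(site_id = t2$site_id, city = t2$city,
                      colonisation = t2$colonisation, group_density = t2$fgd,
                      GS = t2$GS, GA = t2$GA, HD = t2$HD,
                      IND = t2$IND, MG = t2$MG)
  mt <- export_model_table(sites)
  expect_equal(nrow(mt), 14)
  expect_equal(length(unique(mt$CITY)), 8)
  expect_false("GA" %in% names(mt))
  expect_equal(mt$sqrt_fgd, sqrt(t2$fgd))
  expect_true(all(mt$missing_metrics))  # IND/MG unpublished per site
  mt4 <- export_model_table(data.frame(site_id = "s", city = "c",
                                       colonisation = "recent",
                                       group_density = 4.0, GS = 0.2,
                                       HD = 2000, IND = 0.1, MG = 0.3))
  expect_equal(mt4$sqrt_fgd, 2.0)
  expect_false(mt4$missing_metrics)
})
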