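test_that("respondent buffers match closed-form disc areas", {
  one <- respondent_coverage(data.frame(x = 0, y = 0), r = 50)
  expect_equal(one$area_km2 * 1e6, pi * 50^2, tolerance = 0.01)

  near <- respondent_coverage(data.frame(x = c(0, 60), y = c(0, 0)), r = 50)
  expect_length(near$geometry, 1)  # 60 m < 2r: connected

  far <- respondent_coverage(data.frame(x = c(0, 200), y = c(0, 0)), r = 50)
  expect_length(far$geometry, 2)
  expect_equal(far$area_km2 * 1e6, 2 * pi * 50^2, tolerance = 0.01)
})

test_that("polygon_area_km2 is the shoelace area with holes subtracted", {
  expect_equal(polygon_area_km2(square_polyset(1000)), 1.0)

  holed <- polyset(list(
    list(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)),
    list(x = c(450, 450, 550, 550), y = c(450, 550, 550, 450))  # 100x100 hole (cw)
  ))
  expect_equal(polygon_area_km2(holed), 0.99)

  disc <- disc_polygon(0, 0, 200)
  expect_equal(polygon_area_km2(disc), pi * 0.2^2, tolerance = 0.01)

  bowtie <- polyset(list(list(x = c(0, 100, 0, 100), y = c(0, 100, 100, 0))))
  expect_error(polygon_area_km2(bowtie), class = "carnidens_geometry_error")
})

test_that("tiled disc union agrees with a single boolean union", {
  set.seed(11)
  x <- runif(300, 0, 800); y <- runif(300, 0, 800)
  tiled <- carnidens:::discs_union(x, y, 50)
  direct <- carnidens:::ps_union(
    lapply(seq_along(x), function(i) disc_polygon(x[i], y[i], 50)[[1]]))
  expect_equal(carnidens:::polyset_area_m2(tiled),
               carnidens:::polyset_area_m2(direct), tolerance = 1e-6)
})

test_that("coverage area is monotone in respondents", {
  set.seed(21)
  pts <- data.frame(x = runif(40, 0, 600), y = runif(40, 0, 600))
  areas <- vapply(seq(5, 40, 5), function(n)
    respondent_coverage(pts[1:n, ], r = 50)$area_km2, numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("a fully enclosed hole is integrated (edge fraction 1)", {
  cov <- respondent_coverage(ring_respondents(12, 120), r = 50)
  out <- integrate_pockets(cov)
  pk <- attr(out, "pockets")
  holes <- pk[pk$kind == "hole", ]
  expect_equal(nrow(holes), 1)
  expect_equal(holes$fraction, 1.0)
  expect_true(holes$accepted)
  expect_gt(out$area_km2, cov$area_km2)
  # filled output has no interior ring left
  expect_true(all(vapply(out$geometry, carnidens:::ring_signed_area,
                         numeric(1)) > 0))
})

test_that("a pocket with a wide-open mouth is rejected", {
  # open channel: mouth is a large share of the pocket perimeter
  cov <- respondent_coverage(u_respondents(width = 300, depth = 160), r = 50)
  out <- integrate_pockets(cov)
  pk <- attr(out, "pockets")
  big <- pk[pk$area_m2 > 5000, ]
  expect_equal(nrow(big), 1)
  expect_lt(big$fraction, 0.75)
  expect_false(big$accepted)
})

test_that("convex-ish arrangements produce no accepted large pockets (identity)", {
  cov <- respondent_coverage(data.frame(x = c(0, 60, 120), y = c(0, 0, 0)), r = 50)
  out <- integrate_pockets(cov)
  expect_equal(out$area_km2, cov$area_km2, tolerance = 1e-3)
})

test_that("pocket integration never shrinks the coverage and output stays valid", {
  set.seed(31)
  for (k in 1:5) {
    pts <- data.frame(x = runif(25, 0, 500), y = runif(25, 0, 500))
    cov <- respondent_coverage(pts, r = 50)
    out <- integrate_pockets(cov)
    expect_gte(out$area_km2, cov$area_km2 - 1e-12)
    expect_equal(polygon_area_km2(out$geometry), out$area_km2, tolerance = 1e-9)
  }
})

test_that("surveyed greenspace counts toward pocket edge coverage", {
  # channel whose mouth is plugged by a surveyed greenspace polygon
  resp <- u_respondents(width = 300, depth = 160)
  cov <- respondent_coverage(resp, r = 50)
  plug <- polyset(list(list(x = c(-20, 320, 320, -20), y = c(150, 150, 260, 260))))
  out_plug <- integrate_pockets(cov, greenspaces = plug)
  pk <- attr(out_plug, "pockets")
  expect_true(all(pk$accepted[pk$area_m2 > 5000]))
})

test_that("overall survey area unions centroid buffers with the coverage", {
  sq <- structure(list(geometry = square_polyset(1000), area_km2 = 1),
                  class = "coverage_area")
  inside <- overall_survey_area(sq, data.frame(x = 500, y = 500), r = 200)
  expect_equal(inside$area_km2, 1.0)

  none <- overall_survey_area(sq, NULL, r = 200)
  expect_equal(none$area_km2, 1.0)

  outside <- overall_survey_area(sq, data.frame(x = 1300, y = 500), r = 200)
  expect_gt(outside$area_km2, 1.0)
  expect_lte(outside$area_km2, 1.0 + pi * 0.2^2)

  # monotone in centroids
  both <- overall_survey_area(sq, data.frame(x = c(1300, 500), y = c(500, -100)),
                              r = 200)
  expect_gte(both$area_km2, outside$area_km2)
})

test_that("geojson polygon layers round-trip", {
  ring <- ring_respondents(12, 120)
  cov <- integrate_pockets(respondent_coverage(ring, r = 50))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(list(list(geometry = cov$geometry,
                          properties = list(surveyed = TRUE))), f)
  back <- read_greenspaces(f)
  expect_equal(polygon_area_km2(back$surveyed), cov$area_km2, tolerance = 1e-9)
})
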