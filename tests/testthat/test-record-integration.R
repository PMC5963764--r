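test_that("chained records integrate into one centroid", {
  cl <- cluster_records(data.frame(x = c(0, 150, 300), y = c(0, 0, 0),
                                   species = "fox"), threshold = 200)
  expect_equal(count_groups(cl), 1)
  expect_equal(cl$summary$x, 150)
  expect_equal(cl$summary$y, 0)
  expect_equal(cl$summary$diameter_m, 300)
})

test_that("separation at or beyond the threshold keeps records apart (strict <)", {
  expect_equal(count_groups(cluster_records(
    data.frame(x = c(0, 250), y = c(0, 0)), 200)), 2)
  expect_equal(count_groups(cluster_records(
    data.frame(x = c(0, 200), y = c(0, 0)), 200)), 2)  # exactly 200 m
  expect_equal(count_groups(cluster_records(
    data.frame(x = c(0, 199.999), y = c(0, 0)), 200)), 1)
})

test_that("centroids are member means and empty input gives zero groups", {
  cl <- cluster_records(data.frame(x = c(10, 20, 600), y = c(0, 40, 600)), 200)
  expect_equal(count_groups(cl), 2)
  expect_equal(sort(cl$summary$x), sort(c(mean(c(10, 20)), 600)))
  empty <- cluster_records(data.frame(x = numeric(0), y = numeric(0)), 200)
  expect_equal(count_groups(empty), 0)
})

test_that("mixed-species record sets are a validation error", {
  df <- data.frame(x = c(0, 10), y = c(0, 0), species = c("fox", "badger"))
  expect_error(cluster_records(df), class = "carnidens_validation_error")
})

test_that("partition matches the brute-force BFS oracle on random instances", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(5:120, 1)
    df <- data.frame(x = runif(n, 0, 1200), y = runif(n, 0, 1200))
    thr <- sample(c(100, 150, 200, 300), 1)
    cl <- suppressMessages(cluster_records(df, thr))
    oracle <- bfs_components(df$x, df$y, thr)
    expect_identical(canon_partition(cl$assignment), canon_partition(oracle))
    # single-linkage separation: different clusters are >= thr apart
    if (count_groups(cl) > 1) {
      d <- as.matrix(dist(df))
      sep <- d[outer(cl$assignment, cl$assignment, "!=")]
      expect_gte(min(sep), thr)
    }
  }
})

test_that("the partition is invariant to record order", {
  set.seed(7)
  df <- data.frame(x = runif(60, 0, 800), y = runif(60, 0, 800),
                   id = sprintf("k%02d", 1:60))
  cl1 <- suppressMessages(cluster_records(df, 200))
  perm <- sample(60)
  cl2 <- suppressMessages(cluster_records(df[perm, ], 200))
  m1 <- lapply(canon_partition(cl1$assignment), function(ix) sort(df$id[ix]))
  m2 <- lapply(canon_partition(cl2$assignment), function(ix) sort(df$id[perm][ix]))
  expect_identical(sort(vapply(m1, paste, "", collapse = ",")),
                   sort(vapply(m2, paste, "", collapse = ",")))
})

test_that("cluster count is non-increasing in threshold with correct limits", {
  set.seed(13)
  df <- data.frame(x = runif(50, 0, 1000), y = runif(50, 0, 1000))
  thrs <- c(1e-6, seq(25, 1500, 25), 5000)
  counts <- vapply(thrs, function(t)
    count_groups(suppressMessages(cluster_records(df, t))), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], nrow(unique(df)))
  expect_equal(counts[length(counts)], 1)
})

test_that("badger sett types cluster together and main-sett identity is kept", {
  df <- data.frame(x = c(0, 100, 120), y = c(0, 0, 50),
                   species = "badger",
                   record_type = c("badger_sett_main", "badger_sett_other",
                                   "badger_sighting"))
  cl <- cluster_records(df, 200)
  expect_equal(count_groups(cl), 1)
  expect_true(cl$summary$has_main_sett)
})
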