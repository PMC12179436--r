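test_that("descriptive summaries report median, IQR and correlations", {
  tt <- make_tracts(5, occ_contaminants = c(1L, 2L, 3L, 4L, 5L),
                    env_pm25 = c(1, 2, 3, 4, 5),
                    env_diesel = c(2, 4, 6, 8, 10))
  d <- suppressWarnings(describe_exposures(tt))
  row <- d$summary[d$summary$indicator == "occ_contaminants", ]
  expect_equal(row$median, 3)
  expect_equal(c(row$q25, row$q75), c(2, 4))
  expect_equal(c(row$min, row$max), c(1, 5))
  # x vs 2x correlates perfectly
  expect_equal(d$correlation["env_pm25", "env_diesel"], 1)
})

test_that("constant indicators yield missing correlations with a warning", {
  tt <- make_tracts(5, env_pm25 = c(1, 2, 3, 4, 5))  # others constant
  expect_warning(d <- describe_exposures(tt), "constant")
  expect_true(is.na(d$correlation["env_ozone", "env_pm25"]))
  expect_equal(d$correlation["env_pm25", "env_pm25"], 1)
})

test_that("constant exposure gives the diagonal inequality curve", {
  tt <- make_tracts(8, env_pm25 = rep(4, 8),
                    population = as.integer(round(runif(8, 500, 5000))))
  res <- inequality_curve(tt, "env_pm25")
  expect_lt(abs(res$area_deviation), 1e-9)
  expect_equal(res$points$cum_pop_share, res$points$cum_exposure_share,
               tolerance = 1e-12)
})

test_that("fully concentrated exposure hugs zero then jumps to one", {
  tt <- make_tracts(6, pct_minority = c(10, 20, 30, 40, 50, 90),
                    env_traffic = c(0, 0, 0, 0, 0, 5000))
  res <- inequality_curve(tt, "env_traffic")
  n <- nrow(res$points)
  expect_equal(res$points$cum_exposure_share[n - 1], 0)
  expect_equal(res$points$cum_exposure_share[n], 1)
  expect_gt(res$area_deviation, 0)
  tt0 <- make_tracts(4, env_traffic = rep(0, 4))
  expect_error(inequality_curve(tt0, "env_traffic"), "zero")
})

test_that("area deviation matches an independent trapezoid oracle", {
  skip_if_not_installed("pracma")
  set.seed(5)
  tt <- make_tracts(40,
                    pct_minority = runif(40, 0, 100),
                    env_diesel = runif(40, 0.05, 0.9),
                    population = as.integer(round(runif(40, 500, 6000))))
  res <- inequality_curve(tt, "env_diesel")
  x <- res$points$cum_pop_share; y <- res$points$cum_exposure_share
  expect_lt(abs(res$area_deviation - pracma::trapz(x, x - y)), 1e-9)
})

test_that("three separated blobs select k = 3 with accurate labels", {
  g <- simulate_tracts(blob_config(61))
  cl <- cluster_exposures(g$tracts, k_range = 2:6, seed = 61)
  expect_equal(cl$k, 3)
  expect_gt(perm_accuracy(cl$labels, g$truth$cluster_labels), 0.95)
  # relabelling orders clusters by mean normalized exposure
  expect_true(all(diff(rowMeans(cl$centroids)) > 0))
  # profile rows are raw-unit means
  expect_equal(cl$profile["3", "env_traffic"],
               mean(exposure_matrix(g$tracts)[cl$labels == 3, "env_traffic"]))
})

test_that("cluster selection is invariant to duplicating every tract", {
  g <- simulate_tracts(blob_config(71, 8, 8))
  cl1 <- cluster_exposures(g$tracts, k_range = 2:5, seed = 3)
  dup <- as.data.frame(g$tracts)
  dup2 <- dup; dup2$tract_id <- paste0(dup2$tract_id, "_b")
  both <- validate_tract_table(rbind(dup, dup2))
  cl2 <- cluster_exposures(both, k_range = 2:5, seed = 3)
  expect_equal(cl2$k, cl1$k)
  # z-scaling uses the n-1 variance, so duplication rescales by a known
  # factor sqrt(2(n-1)/(2n-1)); compare centroids after undoing it
  f <- sqrt(2 * (nrow(dup) - 1) / (2 * nrow(dup) - 1))
  expect_equal(cl2$centroids * f, cl1$centroids, tolerance = 1e-6)
  expect_equal(cl2$labels, rep(cl1$labels, 2))
})

test_that("package silhouette agrees with the brute-force O(n^2) oracle", {
  g <- simulate_tracts(blob_config(81, 8, 8))   # 64 tracts <= 200
  cl <- cluster_exposures(g$tracts, k_range = 2:4, seed = 7)
  m <- exposure_matrix(g$tracts)
  z <- scale(m); z[, attr(z, "scaled:scale") == 0] <- 0
  oracle <- silhouette_oracle(z, cl$labels)
  expect_equal(unname(cl$silhouette_by_k[as.character(cl$k)]), oracle,
               tolerance = 1e-10)
})

test_that("normalization centres each indicator used for clustering", {
  g <- simulate_tracts(sim_config(n_rows = 7, n_cols = 7, seed = 91))
  cl <- cluster_exposures(g$tracts, k_range = 2:4, seed = 9)
  # size-weighted centroid average is the grand mean, i.e. 0 in z-units
  wmean <- colSums(cl$centroids * cl$sizes) / sum(cl$sizes)
  expect_true(all(abs(wmean) < 1e-9))
})

test_that("missing indicator values are rejected", {
  tt <- make_tracts(12)
  tt$env_pm25[3] <- NA
  expect_error(cluster_exposures(tt, k_range = 2:3), "missing")
})
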