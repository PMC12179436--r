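# small logistic DGP helper: 3 focal exposures, optional covariate effect
logistic_dgp <- function(n, beta, gamma = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(beta * (d$x1 + d$x2 + d$x3) + gamma * d$z))
  d
}

test_that("the odds ratio at the reference quantile is exactly one", {
  d <- logistic_dgp(300, 0.3, seed = 2)
  q <- fit_qgcomp(d, "y", c("x1", "x2", "x3"), covariates = "z",
                  n_boot = 3, pd = FALSE, seed = 5)
  expect_identical(q$joint$or[q$joint$quantile == 0.5], 1)
  expect_identical(q$joint$lo[q$joint$quantile == 0.5], 1)
  expect_identical(q$joint$hi[q$joint$quantile == 0.5], 1)
  expect_equal(nrow(q$joint), 9)
  expect_true(all(q$joint$lo <= q$joint$or & q$joint$or <= q$joint$hi))
})

test_that("point estimates are invariant to row permutation", {
  d <- logistic_dgp(250, 0.4, seed = 3)
  fit1 <- fit_qgcomp(d, "y", c("x1", "x2", "x3"), n_boot = 2,
                     subsample = 1, pd = FALSE, seed = 7)
  perm <- sample(nrow(d))
  fit2 <- fit_qgcomp(d[perm, ], "y", c("x1", "x2", "x3"), n_boot = 2,
                     subsample = 1, pd = FALSE, seed = 7)
  expect_equal(fit1$joint$or, fit2$joint$or, tolerance = 1e-6)
})

test_that("confounder-only DGPs give null joint effects", {
  # outcome depends only on the covariate z; single-dataset ORs are noisy
  # (pointwise tree predictions), so aggregate over datasets
  res <- vapply(1:8, function(s) {
    d <- logistic_dgp(500, 0, gamma = 1.2, seed = 100 + s)
    q <- fit_qgcomp(d, "y", c("x1", "x2", "x3"), covariates = "z",
                    n_boot = 20, pd = FALSE, seed = s)
    top <- q$joint[q$joint$quantile == 0.9, ]
    c(or = top$or, covers = top$lo <= 1 && top$hi >= 1)
  }, numeric(2))
  expect_gte(sum(res["covers", ]), 6)       # most intervals cover the null
  expect_gt(stats::median(res["or", ]), 0.4)
  expect_lt(stats::median(res["or", ]), 2.5)
})

test_that("partial dependence sweeps each focal variable against its median", {
  d <- logistic_dgp(400, 0.6, seed = 17)
  q <- fit_qgcomp(d, "y", c("x1", "x2", "x3"), n_boot = 3,
                  pd_probs = seq(0.1, 0.9, by = 0.2), seed = 19)
  expect_named(q$partial, c("x1", "x2", "x3"))
  pd <- q$partial$x1
  expect_equal(nrow(pd), 5)
  # OR at the median sweep point is 1 by construction
  expect_equal(pd$or[3], 1, tolerance = 1e-10)
  # positive effect: OR increases along the sweep
  expect_gt(pd$or[5], pd$or[1])
})

test_that("input contracts are enforced", {
  d <- logistic_dgp(100, 0.3, seed = 23)
  expect_error(fit_qgcomp(d, "y", "x1", n_boot = 1), "n_boot")
  d1 <- d; d1$y <- 1
  expect_error(fit_qgcomp(d1, "y", "x1", n_boot = 5), "single class")
  expect_error(fit_qgcomp(d, "y", "x1", covariates = "x1", n_boot = 5),
               "overlap")
  expect_error(fit_qgcomp(d, "y", "x1", quantile_grid = c(0, 0.5),
                          n_boot = 5), "quantile_grid")
})

test_that("more bootstrap replicates stabilize interval endpoints", {
  # same data, different bootstrap streams: endpoint spread shrinks
  spread <- vapply(c(5, 40), function(nb) {
    los <- vapply(1:4, function(s) {
      d <- logistic_dgp(250, 0.3, seed = 99)
      q <- fit_qgcomp(d, "y", c("x1", "x2", "x3"), n_boot = nb,
                      n_trees = 100, pd = FALSE, seed = s)
      q$joint$lo[q$joint$quantile == 0.9]
    }, numeric(1))
    stats::sd(los)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})

test_that("marginalization analysis detects enrichment of the top cluster", {
  spec <- default_cluster_spec()
  spec$enrichment <- c(0, 0, 4)   # strong minority enrichment of cluster 3
  g <- simulate_tracts(sim_config(n_rows = 18, n_cols = 18, seed = 31,
                                  cluster_spec = spec))
  res <- marginalization_analysis(g$tracts, g$truth$cluster_labels,
                                  n_boot = 25, pd = FALSE, seed = 33)
  expect_equal(nrow(res$joint), 9)
  top <- res$joint[res$joint$quantile == 0.9, ]
  expect_gt(top$or, 1)
  expect_gt(top$lo, 1)
  bottom <- res$joint[res$joint$quantile == 0.1, ]
  expect_lt(bottom$or, 1)
})

test_that("redlining analysis responds to the generating exposure slopes", {
  g <- simulate_tracts(sim_config(n_rows = 16, n_cols = 16, seed = 41,
                                  redline_coverage = 0.8,
                                  redline_logit_beta = rep(2.5, 13)))
  res <- redlining_analysis(g$tracts, n_boot = 20, pd = FALSE, seed = 43)
  expect_equal(min(res$joint$quantile), 0.15)
  top <- res$joint[res$joint$quantile == 0.9, ]
  expect_gt(top$or, 1)
  g0 <- simulate_tracts(sim_config(n_rows = 12, n_cols = 12, seed = 47,
                                   redline_coverage = 0.8,
                                   redline_logit_beta = rep(0, 13)))
  res0 <- redlining_analysis(g0$tracts, n_boot = 20, pd = FALSE, seed = 49)
  top0 <- res0$joint[res0$joint$quantile == 0.9, ]
  expect_lt(top0$lo, 1); expect_gt(top0$hi, 1)
})
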