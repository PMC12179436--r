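cheap_mcmc <- list(n_chains = 2, n_burnin = 500, n_keep = 1000, thin = 1)

test_that("minority decile design uses left-closed bins with 0-10% reference", {
  d <- data.frame(pct_minority = c(5, 95, 10, 0, 100, 89.99, 90))
  m <- minority_decile_design(d)
  expect_equal(ncol(m), 9)
  expect_equal(sum(m[1, ]), 0)                       # reference bin
  expect_equal(which(m[2, ] == 1), c(minority_90_100 = 9))
  expect_equal(which(m[3, ] == 1), c(minority_10_20 = 1))  # 10 in second bin
  expect_equal(sum(m[4, ]), 0)
  expect_equal(which(m[5, ] == 1), c(minority_90_100 = 9))
  expect_equal(which(m[6, ] == 1), c(minority_80_90 = 8))
  expect_equal(which(m[7, ] == 1), c(minority_90_100 = 9))
  expect_true(all(rowSums(m) <= 1))
})

test_that("with the spatial effect disabled the fit matches the ML GLM", {
  g <- simulate_tracts(sim_config(n_rows = 10, n_cols = 10, seed = 17))
  f <- fit_car(g$tracts, "occ_equipment", predictors = "pct_minority",
               family = "poisson", adjacency = g$adjacency, spatial = FALSE,
               n_chains = 2, n_burnin = 1000, n_keep = 3000, thin = 1,
               seed = 4)
  ml <- stats::glm(occ_equipment ~ pct_minority, stats::poisson,
                   data = g$tracts)
  expect_lt(max(abs(f$summary$mean - stats::coef(ml))), 0.02)
  expect_true(all(f$summary$rhat < 1.1, na.rm = TRUE))
})

test_that("intercept-only gaussian fit recovers a constant outcome", {
  tt <- make_tracts(25, env_pm25 = rep(7.5, 25))
  adj <- queen_adjacency_from_grid(5, 5, tt$tract_id)
  f <- fit_car(tt, "env_pm25", family = "gaussian", adjacency = adj,
               spatial = FALSE, n_chains = 2, n_burnin = 500,
               n_keep = 1000, thin = 1, seed = 2)
  expect_lt(abs(f$summary$mean[1] - 7.5), 0.05)
})

test_that("rate-ratio summaries are the exponential of linear-scale quantiles", {
  g <- simulate_tracts(sim_config(n_rows = 8, n_cols = 8, seed = 23))
  f <- do.call(fit_car, c(list(g$tracts, "occ_disease",
                               predictors = "pct_minority",
                               family = "poisson",
                               adjacency = g$adjacency, seed = 5),
                          cheap_mcmc))
  expect_equal(f$summary$rr_lo, exp(f$summary$q2.5))
  expect_equal(f$summary$rr_hi, exp(f$summary$q97.5))
  expect_true(all(f$summary$rr_lo > 0))
  expect_true(all(f$summary$rr_lo <= f$summary$rr_hi))
})

test_that("poisson family rejects non-integer outcomes and gaussian rejects offsets", {
  tt <- make_tracts(9, env_pm25 = rnorm(9, 8))
  adj <- queen_adjacency_from_grid(3, 3, tt$tract_id)
  expect_error(fit_car(tt, "env_pm25", family = "poisson", adjacency = adj),
               "integer")
  expect_error(fit_car(tt, "env_pm25", family = "gaussian",
                       offset = "workers", adjacency = adj), "offset")
})

test_that("a spatial Poisson fit recovers a known covariate slope", {
  set.seed(7)
  n_side <- 12; n <- n_side^2
  adj <- queen_adjacency_from_grid(n_side, n_side)
  x <- runif(n)
  slope <- 0.8
  tt <- make_tracts(n, tract_id = adj$tract_ids,
                    pct_minority = 100 * x,
                    occ_contaminants = rpois(n, exp(3 + slope * x)))
  tt$x <- x
  f <- do.call(fit_car, c(list(tt, "occ_contaminants", predictors = "x",
                               family = "poisson", adjacency = adj,
                               seed = 11), cheap_mcmc))
  row <- f$summary[f$summary$term == "x", ]
  expect_gt(row$q97.5, slope - 0.3)
  expect_lt(row$q2.5, slope + 0.3)
})

test_that("inequity battery fits all six occupational outcomes", {
  g <- simulate_tracts(sim_config(n_rows = 8, n_cols = 8, seed = 29))
  res <- do.call(inequity_models,
                 c(list(g$tracts, g$adjacency, seed = 3), cheap_mcmc))
  expect_length(res$fits, 6)
  expect_length(res$errors, 0)
  expect_setequal(unique(res$table$outcome),
                  c(day_cols(), "occ_noise_workers"))
  # noise model used the worker offset: its intercept RR is a prevalence < 1
  noise_int <- res$table[res$table$outcome == "occ_noise_workers" &
                           res$table$term == "(Intercept)", ]
  expect_lt(noise_int$rr, 1)
})

test_that("redlining battery returns one effect per indicator and needs D tracts", {
  g <- simulate_tracts(sim_config(n_rows = 10, n_cols = 10, seed = 37,
                                  redline_coverage = 0.6,
                                  redline_fraction = 0.4))
  res <- suppressWarnings(do.call(redlining_exposure_models,
                 c(list(g$tracts, g$adjacency, seed = 3), cheap_mcmc)))
  expect_equal(nrow(res$table), 13)
  expect_setequal(res$table$scale[res$table$family == "gaussian"], "diff")
  noD <- g$tracts
  noD$holc_grade[noD$holc_grade == "D"] <- "C"
  expect_error(redlining_exposure_models(noD, g$adjacency), "grade-D")
  noH <- g$tracts
  noH$holc_grade[] <- NA; noH$holc_score[] <- NA
  expect_error(redlining_exposure_models(noH, g$adjacency), "HOLC")
})

test_that("a known D-tract rate shift is recovered as a rate ratio", {
  set.seed(13)
  n_side <- 10; n <- n_side^2
  adj <- queen_adjacency_from_grid(n_side, n_side)
  is_d <- rbinom(n, 1, 0.3)
  y <- rpois(n, ifelse(is_d == 1, 30, 20))   # true RR 1.5
  tt <- make_tracts(n, tract_id = adj$tract_ids, occ_contaminants = y,
                    holc_grade = ifelse(is_d == 1, "D", "C"),
                    holc_score = ifelse(is_d == 1, 3.5, 2.5))
  res <- suppressWarnings(do.call(redlining_exposure_models,
                 c(list(tt, adj, seed = 9), cheap_mcmc)))
  row <- res$table[res$table$indicator == "occ_contaminants", ]
  expect_gt(row$hi, 1.35)
  expect_lt(row$lo, 1.65)
  expect_lt(abs(row$effect - 1.5), 0.2)
})
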