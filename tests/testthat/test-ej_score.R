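test_that("percentile ranks follow the mean-rank tie convention", {
  expect_equal(percentile_rank(c(1, 2, 3, 4)), c(25, 50, 75, 100))
  expect_equal(percentile_rank(rep(7, 4)), rep(62.5, 4))  # mean rank 2.5
  x <- c(3, 1, 4, 1, 5)
  expect_equal(sort(percentile_rank(x)), sort(percentile_rank(rev(x))))
  expect_equal(percentile_rank(c(NA, 1, 2)), c(NA, 50, 100))
  expect_error(percentile_rank(c(NA_real_, NA_real_)), "missing")
  expect_error(percentile_rank(c(1, NA)), "at least 2")
})

test_that("fixture scores match hand-computed golden values for all schemes", {
  fx <- fixture_small()$tracts
  golden <- list(
    miejscreen_base = c(10.9523809523810, 45, 100, 23.8095238095238, 70),
    occupational_conditions = c(10.4761904761905, 45, 100,
                                24.4047619047619, 70),
    occupational_population = c(8.42490842490843, 41.5384615384615, 100,
                                20.5128205128205, 67.6923076923077))
  for (nm in names(golden)) {
    sc <- compute_scores(fx, ej_scheme(nm))
    expect_equal(sc$table$overall, golden[[nm]], tolerance = 1e-12)
  }
  # hotspot rule: overall >= 90
  sc <- compute_scores(fx, ej_scheme("occupational_conditions"))
  expect_identical(sc$table$hotspot, sc$table$overall >= 90)
})

test_that("a tract maximal on every indicator scores exactly 100", {
  tt <- make_tracts(3,
    pct_minority = c(10, 20, 90), pct_low_income = c(10, 20, 80),
    pct_no_hs = c(2, 5, 20), pct_under5 = c(3, 5, 9),
    pct_over64 = c(10, 15, 30),
    occ_contaminants = c(30L, 50L, 80L), occ_equipment = c(20L, 30L, 50L),
    occ_conditions = c(10L, 20L, 30L), occ_disease = c(10L, 15L, 30L),
    occ_proximity = c(70L, 85L, 110L), occ_noise_workers = c(40L, 60L, 90L),
    env_pm25 = c(7, 8, 9.5), env_diesel = c(0.1, 0.3, 0.8),
    env_ozone = c(41, 43, 46), env_airtox_cancer = c(18, 25, 50),
    env_resp_hazard = c(0.2, 0.3, 0.5), env_traffic = c(50, 500, 4000),
    env_transport_noise_pct = c(0, 3, 12))
  tt$eff_cleanup <- c(0.5, 1, 2); tt$eff_hazwaste <- c(0.4, 1, 2)
  tt$eff_ust <- c(0.2, 0.8, 1.5); tt$eff_rmp <- c(0.1, 0.5, 1.2)
  tt$eff_water <- c(0.3, 0.7, 1.8)
  for (nm in c("miejscreen_base", "occupational_conditions",
               "occupational_population")) {
    sc <- compute_scores(tt, ej_scheme(nm))
    expect_equal(sc$table$overall[3], 100)
    expect_true(sc$table$hotspot[3])
  }
})

test_that("scores are invariant to monotone transforms of raw indicators", {
  fx <- as.data.frame(fixture_small()$tracts)
  sc1 <- compute_scores(validate_tract_table(fx),
                        ej_scheme("occupational_conditions"))
  fx2 <- fx
  fx2$env_traffic <- log1p(fx2$env_traffic) * 3    # strictly increasing
  fx2$eff_cleanup <- fx2$eff_cleanup^3
  sc2 <- compute_scores(validate_tract_table(fx2),
                        ej_scheme("occupational_conditions"))
  expect_equal(sc1$table$overall, sc2$table$overall, tolerance = 1e-12)
})

test_that("schemes referencing unknown or empty categories error", {
  fx <- fixture_small()$tracts
  expect_error(compute_scores(fx, ej_scheme("miejscreen_base",
                                            effects_cols = "nope")),
               "unknown indicator")
  expect_error(score_scheme("bad", list(a = character(0)), c(a = 1),
                            c(a = "conditions")), "empty")
})

test_that("hotspot comparison partitions the tract set", {
  fx <- fixture_small()$tracts
  base <- compute_scores(fx, ej_scheme("miejscreen_base"))
  aug <- compute_scores(fx, ej_scheme("occupational_conditions"))
  cmp <- compare_schemes(base, aug)
  expect_equal(sum(cmp$counts), nrow(fx))
  expect_setequal(names(cmp$counts),
                  c("both", "base_only", "augmented_only", "neither"))
  self <- compare_schemes(base, base)
  expect_equal(unname(self$counts["augmented_only"]), 0L)
  expect_equal(unname(self$counts["base_only"]), 0L)
  # lowering the threshold moves tracts into the "both" class
  cmp50 <- compare_schemes(base, aug, threshold = 50)
  expect_gte(unname(cmp50$counts["both"]), unname(cmp$counts["both"]))
  # mismatched tract sets refuse to compare
  aug2 <- aug; aug2$table <- aug$table[c(2:5, 1), ]
  expect_error(compare_schemes(base, aug2), "different tract sets")
})

test_that("a newly crossing tract lands in the augmented-only class", {
  fx <- as.data.frame(fixture_small()$tracts)
  # make fx5 worst on every occupational indicator so augmentation flips it
  fx$occ_contaminants[5] <- 120L; fx$occ_equipment[5] <- 70L
  fx$occ_conditions[5] <- 45L; fx$occ_disease[5] <- 40L
  fx$occ_proximity[5] <- 130L; fx$occ_noise_workers[5] <- 640L
  tt <- validate_tract_table(fx)
  base <- compute_scores(tt, ej_scheme("miejscreen_base"), threshold = 60)
  aug <- compute_scores(tt, ej_scheme("occupational_conditions"),
                        threshold = 60)
  cmp <- compare_schemes(base, aug, threshold = 60)
  expect_true("fx5" %in% cmp$augmented_only_ids ||
                cmp$counts["augmented_only"] == 0)
  expect_equal(cmp$augmented_only_population,
               sum(tt$population[tt$tract_id %in% cmp$augmented_only_ids]))
})

test_that("vanishing occupational weight recovers the base ordering", {
  fx <- fixture_small()$tracts
  base <- compute_scores(fx, ej_scheme("miejscreen_base"))
  tiny <- ej_scheme("occupational_conditions")
  tiny$weights["occupational"] <- 1e-9
  aug <- compute_scores(fx, tiny)
  expect_equal(order(aug$table$overall), order(base$table$overall))
  expect_equal(aug$table$overall, base$table$overall, tolerance = 1e-6)
})
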