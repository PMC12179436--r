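#' Configuration for the synthetic tract generator
#'
#' Builds the parameter set for [simulate_tracts()]. Defaults emulate the
#' joint structure of a statewide tract-level exposure dataset: demographic
#' marginals with realistic medians (e.g. median percent racial/ethnic
#' minority near 15), spatially autocorrelated occupational day-count
#' indicators following a log-linear Poisson model with a Leroux-form
#' Gaussian Markov random field on the lattice, environmental indicators
#' drawn from a three-component exposure-profile mixture (low-occupational /
#' medium-environmental, high-occupational / low-environmental, and a
#' cumulatively high cluster), and a redlined (HOLC grade D) subset whose
#' probability is logit-linear in the tract's exposure quantiles.
#'
#' @param n_rows,n_cols lattice dimensions (queen contiguity).
#' @param seed integer seed; every stochastic draw derives from it.
#' @param spatial_rho Leroux spatial-dependence parameter in `[0,1)` of the
#'   random field on the occupational log-rates.
#' @param spatial_sd marginal standard deviation of that field (log scale).
#' @param demog_effect slope of `pct_minority/100` on each occupational
#'   indicator's log rate (scalar or length-6, one per indicator; the sixth
#'   acts on the logit of noise-exposure prevalence).
#' @param cluster_spec list with `centroids` (k x 13 matrix, raw units, in
#'   the [exposure_matrix()] column order), `weights` (mixing weights,
#'   sum 1), optional `enrichment` (per-cluster log-odds slope of
#'   `pct_minority/100` on cluster membership) and `cv` (lognormal
#'   coefficient of variation of environmental indicators about their
#'   centroid).
#' @param redline_coverage fraction of tracts that carry any HOLC grade.
#' @param redline_fraction target grade-D prevalence among graded tracts
#'   when `redline_logit_beta` is zero (sets the logit intercept).
#' @param redline_logit_beta length-13 vector of log-odds slopes linking
#'   centred exposure quantiles (percentile/100 - 0.5) to grade D.
#' @param noise_mix list with `n_points` (noise point estimates per tract),
#'   `sd_log` (lognormal spread of the per-tract exceedance fraction about
#'   the cluster target) and `cap` (maximum exceedance fraction).
#' @param demog_spatial smooth the demographic gradient over the lattice
#'   (default `TRUE`, emulating real tract data). Set `FALSE` for
#'   spatially independent demographics — the clean setting for
#'   parameter-recovery tests, where a spatially structured covariate
#'   would be partially confounded with the CAR random effect.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rows = 20, n_cols = 20, seed = 1,
                       spatial_rho = 0.6, spatial_sd = 0.15,
                       demog_effect = 0.2,
                       cluster_spec = NULL,
                       redline_coverage = 0.26, redline_fraction = 0.25,
                       redline_logit_beta = rep(0.4, 13),
                       noise_mix = list(n_points = 150, sd_log = 0.5,
                                        cap = 0.35),
                       demog_spatial = TRUE) {
  if (is.null(cluster_spec)) cluster_spec <- default_cluster_spec()
  if (is.null(cluster_spec$enrichment))
    cluster_spec$enrichment <- c(rep(0, nrow(cluster_spec$centroids) - 1), 1.5)
  if (is.null(cluster_spec$cv)) cluster_spec$cv <- 0.12
  stopifnot(n_rows >= 1, n_cols >= 1,
            spatial_rho >= 0, spatial_rho < 1, spatial_sd >= 0,
            length(demog_effect) %in% c(1L, 6L),
            redline_coverage >= 0, redline_coverage <= 1,
            redline_fraction > 0, redline_fraction < 1,
            length(redline_logit_beta) == 13L)
  w <- cluster_spec$weights
  if (any(w < 0) || sum(w) <= 0)
    stop("degenerate cluster mixing weights", call. = FALSE)
  cluster_spec$weights <- w / sum(w)
  if (nrow(cluster_spec$centroids) != length(cluster_spec$weights))
    stop("cluster_spec: centroids and weights disagree on k", call. = FALSE)
  if (ncol(cluster_spec$centroids) != 13L)
    stop("cluster_spec centroids must have 13 columns", call. = FALSE)
  if (length(demog_effect) == 1L) demog_effect <- rep(demog_effect, 6L)
  structure(list(n_rows = n_rows, n_cols = n_cols, seed = as.integer(seed),
                 spatial_rho = spatial_rho, spatial_sd = spatial_sd,
                 demog_effect = demog_effect, cluster_spec = cluster_spec,
                 redline_coverage = redline_coverage,
                 redline_fraction = redline_fraction,
                 redline_logit_beta = redline_logit_beta,
                 noise_mix = noise_mix, demog_spatial = demog_spatial),
            class = "sim_config")
}

#' Default three-cluster exposure-profile specification
#'
#' Centroids in raw indicator units ([exposure_matrix()] order) sketching
#' the three archetypes the clustering stage is meant to recover: tracts
#' with low occupational and medium environmental exposures, tracts with
#' high occupational but low environmental exposures, and tracts with
#' cumulatively high values of both.
#'
#' @return list with `centroids` (3 x 13), `weights`, `enrichment`, `cv`.
#' @export
default_cluster_spec <- function() {
  cn <- c(occ_indicators(), env_indicators())
  centroids <- rbind(
    low_occ_med_env  = c(48, 26, 19, 19, 82, 10, 8.3, 0.35, 43.5, 24, 0.30, 500, 2.0),
    high_occ_low_env = c(68, 40, 27, 26, 96, 16, 7.6, 0.20, 42.5, 20, 0.22, 80, 0.3),
    cumulative_high  = c(66, 38, 26, 25, 92, 17, 9.0, 0.55, 44.0, 30, 0.40, 1500, 8.0))
  colnames(centroids) <- cn
  list(centroids = centroids, weights = c(0.31, 0.41, 0.28),
       enrichment = c(0, 0, 1.5), cv = 0.12)
}

# Cholesky machinery for a zero-mean Leroux GMRF with precision
# rho*(D-W) + (1-rho)*I; `scale` is the average marginal sd so draws can be
# rescaled to a requested marginal sd. rho = 0 short-circuits to iid.
leroux_chol <- function(adj, rho) {
  if (rho == 0) return(list(iid = TRUE, n = length(adj$tract_ids)))
  W <- adjacency_matrix(adj)
  Q <- rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(nrow(W))
  R <- chol(Q)
  list(iid = FALSE, R = R, scale = sqrt(mean(diag(chol2inv(R)))))
}

sample_leroux_from <- function(ch, sd) {
  if (ch$iid) return(stats::rnorm(ch$n, 0, sd))
  backsolve(ch$R, stats::rnorm(nrow(ch$R))) * sd / ch$scale
}

sample_leroux_field <- function(adj, rho, sd) {
  n <- length(adj$tract_ids)
  if (sd == 0) return(rep(0, n))
  sample_leroux_from(leroux_chol(adj, rho), sd)
}

#' Simulate a synthetic tract dataset with known ground truth
#'
#' Generates a lattice of tracts with queen adjacency and the full canonical
#' tract table: bounded demographic marginals (spatially smoothed percent
#' minority), occupational day counts drawn Poisson with log-rate =
#' log(cluster baseline) + `demog_effect` * pct_minority/100 + spatial
#' Leroux field, noise-exposed worker counts drawn Binomial with a
#' logit-linear prevalence, environmental indicators drawn lognormally about
#' cluster centroids, placeholder environmental-effects columns (`eff_*`)
#' for the scoring stage, a HOLC-graded subset with grade D assigned by a
#' logistic model in the tract's exposure quantiles, and per-tract
#' transportation-noise point sets.
#'
#' @param config a [sim_config()].
#' @return list with `tracts` (validated `tract_table`), `adjacency`
#'   (`tract_adjacency`), `noise` (long data frame `tract_id`, `level_dba`)
#'   and `truth` (all latent labels and generating parameters).
#' @export
simulate_tracts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_rows * config$n_cols
    ids <- sprintf("t%05d", seq_len(n))
    adj <- queen_adjacency_from_grid(config$n_rows, config$n_cols, ids)
    k <- length(config$cluster_spec$weights)
    cen <- config$cluster_spec$centroids

    # counties: coarse blocks of the lattice
    brow <- pmin((seq_len(config$n_rows) - 1) %/% 8 + 1, 26)
    bcol <- pmin((seq_len(config$n_cols) - 1) %/% 8 + 1, 26)
    rr <- rep(seq_len(config$n_rows), each = config$n_cols)
    cc <- rep(seq_len(config$n_cols), times = config$n_rows)
    county <- sprintf("county_%s%s", LETTERS[brow[rr]], LETTERS[bcol[cc]])

    # spatially smoothed percent minority via Gaussian copula on a GMRF
    ch_occ <- if (config$spatial_sd > 0) leroux_chol(adj, config$spatial_rho)
              else NULL
    u <- if (config$demog_spatial) {
      ch_m <- leroux_chol(adj, max(config$spatial_rho, 0.3))
      stats::pnorm(0.7 * sample_leroux_from(ch_m, 1) + 0.71 * stats::rnorm(n))
    } else stats::pnorm(stats::rnorm(n))
    pct_minority <- 100 * stats::qbeta(u, 1.2, 5)
    pct_low_income <- 100 * stats::qbeta(
      stats::pnorm(0.5 * stats::qnorm(u) + 0.87 * stats::rnorm(n)), 2.5, 5)
    pct_no_hs <- 100 * stats::qbeta(
      stats::pnorm(0.5 * stats::qnorm(u) + 0.87 * stats::rnorm(n)), 1.3, 18)
    pct_under5 <- 100 * stats::qbeta(stats::rbeta(n, 5, 5), 6, 94)
    pct_over64 <- 100 * stats::rbeta(n, 5, 25)

    population <- pmax(50L, as.integer(round(4000 * exp(stats::rnorm(n, 0, 0.3)))))
    workers <- stats::rbinom(n, population, 0.45)
    density <- round(exp(stats::rnorm(n, log(1500), 0.8)), 1)

    # latent cluster labels, optionally enriched by percent minority
    enr <- config$cluster_spec$enrichment
    lw <- log(config$cluster_spec$weights)
    labels <- integer(n)
    for (i in seq_len(n)) {
      lo <- lw + enr * pct_minority[i] / 100
      p <- exp(lo - max(lo)); labels[i] <- sample.int(k, 1, prob = p / sum(p))
    }

    # occupational day counts: Poisson log-linear with spatial field
    occ_day <- matrix(0L, n, 5, dimnames = list(NULL, day_cols()))
    phi <- matrix(0, n, 6)
    for (j in 1:5) {
      phi[, j] <- if (is.null(ch_occ)) 0 else
        sample_leroux_from(ch_occ, config$spatial_sd)
      lograte <- log(cen[labels, j]) +
        config$demog_effect[j] * pct_minority / 100 + phi[, j]
      occ_day[, j] <- pmin(stats::rpois(n, exp(lograte)), 250L)
    }
    # occupational noise prevalence: Binomial logit-linear
    phi[, 6] <- if (is.null(ch_occ)) 0 else
      sample_leroux_from(ch_occ, config$spatial_sd)
    pnoise <- stats::plogis(stats::qlogis(cen[labels, 6] / 100) +
      config$demog_effect[6] * pct_minority / 100 + phi[, 6])
    occ_noise_workers <- stats::rbinom(n, workers, pnoise)

    # environmental indicators: lognormal about cluster centroids
    cv <- config$cluster_spec$cv
    env <- matrix(0, n, 7, dimnames = list(NULL, env_indicators()))
    for (j in 1:7)
      env[, j] <- cen[labels, 6 + j] * exp(stats::rnorm(n, 0, cv))
    env[, "env_transport_noise_pct"] <- pmin(env[, "env_transport_noise_pct"], 100)

    # transportation-noise point sets: mixture about the cluster target
    nm <- config$noise_mix
    target <- pmin(cen[labels, "env_transport_noise_pct"] / 100 *
                     exp(stats::rnorm(n, 0, nm$sd_log)), nm$cap)
    noise <- vector("list", n)
    exceed <- numeric(n)
    for (i in seq_len(n)) {
      n_abv <- stats::rbinom(1, nm$n_points, target[i])
      lv <- c(stats::runif(nm$n_points - n_abv, 45, 70),
              stats::runif(n_abv, 70.5, 95))
      exceed[i] <- n_abv / nm$n_points
      noise[[i]] <- data.frame(tract_id = ids[i], level_dba = round(lv, 1))
    }
    env[, "env_transport_noise_pct"] <- 100 * exceed

    # placeholder environmental-effects columns for the scoring stage
    eff <- matrix(exp(stats::rnorm(n * 5, 0, 0.6)), n, 5,
                  dimnames = list(NULL, c("eff_cleanup", "eff_hazwaste",
                                          "eff_ust", "eff_rmp", "eff_water")))
    eff <- eff * (1 + 0.5 * (labels == k))  # cumulative cluster somewhat higher

    # HOLC subset: graded tracts skew urban (dense); grade D logistic in
    # centred exposure quantiles
    exp_mat <- cbind(occ_day, occ_noise_pct = 100 * occ_noise_workers /
                       pmax(workers, 1), env)
    exp_mat <- exp_mat[, c(day_cols(), "occ_noise_pct", env_indicators())]
    qmat <- apply(exp_mat, 2, function(x) (rank(x, ties.method = "average")) /
                    length(x)) - 0.5
    n_graded <- round(config$redline_coverage * n)
    graded_idx <- order(density * exp(stats::rnorm(n, 0, 0.5)),
                        decreasing = TRUE)[seq_len(n_graded)]
    eta_d <- stats::qlogis(config$redline_fraction) +
      as.numeric(qmat %*% config$redline_logit_beta)
    holc_grade <- rep(NA_character_, n)
    holc_score <- rep(NA_real_, n)
    if (n_graded > 0) {
      is_d <- stats::rbinom(n_graded, 1, stats::plogis(eta_d[graded_idx])) == 1
      g <- ifelse(is_d, "D", sample(c("A", "B", "C"), n_graded, TRUE,
                                    prob = c(0.15, 0.35, 0.5)))
      holc_grade[graded_idx] <- g
      sc <- match(g, c("A", "B", "C", "D")) + stats::runif(n_graded, -0.4, 0.4)
      holc_score[graded_idx] <- pmin(pmax(sc, 1), 4)
    }

    df <- data.frame(
      tract_id = ids, county = county,
      centroid_lat = round(42 + (rr - 1) * 0.045 + stats::runif(n, 0, 0.02), 5),
      centroid_lon = round(-86 + (cc - 1) * 0.055 + stats::runif(n, 0, 0.02), 5),
      population = population, workers = workers, density = density,
      pct_minority = round(pct_minority, 2),
      pct_low_income = round(pct_low_income, 2),
      pct_no_hs = round(pct_no_hs, 2),
      pct_under5 = round(pct_under5, 2), pct_over64 = round(pct_over64, 2),
      occ_day,
      occ_noise_workers = occ_noise_workers,
      round(env, 4), eff,
      holc_score = round(holc_score, 3), holc_grade = holc_grade,
      stringsAsFactors = FALSE)

    truth <- list(
      config = config, cluster_labels = labels,
      centroids = cen, weights = config$cluster_spec$weights,
      demog_effect = config$demog_effect,
      spatial_rho = config$spatial_rho, spatial_sd = config$spatial_sd,
      spatial_fields = phi, noise_prevalence = pnoise,
      redline_intercept = stats::qlogis(config$redline_fraction),
      redline_logit_beta = config$redline_logit_beta,
      graded_ids = ids[graded_idx],
      d_ids = ids[graded_idx][!is.na(holc_grade[graded_idx]) &
                                holc_grade[graded_idx] == "D"],
      noise_exceedance = exceed)

    list(tracts = validate_tract_table(df), adjacency = adj,
         noise = do.call(rbind, noise), truth = truth)
  })
}

#' Deterministic five-tract worked-example fixture
#'
#' Hand-chosen values (distinct within every indicator so rank percentiles
#' are multiples of 20), exactly one grade-D tract, a chain adjacency, and a
#' small noise point set. Used by the scoring golden tests and examples.
#'
#' @return list with `tracts`, `adjacency`, `noise` as in [simulate_tracts()].
#' @export
fixture_small <- function() {
  df <- data.frame(
    tract_id = c("fx1", "fx2", "fx3", "fx4", "fx5"),
    county = c("alpha", "alpha", "alpha", "beta", "beta"),
    centroid_lat = c(42.1, 42.2, 42.3, 42.4, 42.5),
    centroid_lon = c(-85.1, -85.2, -85.3, -85.4, -85.5),
    population = c(3000L, 4000L, 5000L, 2500L, 3500L),
    workers = c(1500L, 1800L, 2400L, 1000L, 1600L),
    density = c(500, 1500, 4000, 300, 2500),
    pct_minority = c(5, 20, 80, 10, 40),
    pct_low_income = c(15, 30, 60, 20, 45),
    pct_no_hs = c(3, 6, 15, 4, 9),
    pct_under5 = c(5, 6, 8, 4, 7),
    pct_over64 = c(20, 15, 10, 25, 12),
    occ_contaminants = c(40L, 55L, 70L, 48L, 62L),
    occ_equipment = c(20L, 30L, 45L, 25L, 38L),
    occ_conditions = c(15L, 21L, 30L, 18L, 26L),
    occ_disease = c(16L, 20L, 28L, 18L, 24L),
    occ_proximity = c(80L, 85L, 95L, 82L, 90L),
    occ_noise_workers = c(120L, 216L, 480L, 90L, 256L),
    env_pm25 = c(7.0, 8.0, 9.5, 7.5, 8.8),
    env_diesel = c(0.1, 0.3, 0.8, 0.2, 0.5),
    env_ozone = c(42, 43, 45, 41, 44),
    env_airtox_cancer = c(18, 24, 40, 20, 30),
    env_resp_hazard = c(0.2, 0.3, 0.5, 0.25, 0.4),
    env_traffic = c(50, 400, 3000, 100, 1200),
    env_transport_noise_pct = c(0, 2, 12, 1, 6),
    eff_cleanup = c(0.5, 1.0, 2.5, 0.8, 1.5),
    eff_hazwaste = c(0.4, 1.2, 3.0, 0.6, 2.0),
    eff_ust = c(0.2, 0.9, 2.0, 0.5, 1.4),
    eff_rmp = c(0.1, 0.7, 1.8, 0.3, 1.1),
    eff_water = c(0.3, 0.8, 2.2, 0.4, 1.3),
    holc_score = c(NA, 2.1, 3.8, NA, 2.9),
    holc_grade = c(NA, "B", "D", NA, "C"),
    stringsAsFactors = FALSE)
  adj <- adjacency(df$tract_id,
                   cbind(c("fx1", "fx2", "fx3", "fx4"),
                         c("fx2", "fx3", "fx4", "fx5")))
  noise <- data.frame(
    tract_id = rep(df$tract_id, each = 10),
    level_dba = c(rep(55, 10),
                  c(rep(60, 9), 80),
                  c(rep(62, 8), 75, 85),
                  rep(58, 10),
                  c(rep(65, 9), 72)))
  list(tracts = validate_tract_table(df), adjacency = adj, noise = noise)
}
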