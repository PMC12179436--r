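#' Bayesian conditional autoregressive regression on areal data
#'
#' Fits `y_i ~ family` with linear predictor `x_i' beta (+ log offset) +
#' phi_i`, where `phi` is a Leroux-form CAR random effect on the supplied
#' adjacency: `phi ~ N(0, tau2 * Q(rho)^-1)` with precision
#' `Q(rho) = rho (D - W) + (1 - rho) I`. `rho` interpolates between
#' independent effects (0) and the intrinsic CAR (near 1) and is given a
#' uniform prior unless fixed. Estimation is Metropolis-within-Gibbs (block
#' random-walk for the regression coefficients with a GLM-based proposal
#' covariance, univariate updates for `phi`, conjugate inverse-gamma for
#' the variances, random-walk for `rho` using the eigenvalues of `D - W`
#' for the log-determinant). At least two chains are run and split-chain
#' scale reduction and effective sample size are reported per coefficient.
#'
#' @param data a `tract_table` (or plain data frame).
#' @param outcome name of the outcome column. Poisson outcomes must be
#'   non-negative integers.
#' @param predictors character vector of predictor columns, or `NULL` for
#'   intercept-only. Ignored when `design` is given.
#' @param design optional pre-built numeric design matrix (without
#'   intercept; one is prepended).
#' @param family `"poisson"` (log link) or `"gaussian"` (identity).
#' @param offset optional column name of an exposure count; its log enters
#'   the Poisson linear predictor. Only allowed with the Poisson family.
#' @param adjacency a `tract_adjacency` covering all rows of `data`.
#' @param spatial set `FALSE` to disable the CAR effect entirely, which
#'   collapses the model to a (Bayesian) GLM — the basis of the
#'   oracle-equivalence check against maximum likelihood.
#' @param rho `NULL` to sample the dependence parameter, or a fixed value
#'   in `[0, 1)`.
#' @param n_chains,n_burnin,n_keep,thin MCMC control: `n_keep` draws are
#'   retained per chain after `n_burnin` iterations, keeping every
#'   `thin`-th.
#' @param seed integer seed (per-chain seeds derived from it).
#' @param beta_prior_sd sd of the mean-zero normal prior on coefficients;
#'   default 10 on the log scale for Poisson and `1e4 * sd(y)` (effectively
#'   flat) for Gaussian.
#' @param eigenvalues optional precomputed eigenvalues of `D - W` (reused
#'   across fits on the same adjacency).
#' @return a `car_fit`: `summary` data frame with posterior mean, sd,
#'   2.5/97.5% quantiles on the linear-predictor scale, the exponentiated
#'   (rate-ratio) scale, effective sample size and split-chain Rhat per
#'   term; `rho`, `tau2`, `nu2` posterior summaries; `draws`; `phi_mean`.
#' @export
fit_car <- function(data, outcome, predictors = NULL, design = NULL,
                    family = c("poisson", "gaussian"), offset = NULL,
                    adjacency, spatial = TRUE, rho = NULL,
                    n_chains = 2, n_burnin = 5000, n_keep = 10000, thin = 5,
                    seed = 1, beta_prior_sd = NULL, eigenvalues = NULL) {
  family <- match.arg(family)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)))
    stop("outcome contains missing or non-finite values", call. = FALSE)
  if (family == "poisson" && any(!is_count(y)))
    stop("poisson family requires non-negative integer outcome", call. = FALSE)
  if (!is.null(offset) && family != "poisson")
    stop("offset is only supported with the poisson family", call. = FALSE)
  n <- nrow(data)
  stopifnot(n_chains >= 1, n_burnin >= 0, n_keep >= 2, thin >= 1)
  if (length(adjacency$tract_ids) != n ||
      !all(adjacency$tract_ids == data$tract_id))
    stop("adjacency does not cover the data rows (ids must match in order)",
         call. = FALSE)

  if (is.null(design)) {
    X <- if (length(predictors)) {
      for (p_ in predictors)
        if (is.null(data[[p_]])) stop("predictor not found: ", p_, call. = FALSE)
      as.matrix(data[predictors])
    } else NULL
  } else X <- as.matrix(design)
  X <- cbind(`(Intercept)` = rep(1, n), X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite values in design", call. = FALSE)

  off <- if (is.null(offset)) rep(0, n) else {
    ov <- data[[offset]]
    if (any(ov <= 0)) stop("offset must be positive", call. = FALSE)
    log(ov)
  }

  deg <- adjacency_degree(adjacency)
  if (spatial && any(deg == 0))
    warning(sum(deg == 0), " island tract(s): independent zero-mean effects",
            call. = FALSE)

  # ML fit supplies starting values and the proposal covariance
  glm_fam <- if (family == "poisson") stats::poisson() else stats::gaussian()
  ml <- suppressWarnings(stats::glm.fit(X, y, offset = off, family = glm_fam))
  beta0 <- ifelse(is.finite(ml$coefficients), ml$coefficients, 0)
  R_qr <- qr.R(ml$qr)
  ok <- is.finite(diag(R_qr)) & abs(diag(R_qr)) > 1e-10
  vcov <- tryCatch({
    V <- chol2inv(R_qr)
    disp <- if (family == "gaussian")
      sum(ml$residuals^2 * ml$weights) / max(ml$df.residual, 1) else 1
    V * max(disp, 1e-8)
  }, error = function(e) NULL)
  if (is.null(vcov) || !all(ok) || any(!is.finite(vcov)))
    vcov <- diag(0.01, ncol(X))
  vcov <- vcov + diag(1e-10, ncol(X))
  prop_chol <- chol(vcov * (2.38^2 / ncol(X)))

  if (is.null(beta_prior_sd))
    beta_prior_sd <- if (family == "poisson") 10 else
      max(1e4 * stats::sd(y), 1e2)

  lambda <- numeric(0)
  sample_rho <- spatial && is.null(rho)
  if (sample_rho) {
    if (is.null(eigenvalues)) {
      W <- adjacency_matrix(adjacency)
      eigenvalues <- eigen(diag(deg) - W, symmetric = TRUE,
                           only.values = TRUE)$values
    }
    lambda <- eigenvalues
  }
  nb <- lapply(adjacency_neighbors(adjacency), function(v) as.integer(v - 1L))
  pairs0 <- adjacency$pairs - 1L
  storage.mode(pairs0) <- "integer"

  chains <- lapply(seq_len(n_chains), function(ch) {
    with_seed(derive_seed(seed, paste0("car_chain_", ch)), {
      b0 <- beta0 + if (ch == 1) 0 else stats::rnorm(length(beta0), 0,
        pmax(sqrt(diag(vcov)), 1e-3))
      .car_mcmc_chain(as.double(y), X, off,
                      if (family == "poisson") 0L else 1L,
                      nb, pairs0, lambda, spatial,
                      as.integer(n_burnin), as.integer(n_keep),
                      as.integer(thin), b0, prop_chol, beta_prior_sd,
                      1, 0.01, 1, 0.01,
                      if (sample_rho) -1 else (rho %||% 0))
    })
  })

  terms <- colnames(X)
  summ <- do.call(rbind, lapply(seq_along(terms), function(j) {
    per_chain <- lapply(chains, function(cc) cc$beta[, j])
    d <- unlist(per_chain)
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    data.frame(term = terms[j], mean = mean(d), sd = stats::sd(d),
               q2.5 = q[1], q97.5 = q[2],
               rr = exp(mean(d)), rr_lo = exp(q[1]), rr_hi = exp(q[2]),
               ess = ess_draws(per_chain), rhat = split_rhat(per_chain),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  par_sum <- function(name) {
    per_chain <- lapply(chains, function(cc) cc[[name]])
    d <- unlist(per_chain)
    c(mean = mean(d), stats::quantile(d, c(0.025, 0.975)))
  }
  structure(list(
    summary = summ,
    family = family, outcome = outcome, spatial = spatial,
    rho = if (sample_rho) par_sum("rho") else c(mean = rho %||% 0),
    tau2 = if (spatial) par_sum("tau2") else NULL,
    nu2 = if (family == "gaussian") par_sum("nu2") else NULL,
    draws = lapply(chains, function(cc) {
      colnames(cc$beta) <- terms
      cc$beta
    }),
    phi_mean = chains[[1]]$phi_mean,
    accept_beta = mean(vapply(chains, function(cc) cc$accept_beta, 0)),
    n_chains = n_chains, n_keep = n_keep, thin = thin),
    class = "car_fit")
}

#' @export
print.car_fit <- function(x, ...) {
  cat(sprintf("car_fit: %s family, outcome '%s'%s, %d chains x %d draws\n",
              x$family, x$outcome,
              if (x$spatial) sprintf(", rho mean %.2f", x$rho[["mean"]])
              else " (non-spatial)",
              x$n_chains, x$n_keep))
  print(x$summary[, c("term", "mean", "rr", "rr_lo", "rr_hi", "ess", "rhat")],
        digits = 3)
  invisible(x)
}

#' Decile design matrix for percent racial/ethnic minority
#'
#' Bins `pct_minority` into ten left-closed, right-open deciles
#' `[0,10), [10,20), ..., [80,90)` with `[90,100]` closed; the first bin is
#' the reference and indicator columns are returned for bins 2-10.
#'
#' @param data data frame with `pct_minority` in `[0,100]`.
#' @return numeric matrix with nine 0/1 columns `minority_10_20` ...
#'   `minority_90_100`.
#' @export
minority_decile_design <- function(data) {
  x <- data$pct_minority
  stopifnot(all(x >= 0 & x <= 100))
  bin <- pmin(findInterval(x, seq(0, 90, by = 10)), 10L)
  lab <- sprintf("minority_%d_%d", seq(10, 90, 10), seq(20, 100, 10))
  m <- matrix(0, length(x), 9, dimnames = list(NULL, lab))
  hit <- bin >= 2
  m[cbind(which(hit), bin[hit] - 1L)] <- 1
  m
}

# z-standardize the shared adjustment covariates
adjust_design <- function(data) {
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  cbind(density_z = zs(data$density),
        pct_under5_z = zs(data$pct_under5),
        pct_over64_z = zs(data$pct_over64))
}

#' Occupational inequity CAR models across the minority gradient
#'
#' Fits one Poisson CAR model per occupational indicator: the five
#' day-count indicators as plain counts and noise as the count of
#' noise-exposed workers with a log(workers) offset. Each model uses the
#' minority decile design (reference 0-10%) and adjusts for population
#' density, percent under 5 and percent over 64 (standardized). A failure
#' in one outcome does not abort the others.
#'
#' @param data a `tract_table` with the six occupational indicators.
#' @param adjacency matching `tract_adjacency`.
#' @param ... MCMC control passed to [fit_car()].
#' @return list with `table` (tidy data frame: outcome, term, rr, lo, hi,
#'   ess, rhat), `fits` (the `car_fit` objects), `errors`.
#' @export
inequity_models <- function(data, adjacency, ...) {
  outcomes <- c(day_cols(), "occ_noise_workers")
  dsn <- cbind(minority_decile_design(data), adjust_design(data))
  W <- adjacency_matrix(adjacency)
  ev <- eigen(diag(rowSums(W)) - W, symmetric = TRUE, only.values = TRUE)$values
  fits <- list(); errors <- list()
  for (oc in outcomes) {
    res <- tryCatch(
      fit_car(data, outcome = oc, design = dsn, family = "poisson",
              offset = if (oc == "occ_noise_workers") "workers" else NULL,
              adjacency = adjacency, eigenvalues = ev, ...),
      error = function(e) e)
    if (inherits(res, "error")) errors[[oc]] <- conditionMessage(res)
    else fits[[oc]] <- res
  }
  tab <- do.call(rbind, lapply(names(fits), function(oc) {
    s <- fits[[oc]]$summary
    data.frame(outcome = oc, term = s$term, rr = s$rr, lo = s$rr_lo,
               hi = s$rr_hi, ess = s$ess, rhat = s$rhat,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, fits = fits, errors = errors)
}

#' Per-exposure CAR models contrasting redlined and non-redlined tracts
#'
#' Restricted to HOLC-graded tracts, fits one CAR model per exposure
#' indicator with a grade D versus grades A-C indicator as the predictor:
#' Poisson for the five day-count indicators, Poisson with a log(workers)
#' offset for noise-exposed workers, Gaussian for the seven continuous
#' environmental indicators. Effects are rate ratios (Poisson) or mean
#' differences (Gaussian).
#'
#' @inheritParams inequity_models
#' @return list with `table` (indicator, family, scale, effect, lo, hi,
#'   excludes_null), `fits`, `errors`, `n_graded`, `n_redlined`.
#' @export
redlining_exposure_models <- function(data, adjacency, ...) {
  keep <- !is.na(data$holc_grade)
  if (!any(keep)) stop("no HOLC-graded tracts in data", call. = FALSE)
  sub <- data[keep, , drop = FALSE]
  if (!any(sub$holc_grade == "D"))
    stop("no grade-D tracts in the HOLC subset", call. = FALSE)
  adj <- suppressWarnings(subset_adjacency(adjacency, sub$tract_id))
  dsn <- cbind(redlined = as.numeric(sub$holc_grade == "D"))
  W <- adjacency_matrix(adj)
  ev <- eigen(diag(rowSums(W)) - W, symmetric = TRUE, only.values = TRUE)$values

  specs <- c(
    stats::setNames(rep("poisson", 5), day_cols()),
    occ_noise_workers = "poisson",
    stats::setNames(rep("gaussian", 7), env_indicators()))
  fits <- list(); errors <- list()
  for (oc in names(specs)) {
    res <- tryCatch(
      fit_car(sub, outcome = oc, design = dsn, family = specs[[oc]],
              offset = if (oc == "occ_noise_workers") "workers" else NULL,
              adjacency = adj, eigenvalues = ev, ...),
      error = function(e) e)
    if (inherits(res, "error")) errors[[oc]] <- conditionMessage(res)
    else fits[[oc]] <- res
  }
  tab <- do.call(rbind, lapply(names(fits), function(oc) {
    s <- fits[[oc]]$summary
    s <- s[s$term == "redlined", ]
    pois <- specs[[oc]] == "poisson"
    eff <- if (pois) c(s$rr, s$rr_lo, s$rr_hi) else c(s$mean, s$q2.5, s$q97.5)
    null_val <- if (pois) 1 else 0
    data.frame(indicator = oc, family = specs[[oc]],
               scale = if (pois) "rr" else "diff",
               effect = eff[1], lo = eff[2], hi = eff[3],
               excludes_null = eff[2] > null_val | eff[3] < null_val,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, fits = fits, errors = errors,
       n_graded = nrow(sub), n_redlined = sum(sub$holc_grade == "D"))
}
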