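# build a one-hot / numeric feature matrix from a data frame of covariates
build_features <- function(df) {
  if (is.null(df) || ncol(df) == 0) return(NULL)
  parts <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      m <- vapply(levels(v), function(lv) as.numeric(v == lv),
                  numeric(length(v)))
      colnames(m) <- paste0(nm, "_", levels(v))
      m
    } else matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
  })
  do.call(cbind, parts)
}

fit_brt <- function(X, y, n_trees, learning_rate, max_depth, subsample, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = learning_rate,
                  max_depth = max_depth, subsample = subsample,
                  tree_method = "hist", nthread = 1, seed = seed),
    data = dtrain, nrounds = n_trees, verbose = 0)
}

# joint counterfactual ORs on one dataset: set every focal column to its
# empirical q-quantile (type-7 linear interpolation), average predicted
# probabilities, convert to odds, ratio against the reference quantile
qgcomp_point <- function(model, X, focal_idx, grid, reference) {
  n <- nrow(X)
  qs <- lapply(grid, function(q)
    apply(X[, focal_idx, drop = FALSE], 2, stats::quantile, q, names = FALSE,
          type = 7))
  big <- do.call(rbind, lapply(qs, function(v) {
    Xq <- X
    Xq[, focal_idx] <- matrix(v, n, length(focal_idx), byrow = TRUE)
    Xq
  }))
  p <- stats::predict(model, xgboost::xgb.DMatrix(big, nthread = 1))
  pbar <- vapply(seq_along(grid), function(i)
    mean(p[((i - 1) * n + 1):(i * n)]), numeric(1))
  odds <- pbar / (1 - pbar)
  ref_odds <- odds[match(reference, grid)]
  odds / ref_odds
}

# univariate partial-dependence odds ratios: sweep one focal variable over
# its quantile grid holding everything else at observed values
pd_point <- function(model, X, var_idx, sweep_vals, median_val) {
  n <- nrow(X)
  big <- do.call(rbind, lapply(c(sweep_vals, median_val), function(v) {
    Xv <- X
    Xv[, var_idx] <- v
    Xv
  }))
  p <- stats::predict(model, xgboost::xgb.DMatrix(big, nthread = 1))
  k <- length(sweep_vals) + 1
  pbar <- vapply(seq_len(k), function(i)
    mean(p[((i - 1) * n + 1):(i * n)]), numeric(1))
  odds <- pbar / (1 - pbar)
  odds[-k] / odds[k]
}

#' Quantile-counterfactual joint-effect estimation on boosted trees
#'
#' Fits a gradient boosted classification tree of a binary outcome on a set
#' of focal exposures plus adjustment covariates, then estimates the joint
#' ("mixture") effect g-computation style: for each grid quantile q, every
#' focal variable is set to its empirical q-quantile while covariates keep
#' their observed values; predicted probabilities are averaged across
#' tracts, converted to odds, and expressed as an odds ratio against the
#' reference quantile (the median by default), at which the OR is exactly 1
#' by construction. Percentile confidence bounds come from bootstrapping
#' tracts with replacement and repeating the whole procedure (including the
#' quantile computation). Univariate partial-dependence odds-ratio curves
#' sweep each focal variable singly over its observed quantiles, relative
#' to that variable's median sweep point.
#'
#' @param data data frame holding all referenced columns (the six
#'   occupational and seven environmental indicator names of
#'   [exposure_matrix()] may be used directly).
#' @param outcome name of a binary (0/1 or logical) column, or a vector of
#'   length `nrow(data)`. Both classes must be present.
#' @param focal_vars exposure columns whose joint quantile is manipulated.
#' @param covariates adjustment columns held at observed values; character
#'   columns are one-hot encoded.
#' @param quantile_grid counterfactual quantiles in (0,1); the reference is
#'   added if absent.
#' @param reference_quantile reference quantile (default 0.5).
#' @param n_trees boosting rounds (default 500).
#' @param n_boot bootstrap replicates (>= 2; default 100).
#' @param learning_rate,max_depth,subsample boosting hyperparameters
#'   (defaults 0.05, 3, 0.8).
#' @param pd compute partial-dependence curves (default `TRUE`; disabling
#'   them roughly halves the cost of a bootstrap replicate).
#' @param pd_probs quantile probabilities of the partial-dependence sweep.
#' @param seed master integer seed (per-replicate seeds derived from it).
#' @return a `qgcomp_result`: `joint` data frame (`quantile`, `or`, `lo`,
#'   `hi`), `partial` named list of per-variable data frames (`value`,
#'   `or`, `lo`, `hi`), `n`, `n_boot`, `params`.
#' @export
fit_qgcomp <- function(data, outcome, focal_vars, covariates = NULL,
                       quantile_grid = seq(0.1, 0.9, by = 0.1),
                       reference_quantile = 0.5, n_trees = 500,
                       n_boot = 100, learning_rate = 0.05, max_depth = 3,
                       subsample = 0.8, pd = TRUE,
                       pd_probs = seq(0.05, 0.95, by = 0.05), seed = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  if (any(quantile_grid <= 0 | quantile_grid >= 1))
    stop("quantile_grid values must lie in (0,1)", call. = FALSE)
  if (length(intersect(focal_vars, covariates)))
    stop("focal_vars and covariates overlap", call. = FALSE)
  grid <- sort(unique(c(quantile_grid, reference_quantile)))

  aug <- as.data.frame(data)
  em_cols <- setdiff(c(occ_indicators(), env_indicators()), names(aug))
  if (length(em_cols) && all(tract_columns() %in% names(aug))) {
    em <- exposure_matrix(aug)
    for (cc in em_cols) aug[[cc]] <- em[, cc]
  }
  y <- if (is.character(outcome) && length(outcome) == 1) {
    if (is.null(aug[[outcome]])) stop("outcome column not found", call. = FALSE)
    aug[[outcome]]
  } else outcome
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit", call. = FALSE)

  miss <- setdiff(c(focal_vars, covariates), names(aug))
  if (length(miss)) stop("column(s) not found: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Xf <- as.matrix(aug[focal_vars]); storage.mode(Xf) <- "double"
  Xc <- build_features(aug[covariates])
  X <- cbind(Xf, Xc)
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  focal_idx <- seq_along(focal_vars)
  n <- nrow(X)

  one_run <- function(Xb, yb, run_seed) {
    model <- fit_brt(Xb, yb, n_trees, learning_rate, max_depth, subsample,
                     run_seed)
    ors <- qgcomp_point(model, Xb, focal_idx, grid, reference_quantile)
    pds <- if (pd) lapply(focal_idx, function(j) {
      sw <- stats::quantile(Xb[, j], pd_probs, names = FALSE, type = 7)
      med <- stats::quantile(Xb[, j], 0.5, names = FALSE, type = 7)
      pd_point(model, Xb, j, sw, med)
    }) else NULL
    list(ors = ors, pds = pds)
  }

  point <- one_run(X, y, derive_seed(seed, "fit"))
  pd_sweeps <- lapply(focal_idx, function(j)
    stats::quantile(X[, j], pd_probs, names = FALSE, type = 7))

  boot_or <- matrix(NA_real_, n_boot, length(grid))
  boot_pd <- lapply(focal_idx, function(j)
    matrix(NA_real_, n_boot, length(pd_probs)))
  for (b in seq_len(n_boot)) {
    bseed <- derive_seed(seed, paste0("boot", b))
    idx <- with_seed(bseed, sample.int(n, n, replace = TRUE))
    yb <- y[idx]
    if (length(unique(yb)) < 2) next  # degenerate resample: skip
    run <- one_run(X[idx, , drop = FALSE], yb, bseed)
    boot_or[b, ] <- run$ors
    if (pd) for (j in focal_idx) boot_pd[[j]][b, ] <- run$pds[[j]]
  }
  ci <- function(v, est) {
    q <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    c(min(q[1], est), max(q[2], est))  # bounds always bracket the estimate
  }
  joint <- data.frame(quantile = grid, or = point$ors,
                      lo = NA_real_, hi = NA_real_)
  for (i in seq_along(grid)) {
    b <- ci(boot_or[, i], point$ors[i])
    joint$lo[i] <- b[1]; joint$hi[i] <- b[2]
  }
  partial <- if (!pd) NULL else stats::setNames(lapply(focal_idx, function(j) {
    out <- data.frame(value = pd_sweeps[[j]], or = point$pds[[j]],
                      lo = NA_real_, hi = NA_real_)
    for (i in seq_along(pd_probs)) {
      b <- ci(boot_pd[[j]][, i], point$pds[[j]][i])
      out$lo[i] <- b[1]; out$hi[i] <- b[2]
    }
    out
  }), focal_vars)

  structure(list(joint = joint, partial = partial, n = n, n_boot = n_boot,
                 reference_quantile = reference_quantile,
                 params = list(n_trees = n_trees,
                               learning_rate = learning_rate,
                               max_depth = max_depth, subsample = subsample,
                               seed = seed)),
            class = "qgcomp_result")
}

#' @export
print.qgcomp_result <- function(x, ...) {
  cat(sprintf("qgcomp_result: n = %d tracts, %d bootstrap replicates, ref q = %g\n",
              x$n, x$n_boot, x$reference_quantile))
  print(x$joint, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Marginalization and cumulative-exposure joint-effect analysis
#'
#' Odds of membership in the cumulatively high-exposure cluster (top label)
#' as the percent racial/ethnic minority, percent low-income and percent
#' without a high-school diploma are jointly moved across quantiles 0.1-0.9
#' (reference 0.5), adjusted for population density, percent under 5,
#' percent over 64, county (one-hot) and tract centroid.
#'
#' @param data a `tract_table`.
#' @param clusters a `cluster_result` (or integer label vector); the
#'   maximal label is the high-exposure cluster.
#' @param n_boot bootstrap replicates (default 100).
#' @param ... passed to [fit_qgcomp()].
#' @return a `qgcomp_result`.
#' @export
marginalization_analysis <- function(data, clusters, n_boot = 100, ...) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else as.integer(clusters)
  stopifnot(length(labels) == nrow(data))
  fit_qgcomp(data, outcome = as.numeric(labels == max(labels)),
             focal_vars = c("pct_minority", "pct_low_income", "pct_no_hs"),
             covariates = c("density", "pct_under5", "pct_over64", "county",
                            "centroid_lat", "centroid_lon"),
             quantile_grid = seq(0.1, 0.9, by = 0.1), n_boot = n_boot, ...)
}

#' Historical-redlining cumulative-exposure analysis
#'
#' Restricted to HOLC-graded tracts: odds of a tract having been redlined
#' (grade D versus grades A-C) as all 13 occupational and environmental
#' indicators are jointly moved across quantiles 0.15-0.9 (reference 0.5),
#' adjusted for percent low-income and percent without a high-school
#' diploma.
#'
#' @param data a `tract_table` with HOLC grades on a subset.
#' @param n_boot bootstrap replicates (study-scale default 1000;
#'   reduce for quick runs).
#' @param ... passed to [fit_qgcomp()].
#' @return a `qgcomp_result`.
#' @export
redlining_analysis <- function(data, n_boot = 1000, ...) {
  sub <- data[!is.na(data$holc_grade), , drop = FALSE]
  if (!nrow(sub)) stop("no HOLC-graded tracts", call. = FALSE)
  fit_qgcomp(sub, outcome = as.numeric(sub$holc_grade == "D"),
             focal_vars = c(occ_indicators(), env_indicators()),
             covariates = c("pct_low_income", "pct_no_hs"),
             quantile_grid = c(0.15, seq(0.2, 0.9, by = 0.1)),
             n_boot = n_boot, ...)
}
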