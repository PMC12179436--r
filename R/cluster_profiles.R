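#' Descriptive statistics for the 13 exposure indicators
#'
#' Per-indicator median, interquartile range and range, plus the 13 x 13
#' Pearson correlation matrix of the exposure indicators. Correlations
#' involving a constant indicator are undefined and reported as `NA`.
#'
#' @param data a `tract_table`.
#' @return list with `summary` (indicator, median, q25, q75, min, max) and
#'   `correlation` (13 x 13 matrix).
#' @export
describe_exposures <- function(data) {
  stopifnot(nrow(data) > 0)
  m <- exposure_matrix(data)
  qs <- t(apply(m, 2, stats::quantile, c(0.5, 0.25, 0.75, 0, 1), names = FALSE))
  summary <- data.frame(indicator = colnames(m),
                        median = qs[, 1], q25 = qs[, 2], q75 = qs[, 3],
                        min = qs[, 4], max = qs[, 5],
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  const <- apply(m, 2, stats::sd) == 0
  if (any(const))
    warning("constant indicator(s), correlations undefined: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  corr <- suppressWarnings(stats::cor(m, method = "pearson"))
  corr[const, ] <- NA; corr[, const] <- NA
  diag(corr)[!const] <- 1
  list(summary = summary, correlation = corr)
}

#' Population-weighted exposure inequality curve
#'
#' Lorenz-style construction: tracts are sorted ascending by the ordering
#' variable (percent minority by default); the curve plots cumulative
#' population share against cumulative population-weighted exposure share.
#' The area deviation (trapezoid integral of `x - y`) is positive when the
#' exposure is concentrated in tracts with high values of the ordering
#' variable, zero when exposure is constant.
#'
#' @param data a `tract_table`.
#' @param exposure indicator column name (from [exposure_matrix()] columns
#'   or any non-negative column of `data`).
#' @param ordering ordering column, default `"pct_minority"`.
#' @return list with `points` (data frame `cum_pop_share`,
#'   `cum_exposure_share`, both starting at 0) and `area_deviation`.
#' @export
inequality_curve <- function(data, exposure, ordering = "pct_minority") {
  m <- exposure_matrix(data)
  ev <- if (exposure %in% colnames(m)) m[, exposure] else data[[exposure]]
  if (is.null(ev)) stop("unknown exposure: ", exposure, call. = FALSE)
  if (any(ev < 0)) stop("exposure must be non-negative", call. = FALSE)
  ov <- data[[ordering]]
  if (is.null(ov)) stop("unknown ordering variable: ", ordering, call. = FALSE)
  o <- order(ov)
  pop <- data$population[o]
  wexp <- pop * ev[o]
  if (sum(wexp) == 0)
    stop("total population-weighted exposure is zero; curve undefined",
         call. = FALSE)
  x <- c(0, cumsum(pop) / sum(pop))
  y <- c(0, cumsum(wexp) / sum(wexp))
  dev <- sum((x[-1] - x[-length(x)]) *
               ((x[-1] + x[-length(x)]) - (y[-1] + y[-length(y)])) / 2)
  list(points = data.frame(cum_pop_share = x, cum_exposure_share = y),
       area_deviation = dev)
}

#' Exposure-profile k-means clustering with silhouette-based k selection
#'
#' Z-normalizes the 13 exposure indicators, runs k-means (Euclidean, with
#' multiple restarts) for each candidate cluster count, and selects the k
#' maximizing the average silhouette width (ties broken toward the smallest
#' k). Clusters are relabelled in increasing order of their mean normalized
#' exposure, so the highest label is the cumulatively high-exposure
#' cluster.
#'
#' @param data a `tract_table` with complete exposure indicators.
#' @param k_range candidate cluster counts (default 2:10).
#' @param nstart k-means restarts per candidate k (default 25).
#' @param seed integer seed.
#' @return a `cluster_result`: `k`, `labels` (per tract, 1..k), `centroids`
#'   (k x 13, normalized units), `profile` (k x 13 raw-unit means),
#'   `silhouette_by_k` (named vector), `sizes`.
#' @export
cluster_exposures <- function(data, k_range = 2:10, nstart = 25, seed = 1) {
  m <- exposure_matrix(data)
  if (anyNA(m)) stop("missing exposure indicator values", call. = FALSE)
  if (nrow(m) < max(k_range) + 1)
    stop("need more tracts than the largest candidate k", call. = FALSE)
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0
  d <- stats::dist(z)
  with_seed(derive_seed(seed, "kmeans"), {
    fits <- lapply(k_range, function(k)
      stats::kmeans(z, centers = k, nstart = nstart, iter.max = 50))
    sil <- vapply(seq_along(k_range), function(i) {
      s <- cluster::silhouette(fits[[i]]$cluster, d)
      mean(s[, "sil_width"])
    }, numeric(1))
    names(sil) <- k_range
    best <- which.max(sil)   # which.max takes the first (smallest k) on ties
    fit <- fits[[best]]
    k <- k_range[best]
    # relabel by increasing mean normalized exposure
    ord <- order(rowMeans(fit$centers))
    relab <- match(seq_len(k), ord)
    labels <- relab[fit$cluster]
    centroids <- fit$centers[ord, , drop = FALSE]
    rownames(centroids) <- seq_len(k)
    profile <- t(vapply(seq_len(k), function(cl)
      colMeans(m[labels == cl, , drop = FALSE]), numeric(ncol(m))))
    rownames(profile) <- seq_len(k)
    structure(list(k = k, labels = labels, centroids = centroids,
                   profile = profile, silhouette_by_k = sil,
                   sizes = tabulate(labels, k), tract_id = data$tract_id),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k =", x$k, "(avg silhouette",
      sprintf("%.3f)", x$silhouette_by_k[[as.character(x$k)]]), "\n")
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  print(round(x$profile, 2))
  invisible(x)
}
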