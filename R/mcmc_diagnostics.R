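# Split-chain potential scale reduction (Rhat) and effective sample size
# for a list of equal-length draw vectors (one per chain). ESS uses the
# pooled-chain autocorrelation with Geyer's initial positive sequence.

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-12) return(if (B < 1e-12) 1 else NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_draws <- function(chains) {
  x <- unlist(chains)
  N <- length(x)
  if (stats::var(x) < 1e-12) return(NA_real_)
  max_lag <- min(1000L, N - 2L)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  # Geyer initial positive sequence on paired sums
  s <- 0; t <- 1
  while (t + 1 <= length(ac)) {
    pair <- ac[t] + ac[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- N / (1 + 2 * s)
  min(ess, N)
}
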