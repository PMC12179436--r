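#' Monte Carlo aggregation of transportation-noise point estimates
#'
#' For one tract, repeatedly resamples 24-hr noise point estimates with
#' replacement — one draw per resident — and computes the percent of draws
#' strictly above the hazard threshold (70 dBA by default; a value exactly
#' at the threshold is not hazardous). The mean over replicates is the
#' tract's percent of residents potentially exposed to hazardous
#' transportation noise.
#'
#' The random stream is derived from `(seed, tract_id)`, so per-tract
#' results do not depend on the order in which tracts are processed.
#'
#' @param levels_dba numeric vector of noise point estimates for the tract
#'   (dBA, expected within roughly 45-110).
#' @param population number of residents; each replicate draws this many
#'   values. A zero population yields 0% with a warning.
#' @param n_reps number of Monte Carlo replicates (default 100).
#' @param threshold hazard threshold in dBA (default 70, strict inequality).
#' @param seed master integer seed.
#' @param tract_id id used to derive the tract's stream.
#' @return a `noise_agg` list: `tract_id`, `mean_pct_exposed`,
#'   `per_rep_pct` (length `n_reps`), `threshold_dba`, `n_reps`.
#' @export
aggregate_noise <- function(levels_dba, population, n_reps = 100,
                            threshold = 70, seed = 1, tract_id = "tract") {
  if (length(levels_dba) == 0 || all(is.na(levels_dba)))
    stop("empty noise point set for tract ", tract_id, call. = FALSE)
  stopifnot(population >= 0, n_reps >= 1)
  levels_dba <- levels_dba[!is.na(levels_dba)]
  if (population == 0) {
    warning("population is 0 for tract ", tract_id,
            "; percent exposed defined as 0", call. = FALSE)
    per_rep <- rep(0, n_reps)
  } else {
    per_rep <- with_seed(derive_seed(seed, tract_id), {
      vapply(seq_len(n_reps), function(r) {
        draws <- sample(levels_dba, population, replace = TRUE)
        100 * mean(draws > threshold)
      }, numeric(1))
    })
  }
  structure(list(tract_id = tract_id, mean_pct_exposed = mean(per_rep),
                 per_rep_pct = per_rep, threshold_dba = threshold,
                 n_reps = n_reps),
            class = "noise_agg")
}

#' Aggregate noise point sets for every tract in a table
#'
#' Applies [aggregate_noise()] tract by tract from a long point-estimate
#' table. Tracts without any noise points are returned with `NA`.
#'
#' @param noise long data frame with columns `tract_id`, `level_dba`.
#' @param tracts a `tract_table` supplying populations.
#' @inheritParams aggregate_noise
#' @return data frame `tract_id`, `mean_pct_exposed`, `sd_across_reps`.
#' @export
aggregate_noise_tracts <- function(noise, tracts, n_reps = 100,
                                   threshold = 70, seed = 1) {
  stopifnot(all(c("tract_id", "level_dba") %in% names(noise)))
  split_levels <- split(noise$level_dba, noise$tract_id)
  res <- lapply(tracts$tract_id, function(id) {
    lv <- split_levels[[id]]
    if (is.null(lv)) return(c(NA_real_, NA_real_))
    a <- aggregate_noise(lv, tracts$population[tracts$tract_id == id],
                         n_reps = n_reps, threshold = threshold,
                         seed = seed, tract_id = id)
    c(a$mean_pct_exposed, stats::sd(a$per_rep_pct))
  })
  res <- do.call(rbind, res)
  data.frame(tract_id = tracts$tract_id,
             mean_pct_exposed = res[, 1], sd_across_reps = res[, 2],
             stringsAsFactors = FALSE)
}

#' @export
print.noise_agg <- function(x, ...) {
  cat(sprintf("noise_agg [%s]: %.2f%% of residents above %g dBA (%d reps)\n",
              x$tract_id, x$mean_pct_exposed, x$threshold_dba, x$n_reps))
  invisible(x)
}
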