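`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Stable polynomial string hash folded into the master seed, kept within
#' the 32-bit signed integer range so it is a valid R seed. Used so that
#' per-tract and per-stage random streams are order-independent: the stream
#' for one unit depends only on the master seed and the unit's name.
#'
#' @param seed master integer seed.
#' @param key character scalar naming the stream (tract id, stage name, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# run expr under a local RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable content hash of a list of R objects (used for run-report hashes)
stable_hash <- function(x) rlang::hash(x)

is_count <- function(x) is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
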