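#' Rank-based percentile scores
#'
#' Percentile of rank r among n non-missing values is `100 * r / n`; ties
#' share the mean rank. Missing values receive missing percentiles and are
#' excluded from downstream category averages.
#'
#' @param values numeric vector (at least 2 non-missing).
#' @return numeric vector of percentiles in (0, 100].
#' @export
percentile_rank <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) == 0) stop("all values missing", call. = FALSE)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * rank(values[ok], ties.method = "average") / sum(ok)
  out
}

#' Construct a composite EJ scoring scheme
#'
#' A scheme names indicator groups (categories), assigns each category to
#' one of two subscores ("conditions" or "population"), and gives each a
#' weight. Per tract, each category's score is the mean of its member
#' indicators' percentiles; each subscore is the weighted mean of its
#' category scores (denominator = sum of included weights); subscores are
#' scaled 0-10 by dividing by the maximum across tracts; the overall score
#' is their product (0-100). Scores at or above 90 flag the most burdened
#' (hotspot) tracts.
#'
#' @param name scheme name.
#' @param categories named list: category -> character vector of indicator
#'   columns.
#' @param weights named numeric vector of positive category weights.
#' @param subscore named character vector mapping each category to
#'   `"conditions"` or `"population"`.
#' @return a `score_scheme`.
#' @export
score_scheme <- function(name, categories, weights, subscore) {
  stopifnot(is.list(categories), length(categories) >= 1,
            setequal(names(categories), names(weights)),
            setequal(names(categories), names(subscore)),
            all(subscore %in% c("conditions", "population")),
            all(weights > 0))
  if (any(lengths(categories) == 0))
    stop("empty category in scheme", call. = FALSE)
  structure(list(name = name, categories = categories,
                 weights = weights, subscore = subscore),
            class = "score_scheme")
}

#' Shipped composite-score scheme presets
#'
#' Three presets over the canonical tract-table columns:
#' \describe{
#'   \item{miejscreen_base}{Conditions = environmental exposures (weight 1)
#'     and environmental effects (weight 0.5); Population = sensitive
#'     populations and socioeconomic factors, equally weighted.}
#'   \item{occupational_conditions}{As base, plus the six occupational
#'     indicators in the conditions subscore at weight 1.5 — making the
#'     occupational block equal in weight to the environmental block
#'     (1 + 0.5).}
#'   \item{occupational_population}{Conditions as base; occupational
#'     indicators enter the population subscore instead, equally weighted
#'     with sensitive populations and socioeconomic factors.}
#' }
#'
#' @param which preset name.
#' @param effects_cols environmental-effects indicator columns (defaults to
#'   the placeholder `eff_*` columns the synthetic generator emits).
#' @return a `score_scheme`.
#' @export
ej_scheme <- function(which = c("miejscreen_base", "occupational_conditions",
                                "occupational_population"),
                      effects_cols = c("eff_cleanup", "eff_hazwaste",
                                       "eff_ust", "eff_rmp", "eff_water")) {
  which <- match.arg(which)
  base_cat <- list(
    env_exposures = env_indicators(),
    env_effects = effects_cols,
    sensitive_pops = c("pct_under5", "pct_over64"),
    socioeconomic = c("pct_minority", "pct_low_income", "pct_no_hs"))
  occ_cat <- list(occupational = occ_indicators())
  switch(which,
    miejscreen_base = score_scheme(
      which, base_cat,
      weights = c(env_exposures = 1, env_effects = 0.5,
                  sensitive_pops = 1, socioeconomic = 1),
      subscore = c(env_exposures = "conditions", env_effects = "conditions",
                   sensitive_pops = "population",
                   socioeconomic = "population")),
    occupational_conditions = score_scheme(
      which, c(base_cat, occ_cat),
      weights = c(env_exposures = 1, env_effects = 0.5, occupational = 1.5,
                  sensitive_pops = 1, socioeconomic = 1),
      subscore = c(env_exposures = "conditions", env_effects = "conditions",
                   occupational = "conditions",
                   sensitive_pops = "population",
                   socioeconomic = "population")),
    occupational_population = score_scheme(
      which, c(base_cat, occ_cat),
      weights = c(env_exposures = 1, env_effects = 0.5, occupational = 1,
                  sensitive_pops = 1, socioeconomic = 1),
      subscore = c(env_exposures = "conditions", env_effects = "conditions",
                   occupational = "population",
                   sensitive_pops = "population",
                   socioeconomic = "population")))
}

#' Compute composite EJ scores under a scheme
#'
#' @param data a `tract_table` (plus any extra indicator columns the scheme
#'   references; the derived `occ_noise_pct` prevalence is available
#'   automatically).
#' @param scheme a [score_scheme()].
#' @param threshold hotspot threshold on the overall score (default 90).
#' @param overall_scale `"product"` (default) reports the subscore product
#'   directly on 0-100; `"percentile"` percentile-ranks the product across
#'   tracts, so a threshold of 90 flags the top decile. Screening tools
#'   differ in this final convention; both orderings are identical.
#' @return a `score_table`: `table` data frame (`tract_id`, `population`,
#'   category scores, `conditions`, `population_sub` (both 0-10),
#'   `overall` (0-100), `hotspot`), `percentiles` matrix, `scheme`.
#' @export
compute_scores <- function(data, scheme, threshold = 90,
                           overall_scale = c("product", "percentile")) {
  stopifnot(inherits(scheme, "score_scheme"))
  overall_scale <- match.arg(overall_scale)
  aug <- as.data.frame(data)
  if (!"occ_noise_pct" %in% names(aug) &&
      all(c("occ_noise_workers", "workers") %in% names(aug)))
    aug$occ_noise_pct <- ifelse(aug$workers > 0,
                                100 * aug$occ_noise_workers / aug$workers, 0)
  all_cols <- unique(unlist(scheme$categories))
  miss <- setdiff(all_cols, names(aug))
  if (length(miss))
    stop("scheme references unknown indicator(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pct <- vapply(all_cols, function(cc) percentile_rank(aug[[cc]]),
                numeric(nrow(aug)))
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = 1,
                                       dimnames = list(NULL, all_cols))
  cat_score <- vapply(names(scheme$categories), function(cat)
    rowMeans(pct[, scheme$categories[[cat]], drop = FALSE], na.rm = TRUE),
    numeric(nrow(aug)))
  if (is.null(dim(cat_score)))
    cat_score <- matrix(cat_score, nrow = 1,
                        dimnames = list(NULL, names(scheme$categories)))
  sub_raw <- vapply(c("conditions", "population"), function(s) {
    cats <- names(scheme$subscore)[scheme$subscore == s]
    w <- scheme$weights[cats]
    as.numeric(cat_score[, cats, drop = FALSE] %*% w / sum(w))
  }, numeric(nrow(aug)))
  if (is.null(dim(sub_raw)))
    sub_raw <- matrix(sub_raw, nrow = 1,
                      dimnames = list(NULL, c("conditions", "population")))
  scale10 <- function(v) 10 * v / max(v)
  cond <- scale10(sub_raw[, "conditions"])
  pop <- scale10(sub_raw[, "population"])
  overall <- cond * pop
  if (overall_scale == "percentile") overall <- percentile_rank(overall)
  tab <- data.frame(tract_id = aug$tract_id,
                    population = aug$population,
                    conditions = cond, population_sub = pop,
                    overall = overall, hotspot = overall >= threshold,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(cat_score))
  structure(list(table = tab, percentiles = pct, scheme = scheme,
                 threshold = threshold),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table ('%s'): %d tracts, %d hotspot(s) >= %g\n",
              x$scheme$name, nrow(x$table), sum(x$table$hotspot),
              x$threshold))
  print(utils::head(x$table[, c("tract_id", "conditions", "population_sub",
                                "overall", "hotspot")]), digits = 4)
  invisible(x)
}

#' Compare hotspot classification between two scoring schemes
#'
#' Classifies every tract into the four classes defined by crossing the
#' hotspot rule (overall score >= threshold) under a base and an augmented
#' scheme. The `augmented_only` class holds tracts newly identified as most
#' burdened by the augmented scheme, together with their resident total.
#'
#' @param base,augmented `score_table`s over the same tract set.
#' @param threshold hotspot threshold (default 90).
#' @return a `scheme_comparison`: `classes` data frame (`tract_id`,
#'   `class`), `counts` named vector (`both`, `base_only`,
#'   `augmented_only`, `neither`), `augmented_only_ids`,
#'   `augmented_only_population`.
#' @export
compare_schemes <- function(base, augmented, threshold = 90) {
  stopifnot(inherits(base, "score_table"), inherits(augmented, "score_table"))
  if (!identical(base$table$tract_id, augmented$table$tract_id))
    stop("score tables cover different tract sets", call. = FALSE)
  b <- base$table$overall >= threshold
  a <- augmented$table$overall >= threshold
  cls <- ifelse(b & a, "both",
         ifelse(b & !a, "base_only",
         ifelse(!b & a, "augmented_only", "neither")))
  counts <- c(both = sum(b & a), base_only = sum(b & !a),
              augmented_only = sum(!b & a), neither = sum(!b & !a))
  ids <- base$table$tract_id[cls == "augmented_only"]
  structure(list(
    classes = data.frame(tract_id = base$table$tract_id, class = cls,
                         stringsAsFactors = FALSE),
    counts = counts,
    augmented_only_ids = ids,
    augmented_only_population = sum(base$table$population[cls == "augmented_only"]),
    threshold = threshold),
    class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("scheme_comparison (threshold", x$threshold, "):\n")
  print(x$counts)
  cat("newly identified residents:", x$augmented_only_population, "\n")
  invisible(x)
}
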