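#' Canonical tract-table column names
#'
#' The tract table is the universal input of every analysis stage: one row
#' per census tract carrying demographics, the six occupational exposure
#' indicators, the seven environmental exposure indicators, and optional
#' historical redlining (HOLC) fields. Five occupational indicators are
#' average days exposed per standard 250-day work-year; the sixth is the
#' count of workers exposed to hazardous noise (a prevalence once divided by
#' the worker count).
#'
#' @return `tract_columns()` returns all mandatory column names;
#'   `occ_indicators()` and `env_indicators()` the 6 occupational and 7
#'   environmental indicator names used by the clustering, boosted-tree and
#'   scoring stages (occupational noise appears as the derived prevalence
#'   column `occ_noise_pct`).
#' @export
tract_columns <- function() {
  c("tract_id", "county", "centroid_lat", "centroid_lon",
    "population", "workers", "density",
    "pct_minority", "pct_low_income", "pct_no_hs", "pct_under5", "pct_over64",
    "occ_contaminants", "occ_equipment", "occ_conditions", "occ_disease",
    "occ_proximity", "occ_noise_workers",
    "env_pm25", "env_diesel", "env_ozone", "env_airtox_cancer",
    "env_resp_hazard", "env_traffic", "env_transport_noise_pct")
}

#' @rdname tract_columns
#' @export
occ_indicators <- function() {
  c("occ_contaminants", "occ_equipment", "occ_conditions", "occ_disease",
    "occ_proximity", "occ_noise_pct")
}

#' @rdname tract_columns
#' @export
env_indicators <- function() {
  c("env_pm25", "env_diesel", "env_ozone", "env_airtox_cancer",
    "env_resp_hazard", "env_traffic", "env_transport_noise_pct")
}

pct_cols <- function() {
  c("pct_minority", "pct_low_income", "pct_no_hs", "pct_under5", "pct_over64",
    "env_transport_noise_pct")
}

day_cols <- function() {
  c("occ_contaminants", "occ_equipment", "occ_conditions", "occ_disease",
    "occ_proximity")
}

#' Extract the 13-column exposure matrix from a tract table
#'
#' Returns the six occupational and seven environmental indicators as a
#' numeric matrix, with occupational noise expressed as the percent of
#' workers exposed (`100 * occ_noise_workers / workers`).
#'
#' @param data a validated tract table.
#' @return numeric matrix, one row per tract, 13 named columns.
#' @export
exposure_matrix <- function(data) {
  noise_pct <- ifelse(data$workers > 0,
                      100 * data$occ_noise_workers / data$workers, 0)
  m <- cbind(occ_contaminants = data$occ_contaminants,
             occ_equipment = data$occ_equipment,
             occ_conditions = data$occ_conditions,
             occ_disease = data$occ_disease,
             occ_proximity = data$occ_proximity,
             occ_noise_pct = noise_pct,
             as.matrix(data[env_indicators()]))
  rownames(m) <- data$tract_id
  m
}

# row-level invariant check; returns character vector of violations (empty if ok)
check_tract_row <- function(row) {
  v <- character(0)
  num <- function(f) suppressWarnings(as.numeric(row[[f]]))
  for (f in c("population", "workers")) {
    x <- num(f)
    if (!isTRUE(is_count(x))) v <- c(v, paste0(f, ": not a non-negative integer"))
  }
  if (!isTRUE(is_count(num("occ_noise_workers"))))
    v <- c(v, "occ_noise_workers: not a non-negative integer")
  for (f in pct_cols()) {
    x <- num(f)
    if (!isTRUE(is.finite(x) && x >= 0 && x <= 100))
      v <- c(v, paste0(f, ": outside [0,100]"))
  }
  for (f in day_cols()) {
    x <- num(f)
    if (!isTRUE(is.finite(x) && x >= 0 && x <= 250))
      v <- c(v, paste0(f, ": outside [0,250] days"))
  }
  for (f in c("density", "env_pm25", "env_diesel", "env_ozone",
              "env_airtox_cancer", "env_resp_hazard", "env_traffic")) {
    x <- num(f)
    if (!isTRUE(is.finite(x) && x >= 0)) v <- c(v, paste0(f, ": negative or missing"))
  }
  w <- num("workers"); nw <- num("occ_noise_workers")
  if (isTRUE(is.finite(w) && is.finite(nw) && nw > w))
    v <- c(v, "occ_noise_workers: exceeds workers")
  hs <- row[["holc_score"]]; hg <- row[["holc_grade"]]
  has_score <- !is.null(hs) && !is.na(hs)
  has_grade <- !is.null(hg) && !is.na(hg) && nzchar(as.character(hg))
  if (has_score != has_grade)
    v <- c(v, "holc: score and grade must be present together")
  if (has_score) {
    s <- suppressWarnings(as.numeric(hs))
    if (!isTRUE(is.finite(s) && s >= 1 && s <= 4))
      v <- c(v, "holc_score: outside [1,4]")
    if (!(as.character(hg) %in% c("A", "B", "C", "D")))
      v <- c(v, "holc_grade: not one of A,B,C,D")
  }
  v
}

#' Validate a tract data frame
#'
#' Checks every row against the tract-record invariants (percentages in
#' \[0,100\], counts non-negative integers, day-count indicators within the
#' 250-day work-year, noise-exposed workers bounded by workers, HOLC score
#' and grade present together). Rows violating an invariant are removed and
#' reported; tracts with fewer than `worker_threshold` working residents are
#' retained but flagged, since the analysis-stage filter is applied by the
#' pipeline driver, not at read time.
#'
#' @param df data frame with the canonical columns.
#' @param worker_threshold minimum working residents for full analysis
#'   inclusion (default 20); smaller tracts are flagged, not dropped.
#' @return a `tract_table`: the validated data frame with attributes
#'   `rejected` (row index, tract id, violations) and `flagged` (tract ids
#'   below the worker threshold, or with zero population).
#' @export
validate_tract_table <- function(df, worker_threshold = 20) {
  missing_cols <- setdiff(tract_columns(), names(df))
  if (length(missing_cols))
    stop("tract table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"holc_score" %in% names(df)) df$holc_score <- NA_real_
  if (!"holc_grade" %in% names(df)) df$holc_grade <- NA_character_
  df$holc_grade[!is.na(df$holc_grade) & !nzchar(as.character(df$holc_grade))] <- NA

  num_fields <- setdiff(tract_columns(), c("tract_id", "county"))
  for (f in num_fields) {
    x <- df[[f]]
    if (is.character(x)) {
      bad <- nzchar(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad))
        stop("parse error: non-numeric value in column '", f, "' at row(s) ",
             paste(which(bad), collapse = ", "), call. = FALSE)
    }
    df[[f]] <- suppressWarnings(as.numeric(x))
  }
  df$holc_score <- suppressWarnings(as.numeric(df$holc_score))
  if (anyDuplicated(df$tract_id))
    stop("duplicate tract_id values", call. = FALSE)

  viol <- lapply(seq_len(nrow(df)), function(i) check_tract_row(df[i, ]))
  bad <- lengths(viol) > 0
  rejected <- data.frame(
    row = which(bad),
    tract_id = df$tract_id[bad],
    violation = vapply(viol[bad], paste, "", collapse = "; "),
    stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  flagged <- out$tract_id[out$workers < worker_threshold | out$population == 0]
  structure(out, rejected = rejected, flagged = flagged,
            class = c("tract_table", "data.frame"))
}

#' Read a tract table from CSV
#'
#' Comma-separated with header, UTF-8, `.` decimal; missing values as empty
#' cells. Invalid rows are rejected with row-level diagnostics (see
#' [validate_tract_table()]).
#'
#' @inheritParams validate_tract_table
#' @param path path to the CSV file.
#' @return a validated `tract_table`.
#' @export
read_tract_table <- function(path, worker_threshold = 20) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tract_id = "character"),
                        na.strings = c("NA", ""))
  validate_tract_table(df, worker_threshold = worker_threshold)
}

#' Write a tract table to CSV
#'
#' Inverse of [read_tract_table()]: `read_tract_table(write_tract_table(x))`
#' is the identity on validated tables.
#'
#' @param data a tract table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.tract_table <- function(x, ...) {
  cat("tract_table:", nrow(x), "tracts,",
    sum(!is.na(x$holc_grade)), "HOLC-graded,",
    length(attr(x, "flagged")), "flagged below worker threshold\n")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) cat(" ", nrow(rej), "rows rejected at validation\n")
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
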