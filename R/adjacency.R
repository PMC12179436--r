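#' Construct a tract adjacency structure
#'
#' Symmetric, irreflexive neighbour structure over a set of tracts (queen
#' contiguity in the intended use: areal units sharing any border point,
#' including corners, are neighbours). Stored as an ordered id vector plus a
#' deduplicated pair matrix of integer indices `i < j`.
#'
#' @param tract_ids ordered character vector of tract ids.
#' @param pairs two-column matrix (integer indices into `tract_ids`, or
#'   character ids); self-pairs are dropped with a warning, duplicates and
#'   orientation are collapsed.
#' @return an object of class `tract_adjacency` with elements `tract_ids`
#'   and `pairs` (m x 2 integer matrix, `i < j`).
#' @export
adjacency <- function(tract_ids, pairs) {
  stopifnot(is.character(tract_ids), !anyDuplicated(tract_ids))
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  if (is.character(pairs)) {
    idx <- match(pairs, tract_ids)
    if (anyNA(idx)) {
      unknown <- unique(pairs[is.na(idx)])
      stop("adjacency references unknown tract id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pairs <- matrix(idx, ncol = 2)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 1 | pairs > length(tract_ids)))
    stop("adjacency pair index out of range", call. = FALSE)
  self <- pairs[, 1] == pairs[, 2]
  if (any(self)) {
    warning("dropping ", sum(self), " self-edge(s)", call. = FALSE)
    pairs <- pairs[!self, , drop = FALSE]
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(tract_ids = tract_ids, pairs = pairs),
            class = "tract_adjacency")
}

#' Read an adjacency edge list from CSV
#'
#' Two-column edge list of tract ids (header required, column names free).
#' Edges are symmetrised and deduplicated; self-edges dropped with a
#' warning; ids absent from `tract_ids` raise a referential error.
#'
#' @param path CSV path.
#' @param tract_ids the full ordered id vector the edges must refer to.
#' @return a `tract_adjacency`.
#' @export
read_adjacency <- function(path, tract_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("empty adjacency edge list: ", path, call. = FALSE)
  if (ncol(df) < 2) stop("adjacency edge list needs two columns", call. = FALSE)
  adjacency(tract_ids, cbind(df[[1]], df[[2]]))
}

#' Write an adjacency edge list to CSV
#' @param adj a `tract_adjacency`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  df <- data.frame(from = adj$tract_ids[adj$pairs[, 1]],
                   to = adj$tract_ids[adj$pairs[, 2]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Queen-contiguity adjacency of a rectangular lattice
#'
#' Cells sharing an edge or a corner (a queen move) are neighbours. Cells
#' are ordered row-major. An interior cell therefore has 8 neighbours; an
#' `r x c` lattice with `r, c >= 2` has `4rc - 3r - 3c + 2` pairs.
#'
#' @param n_rows,n_cols lattice dimensions (>= 1).
#' @param tract_ids optional ids, default `t00001...`; length `n_rows * n_cols`.
#' @return a `tract_adjacency`.
#' @export
queen_adjacency_from_grid <- function(n_rows, n_cols, tract_ids = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  n <- n_rows * n_cols
  if (is.null(tract_ids)) tract_ids <- sprintf("t%05d", seq_len(n))
  stopifnot(length(tract_ids) == n)
  cell <- function(r, c) (r - 1L) * n_cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    i <- cell(r, c)
    # right, down-left, down, down-right: each pair emitted once
    if (c < n_cols)              { from <- c(from, i); to <- c(to, cell(r, c + 1L)) }
    if (r < n_rows && c > 1L)    { from <- c(from, i); to <- c(to, cell(r + 1L, c - 1L)) }
    if (r < n_rows)              { from <- c(from, i); to <- c(to, cell(r + 1L, c)) }
    if (r < n_rows && c < n_cols){ from <- c(from, i); to <- c(to, cell(r + 1L, c + 1L)) }
  }
  if (length(from) == 0)
    return(structure(list(tract_ids = tract_ids,
                          pairs = matrix(integer(0), ncol = 2)),
                     class = "tract_adjacency"))
  adjacency(tract_ids, cbind(from, to))
}

#' Restrict an adjacency to a subset of tracts
#'
#' Keeps edges with both endpoints in `keep_ids`; tracts left without any
#' neighbour (islands) are retained and reported with a warning, since the
#' spatial models handle them with an independent zero-mean effect.
#'
#' @param adj a `tract_adjacency`.
#' @param keep_ids ids to retain (order taken from `keep_ids`).
#' @return a `tract_adjacency` over `keep_ids`.
#' @export
subset_adjacency <- function(adj, keep_ids) {
  stopifnot(all(keep_ids %in% adj$tract_ids))
  old <- match(keep_ids, adj$tract_ids)
  map <- rep(NA_integer_, length(adj$tract_ids))
  map[old] <- seq_along(keep_ids)
  p <- adj$pairs
  keep <- !is.na(map[p[, 1]]) & !is.na(map[p[, 2]])
  pairs <- cbind(map[p[keep, 1]], map[p[keep, 2]])
  out <- structure(list(tract_ids = keep_ids,
                        pairs = matrix(as.integer(pairs), ncol = 2)),
                   class = "tract_adjacency")
  deg <- adjacency_degree(out)
  if (any(deg == 0))
    warning(sum(deg == 0), " island tract(s) after subsetting; ",
            "modelled with independent random effects", call. = FALSE)
  out
}

# list of neighbour index vectors, one per tract
adjacency_neighbors <- function(adj) {
  n <- length(adj$tract_ids)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  p <- adj$pairs
  for (k in seq_len(nrow(p))) {
    nb[[p[k, 1]]] <- c(nb[[p[k, 1]]], p[k, 2])
    nb[[p[k, 2]]] <- c(nb[[p[k, 2]]], p[k, 1])
  }
  nb
}

adjacency_degree <- function(adj) {
  n <- length(adj$tract_ids)
  tabulate(c(adj$pairs[, 1], adj$pairs[, 2]), nbins = n)
}

# dense n x n 0/1 neighbour matrix (used for eigenvalues of D - W)
adjacency_matrix <- function(adj) {
  n <- length(adj$tract_ids)
  W <- matrix(0, n, n)
  p <- adj$pairs
  W[cbind(p[, 1], p[, 2])] <- 1
  W[cbind(p[, 2], p[, 1])] <- 1
  W
}

#' @export
print.tract_adjacency <- function(x, ...) {
  cat("tract_adjacency:", length(x$tract_ids), "tracts,",
      nrow(x$pairs), "neighbour pairs\n")
  invisible(x)
}
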