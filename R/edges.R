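#' Canonical edge ordering for symmetric connectivity matrices
#'
#' All edge-level statistics in this package operate on the upper triangle of
#' an R x R symmetric matrix, flattened in row-major order:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). `edge_index()` returns the
#' region-pair indices in that order; `vectorize_upper()` and `devectorize()`
#' convert between matrices and edge vectors.
#'
#' @param R number of regions.
#' @return `edge_index()`: an `E x 2` integer matrix (`E = R*(R-1)/2`) with
#'   columns `i < j`.
#' @examples
#' edge_index(4)
#' vectorize_upper(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
#' @export
edge_index <- function(R) {
  stopifnot(R >= 2)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' @rdname edge_index
#' @param m a square symmetric numeric matrix (or a connectome object).
#' @return `vectorize_upper()`: numeric vector of length `R*(R-1)/2`.
#' @export
vectorize_upper <- function(m) {
  if (inherits(m, "connectome")) m <- m$values
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`m` must be a square matrix", call. = FALSE)
  }
  # column-major traversal of t(m)'s lower triangle == row-major upper triangle
  t(m)[lower.tri(m)]
}

#' @rdname edge_index
#' @param v an edge vector in canonical order.
#' @return `devectorize()`: an `R x R` symmetric matrix with zero diagonal.
#' @export
devectorize <- function(v, R = NULL) {
  if (is.null(R)) {
    R <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (R != round(R)) {
      stop("length of `v` is not a triangular number; pass `R` explicitly",
           call. = FALSE)
    }
    R <- as.integer(R)
  }
  if (length(v) != R * (R - 1) / 2) {
    stop(sprintf("edge vector of length %d does not match R = %d (expected %d)",
                 length(v), R, R * (R - 1) / 2), call. = FALSE)
  }
  m <- matrix(0, R, R)
  m[lower.tri(m)] <- v  # fills t(target) column-major
  m <- t(m)
  m + t(m)
}

#' Number of edges for a given region count
#' @param R number of regions.
#' @return `R*(R-1)/2`.
#' @export
n_edges <- function(R) as.integer(R * (R - 1) / 2)
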