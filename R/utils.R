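#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are reproducible
#' from their `seed` argument without disturbing the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

#' Row-wise Pearson correlation of two conformable matrices
#' @param a,b numeric matrices of identical dimension; correlations are taken
#'   across columns, one per row.
#' @return numeric vector of length `nrow(a)`.
#' @keywords internal
rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# derive a child seed below 2^31 from a master seed and a stream index
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647)
}
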