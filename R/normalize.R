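# Quantile normalization within a matrix, and cross-platform normalization
# of independently-collected samples onto the empirical distribution of a
# reference pool. The latter is what lets profiles from one array platform
# be deconvoluted against a signature built on another: each sample's
# values are replaced by the pool quantiles at their within-sample ranks,
# which preserves rank order while matching the reference ECDF.

#' Quantile-normalize an expression matrix
#'
#' Makes every column share the same distribution: each value is replaced
#' by the mean, across columns, of the values at its rank (average-rank
#' convention for ties). Delegates to [limma::normalizeQuantiles()];
#' row/column labels are preserved. A single-column matrix is returned
#' unchanged with a warning.
#'
#' @param expr Expression matrix (features x samples), complete (no NAs).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr))
  if (any(!is.finite(expr))) stop("non-finite values", call. = FALSE)
  if (ncol(expr) < 2L) {
    warning("single-column matrix: quantile normalization is the identity",
            call. = FALSE)
    return(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Build a reference pool from an expression matrix
#'
#' Pools every entry of the reference compendium into one ascending vector
#' of values; its order statistics define the target distribution for
#' [crossplatform_normalize()].
#'
#' @param expr Reference expression matrix.
#' @param description Free-text provenance of the pool.
#' @return A list of class `reference_pool`: `sorted_values`, `description`.
#' @export
reference_pool <- function(expr, description = "reference expression pool") {
  stopifnot(is.matrix(expr))
  if (any(!is.finite(expr))) stop("non-finite values", call. = FALSE)
  out <- list(sorted_values = sort(as.vector(expr)),
              description = description)
  class(out) <- "reference_pool"
  out
}

#' Map samples onto a reference distribution
#'
#' For each target column independently, value with average rank r of n is
#' replaced by the pool quantile at probability (r - 0.5)/n, linearly
#' interpolated between pool order statistics (plotting-position
#' convention, `stats::quantile` type 5). Rank order within each sample is
#' preserved, ties map to identical outputs, and outputs lie within
#' [pool min, pool max]. A constant column maps entirely to the pool
#' median, with a warning.
#'
#' @param target Expression matrix to transform (features x samples).
#' @param pool A `reference_pool`.
#' @return Matrix of the same shape and dimnames as `target`.
#' @export
crossplatform_normalize <- function(target, pool) {
  stopifnot(is.matrix(target), inherits(pool, "reference_pool"))
  if (length(pool$sorted_values) == 0L) stop("empty reference pool", call. = FALSE)
  if (any(!is.finite(target))) stop("non-finite values", call. = FALSE)
  n <- nrow(target)
  out <- apply(target, 2L, function(v) {
    if (length(unique(v)) == 1L) {
      warning("constant sample: all values mapped to the pool median",
              call. = FALSE)
    }
    r <- rank(v, ties.method = "average")
    quantile(pool$sorted_values, probs = (r - 0.5) / n, type = 5,
             names = FALSE)
  })
  out <- matrix(out, nrow = n, ncol = ncol(target))
  dimnames(out) <- dimnames(target)
  out
}
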