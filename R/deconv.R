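# Core deconvolution. The bulk profile is modeled as a weighted sum of the
# signature columns, b_i = sum_j a_ij x_j, and the weights are estimated by
# linear epsilon-insensitive support vector regression with an L1
# (epsilon-insensitive) loss — robust to the outlier genes that dominate a
# squared loss. Raw coefficients are then clipped at zero and renormalized
# onto the probability simplex. Expression values are used as provided
# (log2-like RMA scale); no de-logging is applied.

#' Deconvolution configuration
#'
#' @param epsilon Width of the insensitivity tube (default 0: pure L1
#'   loss, minimizing mean absolute error).
#' @param C Regularization trade-off of the SVR (> 0, default 1). Larger C
#'   weights the data-fit term more against the L2 penalty on the
#'   coefficients.
#' @param fit_intercept Fit an intercept to absorb baseline offsets between
#'   platforms (default `TRUE`); the intercept is excluded from fraction
#'   normalization.
#' @param standardize Z-score the signature columns before fitting
#'   (default `FALSE`; signature and mixture normally share a scale).
#' @param tol Solver convergence tolerance (default 1e-6).
#' @param max_iter Solver iteration cap (default 10000).
#' @param min_overlap_error,min_overlap_warn Gene-overlap fractions below
#'   which [intersect_features()] errors (default 0.1) or warns (0.5).
#' @return A list of class `deconv_config`.
#' @export
deconv_config <- function(epsilon = 0, C = 1, fit_intercept = TRUE,
                          standardize = FALSE, tol = 1e-6, max_iter = 10000L,
                          min_overlap_error = 0.1, min_overlap_warn = 0.5) {
  stopifnot(epsilon >= 0, C > 0, tol > 0, max_iter >= 1)
  out <- list(epsilon = epsilon, C = C, fit_intercept = fit_intercept,
              standardize = standardize, tol = tol,
              max_iter = as.integer(max_iter),
              min_overlap_error = min_overlap_error,
              min_overlap_warn = min_overlap_warn)
  class(out) <- "deconv_config"
  out
}

#' Align a mixture profile and a signature on their shared genes
#'
#' Restricts both matrices to the gene IDs they share, in the signature's
#' row order. Errors when fewer than `min_overlap_error` of the signature
#' genes are found in the mixture; warns below `min_overlap_warn`.
#'
#' @param mixture Expression matrix of the bulk profile(s) (genes x
#'   samples).
#' @param sig Signature matrix (genes x cell types).
#' @param cfg A `deconv_config` (overlap thresholds).
#' @return List with elements `mixture`, `sig` (row-aligned) and
#'   `n_genes_used`.
#' @export
intersect_features <- function(mixture, sig, cfg = deconv_config()) {
  stopifnot(is.matrix(mixture), is.matrix(sig))
  shared <- intersect(rownames(sig), rownames(mixture))
  frac <- length(shared) / nrow(sig)
  if (frac < cfg$min_overlap_error) {
    stop(sprintf("only %d of %d signature genes found in the mixture (%.1f%%)",
                 length(shared), nrow(sig), 100 * frac), call. = FALSE)
  }
  if (frac < cfg$min_overlap_warn) {
    warning(sprintf("low gene overlap: %d of %d signature genes (%.1f%%)",
                    length(shared), nrow(sig), 100 * frac), call. = FALSE)
  }
  list(mixture = mixture[shared, , drop = FALSE],
       sig = sig[shared, , drop = FALSE],
       n_genes_used = length(shared))
}

# Linear eps-SVR fit via the deterministic primal Newton solver in
# src/svr_fit.cpp. The intercept is an appended all-ones column.
.fit_linear_svr <- function(A, b, cfg) {
  X <- if (cfg$fit_intercept) cbind(A, `(intercept)` = 1) else A
  fit <- svr_primal_fit(X, b, C = cfg$C, eps = cfg$epsilon,
                        tol = cfg$tol, max_iter = cfg$max_iter)
  if (!fit$converged) {
    warning("SVR solver hit the iteration cap (", cfg$max_iter,
            ") before reaching tol = ", cfg$tol, call. = FALSE)
  }
  w <- fit$w
  k <- ncol(A)
  list(coefficients = setNames(w[seq_len(k)], colnames(A)),
       intercept = if (cfg$fit_intercept) w[k + 1L] else 0,
       iterations = fit$iterations)
}

#' Clip-and-renormalize raw coefficients onto the simplex
#'
#' Negative coefficients are set to zero and the remainder is divided by
#' its sum, yielding nonnegative fractions summing to 1.
#'
#' @param raw Numeric vector of raw regression coefficients.
#' @return Numeric vector of the same length on the probability simplex.
#' @export
postprocess_fractions <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  clipped <- pmax(raw, 0)
  s <- sum(clipped)
  if (s <= 0) stop("all coefficients non-positive: no cell type supported",
                   call. = FALSE)
  clipped / s
}

#' Deconvolute a single bulk profile
#'
#' Aligns the mixture with the signature on shared genes, fits a linear
#' epsilon-SVR of the mixture values on the signature columns, and converts
#' the raw coefficients to fractions with [postprocess_fractions()]. The
#' fit is deterministic for fixed inputs and configuration.
#'
#' @param mixture_profile Single-column expression matrix (or named numeric
#'   vector) of the bulk sample.
#' @param sig Signature matrix (genes x cell types).
#' @param cfg A `deconv_config`.
#' @return A list of class `fraction_estimate`: `cell_types`,
#'   `raw_coefficients`, `fractions` (simplex), `intercept`,
#'   `n_genes_used`.
#' @export
deconvolve <- function(mixture_profile, sig, cfg = deconv_config()) {
  if (is.numeric(mixture_profile) && is.null(dim(mixture_profile))) {
    mixture_profile <- matrix(mixture_profile,
                              dimnames = list(names(mixture_profile), "sample"))
  }
  stopifnot(is.matrix(mixture_profile), ncol(mixture_profile) == 1L,
            is.matrix(sig), inherits(cfg, "deconv_config"))
  if (all(mixture_profile == 0)) stop("all-zero mixture profile", call. = FALSE)
  al <- intersect_features(mixture_profile, sig, cfg)
  A <- al$sig
  b <- as.vector(al$mixture)
  if (anyDuplicated(t(A))) {
    warning("signature has identical cell-type columns; their fractions are ",
            "not identifiable and the split between them is arbitrary",
            call. = FALSE)
  }
  scale_sd <- NULL
  if (cfg$standardize) {
    scale_sd <- apply(A, 2L, sd)
    scale_sd[scale_sd == 0] <- 1
    A <- sweep(sweep(A, 2L, colMeans(A)), 2L, scale_sd, "/")
  }
  fit <- .fit_linear_svr(A, b, cfg)
  raw <- fit$coefficients
  if (cfg$standardize) raw <- raw / scale_sd
  est <- list(cell_types = colnames(sig),
              raw_coefficients = raw,
              fractions = setNames(postprocess_fractions(raw), colnames(sig)),
              intercept = fit$intercept,
              n_genes_used = al$n_genes_used)
  class(est) <- "fraction_estimate"
  est
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("Cell-type fraction estimate (", x$n_genes_used, " genes)\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Aggregate predicted fractions into assay-level cell types
#'
#' Sums the fractions of each aggregation group (e.g. monocyte-derived
#' signature types summed to compare against a flow-cytometry monocyte
#' gate) and renormalizes the retained set to 1, so the output is again a
#' simplex over the assay cell types.
#'
#' @param est A `fraction_estimate`.
#' @param map Named list from [read_celltype_map()]: assay type ->
#'   character vector of signature types.
#' @return A `fraction_estimate` over the assay cell types
#'   (`raw_coefficients` are the pre-normalization group sums).
#' @export
aggregate_cell_types <- function(est, map) {
  stopifnot(inherits(est, "fraction_estimate"), is.list(map))
  members <- unlist(map, use.names = FALSE)
  unknown <- setdiff(members, est$cell_types)
  if (length(unknown)) {
    stop("aggregation map references unknown cell type(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sums <- vapply(map, function(m) sum(est$fractions[m]), numeric(1))
  out <- list(cell_types = names(map),
              raw_coefficients = sums,
              fractions = postprocess_fractions(sums),
              intercept = est$intercept,
              n_genes_used = est$n_genes_used)
  class(out) <- "fraction_estimate"
  out
}

#' Deconvolute a batch of bulk profiles
#'
#' Applies [deconvolve()] to each column of `mixtures`. A failing sample is
#' recorded as a row of NAs and reported in a warning; the run continues.
#'
#' @param mixtures Expression matrix (genes x samples).
#' @param sig Signature matrix.
#' @param cfg A `deconv_config`.
#' @param map Optional cell-type aggregation map applied per sample.
#' @return Numeric matrix of fractions, samples x cell types.
#' @export
deconvolve_batch <- function(mixtures, sig, cfg = deconv_config(), map = NULL) {
  stopifnot(is.matrix(mixtures))
  types <- if (is.null(map)) colnames(sig) else names(map)
  out <- matrix(NA_real_, nrow = ncol(mixtures), ncol = length(types),
                dimnames = list(colnames(mixtures), types))
  if (ncol(mixtures) == 0L) {
    warning("empty mixture set: nothing to deconvolute", call. = FALSE)
    return(out)
  }
  failed <- character()
  for (j in seq_len(ncol(mixtures))) {
    est <- tryCatch({
      e <- deconvolve(mixtures[, j, drop = FALSE], sig, cfg)
      if (!is.null(map)) e <- aggregate_cell_types(e, map)
      e
    }, error = function(e) {
      failed <<- c(failed, paste0(colnames(mixtures)[j], " (", conditionMessage(e), ")"))
      NULL
    })
    if (!is.null(est)) out[j, ] <- est$fractions
  }
  if (length(failed)) {
    warning("deconvolution failed for ", length(failed), " sample(s): ",
            paste(failed, collapse = "; "), call. = FALSE)
  }
  out
}
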