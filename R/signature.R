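# Building the reference gene expression signature matrix (RefGES):
# one-way ANOVA ranks features by how strongly they separate the cell
# types, a condition-number scan picks how many of the top-ranked features
# to keep, per-type medians collapse replicates, and a probe->gene map
# collapses probes. The selected medians form the regressor matrix used by
# the deconvolution step.

# Row-wise one-way fixed-effects ANOVA via group-sum algebra. Rows are
# centered first so the between/within split is numerically stable; a row
# whose total sum of squares is (relatively) zero is flagged degenerate.
.row_oneway_f <- function(x, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- ncol(x)
  if (k < 2L) stop("need >= 2 cell types", call. = FALSE)
  sizes <- as.vector(table(group))
  if (any(sizes < 2L)) {
    stop("cell type(s) with < 2 replicates (within-group variance undefined): ",
         paste(levels(group)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  xc <- x - rowMeans(x)
  ind <- stats::model.matrix(~ group - 1)           # n x k indicator
  gsum <- xc %*% ind                                 # row group sums
  ssb <- as.vector((gsum^2) %*% (1 / sizes))
  sst <- rowSums(xc^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- k - 1L
  df_w <- n - k
  f <- (ssb / df_b) / (ssw / df_w)
  # degenerate rows: constant across all samples -> no evidence, p = 1
  zero_var <- sst <= 1e-12 * pmax(rowSums(x^2) / n, 1)
  f[zero_var] <- 0
  # perfect separation: zero within-group variance but real between-group
  exact <- !zero_var & ssw <= 1e-12 * sst
  f[exact] <- Inf
  p <- pf(f, df_b, df_w, lower.tail = FALSE)
  p[zero_var] <- 1
  p[exact] <- 0
  list(F_statistic = f, p_value = p)
}

#' Rank features by one-way ANOVA across cell types
#'
#' For each feature, a one-way fixed-effects ANOVA tests whether mean
#' expression differs among the annotated cell types. Features are sorted
#' by p-value ascending (ties broken by descending F, then by feature ID)
#' and flagged significant at `alpha` on the raw, uncorrected p-values.
#' Features constant across all samples get p = 1 and are never selected;
#' features with zero within-type variance but real between-type spread get
#' F = Inf, p = 0.
#'
#' @param expr Expression matrix (features x samples).
#' @param ann `sample_annotation` covering every column of `expr`; every
#'   cell type needs >= 2 replicates.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A `data.frame` of class `ranked_probes` with columns `probe_id`,
#'   `F_statistic`, `p_value`, `significant`, `rank`, sorted by p-value.
#' @export
anova_rank <- function(expr, ann, alpha = 0.05) {
  stopifnot(is.matrix(expr), alpha > 0, alpha < 1)
  missing <- setdiff(colnames(expr), ann$sample_id)
  if (length(missing)) {
    stop("unannotated sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  group <- ann$cell_type[match(colnames(expr), ann$sample_id)]
  res <- .row_oneway_f(expr, group)
  tab <- data.frame(probe_id = rownames(expr),
                    F_statistic = res$F_statistic,
                    p_value = res$p_value,
                    stringsAsFactors = FALSE)
  ord <- order(tab$p_value, -tab$F_statistic, tab$probe_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab$significant <- tab$p_value < alpha
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  class(tab) <- c("ranked_probes", "data.frame")
  tab
}

#' Condition number of a matrix
#'
#' The 2-norm condition number, the ratio of the largest to the smallest
#' singular value. A low value means the downstream regression is robust to
#' perturbations of its inputs. `mode = "exact"` computes the full SVD;
#' `mode = "approx"` uses the fast triangular-factor estimate of base R's
#' [kappa()], provided as a compatibility switch because many analysis
#' pipelines report that estimate rather than the exact ratio.
#'
#' @param m Numeric matrix with finite entries.
#' @param mode `"exact"` (default) or `"approx"`.
#' @return A single number >= 1, or `Inf` when the smallest singular value
#'   is zero (rank-deficient input).
#' @export
condition_number <- function(m, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values", call. = FALSE)
  if (mode == "approx") return(kappa(m, exact = FALSE))
  d <- svd(m, nu = 0, nv = 0)$d
  smin <- min(d)
  # singular values below the numerical rank threshold mean the matrix is
  # rank-deficient for any practical purpose
  if (smin <= max(d) * max(dim(m)) * .Machine$double.eps) return(Inf)
  max(d) / smin
}

#' Scan for the feature count minimizing the condition number
#'
#' Evaluates the condition number of the submatrix made of the top-G ranked
#' features (all samples as columns) for G = step, 2*step, ... up to the
#' number of significant features, and returns the grid together with the
#' G attaining the minimal condition number (first G wins on exact ties).
#' If fewer than `step` features are significant the grid is the single
#' point at the significant count. The final partial bin (a significant
#' count that is not a multiple of `step`) is appended only when
#' `include_partial = TRUE`.
#'
#' @param ranked A `ranked_probes` table from [anova_rank()].
#' @param expr The expression matrix the ranking came from.
#' @param step Grid step (default 500).
#' @param mode Condition-number mode, see [condition_number()].
#' @param include_partial Append the non-multiple significant count as a
#'   final grid point (default `FALSE`).
#' @return A list of class `condition_scan`: `grid` (data.frame with
#'   columns `G`, `kappa`), `G_star`, `kappa_star`.
#' @export
scan_optimal_G <- function(ranked, expr, step = 500L,
                           mode = c("exact", "approx"),
                           include_partial = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranked, "ranked_probes"), is.matrix(expr), step >= 1L)
  if (!all(ranked$probe_id %in% rownames(expr)))
    stop("ranked table contains features absent from the expression matrix",
         call. = FALSE)
  n_sig <- sum(ranked$significant)
  if (n_sig == 0L) stop("no significant features to scan", call. = FALSE)
  gs <- if (n_sig < step) n_sig else seq.int(step, n_sig, by = step)
  if (include_partial && n_sig > step && n_sig %% step != 0L)
    gs <- c(gs, n_sig)
  kap <- vapply(gs, function(g) {
    condition_number(expr[ranked$probe_id[seq_len(g)], , drop = FALSE],
                     mode = mode)
  }, numeric(1))
  i_star <- which.min(kap)                 # which.min takes the first tie
  out <- list(grid = data.frame(G = as.integer(gs), kappa = kap),
              G_star = as.integer(gs[i_star]), kappa_star = kap[i_star])
  class(out) <- "condition_scan"
  out
}

#' Collapse replicates to per-cell-type medians
#'
#' For each feature and cell type, takes the median expression over that
#' type's replicate columns. Columns follow `cell_type_order` if given,
#' otherwise alphabetical label order.
#'
#' @param expr Expression matrix restricted to the selected features.
#' @param ann `sample_annotation` covering every column.
#' @param cell_type_order Optional explicit column order.
#' @return Numeric matrix, features x cell types.
#' @export
summarize_by_cell_type <- function(expr, ann, cell_type_order = NULL) {
  stopifnot(is.matrix(expr))
  group <- ann$cell_type[match(colnames(expr), ann$sample_id)]
  if (anyNA(group)) stop("unannotated sample(s) present", call. = FALSE)
  types <- if (is.null(cell_type_order)) sort(unique(group)) else cell_type_order
  if (!setequal(types, unique(group)))
    stop("cell_type_order does not match the annotated cell types", call. = FALSE)
  med <- vapply(types, function(ct) {
    cols <- which(group == ct)
    if (length(cols) == 1L) expr[, cols] else
      apply(expr[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(expr)))
  med <- matrix(med, nrow = nrow(expr),
                dimnames = list(rownames(expr), types))
  med
}

#' Collapse probe-level signature rows to genes
#'
#' Several probes may measure one gene; the retained probe for each gene is
#' the one with the highest median expression across ALL source samples
#' (ties broken by lexicographic probe ID). Probes without a mapping are
#' dropped with a message reporting the count.
#'
#' @param sig Probe-level signature matrix (probes x cell types).
#' @param source_expr The full expression matrix the medians are judged on
#'   (must contain every probe of `sig`).
#' @param map Probe-to-gene map from [read_probe_gene_map()], or a
#'   data.frame with columns `probe_id`, `gene_symbol`.
#' @return Gene-level signature matrix (genes x cell types), rows in
#'   lexicographic gene order.
#' @export
collapse_probes <- function(sig, source_expr, map) {
  stopifnot(is.matrix(sig), is.matrix(source_expr))
  probes <- rownames(sig)
  gene <- map$gene_symbol[match(probes, map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message(sum(unmapped), " probe(s) without a gene mapping dropped")
  }
  probes <- probes[!unmapped]
  gene <- gene[!unmapped]
  if (length(probes) == 0L) stop("no mapped probes to collapse", call. = FALSE)
  allmed <- apply(source_expr[probes, , drop = FALSE], 1L, median)
  ord <- order(gene, -allmed, probes, method = "radix")
  keep <- ord[!duplicated(gene[ord])]
  out <- sig[probes[keep], , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Build the reference gene expression signature matrix
#'
#' Full signature pipeline: [anova_rank()] over the labeled replicate
#' compendium, [scan_optimal_G()] to pick how many top-ranked features to
#' keep, [summarize_by_cell_type()] medians over replicates, and — when a
#' probe map is supplied — [collapse_probes()] down to one row per gene.
#' With `map = NULL` the features are assumed to already be genes and the
#' probe-level medians are returned as the signature.
#'
#' @param expr Expression matrix (features x samples), normalized,
#'   log2-like scale.
#' @param ann `sample_annotation` for every column.
#' @param map Optional probe-to-gene map (`NULL` to skip collapsing).
#' @param alpha ANOVA significance threshold (default 0.05).
#' @param step Condition-scan grid step (default 500).
#' @param kappa_mode `"exact"` or `"approx"`, see [condition_number()].
#' @param cell_type_order Optional explicit signature column order.
#' @return A list of class `signature_build`: `signature` (genes x cell
#'   types), `scan` (`condition_scan`), `ranked` (`ranked_probes`),
#'   `selected_probes` (character).
#' @export
build_signature <- function(expr, ann, map = NULL, alpha = 0.05, step = 500L,
                            kappa_mode = c("exact", "approx"),
                            cell_type_order = NULL) {
  kappa_mode <- match.arg(kappa_mode)
  ranked <- anova_rank(expr, ann, alpha = alpha)
  scan <- scan_optimal_G(ranked, expr, step = step, mode = kappa_mode)
  selected <- ranked$probe_id[seq_len(scan$G_star)]
  sig <- summarize_by_cell_type(expr[selected, , drop = FALSE], ann,
                                cell_type_order = cell_type_order)
  if (!is.null(map)) sig <- collapse_probes(sig, expr, map)
  out <- list(signature = sig, scan = scan, ranked = ranked,
              selected_probes = selected)
  class(out) <- "signature_build"
  out
}

#' @export
print.signature_build <- function(x, ...) {
  cat("Reference signature build\n")
  cat("  signature: ", nrow(x$signature), " genes x ",
      ncol(x$signature), " cell types\n", sep = "")
  cat("  G* = ", x$scan$G_star, " (kappa = ",
      format(x$scan$kappa_star, digits = 6), ") over ",
      nrow(x$scan$grid), " grid point(s)\n", sep = "")
  cat("  significant features: ", sum(x$ranked$significant), " of ",
      nrow(x$ranked), "\n", sep = "")
  invisible(x)
}

#' Fisher linear discriminant embedding of labeled samples
#'
#' Projects samples onto the leading Fisher discriminant axes (at most
#' min(k - 1, `n_axes`) for k classes), the directions maximizing
#' between-class relative to within-class scatter. Used as a QA view of how
#' well the signature genes separate the cell types. When the within-class
#' scatter matrix is singular (always the case when features outnumber
#' samples) a scale-aware ridge, `1e-6 * trace(S_W)/p`, is added to its
#' diagonal with a warning.
#'
#' @param expr Expression matrix (features x samples), typically restricted
#'   to the signature genes.
#' @param ann `sample_annotation` for every column.
#' @param n_axes Number of axes requested (default 3).
#' @return A numeric matrix, samples x axes, with an attribute
#'   `"directions"` (features x axes).
#' @export
lda_embed <- function(expr, ann, n_axes = 3L) {
  stopifnot(is.matrix(expr))
  group <- as.factor(ann$cell_type[match(colnames(expr), ann$sample_id)])
  if (anyNA(group)) stop("unannotated sample(s) present", call. = FALSE)
  k <- nlevels(group)
  if (k < 2L) stop("need >= 2 classes", call. = FALSE)
  x <- t(expr)                                     # samples x features
  p <- ncol(x)
  mu <- rowsum(x, group) / as.vector(table(group))
  xc <- x - mu[group, , drop = FALSE]
  sw <- crossprod(xc)
  gm <- colMeans(x)
  md <- sweep(mu, 2L, gm)
  sb <- crossprod(md * sqrt(as.vector(table(group))))
  if (rcond(sw) < .Machine$double.eps * 100) {
    warning("singular within-class scatter; applying ridge 1e-6 * trace(S_W)/p",
            call. = FALSE)
    # floor at 1e-6 so an all-zero scatter (identical points per class)
    # still yields a usable system
    diag(sw) <- diag(sw) + max(1e-6 * sum(diag(sw)) / p, 1e-6)
  }
  ev <- eigen(solve(sw, sb))
  n_axes <- min(n_axes, k - 1L, p)
  dirs <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])
  proj <- sweep(x, 2L, gm) %*% dirs
  rownames(proj) <- colnames(expr)
  colnames(proj) <- paste0("LD", seq_len(n_axes))
  colnames(dirs) <- colnames(proj)
  rownames(dirs) <- rownames(expr)
  attr(proj, "directions") <- dirs
  proj
}

#' Write the artifacts of a signature build
#'
#' @param build A `signature_build`.
#' @param signature_path,scan_path,ranked_path Output TSV paths (`NULL` to
#'   skip any of them).
#' @param header Optional `#`-prefixed provenance lines.
#' @return `build`, invisibly.
#' @export
write_signature_build <- function(build, signature_path = NULL,
                                  scan_path = NULL, ranked_path = NULL,
                                  header = NULL) {
  stopifnot(inherits(build, "signature_build"))
  if (!is.null(signature_path))
    write_expression_matrix(build$signature, signature_path,
                            id_column = "gene_id", header = header)
  if (!is.null(scan_path)) {
    con <- file(scan_path, open = "wt")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(build$scan$grid, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  if (!is.null(ranked_path)) {
    con <- file(ranked_path, open = "wt")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(as.data.frame(build$ranked), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  invisible(build)
}
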