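# Benchmark designs with known ground truth: leave-one-out deconvolution
# of pure-cell samples, in silico mixtures of one sampled replicate per
# cell type under random simplex weights, and simulated bulk tissues where
# a tissue profile contributes a fixed share of the signal. Every design
# rebuilds the signature WITHOUT the profiles being tested, so no
# information leaks from test to reference.

#' Ground-truth design of one in silico mixture
#'
#' @param component_sample_ids Named character vector, one reference sample
#'   per cell type (names are the cell types).
#' @param weights Named simplex vector over the same cell types.
#' @param tissue_fraction Share of the final signal contributed by a
#'   tissue profile (0 for a pure immune mixture).
#' @param seed Integer seed recorded for provenance.
#' @return A list of class `mixture_design`.
#' @export
mixture_design <- function(component_sample_ids, weights,
                           tissue_fraction = 0, seed = NA_integer_) {
  stopifnot(length(component_sample_ids) == length(weights),
            !is.null(names(weights)),
            setequal(names(component_sample_ids), names(weights)))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be a simplex vector", call. = FALSE)
  if (tissue_fraction < 0 || tissue_fraction > 1)
    stop("tissue_fraction must be in [0, 1]", call. = FALSE)
  weights <- weights[names(component_sample_ids)]
  out <- list(component_sample_ids = component_sample_ids,
              weights = weights, tissue_fraction = tissue_fraction,
              seed = seed)
  class(out) <- "mixture_design"
  out
}

# Uniform simplex draw (Dirichlet(1, ..., 1)) via normalized gamma variates.
.runif_simplex <- function(k) {
  w <- rgamma(k, shape = 1)
  w / sum(w)
}

#' Synthesize an in silico mixture profile
#'
#' The mixture value of each gene is the weight-weighted sum, over cell
#' types, of the chosen reference sample of that type.
#'
#' @param reference Reference expression matrix (genes x samples).
#' @param ann `sample_annotation` of the reference.
#' @param design A [mixture_design()]; its component samples must exist and
#'   carry the cell types the design names.
#' @return Single-column expression matrix named `"mixture"`.
#' @export
make_insilico_mixture <- function(reference, ann, design) {
  stopifnot(is.matrix(reference), inherits(design, "mixture_design"))
  ids <- design$component_sample_ids
  missing <- setdiff(ids, colnames(reference))
  if (length(missing)) stop("component sample(s) not in reference: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  actual <- ann$cell_type[match(ids, ann$sample_id)]
  if (!identical(unname(actual), unname(names(ids))))
    stop("component sample cell types disagree with the design", call. = FALSE)
  m <- reference[, ids, drop = FALSE] %*% matrix(design$weights, ncol = 1L)
  colnames(m) <- "mixture"
  m
}

#' Spike an immune mixture into a tissue profile
#'
#' Per gene: `tissue_fraction * tissue + (1 - tissue_fraction) * immune`.
#'
#' @param tissue_profile Single-column expression matrix.
#' @param immune_mixture Single-column expression matrix with identical
#'   gene IDs in identical order.
#' @param tissue_fraction Share of the tissue signal, in [0, 1].
#' @return Single-column expression matrix named `"simulated_bulk"`.
#' @export
spike_into_tissue <- function(tissue_profile, immune_mixture, tissue_fraction) {
  stopifnot(is.matrix(tissue_profile), is.matrix(immune_mixture),
            ncol(tissue_profile) == 1L, ncol(immune_mixture) == 1L,
            tissue_fraction >= 0, tissue_fraction <= 1)
  if (!identical(rownames(tissue_profile), rownames(immune_mixture)))
    stop("tissue and immune profiles are not gene-aligned", call. = FALSE)
  out <- tissue_fraction * tissue_profile +
    (1 - tissue_fraction) * immune_mixture
  colnames(out) <- "simulated_bulk"
  out
}

#' Leave-one-out deconvolution of pure-cell samples
#'
#' Each reference sample in turn is held out, the signature is rebuilt from
#' the remaining samples, and the held-out (pure) profile is deconvoluted.
#' Since the truth is 1.0 for the sample's own type, the per-type mean and
#' SD of the fraction assigned to the true type summarize how well pure
#' profiles are recovered.
#'
#' @param reference Reference expression matrix (genes x samples).
#' @param ann `sample_annotation`; every type must retain >= 2 replicates
#'   after holding one out.
#' @param cfg A [deconv_config()].
#' @param alpha,step,kappa_mode Signature-build settings, see
#'   [build_signature()].
#' @param map Optional probe-to-gene map passed to the rebuilds.
#' @return List: `fractions` (samples x cell types), `true_type` (named
#'   character), `summary` (data.frame `cell_type`, `n`, `mean_dominant`,
#'   `sd_dominant` — statistics of the fraction assigned to the true type).
#' @export
run_pure_cell_loo <- function(reference, ann, cfg = deconv_config(),
                              alpha = 0.05, step = 500L,
                              kappa_mode = "exact", map = NULL) {
  stopifnot(is.matrix(reference))
  census <- cell_type_census(ann)
  if (any(census < 3L))
    stop("every cell type needs >= 3 replicates so 2 remain after holdout",
         call. = FALSE)
  samples <- colnames(reference)
  types <- sort(unique(ann$cell_type))
  fr <- matrix(NA_real_, nrow = length(samples), ncol = length(types),
               dimnames = list(samples, types))
  for (s in samples) {
    keep <- setdiff(samples, s)
    ann_s <- ann[ann$sample_id %in% keep, , drop = FALSE]
    build <- build_signature(reference[, keep, drop = FALSE], ann_s,
                             map = map, alpha = alpha, step = step,
                             kappa_mode = kappa_mode)
    est <- deconvolve(reference[, s, drop = FALSE], build$signature, cfg)
    fr[s, est$cell_types] <- est$fractions
  }
  true_type <- setNames(ann$cell_type[match(samples, ann$sample_id)], samples)
  dominant <- fr[cbind(samples, true_type)]
  summ <- do.call(rbind, lapply(types, function(ct) {
    d <- dominant[true_type == ct]
    data.frame(cell_type = ct, n = length(d), mean_dominant = mean(d),
               sd_dominant = sd(d), stringsAsFactors = FALSE)
  }))
  list(fractions = fr, true_type = true_type, summary = summ)
}

#' In silico mixture benchmark with per-run signature rebuilds
#'
#' For each of `n_mixtures` runs: one replicate per cell type is sampled
#' (uniformly, without replacement within type), simplex weights are drawn
#' from Dirichlet(1, ..., 1), the signature is rebuilt from all remaining
#' reference samples, the mixture is synthesized (and, for each requested
#' tissue fraction, spiked into the tissue profile), and the deconvoluted
#' fractions are recorded against the true weights. Passing several
#' `tissue_fractions` reuses the same components, weights and signature per
#' run, so degradation with growing tissue share is measured on matched
#' designs.
#'
#' @param reference Reference expression matrix.
#' @param ann `sample_annotation`.
#' @param n_mixtures Number of runs (default 100).
#' @param seed Integer seed; run i draws from its own child stream.
#' @param cfg A [deconv_config()].
#' @param alpha,step,kappa_mode,map Signature-build settings.
#' @param tissue_profile Single-column matrix, required when any
#'   `tissue_fractions` > 0.
#' @param tissue_fractions Numeric vector of tissue shares (default 0).
#' @return List of class `mixture_benchmark`: `ledger` (data.frame `run`,
#'   `tissue_fraction`, `cell_type`, `truth`, `predicted`), `designs`
#'   (list of `mixture_design`, one per run).
#' @export
run_mixture_benchmark <- function(reference, ann, n_mixtures = 100L,
                                  seed = 1L, cfg = deconv_config(),
                                  alpha = 0.05, step = 500L,
                                  kappa_mode = "exact", map = NULL,
                                  tissue_profile = NULL,
                                  tissue_fractions = 0) {
  stopifnot(is.matrix(reference), n_mixtures >= 1L,
            all(tissue_fractions >= 0), all(tissue_fractions <= 1))
  if (any(tissue_fractions > 0) && is.null(tissue_profile))
    stop("tissue_profile required when tissue_fractions > 0", call. = FALSE)
  types <- sort(unique(ann$cell_type))
  designs <- vector("list", n_mixtures)
  rows <- vector("list", n_mixtures)
  for (i in seq_len(n_mixtures)) {
    child <- .child_seed(seed, i)
    set.seed(child)
    ids <- vapply(types, function(ct) {
      pool <- ann$sample_id[ann$cell_type == ct]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    w <- setNames(.runif_simplex(length(types)), types)
    designs[[i]] <- mixture_design(ids, w, tissue_fraction = 0, seed = child)
    keep <- setdiff(colnames(reference), ids)
    ann_i <- ann[ann$sample_id %in% keep, , drop = FALSE]
    build <- build_signature(reference[, keep, drop = FALSE], ann_i,
                             map = map, alpha = alpha, step = step,
                             kappa_mode = kappa_mode)
    mix <- make_insilico_mixture(reference, ann, designs[[i]])
    rows[[i]] <- do.call(rbind, lapply(tissue_fractions, function(tf) {
      profile <- if (tf > 0) {
        spike_into_tissue(tissue_profile, mix, tf)
      } else mix
      est <- deconvolve(profile, build$signature, cfg)
      data.frame(run = i, tissue_fraction = tf, cell_type = est$cell_types,
                 truth = unname(w[est$cell_types]),
                 predicted = unname(est$fractions),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(ledger = do.call(rbind, rows), designs = designs)
  class(out) <- "mixture_benchmark"
  out
}
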