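# Seeded synthetic fixtures: labeled replicate compendia with
# cell-type-specific marker structure, and tissue-like background
# profiles. These emulate the statistical shape of a reference immune-cell
# compendium — within-type replicates of type-specific expression on a
# log2-like scale — so the whole pipeline is testable without downloads.
# All randomness flows from one integer seed via a fixed splitting scheme
# (one child stream per sample).

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Specification of a synthetic reference compendium
#'
#' Defaults describe the study conditions the package is validated under:
#' 9 immune-like cell types with 10 replicates each, 2,000 genes of which
#' 200 per type are disjoint markers, a gene-specific baseline drawn from
#' N(6, 1) on a log2-like scale, a marker shift of 4 units in the marker's
#' own type, and replicate-level Gaussian noise with SD 1 (a quarter of the
#' marker effect).
#'
#' @param n_cell_types Number of cell types (>= 2).
#' @param n_replicates_per_type Replicates per type (>= 2).
#' @param n_genes Total genes.
#' @param n_markers_per_type Marker genes per type (disjoint across types;
#'   `n_markers_per_type * n_cell_types <= n_genes`).
#' @param marker_effect Mean expression shift of a marker in its own type
#'   (expression units, > 0).
#' @param noise_sd Replicate-level Gaussian SD (>= 0).
#' @param baseline_mean,baseline_sd Distribution of the gene-specific
#'   baseline level.
#' @param seed Integer seed; fixes every downstream draw.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cell_types = 9L, n_replicates_per_type = 10L,
                           n_genes = 2000L, n_markers_per_type = 200L,
                           marker_effect = 4, noise_sd = 1,
                           baseline_mean = 6, baseline_sd = 1, seed = 1L) {
  stopifnot(n_cell_types >= 2L, n_replicates_per_type >= 2L, n_genes >= 1L,
            n_markers_per_type >= 1L, marker_effect > 0, noise_sd >= 0,
            n_markers_per_type * n_cell_types <= n_genes)
  out <- list(n_cell_types = as.integer(n_cell_types),
              n_replicates_per_type = as.integer(n_replicates_per_type),
              n_genes = as.integer(n_genes),
              n_markers_per_type = as.integer(n_markers_per_type),
              marker_effect = marker_effect, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' Generate a labeled synthetic reference compendium
#'
#' Gene g that is a marker of type t has mean `baseline_g + marker_effect`
#' in type t and `baseline_g` elsewhere; every replicate adds independent
#' N(0, noise_sd^2). Output is fully determined by the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `expr` (genes x samples matrix), `annotation`
#'   (`sample_annotation`), `markers` (data.frame `gene_id`, `cell_type`).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_cell_types
  r <- spec$n_replicates_per_type
  g <- spec$n_genes
  types <- sprintf("type%02d", seq_len(k))
  genes <- sprintf("gene%05d", seq_len(g))
  samples <- as.vector(vapply(types, function(t)
    paste0(t, "_rep", sprintf("%02d", seq_len(r))), character(r)))
  type_of <- rep(types, each = r)

  set.seed(.child_seed(spec$seed, 0L))
  baseline <- rnorm(g, spec$baseline_mean, spec$baseline_sd)
  marker_type <- rep(NA_character_, g)
  marker_idx <- seq_len(spec$n_markers_per_type * k)
  marker_type[marker_idx] <- rep(types, each = spec$n_markers_per_type)

  mean_mat <- matrix(baseline, nrow = g, ncol = k,
                     dimnames = list(genes, types))
  for (t in types) {
    mean_mat[which(marker_type == t), t] <-
      mean_mat[which(marker_type == t), t] + spec$marker_effect
  }

  expr <- matrix(0, nrow = g, ncol = length(samples),
                 dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    set.seed(.child_seed(spec$seed, s))
    expr[, s] <- mean_mat[, type_of[s]] + rnorm(g, 0, spec$noise_sd)
  }

  ann <- suppressWarnings(
    sample_annotation(samples, type_of, min_replicates = 2L))
  markers <- data.frame(gene_id = genes[marker_idx],
                        cell_type = marker_type[marker_idx],
                        stringsAsFactors = FALSE)
  list(expr = expr, annotation = ann, markers = markers)
}

#' Generate a tissue-like background profile
#'
#' A heavy-tailed positive expression profile, log-normal on the same
#' log2-like scale as [generate_reference()], independent of any marker
#' structure. Stands in for a non-immune bulk tissue (e.g. breast) when
#' simulating spiked bulk samples.
#'
#' @param n_genes Number of genes; gene IDs match [generate_reference()]'s.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the profile.
#' @return Single-column expression matrix (genes x 1).
#' @export
generate_tissue_profile <- function(n_genes, seed = 1L,
                                    meanlog = log(6), sdlog = 0.6) {
  stopifnot(n_genes >= 1L)
  set.seed(.child_seed(seed, 999983L))
  v <- rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  matrix(v, ncol = 1L,
         dimnames = list(sprintf("gene%05d", seq_len(n_genes)), "tissue"))
}
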