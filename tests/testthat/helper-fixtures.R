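# Small programmatic fixtures shared across test files.

# A tiny labeled compendium: k types x r replicates, g genes with m
# disjoint markers per type. Thin wrapper with unit-test-sized defaults.
tiny_reference <- function(k = 4, r = 5, g = 400, m = 40, noise_sd = 1,
                           seed = 7) {
  generate_reference(synthetic_spec(
    n_cell_types = k, n_replicates_per_type = r, n_genes = g,
    n_markers_per_type = m, noise_sd = noise_sd, seed = seed))
}

# Deterministic random expression matrix with unique IDs.
random_expr <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, 8, 2), nr, nc,
         dimnames = list(sprintf("g%03d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

# Annotation for a matrix whose columns are named <type>_rep<i>.
ann_from_colnames <- function(expr) {
  suppressWarnings(sample_annotation(
    colnames(expr), sub("_rep.*$", "", colnames(expr)), min_replicates = 2L))
}

# Brute-force one-way ANOVA oracle: explicit SSB/SSW from group means.
brute_force_f <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# NNLS oracle via an independent solver (Lawson-Hanson, pracma), with the
# same intercept handling and simplex postprocessing as deconvolve().
nnls_fractions <- function(mix, sig) {
  x <- pracma::lsqnonneg(cbind(sig, 1), as.vector(mix))$x
  w <- x[seq_len(ncol(sig))]
  w / sum(w)
}

# The reference compendium census: replicate counts per immune cell type
# (row sums over subtypes/treatments of the published compendium table).
compendium_census <- c(DC = 24, naive_CD4_T = 9, naive_CD8_T = 13,
                       memory_CD8_T = 12, NK = 12, M1 = 14, M2 = 25,
                       Th = 23, Treg = 16)
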