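---
title: "Methods: signature construction and epsilon-SVR deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction and epsilon-SVR deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrdeconv)
```

## The model

A bulk expression profile is modeled as a linear mixture of cell-type
expression programs. For gene $i$,

$$ b_i = \sum_j a_{ij} x_j, $$

where $b_i$ is the bulk expression of gene $i$, $a_{ij}$ the reference
expression of gene $i$ in cell type $j$ (a column of the reference gene
expression signature matrix, RefGES), and $x_j$ the unknown proportion of
cell type $j$. Two assumptions are load-bearing. First, linearity of
mixing: expression values are used exactly as provided (a log2-like
RMA-style scale), because the reference compendia this class of method is
built from are distributed on that scale; strictly, mixing is linear in
linear space, so using log-scale values is an approximation the benchmark
designs quantify rather than hide. Second, completeness: the signature's
cell types are assumed to span the sample. The tissue-spiking benchmark
measures exactly what happens when that fails.

## Building the signature matrix

1. **ANOVA ranking.** Each feature gets a one-way fixed-effects ANOVA F
   and p-value across the annotated cell types; features are sorted by
   p-value ascending (ties: descending F, then feature ID) and flagged
   significant at a raw `alpha` (default 0.05). No multiple-testing
   correction is applied: the ranking feeds a selection step whose size is
   chosen by conditioning, not by the nominal error rate, so a correction
   would only rescale the threshold. Features that are constant across all
   samples get p = 1 and can never enter the signature; features with
   zero within-type variance but real between-type spread get p = 0.
2. **Condition-number scan.** For G = `step`, 2·`step`, … up to the
   significant count, the 2-norm condition number $\kappa$ (ratio of
   extreme singular values) of the top-G-by-all-samples submatrix is
   computed, and the G with minimal $\kappa$ wins (first on ties). A low
   $\kappa$ means the downstream regression is robust to perturbations in
   the mixture profile. The default estimator is the exact SVD ratio
   because it is directly testable against an oracle; `kappa_mode =
   "approx"` switches to the fast triangular-factor estimate many R
   pipelines report, for compatibility when reproducing runs that used
   it. The final partial bin (a significant count that is not a multiple
   of `step`) is skipped by default, mirroring the "top 500, 1000, 1500,
   …" convention; `include_partial = TRUE` appends it.
3. **Medians and collapsing.** Replicates collapse to per-type medians
   (`summarize_by_cell_type`); probes collapse to genes by keeping, per
   gene, the probe with the highest median over *all* samples
   (`collapse_probes`), ties to the lexicographically first probe.
   Selection happens at probe level first and mapping last, preserving
   the order of operations the upstream compendium pipelines use.

`lda_embed` provides the QA view: a Fisher discriminant projection of the
samples onto up to three axes. With more features than samples the
within-class scatter is always singular, so a scale-aware ridge
(`1e-6 · trace(S_W)/p`, floored at `1e-6` for an all-zero scatter) is
added with a warning. It is a diagnostic, not part of the estimator.

### Degenerate inputs worth knowing about

With literally zero replicate noise, every marker separates its type
perfectly, all marker p-values tie at zero, and the ranked order within
the tie is the deterministic ID order — so a partial top-G cut can cover
some cell types and miss others entirely, and every grid submatrix is
numerically rank-deficient (replicate columns are identical), making the
argmin of $\kappa$ meaningless. Noise-free runs should therefore use a
`step` at least as large as the significant count, which collapses the
scan to the single "all significant features" point. Real (noisy) data do
not hit this: p-values are continuous, ties have measure zero, and the
ranking interleaves the types.

## The regression

Fractions are estimated by linear $\varepsilon$-insensitive support
vector regression with an L1 loss:

$$ \min_w \; \tfrac12\lVert w\rVert^2
   + C \sum_i \max(0, \lvert b_i - a_i^\top w\rvert - \varepsilon). $$

With the default $\varepsilon = 0$ this minimizes the mean absolute
error plus a small ridge — robust to the outlier genes that dominate a
squared loss. Defaults $\varepsilon = 0$, $C = 1$: the conventional
linear-SVR settings, exposed in `deconv_config()` for experimentation.
An intercept is fitted by default (as an L2-penalized constant column,
the common linear-SVR convention) to absorb additive baseline offsets
between platforms; it is excluded from fraction normalization and can be
disabled for strict fidelity to the intercept-free mixture equation.
Features are not standardized by default since signature and mixture
share a normalized scale.

**Solver.** The objective is strictly convex in $w$ and $w$ has only
(cell types + 1) dimensions, so the package solves the *primal* with a
damped Newton method on a Huber-smoothed loss, driving the smoothing
parameter $\mu$ from the data scale down to $10^{-8}$ of it
(continuation). Each iteration solves a tiny symmetric system; the whole
fit takes a few dozen iterations and is bit-for-bit deterministic — no
random working-set selection, no seed. Stopping: gradient sup-norm below
`tol · (1 + C)` (default `tol = 1e-6`), with objective-floor and
line-search-stall exits for exactly-representable optima; `max_iter`
(default 10,000) caps total iterations. The test suite cross-checks the
fits against an independent $\varepsilon$-regression solver (libsvm via
e1071) and a non-negative least squares oracle (Lawson–Hanson via
pracma).

**Post-processing.** Raw coefficients may be slightly negative; they are
clipped at zero and renormalized to sum to one (`postprocess_fractions`).
Reported fractions are therefore *relative* abundances on the simplex.
All-non-positive coefficients are an error, not a silent zero vector.
`aggregate_cell_types` sums fractions over user-defined groups (e.g.
monocyte-lineage types against a flow-cytometry monocyte gate) and
renormalizes the retained set, so comparisons against assays that resolve
fewer types stay on the simplex.

## Normalization

`quantile_normalize` (via limma) equalizes column distributions within a
matrix. `crossplatform_normalize` maps independently collected samples
onto the pooled empirical distribution of a reference compendium: the
value with average rank $r$ of $n$ in its sample is replaced by the pool
quantile at $(r - 0.5)/n$, linearly interpolated between pool order
statistics (plotting-position convention, `quantile(type = 5)`). The
choices that the underlying idea — "make the ECDFs similar" — leaves
open are fixed as: average ranks for ties (so tied inputs stay tied),
the $(r-0.5)/n$ position (avoids endpoint degeneracy), and per-sample
mapping (each profile arrives independently).

## Benchmark designs and the synthetic compendium

Three ground-truthed designs drive validation, each rebuilding the
signature *without* the profiles being tested so nothing leaks:

- **Pure-cell leave-one-out** (`run_pure_cell_loo`): each reference
  sample is held out, the signature rebuilt from the rest, and the pure
  profile deconvoluted; truth is 1.0 for its own type.
- **In silico mixtures** (`run_mixture_benchmark`): per run, one
  replicate per type is sampled and combined under Dirichlet(1, …, 1)
  weights — the uniform distribution on the simplex, the canonical
  choice where the design only says "random" — and the signature is
  rebuilt from the remaining samples.
- **Simulated bulk tissues** (`spike_into_tissue`): the immune mixture
  contributes $1 - f$ of the signal and a tissue profile contributes
  $f \in \{0, 0.3, 0.5, 0.7\}$. Passing all four fractions in one call
  reuses components, weights and signatures per run, so degradation is
  measured on matched designs.

Agreement is summarized by MAPE (zero-truth entries excluded with a
logged count — a relative error against zero is undefined; the designs
draw strictly positive weights, so this is a guard, not a data path),
Bland–Altman limits of agreement (mean difference ± 1.96 × sample SD,
n − 1 denominator), and cumulative difference tables with default edges
|difference| ≤ 0.01, 0.02, 0.05, 0.10, 0.20, 0.50.

The synthetic generator (`generate_reference`) emulates the statistical
shape the pipeline depends on: per-gene baselines N(6, 1) on a log2-like
scale, 9 cell types × 10 replicates, 2,000 genes with 200 disjoint
markers per type elevated by 4 units in their own type, and replicate
noise N(0, 1) — one quarter of the marker effect. Those are the study
conditions all desk-scale validation numbers refer to; they were chosen
once as a realistic marker-to-noise regime for sorted-cell microarray
replicates and are not tuned per test. What the generator deliberately
does *not* model: probe-level effects, saturation, correlated noise,
shared markers between related types, and platform batch structure. A
passing suite therefore demonstrates correctness of the machinery and
behavior under idealized marker structure, not performance on any real
compendium. The tissue stand-in (`generate_tissue_profile`) is a
synthetic log-normal profile uncorrelated with the markers, standing in
for a real non-immune expression profile in the spiking design.

Determinism: every stochastic step flows from one integer seed through a
fixed splitting scheme (one child stream per sample/run), so ledgers are
bit-reproducible and mixtures can be re-synthesized from their recorded
designs exactly.

## Problem sizes used in validation

The shipped validation runs use the study-condition fixture above: 90
leave-one-out rebuilds, 100 in silico mixtures, and 50 matched runs ×
4 tissue fractions, plus 100-instance oracle sweeps for the condition
number and ANOVA F. These sizes give stable medians and limits of
agreement at desk scale; all of them are parameters, and larger designs
only cost linearly more signature rebuilds.

## Known limitations

- Relative, not absolute, abundances; no uncertainty quantification on
  the fractions (the underlying method computes none).
- Log-scale mixing is an approximation; heavy non-immune content (the
  70% tissue design) degrades accuracy markedly and monotonically — that
  behavior is asserted, not hidden.
- The condition-number scan assumes the ANOVA ranking is meaningful; at
  zero noise see the degenerate-input note above.
- Gene-symbol aliasing is out of scope: feature IDs are matched as
  opaque strings.

## A minimal run

```{r example, eval = FALSE}
ref <- generate_reference(synthetic_spec(seed = 1))
build <- build_signature(ref$expr, ref$annotation)
mixes <- run_mixture_benchmark(ref$expr, ref$annotation,
                               n_mixtures = 20, seed = 1)
agreement_report(mixes$ledger, group_by = "cell_type")$stats
```
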