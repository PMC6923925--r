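# svrdeconv

Estimating the immune cell composition of a bulk tissue from its gene
expression profile. Given a compendium of expression profiles of sorted,
labeled immune cells, `svrdeconv` builds a reference gene expression
signature matrix (RefGES) and uses it to deconvolute bulk profiles into
cell-type fractions. It is aimed at transcriptomics analysts who have
normalized (RMA-style, log2-scale) expression matrices — microarray or
comparable — and want CIBERSORT-style cell-type enumeration with a fully
inspectable, scriptable pipeline, including the benchmark designs needed
to judge whether the estimates can be trusted on a given kind of input.

## Method

A bulk profile is modeled as a linear mixture of cell-type expression
programs: for gene *i*,

> b_i = Σ_j a_ij · x_j

with b the bulk profile, A = (a_ij) the gene × cell-type signature
matrix of per-type median expression, and x the unknown cell-type
proportions. The package's two core pieces:

**Signature construction** — one-way ANOVA ranks features by how strongly
they separate the cell types; the number G of top-ranked features kept is
chosen by scanning G in steps of 500 and minimizing the 2-norm condition
number κ of the G × samples submatrix, which makes the downstream
regression robust to perturbations; replicates collapse to per-type
medians, and probes collapse to genes by highest overall median.

**Deconvolution** — x is estimated by linear ε-insensitive support vector
regression with an L1 loss (ε = 0 and C = 1 by default, i.e. mean
absolute error plus a small ridge), solved by a deterministic primal
Newton method; coefficients are clipped at zero and renormalized onto the
probability simplex.

Around these sit quantile and cross-platform normalization (mapping a
foreign platform's profiles onto the reference compendium's empirical
distribution), cell-type aggregation for comparing against assays that
resolve fewer types, three ground-truthed benchmark designs (pure-cell
leave-one-out, in silico mixtures, tissue spiking at 30/50/70%), and
agreement statistics (MAPE, Bland–Altman limits of agreement, cumulative
difference tables). A seeded synthetic compendium generator makes the
whole pipeline runnable and testable without any external data.

## Worked example

Build a signature from a synthetic 9-type compendium (10 replicates per
type, 2,000 genes), mix one sampled replicate per type under known
weights, and deconvolute the mixture:

```r
library(svrdeconv)

ref   <- generate_reference(synthetic_spec(seed = 1))
build <- build_signature(ref$expr, ref$annotation)
build
#> Reference signature build
#>   signature: 1500 genes x 9 cell types
#>   G* = 1500 (kappa = 81.8965) over 3 grid point(s)
#>   significant features: 1814 of 2000

set.seed(42)
w   <- rgamma(9, 1); w <- w / sum(w)          # ground-truth simplex weights
ids <- vapply(sort(unique(ref$annotation$cell_type)), function(ct)
  ref$annotation$sample_id[ref$annotation$cell_type == ct][1], character(1))
mix <- make_insilico_mixture(ref$expr, ref$annotation,
                             mixture_design(ids, setNames(w, names(ids))))
est <- deconvolve(mix, build$signature)
est
#> Cell-type fraction estimate (1500 genes)
#> type01 type02 type03 type04 type05 type06 type07 type08 type09
#> 0.2832 0.0281 0.0953 0.0000 0.0787 0.0147 0.4303 0.0698 0.0000

round(setNames(w, names(ids)), 4)             # the truth
#> type01 type02 type03 type04 type05 type06 type07 type08 type09
#> 0.2904 0.0270 0.0800 0.0036 0.0641 0.0214 0.4411 0.0684 0.0040

bland_altman(est$fractions, w)$stats[c("mean_difference", "loa_lower", "loa_upper")]
#> $mean_difference  [1] -3.81e-18
#> $loa_lower        [1] -0.0183
#> $loa_upper        [1]  0.0183
```

Reading the output: 1,814 of 2,000 features were significant in the
ANOVA; the condition-number scan kept the top G\* = 1,500 (κ ≈ 82); the
estimated fractions track the true weights with every per-type error
inside ±0.02 — the Bland–Altman limits of agreement for this single
mixture. Mixtures of noisy replicates never match the median signature
exactly, which is what the MAPE and LoA quantify across the benchmark
designs.

The same pipeline is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "svrdeconv.R", package = "svrdeconv"))')
Rscript "$CLI" simulate --out-dir sim --seed 1
Rscript "$CLI" build-signature --expr sim/expression.tsv \
    --annotations sim/annotation.tsv --out-signature signature.tsv
Rscript "$CLI" deconvolve --mixture sim/expression.tsv \
    --signature signature.tsv --out fractions.tsv
```

## Layout

- `R/`, `src/` — pipeline and the Newton ε-SVR solver (RcppArmadillo)
- `vignettes/deconvolution-methods.Rmd` — model, assumptions, parameter
  choices, degenerate cases, limitations
- `tests/testthat/` — unit, property and acceptance suites
- `inst/cli/svrdeconv.R` — command-line entry point
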