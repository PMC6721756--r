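---
title: "Dissecting an induced transcriptome by dual knockdown: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an induced transcriptome by dual knockdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstalkdeg)
```

## The question and the design

Cells stimulated with a cytokine combination (the motivating system is
IFNβ + TNF acting on STAT1-deficient cells) induce hundreds of genes. Two
transcription factors, STAT2 and IRF9, may drive an induced gene together,
singly, in opposite directions, or not at all. The experimental design that
resolves this is a four-group RNA-seq layout with three replicates each:

* `NS / siCTRL` — unstimulated control knockdown,
* `IFNB_TNF / siCTRL` — stimulated control knockdown,
* `IFNB_TNF / siSTAT2` and `IFNB_TNF / siIRF9` — stimulated single
  knockdowns.

Three contrasts are formed: stimulation (stimulated vs unstimulated
control) defines the induced genes; the two knockdown contrasts (each
knockdown vs the stimulated control) define each induced gene's dependence
on each factor. Unstimulated knockdown groups are not part of the design:
the contrasts only ever compare stimulated knockdowns with the stimulated
control, so unstimulated knockdown samples would not enter any comparison.

Crossing the two knockdown outcomes (transcript drops / rises / unchanged
upon silencing) gives nine theoretical categories A–I. The orientation of
the two opposite-effect classes is a package convention, frozen and covered
by a mirror-symmetry test: H = (STAT2 drop, IRF9 rise), I = the mirror.
Only baseline-induced (UP) genes are classified by default; an analyst can
apply the same grid to downregulated genes by calling `classify_genes()`
on relabelled inputs, but the package's own pipeline does not.

## The count model and the test

Counts are modelled as negative binomial with the standard RNA-seq
parameterisation, Var = μ + αμ². Normalisation uses median-of-ratios size
factors computed over genes positive in every sample and rescaled to
geometric mean 1; when no such gene exists the factors fall back to
relative library sizes with a warning.

The differential test is a Wald test on the log2 ratio of normalised group
means, with a pseudo-count c = 0.5 added to both means so that zero-count
groups give finite fold changes. The standard error propagates the NB
variance of each group mean. Two dispersion modes are provided:

* **`common` (default).** One α shared by all genes, estimated by pooling
  the within-group moment equations across the entire matrix. With three
  replicates per group a per-gene variance estimate rests on four residual
  degrees of freedom and is extremely noisy; pooling across thousands of
  genes makes α essentially exact under the common-dispersion model, and
  the Wald statistic can be referred to the normal distribution. Measured
  on 2000 simulated null genes (μ = 100, α = 0.05, n = 3) the test rejects
  at 5.3–6.2% for a nominal 5% — calibrated — while p-values for strong
  effects remain small enough to survive Benjamini–Hochberg correction in
  sparse-signal contrasts.
* **`genewise`.** The per-gene method-of-moments estimate (pooled over the
  two groups only), floored at 1e-8 and capped at 10. Because the
  statistic's denominator is then itself highly variable, it is referred
  to a Student t on n_t + n_r − 2 degrees of freedom, which restores the
  null calibration (~4.5% at nominal 5%) but bounds the smallest
  attainable p at roughly 2·pt(−|z|max, 4); with three replicates this
  costs substantial power after FDR correction. It is the right choice
  when per-gene dispersions genuinely differ and calibration matters more
  than ranking depth.

The common mode is the package default because the pipeline's deliverable
is a thresholded DEG list per contrast, and with n = 3 the genewise mode
cannot simultaneously hold its size and retain power through the BH step.
This is a modelling assumption, not empirical-Bayes shrinkage: no prior is
estimated and no gene borrows partially from the ensemble. Its known
limitation is real data with strongly mean-dependent dispersion, where a
common α misstates the variance of the extremes; the `genewise` mode and
the rank-based validation below are the guard rails.

Calling thresholds are strict: UP iff log2FC > log2(1.5) and p < 0.05 and
q < 0.05 (DOWN mirrored). A gene sitting exactly at FC = 1.5 is NS. The BH
family is all CPM-passing genes of one contrast — the three contrasts are
corrected separately.

The test is validated against independent oracles rather than against any
reference package: a type-I-error simulation at the design's replicate
number, and rank agreement (Spearman ≥ 0.9) with an exact permutation test
over all C(6,3) = 20 relabelings on small-count genes.

## The ε-centering and its calibration

For clustering, each classified gene contributes a 2-D profile of its two
knockdown log2 fold changes. The pre-clustering transformation

FC_new = FC_old − ε · (mean FC of the gene's category)

is applied coordinate-wise. Two anchor points make its behaviour concrete:
ε = 0 is the identity, and ε = 1 centres every category exactly at the
origin (which *erases* between-category structure — the transformed
centroid is (1 − ε) times the original, so ε < 0 amplifies separation
while ε → 1 collapses it). Because the transformation's useful sign and
magnitude depend on the data, ε is treated as a free calibration
parameter: the grid default [−5, 5] in steps of 0.05 covers both regimes,
and for each candidate the profiles are transformed, clustered
(average-linkage hierarchical clustering on Euclidean distance), cut into
K = number of nonempty categories, and scored by the adjusted Rand index
against the predefined labels. "Perfect match" is operationalised as
ARI = 1. Ties are broken towards the smallest |ε|, then the smallest ε —
the least intervention that achieves the best agreement. Average linkage
is a frozen, configurable choice; the distance metric (Euclidean) is
fixed. With a single nonempty category the agreement is undefined and the
fit returns ε = 0 with `NA` agreement.

On well-separated profiles (centroid gaps ≥ 5 within-category standard
deviations) the calibration attains ARI = 1, frequently already at ε = 0 —
the transformation earns its keep only when categories overlap.

## Module enrichment

Per-category over-representation uses the exact hypergeometric upper tail
including the observed overlap, P[X ≥ b], with BH correction over all
modules of one run. The universe is an explicit parameter; the pipeline
uses all CPM-passing genes. Modules with fewer than 3 genes inside the
universe are skipped by default (configurable): a 1- or 2-gene module
cannot produce a stable enrichment statement. Because the statistic is
discrete, the null rejection rate at p < 0.05 is below 0.05; the test
suite compares the simulated rate against the exact attainable level
P[X ≥ k*] rather than against the nominal one.

## What the generator emulates — and what it does not

`simulation_spec()` defaults define the package's reference conditions:

* 2000 genes, 3 replicates per group, the four-group design above;
* NB counts with a single shared dispersion α = 0.05 (a typical cell-line
  value), log-normal baseline means (median 100, log-sd 1);
* library size factors log-uniform in [0.5, 2], so normalisation is
  genuinely exercised;
* a minority of genes induced: 180 induced across categories
  (A = 40, B = 12, C = 80, D = 12, E = 8, F = 15, G = 12, I = 1) plus 30
  downregulated. The split mirrors the motivating system's findings at
  desk scale: the knockdown-independent class C is the largest, D is
  small, and the opposite-effect classes are essentially absent (H = 0,
  I = 1);
* planted effect magnitudes |log2FC| uniform in [1, 3] by default; the
  validation runs plant |log2FC| = 2 throughout, a strong but realistic
  knockdown effect. No published effect-size distribution exists for this
  design, so these are fixture choices, not claims about any dataset;
* silencing effects multiply the stimulation effect in the corresponding
  stimulated knockdown group only; the unstimulated group sees baseline
  means alone — matching the contrast structure;
* one integer seed drives every draw through a single RNG stream, so the
  whole fixture is bit-reproducible.

Not emulated: gene-length effects (no FPKM modelling), isoform structure,
batch effects, correlated genes, outlier samples, and mean-dependent
dispersion trends. Passing the recovery tests therefore demonstrates that
the pipeline's logic is correct under its stated model — not that real
tissue data will classify with 100% accuracy; on real data the category
boundaries inherit the uncertainty of three-replicate testing near the
thresholds.

Problem sizes used by the validation suite (2000 genes for recovery and
calibration runs, 600–800 for structural checks, 500 resampling replicates
for the discrete-null check) were chosen as the smallest sizes at which
the Monte-Carlo error is comfortably below the tolerances being asserted.

## Numerical and degenerate-input choices

* Dispersion floored at 1e-8 and capped at 10; p-values clamped to
  (0, 1]; identical groups give log2FC = 0, p = 1 exactly.
* Genes dropped by filtering in one knockdown contrast are treated as NS
  there (with a warning) rather than erroring — classification stays
  total over the induced set.
* An empty induced set, an all-filtered matrix, or an empty GMT all
  return empty, well-formed results without error.
* Size-factor estimation requires at least one gene positive everywhere;
  otherwise library-size fallback plus warning.
* The pipeline contains no randomness: rerunning it on the same inputs is
  bit-identical; all randomness lives in the generator behind one seed.

## Interfaces

Every on-disk artifact is plain TSV (tab-separated, '.' decimal, no
quoting) or standard GMT; configuration is YAML read by `read_config()`,
with function arguments (and CLI flags in the wrapper script) taking
precedence over file values. `run_pipeline()` logs stage progress to
standard error and writes results only to files or the returned object.
The package's interface is its functions; `inst/scripts/crosstalk.R`
wraps them in `simulate` / `run-all` subcommands for shell use.
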