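# crosstalkdeg

Classification of a stimulation-induced transcriptome by dual knockdown.

When two cytokines act together they can induce genes through transcription
factors acting jointly, separately, or not at all. Given bulk RNA-seq counts
from a four-group design — unstimulated control, stimulated control, and two
stimulated single-knockdown groups (here siSTAT2 and siIRF9 under combined
IFNβ + TNF stimulation) — this package answers, gene by gene, *which of the
two factors drives each induced gene*, and summarises the answer at the
level of regulation categories and functional gene modules. It is aimed at
computational biologists analysing knockdown/stimulation RNA-seq designs,
and ships a fully specified synthetic-data generator so every stage can be
validated against known ground truth.

## The method

1. **Expression filter.** Keep genes with ≥ 1 count-per-million in ≥ 3
   samples (CPM computed against raw library sizes).
2. **Normalisation.** Median-of-ratios size factors (geometric-mean
   reference), rescaled to geometric mean 1.
3. **Differential expression.** For each of the three contrasts
   (stimulated vs unstimulated control; each stimulated knockdown vs
   stimulated control) a negative-binomial Wald test:
   counts ~ NB(μ, α) with Var = μ + αμ², log₂FC = log₂((m_t + c)/(m_r + c))
   with pseudo-count c = 0.5, dispersion α estimated by method of moments
   (a single common α pooled across genes by default), and
   z = log₂FC / SE referred to the normal distribution. q-values are
   Benjamini–Hochberg within each contrast. A gene is called
   UP/DOWN iff |FC| > 1.5, p < 0.05 **and** FDR < 0.05 (strict).
4. **Category classification.** Every baseline-UP gene is placed on the
   3 × 3 grid of its two knockdown calls: A = (DOWN, DOWN),
   B = (UP, UP), C = (NS, NS), D = (DOWN, NS), E = (UP, NS),
   F = (NS, DOWN), G = (NS, UP), H = (DOWN, UP), I = (UP, DOWN).
5. **ε-calibrated clustering.** Knockdown fold-change profiles are
   centred by FC_new = FC_old − ε·(category mean FC); ε is chosen on a
   grid ([−5, 5] by 0.05) to maximise the adjusted Rand index between an
   average-linkage Euclidean tree cut (K = nonempty categories) and the
   category labels.
6. **Modular enrichment.** Per category, hypergeometric
   over-representation p = Σ_{k≥b} C(B,k)C(N−B,n−k)/C(N,n) against a GMT
   module collection, BH-corrected within each run.

## Worked example

```r
library(crosstalkdeg)

spec   <- simulation_spec(effect_lfc = c(2, 2), seed = 1)
bundle <- simulate_experiment(spec)          # counts, sheet, truth, modules
res    <- run_pipeline(bundle$counts, bundle$sheet, bundle$modules)
print(res)
```

```
crosstalk_result
  genes passing filter: 2000
  stim: 182 UP, 41 DOWN of 2000 tested
  stat2: 21 UP, 52 DOWN of 2000 tested
  irf9: 30 UP, 59 DOWN of 2000 tested
  category counts:  A=40 B=12 C=82 D=12 E=8 F=15 G=12 H=0 I=1
  epsilon = 0 (ARI 1)
```

The simulation planted 40 A, 12 B, 80 C, 12 D, 8 E, 15 F, 12 G and 1 I
gene (plus 30 downregulated and 1790 unregulated): the run recovers all
180 planted labels (the two extra C genes are unregulated genes that
crossed the baseline thresholds), and the ε calibration separates the
occupied categories perfectly (ARI = 1). Per-category enrichment ranks
the five planted modules (`ENR01`–`ENR05`) top-5 in category A and leaves
them non-significant in category C.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/crosstalk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/crosstalk.R", package="crosstalkdeg"))')" \
    simulate --out data/ --seed 17
Rscript .../crosstalk.R run-all --counts data/counts.tsv \
    --samples data/samples.tsv --gmt data/modules.gmt --out results/
```

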