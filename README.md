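# nascentshift

Spike-in-anchored analysis of nascent transcription and FACS-sorted CRISPR
screens, built for the question: *how much does a cell's transcriptional
output change globally after DNA damage, and which genes drive the change?*

Global shifts are invisible to ordinary RNA-seq normalization — equalizing
library sizes erases them by construction. This package analyses the
experimental design that makes them measurable: short-pulse metabolic
labeling (EU) to capture nascent transcripts, plus ERCC spike-ins added in
fixed amount per cell-equivalent as an internal yardstick. It is aimed at
computational biologists analysing nascent RNA-seq with spike-ins, or
pooled knockout screens read out by cell sorting.

## What it computes

**Normalization.** Per-sample scale factors `f_s = E_ref / E_s` from total
spike-in counts `E_s`; normalized counts `x̃ = x · f_s`; class-level totals
(rDNA / histone / protein-coding / all genes) whose condition ratios *are*
the global shift estimate. A `library_size_factors()` foil shows what
conventional normalization misses on the same data.

**Differential testing.** An exact one-tail Poisson two-sample test on raw
pooled counts: conditioning on `n = x_ref + x_alt` makes the perturbed
count `Binomial(n, p0)` with `p0 = w_alt / (w_ref + w_alt)` and exposures
`w` taken from pooled spike-in totals. Benjamini–Hochberg FDR; calls at
fold change ≥ 1.5, FDR < 0.05. Plus per-gene z-score matrices,
spike-anchored RPKM ranking (top-100 highly expressed DEG slices), and
Wilcoxon gene-length comparisons across call groups.

**Metagene profiles.** bedGraph coverage, spike-scaled, averaged over gene
bodies rescaled to 100 bins with 3 kb fixed-width flanks, strand-aware. A
5′/3′ ratio-of-ratios statistic separates initiation-level repression
(uniform body loss, ratio ≈ 1) from elongation-level repression (3′-biased
loss, ratio > 1).

**Screen scoring.** Guide extraction from FASTQ by exact anchor matching;
reads-per-million + 1 normalization; per-guide fold change,
`CRISPR score = log2(FC)`, exact Poisson enrichment p-values (sorted vs
unsorted, population totals as exposures), BH adjustment; gene-level hits
by the at-least-one-guide rule at padj ≤ 0.01 and FC ≥ 1.5.

**Synthetic data.** Generators for count matrices, coverage tracks, guide
libraries/counts and screen FASTQ with recorded ground truth, so every
recovery claim above is tested against programmed truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run the
scripts in order from the repository root (outputs land in `results/`):

```sh
Rscript analysis/01_simulate_nascent.R
Rscript analysis/02_normalize.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_metagene.R
Rscript analysis/05_crispr_screen.R
```

Step 2 prints the headline contrast — the spike-in totals are flat across
samples, so scale factors expose the programmed global decline that
library-size normalization cannot see:

```
condition-level shifts (ir / ctrl), ERCC-normalized:
  rdna               0.503
  histone            0.503
  protein_coding     1.151
  total_non_spikein  0.790
library-size-normalized global shift: 1.000  (blind to the decline)
```

The simulation halved rDNA and histone output (both recovered at 0.503) and
doubled 15% of protein-coding genes (class total up 1.15×); overall nascent
output fell to 0.79 of control. Step 3 then calls the genes:

```
            histone protein_coding rdna
  down           50              7   20
  unchanged       0           1735    0
  up              0            258    0
up calls that were truly programmed up: 98.1%
```

and step 5 scores a simulated screen end-to-end (FASTQ → extraction →
normalization → hits), recovering 20/20 programmed regulators with 0 false
genes at the default thresholds.

## Layout

```
R/                  package code (types/IO, simulators, normalization,
                    differential testing, screen scoring, metagene)
analysis/           numbered narrative workflow over the package
tests/testthat/     unit, property and end-to-end tests
scripts/acceptance.R  from-scratch recomputation of the headline numbers
vignettes/          methods vignette: models, assumptions, design choices
```
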