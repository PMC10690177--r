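---
title: "Spike-in-anchored nascent transcription analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in-anchored nascent transcription analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentshift)
options(nascentshift.log_level = "WARN")
```

## The problem

After DNA double-strand-break damage (e.g. ionizing radiation), cells
transiently shut down much of their transcription. Measuring that shutdown
with RNA-seq is harder than it sounds: most normalization schemes equalize
total signal between samples and therefore erase exactly the global shift
one wants to measure. Two experimental handles make it tractable:

* **Metabolic labeling** (a uridine analog such as EU, incorporated during a
  short pulse) isolates *nascent* transcripts — what polymerases made during
  the labeling window — instead of the slowly-turning-over steady-state pool.
* **ERCC spike-ins** — 92 synthetic RNA standards added in fixed amount per
  cell-equivalent — provide an internal yardstick that experiences the
  sample's sequencing depth but not its biology.

`nascentshift` implements the computational side of this design: spike-in
scale factors and normalized count matrices, an exact one-tail Poisson test
for differential nascent transcription, expression- and length-stratified
summaries, spike-scaled metagene profiles with an initiation-versus-
elongation statistic, and enrichment scoring for a FACS-sorted pooled CRISPR
screen that looks for genes required for the shutdown. A synthetic-data
generator with recorded ground truth makes every claim testable.

## Normalization model

Let $E_s$ be the total spike-in read count of sample $s$. The scale factor
of $s$ relative to a reference sample $r$ is

$$ f_s = E_r / E_s, $$

and normalized counts are $\tilde{x}_{gs} = x_{gs} f_s$. After scaling, the
total spike-in signal is identical across samples by construction; any
remaining difference in class totals (rDNA, histone, protein-coding, or all
genes pooled) is a biological shift. Because factors are ratios, every
downstream ratio is invariant to the choice of reference (a tested
property); the default reference is the first sample in column order.

`library_size_factors()` implements the conventional alternative —
normalizing by total gene reads — purely as a foil: it equalizes the
non-spike-in totals by construction, so its estimate of any global shift is
1. The package tests assert both behaviours side by side on data with a
programmed shift.

**RPKM.** The expression ranking uses an ERCC-anchored RPKM: for gene $g$
with body length $L_g$ and condition mean normalized count $\bar{x}_g$,

$$ \mathrm{RPKM}_g = \frac{\bar{x}_g \cdot 10^9}{L_g \cdot T}, \qquad
   T = \sum_{g'} \bar{x}_{g'} \text{ (non-spike-in)} . $$

With all factors at 1 this is standard RPKM. The denominator after spike-in
normalization is a convention choice; any monotone variant preserves the
ranking, which is the only use this quantity has here. Ties rank
lexicographically by feature id so slices are reproducible.

## The exact one-tail Poisson test

Counts for gene $g$ are modelled $X_c \sim \mathrm{Poisson}(\lambda_c w_c)$
per condition $c$, where the exposure $w_c$ is the pooled spike-in total of
the condition's samples (a deeper-sequenced condition is expected to
collect proportionally more reads under the null
$\lambda_{\mathrm{ref}} = \lambda_{\mathrm{alt}}$). Conditioning on
$n = x_{\mathrm{ref}} + x_{\mathrm{alt}}$ gives

$$ X_{\mathrm{alt}} \mid n \;\sim\; \mathrm{Binomial}\!\left(n,\;
   p_0 = \frac{w_{\mathrm{alt}}}{w_{\mathrm{ref}} + w_{\mathrm{alt}}}\right), $$

and the one-tail p-value is the exact binomial tail in the direction of the
observed normalized fold change (no doubling; $n = 0$ gives $p = 1$). The
test runs on raw integer counts with exposures — rescaled non-integer counts
never enter a likelihood. Replicates are pooled by summing raw counts:
Poisson sums are Poisson, so the pooled count is the sufficient statistic. A
per-replicate-pair mode (keeping each gene's least significant pair) is
available for sensitivity analysis.

Calls use fold change $\geq 1.5$ (computed on normalized pooled counts with
a pseudocount, default 1 normalized unit) and Benjamini–Hochberg FDR
$< 0.05$. BH runs jointly across all tested (non-spike-in) features, so the
histone- or rDNA-restricted summaries are plain subsets of one result table
rather than separately adjusted analyses. The BH step-up is implemented
in-package (three lines: sort, scale by $m/i$, running minimum) and is
checked for exact agreement against `stats::p.adjust` on $10^4$ random
vectors.

Z-score heatmap values standardize each gene across all samples with the
sample ($n-1$) standard deviation; zero-variance rows map to all zeros
rather than NaN. Z-scores are computed on normalized counts: raw counts
would fold the depth differences back in.

**Gene length.** Gene "size" is the annotated body span (end − start), not
summed exon length — nascent transcription covers introns, and the body span
is the quantity the coverage profiling uses. Length comparisons between
activated/unchanged/repressed groups use the two-sided Wilcoxon rank-sum
test, exact when both groups have ≤ 10 genes and the normal approximation
with continuity correction above; fully tied groups report $p = 1$ and empty
groups report NA rather than erroring.

## Screen scoring

Guides are recovered from reads by exact anchor matching: the first exact
occurrence of the 5′ anchor, the next 20 nt as candidate guide, and an
immediately following exact 3′ anchor; the candidate must match a library
sequence exactly. No mismatch tolerance is allowed — fuzzy matching would
change counts silently, and the round-trip identity (simulated counts →
FASTQ → extraction) would no longer be exact. Everything else counts as
unassigned.

Per population, normalized abundance is reads-per-million plus one:
$\tilde{n} = (x / N) \cdot 10^6 + 1$, so unobserved guides get 1 and ratios
stay finite. Then per guide:

* fold change $\mathrm{FC} = \tilde{n}_{\mathrm{sorted}} /
  \tilde{n}_{\mathrm{unsorted}}$;
* $\mathrm{CRISPR\ score} = \log_2 \mathrm{FC}$;
* enrichment p-value from the same exact conditional test, raw counts with
  population totals as exposures, tail fixed to enrichment (the sort
  selects EU-high cells, so the screen's signal is one-sided);
* BH across all guides jointly (not per gene).

A guide passes at adjusted $p \leq 0.01$ and $\mathrm{FC} \geq 1.5$; a gene
is a hit when at least one of its guides passes. The one-guide rule is
deliberately sensitive — with 5 guides per gene and partial knockout
efficiency it trades specificity for recall, which the per-gene
`n_guides_passing` column lets users re-tighten.

## Metagene profiles

Coverage is held as run-length-encoded per-base values built from 4-column
bedGraph (0-based half-open; overlapping intervals are an input error,
uncovered bases read 0). All genomic coordinates in the package are 0-based
half-open; GTF input is converted on read, which removes a whole class of
off-by-one bugs between annotation and coverage.

Each gene body is rescaled to `body_bins` bins (default 100): base $i$ of an
$L$-bp body joins bin $\lfloor i \cdot \mathrm{bins} / L \rfloor$, a
deterministic floor rule with no platform-dependent rounding. Flanks
(default 3 kb) are binned at fixed width (default 60 bins of 50 bp). Minus-
strand windows are reversed before binning so bin 1 is always 5′. The
profile is the unweighted mean across genes — each gene counts equally, the
usual average-profile semantics; genes shorter than the bin count are
skipped with a logged warning and a tally rather than silently dropped.

The initiation-versus-elongation statistic compares body ends: $r_5$ and
$r_3$ are the means of the first and last half of the body bins (the window
is configurable; the half-split is the default since "ends" has no canonical
width), and the cross-condition readout is

$$ R = \frac{(r_5/r_3)_{\mathrm{alt}}}{(r_5/r_3)_{\mathrm{ref}}} . $$

$R \approx 1$ means coverage dropped uniformly along the body — polymerases
were lost everywhere at once, the signature of reduced initiation. $R > 1$
means 3′-biased loss, as a block to elongation would produce. On
constructed tracks the statistic is exact: body-wide halving gives $R = 1$,
halving only the 3′ half gives $R = 2$.

## What the simulator emulates — and what it does not

`simulate_nascent_experiment()` draws every count independently Poisson with
mean `baseline(gene) × fold-change(gene, condition) × depth(sample)`.
Spike-in means multiply by depth but never by condition — that conditional
independence *is* the spike-in assumption, and a property test confirms the
ERCC ratio between conditions tracks programmed depth, not biology.

Defaults mirror the modelled experiment and were fixed once: 2 conditions ×
2 replicates; 92 spike-ins; 20 rDNA-like features at 100× the
protein-coding baseline (rDNA dominates nascent RNA); 50 histone-like genes
at 10×; rDNA and histone halved in the perturbed condition; 15% of
protein-coding genes doubled. Per-gene baselines spread log-uniformly
(default 10× either way) so expression rankings exist; body lengths are
class-realistic (rDNA repeat units ≈ 13 kb, histone genes ≈ 0.6 kb and
intronless, protein-coding broad around 2.5 kb), which is what makes the
length stratification scientifically meaningful rather than decorative.

The screen simulator draws a log-normal library skew (σ = 0.5) so
normalization is non-trivial, Poisson unsorted counts at the requested
depth, and sorted counts around skew × programmed guide fold change,
renormalized — sorting changes composition, not depth. Regulators get the
enrichment on 3 of 5 guides by default, reflecting partial guide efficacy.

Deliberate omissions, hence limits on what green tests show about real
data: **no overdispersion by default** (the inference is exact under the
Poisson model it assumes; an optional negative-binomial switch `nb_size`
exists for robustness experiments, and on real biological replicates the
Poisson test will be anti-conservative), no batch or GC effects, no
mapping/multimapping artifacts (the rDNA-first alignment step of a real
pipeline is represented by the class label on count rows), no doublet
spike-in dose errors, and read-level RNA-seq is not simulated — counts are
the unit everywhere except the screen FASTQ, which exists to exercise the
extraction path.

Determinism: each generator derives a private stream from its seed via a
stable sub-seed, so adding a new generator call never perturbs existing
outputs; identical seeds give bitwise-identical artifacts.

## Numerical and design choices

* Exact binomial tails come from `pbinom`; the package's own tests compare
  them against independent log-space term summation to $10^{-12}$ over all
  count pairs up to 50 at three exposure ratios.
* Output tables render floats at 6 significant digits; write/read
  round-trips reproduce values to that precision, keeping diffs stable.
* The fold-change pseudocount (default 1 normalized unit) only matters for
  near-zero genes; the exact test, not the fold change, carries the
  inference.
* Problem sizes in the test-suite and acceptance runs (2,000-gene
  matrices, 20-seed replications, one full-depth 10^6-read screen
  round-trip) were chosen as the smallest scales at which the law-of-large-
  numbers claims they verify hold comfortably.
* `call_degs` exposes `ref_condition`; condition order in the input is
  otherwise the only thing that distinguishes reference from perturbed.

## Worked mini-example

```{r example}
cfg <- nascent_sim_config(n_protein_coding = 300, rng_seed = 42)
sim <- simulate_nascent_experiment(cfg)
sf <- compute_scale_factors(sim$counts)
nm <- normalize_counts(sim$counts, sf)
ct <- compute_class_totals(nm)$per_condition
reshape(ct, idvar = "class", timevar = "condition", direction = "wide")

res <- call_degs(sim$counts, sf)
table(res$call, res$class)
```

The rDNA and histone totals drop by half after normalization while the
spike-in totals match exactly; the call table recovers the programmed
structure (all rDNA/histone features down, a subset of protein-coding genes
up).

## Known limitations

* Poisson-only inference: real replicate variability will inflate false
  positives; treat calls on real data as a ranking and validate.
* The one-guide hit rule is sensitive, not specific; require
  `n_guides_passing >= 2` for a conservative list.
* RPKM here is a ranking key anchored to spike-ins, not an absolute
  abundance estimate.
* The 5′/3′ statistic summarizes the body halves; localized promoter-
  proximal effects need the full profile, which is always emitted.
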