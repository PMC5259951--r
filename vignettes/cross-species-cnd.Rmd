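---
title: "Detecting gene copy-number divergence by cross-species array-CGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene copy-number divergence by cross-species array-CGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(xscnd)
library(dplyr)
```

## The problem

Array comparative genomic hybridization (array-CGH) infers DNA copy
number from the hybridization signal of genomic DNA on a microarray.
Used *across* species — genomic DNA of a relative hybridized to an
array designed for a reference species — it can reveal which gene
families have expanded or contracted since the two species diverged.
The catch is that the heterologous targets inevitably carry sequence
mismatches against the 25-mer probes, and every mismatch weakens
hybridization. Without correction, the dimmer heterologous signal is
misread as genome-wide copy-number loss.

`xscnd` implements a two-step normalization that addresses this
directly:

1. **Within-species normalization.** Replicate hybridizations of each
   species are background-corrected, masked, and calibrated onto a
   common scale with a variance-stabilizing generalized-log transform.
2. **Between-species global scaling.** The average signal loss caused
   by probe–target mismatches is estimated from a small curated
   *reference dataset* of genes whose heterologous sequences are known,
   and the entire heterologous data set is multiplied by the resulting
   global scaling factor.

Scaled signals are then compared gene by gene with a moderated
probe-level test, and genes are classified as copy-number expanded
(CNE), copy-number reduced (CNR) or neutral.

## The mismatch model

Each of the $n = 25$ probe positions either matches its target or not,
so the number of mismatches $k$ per probe is modelled as
$K \sim \mathrm{Binomial}(n, p)$. The default per-base mismatch
probability $p = 0.06$ corresponds to 94% average coding-sequence
identity between the hybridized species pair; at these values more than
four mismatches are expected for only about 1.5% of probes, which
motivates truncating the correction at $k_{\max} = 4$.

```{r binomial}
m <- mismatch_model(n = 25, p = 0.06, kmax = 4)
round(mismatch_pmf(m, 0:5), 4)
round(1 - sum(mismatch_pmf(m, 0:4)), 4)   # P(K > 4)
```

`mismatch_gof()` checks an observed mismatch histogram against this
expectation with a Pearson chi-square test, pooling the upper tail
(default at $k \ge 4$) so no bin has a vanishing expected count. The
upper-tail p-value is computed from the standard chi-square
distribution.

## Incremental and global correction factors

For the reference-dataset probes with exactly $k$ mismatches, the
incremental correction factor is the arithmetic mean of the
homologous-to-heterologous intensity ratios,

$$S_k = \frac{1}{N_k} \sum_{i=1}^{N_k} \frac{H_{ik}}{I_{ik}},$$

and the global factor is the binomial-weighted combination truncated at
$k_{\max}$:

$$S = \sum_{k=0}^{4} S_k \, P_n(k).$$

Two numerical choices deserve note:

* The truncated weights sum to $\approx 0.985$, not 1, so all-unit
  $S_k$ give $S \approx 0.985$. This is the literal definition and the
  package's default; `renormalize = TRUE` divides the weights by their
  sum for users who prefer unit factors to map to exactly 1.
* Replicates are averaged per probe *before* the ratio is formed
  (ratios of means). This damps the heavy right tail that ratios of
  noisy low-intensity values otherwise develop. The mean-of-ratios
  estimator is still mildly upward-biased for low-intensity probes —
  a property of the published estimator itself, visible in the
  simulations below.

A stratum with fewer than `min_probes = 2` probes is filled by linear
interpolation from its neighbours (with a warning); a fitted $S_k$
sequence that decreases in $k$ triggers a warning rather than an error,
because measured attenuation curves plateau after the first mismatch.

Whether the published ratios used normalized or raw background-corrected
intensities is ambiguous in the source material; the `value_col`
argument of `scaling_factors()` exposes both (the calibrated linear
scale is the default).

## Preprocessing choices

**Background.** Without chip geometry (the package reads tabulated
intensities, not binary chip files), zone-based background estimation
is undefined. The package subtracts a per-sample low-quantile floor
($q = 0.02$ by default) instead, preserving the contract — remove the
additive offset, keep positivity. The clamp after subtraction is
*proportional* to the sample's own background,
$\max(\varepsilon, 0.05 \cdot \mathrm{bg})$: clamping both species to
one absolute constant would map sub-background probes of a dim
heterologous hybridization and a bright homologous one onto the same
value, and the subsequent $\times S$ scaling would then fabricate
consistent spurious positive ratios among low-intensity genes. With the
proportional clamp those probes keep a comparable relative level in
both species and fall out as neutral.

**Normalization.** Full maximum-likelihood variance-stabilizing
normalization is replaced by a deterministic two-parameter calibration
per sample: the scale $b_s$ equalizes the MAD across replicates (a
replicate measured at twice the gain gets half the scale) and the
offset $a_s$ then matches the medians; the transform is
$h(x) = \mathrm{glog}_2(a_s + b_s x)$ with
$\mathrm{glog}_2(y) = \log_2(y + \sqrt{y^2 + 1}) - 1$, which equals
$\log_2 y$ in the large-signal limit. The calibration is monotone, so
within-sample ranks are untouched. Gene-level ratios are computed on
the back-transformed calibrated linear scale; the glog scale is used
for variance stabilization diagnostics.

## Calling copy-number divergence

Probe-level $\log_2(\mathrm{het}/\mathrm{home})$ ratios are formed per
replicate pairing. For each probeset the fold change is the unweighted
mean over probes and replicates (the median is available via
configuration), and "mean ratio = 0" is tested with probe as a blocking
factor: the residual variance is the within-probe between-replicate
variance on $d$ degrees of freedom. Variances are shrunk across
probesets, empirical-Bayes style,

$$s^2_{\mathrm{mod}} = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

with $(d_0, s_0^2)$ estimated by method of moments from the marginal
scaled-$F$ distribution of the $s^2$; the moderated $t$ is referred to
$t_{d_0 + d}$. When the moment system is degenerate (homogeneous
variances) the estimate collapses to complete pooling, which is the
correct limit. The test suite cross-checks this moderated test against
an independent moderated-variance implementation and verifies that null
p-values are uniform.

Calling uses the published thresholds: CNE requires
$\log_2 \mathrm{ratio} \ge 1$ and Benjamini–Hochberg adjusted
$p \le 0.1$; CNR the mirror image. BH is applied across all callable
probesets (probesets with at least 3 unmasked probes); whether the
original analysis adjusted over all or only fold-change-passing
probesets is unstated, and all-callable is the more conservative
default. Probesets mapping ambiguously to several gene ids are carried
as one unit keyed by `probeset_id`.

**A knife-edge worth knowing about.** A clean 2× duplication has true
$\log_2$ ratio exactly 1 — *on* the calling threshold. Any unbiased
estimate therefore exceeds the threshold only about half the time; the
observed sensitivity for 2× events rides on the small upward bias of
the arithmetic-mean scaling estimator and fluctuates between datasets.
Sensitivity figures for 2× gains should always be read with this in
mind (3× and larger expansions sit far from the threshold and are
essentially always recovered); it also mirrors the low-sensitivity /
high-specificity character of the published validation. The package's
own checks measure this sensitivity pooled over three replicate
simulations for a stable estimate.

## Validation metrics and baselines

`confusion_metrics()` scores calls against a truth set of genes with
known copy number: sensitivity ($TP/(TP+FN)$), specificity
($TN/(TN+FP)$) and precision ($TP/(TP+FP)$), as percentages; truth
genes missing from the calls count as predicted-negative with a
warning, and precision is `NA` when nothing was predicted positive.

Two previously published cross-species array-CGH callers are
re-implemented for head-to-head comparison:

* **Conserved-gene loess** (`baseline_conserved_loess()`): loess
  normalization (local linear regression, tricube weights, span 0.5 —
  the span and the exact average-difference variant are unstated in the
  original, so these defaults are documented here) fitted on the probes
  of up to 1,000 conserved single-copy genes, average-difference
  probeset summarization with a single 3-SD trim whose centre and
  spread are computed after dropping the extremes, and calling at
  $\log_2$ ratio $\gtrless 0$ with adjusted $p \le 0.1$.
* **Affinity + control probes** (`baseline_affinity_scaled()`):
  probe-level adjustment of $\log_2$ intensity on the nearest-neighbour
  duplex free energy $\Delta G_{37}$ (unified parameter table at 37 °C,
  1 M NaCl; salt correction omitted, matching the use of a stock
  calculator), scaling by the control-probe median, probeset-mean
  ratios, thresholds $\pm 0.25$.

Both baselines use more lenient thresholds than the main caller and are
accordingly more sensitive but far less precise on data with realistic
mismatch attenuation — the directional property asserted by the test
suite.

## Over-representation analysis

`ora()` tests each functional category for enrichment in a gene list
against the array background with a one-sided Fisher's exact test
(enrichment is the ORA convention; a two-sided variant is a flag),
BH-adjusted across categories at $\alpha = 0.05$. Hierarchical category
codes collapse to their top level by default, and multi-category genes
count once per category.

## Segment scan

Large segmental events are detected from gene-level calls: a 20-kb
window slides in 10-kb steps along each chromosome; a window is
positive for a class when at least 5 kb of it is covered by gene bodies
of that class (gene intervals are merged first, so overlapping genes
are not double-counted — coverage, rather than a contiguity
requirement, is the operationalization chosen here because it is
well-defined and testable); a window reaching 5 kb for *both* classes
is ambiguous and scored `none` with a warning. Three or more
step-adjacent concordant positive windows merge into one segment, so
the minimal segment spans 40 kb. Windows are anchored at position 0 and
always span the full window width; a trailing window is kept while at
least half of it lies on the chromosome.

## The synthetic-data generator

`simulate_dataset()` generates the full input bundle with known truth:

* probe 25-mers drawn uniformly; heterologous targets by per-base
  substitution with probability 0.06, giving exact mismatch counts;
* signal attenuation $\alpha_k$ per mismatch count: $\alpha_0 = 1$,
  $\alpha_1 = 0.63$ (the midpoint of the 34% and 40% single-mismatch
  losses measured in the two heterologous species), then a geometric
  0.928 per further mismatch so that four mismatches sit a further
  ~20% below one — a qualitative emulation of the measured plateau,
  not a reproduction of it;
* gene baseline intensities log-normal ($\log_2$ mean 9, SD 1), probe
  affinity effects (SD 0.5), independent replicate noise (SD 0.25 on
  the $\log_2$ scale), two replicates per species;
* planted copy states: 5% of genes at 2× (CNE truth) and 5% at 0.5×
  (CNR truth), optionally clustered into contiguous blocks to exercise
  the segment scanner;
* a 20-category map with one planted category enriched 2-fold among
  the CNE genes. The planted category's baseline frequency is 25% of
  genes — the size of the largest real top-level functional classes —
  because a 2-fold enrichment of a *small* category is statistically
  undetectable in a ~100-gene list: with a one-sided Fisher test and
  BH over 20 categories, detection with probability well above 0.9
  requires the in-list count to clear roughly
  $nf + 2.8\sqrt{nf(1-f)}$ at list size $n = 100$, which a base
  frequency $f \approx 0.25$ satisfies with margin ($z \approx 2$)
  while $f \approx 0.08$ does not ($z < 0$ relative to the needed
  threshold about half the time);
* a deterministic genome layout: 2-kb genes every 5 kb across two
  chromosomes.

What the generator does **not** emulate: chip spatial artifacts and
defects, mismatch-position effects (deliberately, since the measured
position profile is noisy and the method ignores position),
cross-hybridization between paralogs, probe GC-content biases
correlated with binding affinity, and non-multiplicative noise. Passing
tests on this generator therefore demonstrate the internal consistency
and statistical calibration of the method, not its performance on real
hybridizations.

`make_reference_subset()` mirrors the construction of the curated
reference dataset: a random draw of single-copy genes (default 40,
matching the scale of the 33- and 44-gene curated sets), excluding
planted divergent genes just as known expanded genes were removed from
the curated reference.

## Problem sizes and runtimes

The test suite and the acceptance script use 2,000-gene genomes with 11
probes per gene and 2 replicates per species (≈ 88,000 intensity
values per dataset) for calibration and power measurements, 200 probes
per mismatch stratum for scaling recovery, and 250–1,000-gene genomes
for the baseline comparisons and segment scans. These sizes keep every
check inside a few seconds while leaving the binomial sampling error of
the measured rates well below the asserted margins.

## Known limitations

* The global factor corrects the *average* mismatch attenuation; a
  gene whose probes happen to carry many (or few) mismatches retains a
  residual bias of up to a few tenths of a $\log_2$ unit. This is
  inherent to the published design, which deliberately avoids
  per-probe correction outside the reference dataset.
* Sensitivity for events at exactly the calling threshold (2× gains,
  0.5× losses) is a knife-edge quantity (see above).
* The arithmetic-mean $S_k$ estimator is upward-biased under
  multiplicative noise; at the default noise level the bias is ~1.5%
  per stratum and partially compensates the knife-edge effect.
* Alignment of probes to heterologous genomes (the source of the
  mismatch table) is treated as upstream input, as is orthology
  assignment for truth sets.
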