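# xscnd — cross-species array-CGH detection of copy-number divergence

`xscnd` finds genes whose copy number has diverged between a reference
species and a heterologous relative, from comparative genomic
hybridization (array-CGH) of genomic DNA on a short-oligonucleotide
(25-mer probe) microarray designed for the reference species. Its
audience is comparative genomicists working with species pairs where
only the reference has an array (or a genome): the classic setting is a
model plant and its congeneric relatives.

The obstacle in cross-species hybridization is sequence divergence:
heterologous targets mismatch the probes, every mismatch attenuates the
signal, and uncorrected data look like genome-wide loss. `xscnd`
corrects this with a binomial mismatch model and a global signal
scaling estimated from a small curated reference dataset:

- mismatches per 25-mer probe: K ~ Binomial(n = 25, p = 0.06)
  (p from ~94% average coding-sequence identity);
- incremental correction factor per mismatch count, from the reference
  dataset: S_k = (1/N_k) Σ_i H_ik / I_ik (homologous over heterologous
  intensity, probes with exactly k mismatches);
- global scaling factor: S = Σ_{k=0..4} S_k · P_n(k), applied
  multiplicatively to all heterologous intensities.

Scaled signals are tested probe-wise per gene with a moderated
(empirical-Bayes) linear model; genes with log2 ratio ≥ 1 and
BH-adjusted p ≤ 0.1 are called copy-number expanded (CNE), ≤ −1
copy-number reduced (CNR). Around this core the package provides
within-species variance-stabilizing normalization, validation metrics
against truth sets, Fisher's-exact over-representation analysis of
functional categories, a 20-kb/10-kb sliding-window scan for large
divergent segments, two previously published baseline callers for
comparison, and a fully seeded synthetic-data generator with planted
copy states. All user-facing functions take and return tibbles; fitted
objects support `tidy()`/`glance()` and results have `autoplot()`
methods. See the methods vignette (`vignettes/cross-species-cnd.Rmd`)
for the model details and design choices.

## Worked example

Simulate a 2,000-gene two-species experiment with 5% planted 2×
expansions and 5% planted 0.5× reductions, draw a 40-gene single-copy
reference subset, and run the full pipeline:

```r
library(xscnd)

ds  <- simulate_dataset(sim_config(), seed = 1)
ref <- make_reference_subset(ds, n_genes = 40, seed = 2)
res <- run_cnd_pipeline(ds$intensities, ref$mismatch, gene_map = ds$probes)
res
#> <cnd_pipeline> 2000 probesets tested; global S = 1.5470
#> calls: 107 CNE, 89 CNR
res$scaling
#> <scaling_factors>
#> # A tibble: 5 × 4
#>       k n_probes   s_k estimated
#>   <int>    <int> <dbl> <lgl>
#> 1     0       90 0.920 TRUE
#> 2     1      135 1.53  TRUE
#> 3     2      116 1.80  TRUE
#> 4     3       69 2.03  TRUE
#> 5     4       24 2.32  TRUE
#> global S = 1.5470 (renormalized = FALSE)
```

The fitted incremental factors rise with the mismatch count — one
mismatch costs roughly a third of the signal — and combine into a
global scaling factor S = 1.55 for this species pair. Scoring the calls
against the planted truth:

```r
confusion_metrics(res$calls, ds$truth, positive_class = "CNE")
#> # A tibble: 1 × 7
#>      tp    fp    tn    fn sensitivity specificity precision
#>   <int> <int> <int> <int>       <dbl>       <dbl>     <dbl>
#> 1    96    11  1889     4          96        99.4      89.7
```

96 of the 100 planted duplications are recovered at 99.4% specificity.
Over-representation analysis of the CNE list against the array
background recovers the planted enriched category (`B01`, 2-fold
enriched among planted expansions) at the top:

```r
cne <- subset(res$calls, cnd_class == "CNE")$probeset_id
head(ora(cne, ds$categories, res$calls$probeset_id), 1)
#> # A tibble: 1 × 9
#>   category in_list in_background pct_list pct_background  fold   p_raw    p_adj
#>   <chr>      <int>         <int>    <dbl>          <dbl> <dbl>   <dbl>    <dbl>
#> 1 B01           52           513     48.6           25.6  1.89 1.25e-7  2.50e-6
```

`autoplot(res$calls)` draws the volcano of calls and
`autoplot(res$scaling)` the S_k curve. A thin command-line wrapper over
the same functions is installed at `inst/cli/xscnd.R`
(`Rscript xscnd.R simulate|run|validate|enrich|segments ...`).

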