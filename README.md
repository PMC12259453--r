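# tcrcyto

Integrated analysis of T-cell receptor (TCR) beta-chain repertoires and
multiplex cytokine panels profiled in paired cerebrospinal fluid (CSF) and
blood — the setting of a multiple sclerosis (MS) case–control study with an
external healthy-donor reference repertoire cohort. The package is aimed at
neuro-immunology groups who have immunoSEQ-style rearrangement exports and a
48-analyte bead-panel table per patient and want to go from those raw files
to correlation networks, clone-sharing statistics, disease-associated
sequence clusters and sequence–cytokine association tables in a single
reproducible pipeline.

## What it computes

**Cytokine networks.** Raw concentrations are screened for outliers with the
IQR rule (flag `x` if `x < Q1 − 2·IQR` or `x > Q3 + 2·IQR`, type-7
quartiles), transformed as `log2(x + 1)`, and Winsorized at the 12.5%
quantile of each tail. All analyte pairs are then correlated (Pearson, on
pairwise-complete samples) and an edge is kept iff

```
|r| ≥ 0.6   and   p_BH < 0.05
```

with Benjamini–Hochberg control per (group, compartment) matrix. Clusters
are the connected components; layouts use the seeded Fruchterman–Reingold
algorithm.

**Repertoire statistics.** Clonotypes are collapsed to CDR3 amino-acid
identity (template counts summed). Per patient, a clone found in both CSF
and blood is *shared*, in one compartment *unique*; a clone found in more
than one individual is *public*. The package reports both recovery
directions per patient (% of blood clones also in CSF and vice versa),
Simpson clonality `sqrt(Σ p_i²)`, per-sample template totals and maximum
clone frequency, TRBV gene usage with Mann–Whitney/BH comparisons, and
Fisher's exact test (conditional-MLE odds ratio) for HLA carriage tables.

**PRS clustering.** Potentially relevant sequences (PRS) are CDR3.aa that
are top-10 by clone count (count ≥ 2) in some MS CSF sample, or occur in ≥ 2
MS CSF samples. Their per-sample clone-count ranks over the MS blood +
healthy reference samples feed k-means (k = 2); the cluster with higher mean
MS occurrence is the MS-associated cluster, visualised by PCA and tested
with Welch's t-test on per-sequence occurrence.

**TCR–cytokine integration.** Public sequences (≥ 2 samples) that are either
present in ≥ 5 MS patients and no control, or ≥ 10-fold enriched in mean
blood clone proportion in MS, are correlated with blood cytokine levels by
tie-corrected Kendall tau-b; associations are significant at BH-adjusted
p < 0.05 and `|tau| > 0.5`, and are tabulated per analyte and functional
category.

**Synthetic cohorts.** `simulate_cohort()` generates a full study with known
ground truth — planted fold changes, correlation blocks, sharing rates,
MS-enriched sequences and copula-planted Kendall links — so every stage of
the pipeline is validated by parameter recovery.

## Worked example

```r
library(tcrcyto)

cohort <- simulate_cohort(cohort_config(seed = 7))
ledger <- clone_ledger(cohort$rearrangements)

sharing <- sharing_summary(ledger)
glance(sharing)
#> # A tibble: 2 × 8
#>   direction            n_ms n_ctrl mean_ms mean_ctrl statistic    df p_value
#>   <chr>               <int>  <int>   <dbl>     <dbl>     <dbl> <dbl>   <dbl>
#> 1 pct_shared_of_blood    21      9   0.107    0.0333      3.33  28.0 0.00244
#> 2 pct_shared_of_csf      21      9   0.530    0.167       3.32  28.0 0.00250
```

On this simulated cohort, 0.53% of the CSF-detected clones of an average MS
patient are recovered in the paired blood versus 0.17% in controls (the
generator planted 0.5% vs 0.1%), and Welch's t-test flags the difference
(p ≈ 0.0025). The same session recovers a planted sequence–cytokine link:

```r
pred  <- select_predominant(ledger)
assoc <- associate_cytokines(pred, ledger, cohort$cytokines$blood)
dplyr::filter(assoc, significant)[, c("cdr3_aa", "analyte", "tau", "adjusted_p")]
#> # A tibble: 2 × 4
#>   cdr3_aa         analyte   tau adjusted_p
#>   <chr>           <chr>   <dbl>      <dbl>
#> 1 CASSRKREKAQPQHF TNF-b   0.8     0.000282
#> 2 CASSRKREKTTQYF  Eotaxin 0.771   0.000360
```

Two of the three links planted at Kendall tau 0.7 cross the double threshold
in this replicate (the third lands at tau 0.51 and misses it) — at n = 21 MS
blood samples the tau estimate is noisy, which is why recovery is asserted
across 200 replicate cohorts in the test suite rather than on any single
one. `run_pipeline(pipeline_config(outdir = "run1", seed = 7))` executes the
whole chain and writes per-stage artifacts plus `report.json`.

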