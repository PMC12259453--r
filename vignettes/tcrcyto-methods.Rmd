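---
title: "Methods: integrated TCR-repertoire and cytokine-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated TCR-repertoire and cytokine-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcyto)
```

# Overview

`tcrcyto` links two data modalities measured on the same patients: a
48-analyte multiplex cytokine panel and deep TCR-beta CDR3 sequencing, each
in two compartments (cerebrospinal fluid and peripheral blood), for a
case-control design (MS patients vs non-inflammatory controls) with an
external healthy-donor blood repertoire as reference. This vignette
documents the statistical procedures, their assumptions, every tunable
parameter, the synthetic-data model used for validation, and the numerical
conventions that a reimplementation would need to match our outputs.

# Cytokine preprocessing and group comparison

Raw concentrations (pg/mL) arrive as a samples-by-analytes matrix with a
not-detected mask: values below the assay's detection limit carry no
number and are excluded from every quantile, test and correlation
(pairwise-complete handling), never imputed.

The preprocessing chain is fixed, in this order:

1. **Outlier screening (IQR rule).** Within each (analyte, group), values
   below `Q1 - k*IQR` or above `Q3 + k*IQR` are flagged (`k = 2`; strict
   inequalities, so a constant analyte flags nothing). Quartiles need at
   least 4 detected values; sparser analyte/group pairs are skipped with a
   warning. A *sample* is removed when it is flagged in at least 25% of
   the analytes evaluated for it (`sample_flag_fraction = 0.25`). The
   per-cytokine rule is standard; how many analyte flags justify dropping
   a whole sample is a judgement call, so the threshold is exposed and the
   report lists every flagged cell.
2. **`log2(x + 1)`.** Variance stabilisation; the pseudocount of 1 keeps
   true zeros finite.
3. **Winsorization.** Each analyte's transformed values are clamped to its
   12.5% and 87.5% quantiles (`tail_prob = 0.125` per tail) to blunt the
   influence of extreme measurements on Pearson correlation.

**Quantile convention.** One convention is used everywhere (outlier bounds
and Winsorization): linear interpolation between order statistics, i.e.
`stats::quantile(type = 7)`. A consequence worth knowing: with an
interpolated quantile, winsorizing twice is exactly equal to winsorizing
once only when the tail index `(n - 1) * p + 1` lands on an order
statistic (e.g. n = 9, 17, 41 at p = 0.125); otherwise the second pass
moves the clamped extremes by a small amount. The tests assert exact
idempotence on aligned lengths and, everywhere, equality with a direct
order-statistic clamping oracle.

**Group comparison.** Per analyte, MS vs control on the *raw* scale:
Mann-Whitney U by default (rank-based, so indifferent to the monotone
transforms) or Welch's t. The fold change is the ratio of raw group means;
the ratio of medians is also reported, because a mean- vs median-based
fold cannot be distinguished from published two-digit fold values alone.
BH adjustment runs across the analytes of one compartment (not across
compartments), matching per-panel reporting; significance is
`adjusted p < 0.05`.

**Mann-Whitney details.** For group sizes up to 12 the two-sided p-value
is exact: the permutation distribution of the rank sum conditional on the
observed tie pattern is built by dynamic programming over subsets (doubled
mid-ranks keep the grid integral), and the p-value is the probability of a
deviation from the null mean at least as large as observed. Beyond that,
a normal approximation with tie correction and continuity correction is
used. The exact path is checked against full subset enumeration and, in
the tie-free case, against the exact Wilcoxon distribution.

# Correlation networks

All unordered analyte pairs of one preprocessed (group, compartment)
matrix are correlated with Pearson's r on pairwise-complete samples; the
two-sided p comes from the t distribution with `n - 2` degrees of freedom.
Pairs with fewer than `min_pairs = 4` complete observations, or involving
a zero-variance analyte, are skipped and recorded. BH runs across all
pairs of that matrix. An edge is kept iff `|r| >= 0.6` **and**
`adjusted p < 0.05`; the absolute-value form of the rule is used even
where a one-sided phrasing would read more naturally, so strong negative
correlations are edges too. Analytes without any surviving edge remain in
the network as degree-0 nodes.

"Clusters" are operationalised as connected components of the thresholded
graph — a reproducible stand-in for clusters circled by eye on a layout.
Layouts use igraph's Fruchterman-Reingold with `|r|` edge weights, 200
iterations, and a caller-supplied seed so coordinates are reproducible.

# Clone accounting and repertoire statistics

The identity key throughout is the CDR3 amino-acid sequence: template
counts of clonotypes (distinct nucleotide rearrangements / V-J calls)
sharing a CDR3.aa are summed per (patient, compartment). Non-productive
rows (frame type other than "In") are excluded from clone-level analyses
by default but counted in per-sample template totals, which is how the
"total T cells" vs "productive templates" readouts differ.

Per patient with both compartments, sharing is reported in both
directions — the percentage of distinct blood clones also found in CSF and
the percentage of distinct CSF clones also found in blood. The two
directions share one intersection count, a conservation law the tests
assert exactly. Distinct-clone counts, not template-weighted counts, form
the denominators. Group differences use Welch's t-test. Published
recovery-rate numbers do not always pin down which denominator is meant,
so both are always computed.

Simpson clonality is `sqrt(sum(p_i^2))` over productive clone frequencies
(the assay vendor's convention: 1 = monoclonal, `1/sqrt(N)` for a uniform
N-clone repertoire); the normalized-entropy alternative `1 - H/ln(R)` is
available via an argument. TRBV usage is the per-sample proportion of
productive templates per V gene (summing to 1), compared per gene with
Mann-Whitney and BH across genes within a compartment. Fisher's exact test
on 2x2 carriage tables reports the *conditional maximum-likelihood* odds
ratio (the root of the noncentral hypergeometric mean equation, as
`stats::fisher.test` computes it), not the sample cross-product ratio —
the two differ noticeably in small tables.

# PRS selection and clustering

A CDR3.aa is a *potentially relevant sequence* (PRS) if (1) it is among
the top `top_n = 10` clone counts of some MS CSF sample with a count of at
least `min_count = 2` (ties at the boundary rank are all included), or
(2) it occurs in at least `min_patients = 2` MS CSF samples. Both
criterion tallies and the union are reported separately, since a single
published total can refer to either.

For every PRS, its clone counts across the analysis samples (healthy
reference blood plus the MS blood samples that exist — availability is
taken from metadata rather than hard-coding a dimension count) are ranked
within each sample: rank 1 is the largest count, ties get average ranks,
and sequences absent from a sample share the tied bottom rank. Absent
sequences must rank *somewhere* for the vectors to exist at all; the
bottom-tie convention is the only one that treats "not observed" as
exchangeable. The ranking direction itself is immaterial to k-means
geometry but is fixed for reproducibility.

k-means with k = 2 (Euclidean, 25 seeded restarts) splits the rank
profiles; the cluster whose members occur in a higher mean fraction of MS
samples is labelled `ms_associated` post hoc. Occurrence of a sequence in
a group is the percentage of that group's samples containing it; the
per-cluster MS vs healthy occurrence vectors are compared with Welch's
t-test over sequences. PCA (centred, signs fixed by making each
component's largest loading positive) provides the 2-D visualisation. A
degenerate matrix of identical profiles is rejected with advice rather
than silently returning one cluster.

# TCR-cytokine association

Public sequences are those detected in at least 2 samples of the analysis
set. *MS-predominant* sequences are public sequences either present in at
least `min_ms = 5` MS patients' blood and absent from all controls
(rule A), or present in both groups with mean MS blood clone proportion at
least `enrichment_fold = 10` times the control mean (rule B; rule A takes
precedence). A clone's proportion is its summed CDR3.aa productive
templates over the sample's productive total; a patient not carrying the
sequence contributes proportion 0, not a missing value — required for rank
correlation over the full cohort, with tau-b absorbing the resulting ties.
The log2 enrichment uses a pseudocount of half the smallest nonzero
proportion observed cohort-wide, so rule-A sequences (control mean 0)
still get a finite fold change.

Each (sequence, analyte) pair is tested with tie-corrected Kendall tau-b
between MS blood proportions and MS blood cytokine concentrations,
dropping not-detected patients pairwise (at least `min_pairs = 5`
complete pairs). Only MS patients enter the correlation; mixing in
controls would confound the association with the group contrast itself.
For n <= 8 the p-value is exact by permutation enumeration; otherwise a
normal approximation with the full tie-corrected variance of the
concordance statistic is used. BH runs across all tested pairs as one
family (a per-analyte option exists), and significance needs both
`adjusted p < 0.05` and `|tau| > 0.5`. Tallies count significant positive
and negative associations per analyte and per functional category, with a
grand-total row that the tests check for conservation.

# The synthetic cohort

`cohort_config()` fixes the emulated study design; `simulate_cohort()`
realises it deterministically from a seed (three Mersenne-Twister
substreams: metadata, cytokines, repertoires — so the panels and the
repertoires can also be generated independently).

Default design, chosen once: 24 MS patients and 9 controls with paired
CSF/blood, 88 healthy-reference blood donors, 48 analytes. Cytokines are
log-normal: per-analyte baselines uniform on 3-8 log2 units (8-256 pg/mL,
a typical bead-panel mid-range), correlated Gaussian noise with
`noise_sdlog2 = 0.4` (a moderate within-batch biological+technical
spread; all samples of the emulated study were assayed in one run), a +1
log2 offset in blood, and a detection limit of 2 pg/mL applied after
noise, producing the not-detected mask. Planted structure: CSF fold
changes of 2.57 and 1.91 on two chemokines, and one 4-analyte block at
latent correlation r = 0.9 (block validity is checked against the
positive-semi-definiteness bound `r >= -1/(k-1)`; offending blocks are
rejected by name).

Repertoires: clone counts are a multinomial draw over a Zipf profile
(`zipf_exponent = 1.1`, in the range reported for human TCR repertoires)
plus one, so every listed clone is observed and sharing stays exactly as
planted; blood repertoires have 2000 clones / 20000 templates, CSF 400 /
3000 (doubled total in MS, emulating the higher intrathecal T-cell load),
healthy reference 1000 / 20000. These sizes are deliberately desk-scale —
orders of magnitude below real immunoSEQ exports — chosen so that hundreds
of replicate cohorts can be generated during validation; all rate- and
rank-based statistics are size-consistent, but absolute counts (e.g.
numbers of public or predominant sequences) are *shape* analogues of
published values, not numeric targets. Clone identities mix a shared
public pool (10% of each repertoire from a 200,000-id pool) with private
ids; the pool is split into a blood half and a CSF half so that
cross-compartment sharing arises *only* from the explicit mechanism: each
CSF clone is copied into the paired blood repertoire with probability
`sharing_rate` (0.5% MS, 0.1% control), with its blood count re-drawn.
With 400 CSF clones and a 0.1% rate the per-patient shared count is 0 or
1, so single-cohort control means are granular; recovery of the planted
rates is therefore asserted on the average over replicate cohorts, while
the Welch-test detection rate is asserted per replicate.

Planted sequence-cytokine links use a Gaussian copula: for target Kendall
tau, latent correlation `rho = sin(pi * tau / 2)`; the sequence's counts
in each MS blood sample are a monotone transform of
`rho * z_analyte + sqrt(1 - rho^2) * eps`. Planted MS-cluster sequences
occur in 20% of MS blood and 4% of healthy/control samples (25 of them),
background "general" sequences at 5% everywhere (25), and each is seeded
into two MS CSF samples — preferentially patients whose blood lacks it, so
the planted sharing rates stay untouched — which qualifies them as PRS.
Sequence strings themselves are synthetic: a base-16 encoding of an
integer id flanked by CASS/-QYF-style motifs, which guarantees uniqueness
and makes generation allocation-cheap; they are valid-looking but not
biological CDR3s, and V/D/J labels are sampled from a fixed gene table
with a mildly skewed weight profile (optionally shifting one gene's weight
in MS to plant a usage difference).

What the generator does **not** emulate: sequencing error and PCR bias,
V(D)J recombination statistics, repertoire sizes at experimental scale,
cross-sample batch effects, covariate structure (age/sex/EDSS are
decorative), or any dependence between cytokine levels and the bulk
repertoire beyond the planted links. Passing recovery tests therefore
demonstrates that the *pipeline* retrieves known structure through the
full file-format round trip at realistic group sizes — not that real MS
data would behave this way.

# Validation strategy and problem sizes

Every statistical primitive is tested against an independent brute-force
oracle: BH against the literal step-up definition; Kendall tau-b against
exhaustive pair counting (1000 random tie-heavy cases); the Mann-Whitney
exact path against full subset enumeration (small groups) and the exact
Wilcoxon distribution (12 per group, tie-free); Fisher's p against
hypergeometric enumeration from binomial coefficients and the odds ratio
against direct maximisation of the conditional likelihood; Winsorization
and quartiles against direct order-statistic computation.

Parameter recovery runs on 200 replicate cohorts at study scale (24/9/88):
the 2.57-fold analyte must be significant with a fold estimate within 25%
in at least 90% of replicates; the r = 0.9 block must land in one
connected component in at least 90%; planted tau = 0.7 links must reach
the double significance threshold in at least 80% (at n = 21 the tau
estimate has a standard error near 0.1, so occasional misses are
expected); the sharing-rate contrast must be detected by Welch's test in
at least 80%; and the planted MS-enriched sequences must drive a
significant MS-associated cluster in at least 80%. Two panel-only and
cohort-level Monte-Carlo loops share replicates so the whole suite stays
within a desk-scale compute budget.

# Known limitations

* The pipeline treats CDR3.aa identity as clone identity; nucleotide-level
  lineage structure is collapsed by design.
* Connected components are a coarse operationalisation of visually circled
  network clusters; greedy-modularity sub-clusters are heuristic.
* The Kendall normal approximation is anti-conservative for very sparse
  sequences (many zero proportions concentrate ties); the `min_pairs` and
  `|tau|` thresholds blunt but do not remove this.
* Winsorization clamps the tails that carry part of a strong correlation's
  signal, so sample correlations after the full chain sit slightly below
  the latent value; the edge rule is effectively a touch stricter than the
  nominal `|r| >= 0.6`.
* The synthetic cohort is a validation instrument, not a simulator of MS
  biology; see the generator section for the full list of omissions.
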