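---
title: "Analysing intraoperative microdialysis metabolomics with microdialysR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing intraoperative microdialysis metabolomics with microdialysR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdialysR)
```

## The problem

Intraoperative microdialysis samples the extracellular fluid of the living
brain through semi-permeable catheters placed, during surgery, in
radiographically distinct regions of a glioma: contrast-enhancing tumour
(E, where the blood-brain barrier is disrupted), non-enhancing tumour (NE),
and relatively normal brain adjacent to the tumour (B). Untargeted LC-MS
profiling of the recovered microdialysate yields a metabolites-by-catheters
peak-area matrix. Cohorts are tiny (tens of catheters from ~15 surgeries),
patients are metabolically heterogeneous, and peak areas are relative, so
the analysis leans entirely on within-patient pairing: each patient's brain
catheter is their own control, and cross-patient claims are made on *ranks*
rather than abundances. CSF samples with graded blood contamination provide
a reference signature for plasma-derived metabolites, used to ask how much
of the tumour's extracellular metabolome simply diffuses in from blood
where the barrier is disrupted.

microdialysR implements this analysis end to end: data model and formats,
normalization and filtering, paired fold-change ranked lists, metabolite-set
enrichment, exact paired differential testing, correlation/clustering maps,
bloodiness signatures, and a generative simulator with ground truth.

## Data model and preprocessing

A `peak_matrix` holds strictly positive peak areas with explicit `NA`
non-detects. Zeros in input files are rejected rather than treated as
missing: vendor pipelines report blanks for non-detects, and a literal zero
peak area is an encoding error. Identifiers are matched exactly (after
trimming surrounding whitespace) because metabolite names carry meaningful
punctuation and case.

`median_normalize()` divides each value by the median of its metabolite
within its analysis batch (non-missing values only), so every (metabolite,
batch) group has median exactly 1. The even-count median is the midpoint
mean. Normalization is idempotent and never alters the missingness mask.

`presence_filter()` keeps metabolites observed in at least
`ceiling(min_fraction * n_samples)` samples, default `min_fraction = 0.90`;
with 44 catheters the threshold is 40. The ceiling rule is chosen so the
behaviour extrapolates predictably to other cohort sizes. Survivors keep
their input order.

`apply_perfusate_exclusions()` masks (metabolite, case) combinations where
the perfusion fluid itself contained the analyte (the classic example is
lactate in lactate-buffered perfusate). Masking, rather than dropping the
metabolite, preserves the metabolite universe for ranked lists while paired
statistics simply lose the affected cases.

A deliberate choice throughout: no imputation for ranked lists or tests. A
catheter-pair fold change requires both members observed; otherwise the
metabolite is omitted from that list and recorded in its provenance.

## Ranked lists

`make_ranked_list()` ranks the analyzable universe by the within-case fold
change between two catheters (e.g. E over B). Rank 1 is the most
numerator-associated metabolite; rank N the most denominator-associated.
The stored `rank_score` is `log2(FC)`: the ordering is identical to raw FC
(a monotone transform), but the enrichment statistic below weights hits by
score magnitude, and the symmetric log scale gives positive and negative
enrichment comparable weight. Whether the original analyses used raw or
log fold change as the weighting metric is not knowable from a rank
ordering alone, so the exponent and metric are recorded in every result,
and the suite checks that sign-level conclusions on synthetic data are
stable across weighting exponents 0 and 1. Ties in fold change break by
ascending metabolite name - deterministic and seed-free.

`average_rank_table()` assembles the cross-case rank heat-map: per-case
ranks plus the mean rank, sorted ascending. A conserved tumour signature
appears as stable small ranks across columns.

## Metabolite-set enrichment

The enrichment statistic is the weighted running-sum (Kolmogorov-Smirnov
style) score. Walking the list from rank 1 to N, a hit (set member) at
position *i* adds \(|s_i|^p / N_R\) with \(N_R = \sum_{hits} |s_j|^p\), and a
miss subtracts \(1/(N - N_H)\). The enrichment score ES is the running
sum's maximum-magnitude deviation from zero, signed. `p = 1` (the classic
weighted default) is used throughout; `p = 0` gives the unweighted
statistic. If every hit has score exactly zero the weighted sum is
undefined and the computation falls back to `p = 0`, recorded in the
result.

Because each ranked list derives from a single catheter pair, there are no
sample labels to permute: the null redraws the set's in-list members
uniformly without replacement from the list (metabolite permutation), 1000
draws by default, with a mandatory seed. The normalized score NES divides
ES by the mean magnitude of same-sign null scores, calibrating positive
and negative enrichment separately. The nominal p is the same-sign null
exceedance fraction. FDR q across a family of results is the GSEA-style
ratio of the pooled-null and observed tail fractions at each |NES|,
clipped to [0, 1] and monotonized within each sign family so q never
decreases as |NES| decreases. Zero permutation estimates are displayed at
the floor `1e-5` (rendered `<1e-05`); raw estimates are always retained in
`p_raw` / `fdr_q_raw`.

Signature sets are the top and bottom 35 metabolites of a ranked list
(`build_sets_from_list()`). `cross_case_enrichment_matrix()` queries every
case's signatures against every other case's list (self-matches excluded
by default since a list trivially enriches its own extremes).

## Exact paired differential testing

`exact_wilcoxon_signed_rank()` tests paired differences of normalized peak
areas. Zero differences are discarded (Wilcoxon's original treatment) and
tied magnitudes get midranks. The p-value comes from the exact permutation
distribution of the signed-rank sum over all \(2^n\) sign assignments,
computed by convolution over the doubled (hence integer) midranks;
two-sided p doubles the smaller tail, capped at 1. No normal approximation
is used at any n this design produces. The attainable minima under this
convention are `2/2^9 = 0.0039` for nine concordant pairs and
`2/2^7 = 0.0156` for seven - the floors visible throughout per-contrast
tables at these cohort sizes, which is also the evidence that discarding
(rather than splitting) zeros matches the reference behaviour.

`paired_contrast_table()` reports, per metabolite: the number of usable
pairs, the arithmetic mean of per-case fold changes (`mean_fc`, the
quantity that drives classification), the ratio of paired means
(`fc_of_means`, for reference - note only this variant inverts exactly
under contrast reversal), the exact p, and a class: `up` when
`p <= 0.05` and `mean_fc >= 2`, `down` when `p <= 0.05` and
`mean_fc <= 0.5`, else `ns`. A Benjamini-Hochberg column is emitted for
reference but never drives the class, matching the convention of pairing a
raw exact p with a fold-change cut-off at these sample sizes. Metabolites
with fewer than two usable pairs are listed as untestable rather than
silently dropped.

`cross_platform_concordance()` regresses untargeted peak areas on targeted
concentrations (ordinary least squares on untransformed values) and
reports the squared Pearson correlation - the check that relative peak
areas are quantitatively meaningful.

## Correlation maps and clustering

`spearman_matrix()` computes pairwise-complete Spearman correlations
between samples; monotone association is the right scale for peak areas.
Pairs sharing fewer than 3 metabolites are undefined and flagged.
`hierarchical_cluster()` autoscales metabolites (mean 0, sd 1), fills
remaining non-detects with half the metabolite's minimum observed value (a
conventional metabolomics floor - the choice is recorded in the result
since the upstream tools leave it unstated), drops zero-variance
metabolites with a warning, and applies Ward linkage on Euclidean
distances. Samples are sorted lexicographically first so the dendrogram is
invariant to input column order. The display clip of autoscaled values to
[-6, 6] (`clip_for_display()`) never touches the distances.

## Bloodiness signatures and plasma contamination

Two constructions of the plasma-contamination reference list:

* **Paired** (`paired_bloodiness_list()`): one subject's bloody and clean
  CSF samples drawn minutes apart; FC = bloody/clean over metabolites
  present in both samples and in the microdialysate universe.
* **Pooled** (`pooled_bloodiness_list()`): CSF samples ranked by heme
  content (units arbitrary - only order is used); after removing excluded
  subjects, the top and bottom `ceiling(n/4)` form bloody and clean pools
  (7 each from 26), FC = ratio of pool means over metabolites present in
  >85% of CSF samples and in the microdialysate universe. Heme ties break
  by sample id; a tie straddling a pool boundary warns.

`plasma_enrichment()` queries the signature's top-35 (bloody) and
bottom-35 (clean) sets against each case's E-vs-NE list. A significantly
positive bloody-set NES means the enhancing catheter resembles
blood-contaminated CSF; a significantly negative clean-set NES means the
non-enhancing catheter resembles clean CSF. The summary counts cases
significant for either and both directions.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the analysis assumes,
plus full ground truth, so every stage has a parameter-recovery test. The
model is multiplicative log-normal:
\(y_{ms} = \exp(\mu_m + u_{mc} + \beta_{m,\ell(s)} + \varepsilon_{ms})\)
with metabolite baselines \(\mu_m \sim N(10, 1.5^2)\), patient effects
\(u_{mc} \sim N(0, \tau^2)\) per (metabolite, case), noise
\(\varepsilon \sim N(0, \sigma^2)\), and class-by-location multiplicative
effects \(e^{\beta}\). Defaults (all overridable): 15 cases (7 with all
three catheters, 2 with E+B, 5 with NE+B, 1 all-tumour E+NE - 9 E/B and 8
E/NE pairs), 200 metabolites, \(\tau = 0.5\), \(\sigma = 0.4\), 4%
intensity-dependent missingness (logistic in log-abundance, emulating
non-detects), and class proportions 20% plasma-derived, 5%
tumour-produced, 10% brain-associated, one oncometabolite, the rest
background. The plasma-derived share is sized so that the class fills the
top quartile of a bloodiness list the way the amino-acid/carnitine-heavy
blood signature does in real microdialysate, which is what makes the
paired and pooled constructions agree on top-quartile membership
(Jaccard >= 0.5) at defaults.

Location effects: plasma-derived x6 in E, x1.5 in NE; tumour-produced x8
in E, x3 in NE; brain-associated x5 in B; the oncometabolite sentinel
(`2HG_like`) x20/x25 in E/NE of IDH-mutant cases only. Three sentinels
(`GAA_like` at x128 E and x14 NE, `2HG_like`, `NAA_like`) get a fixed
above-average baseline rather than a random draw: they emulate robustly
detected compounds, and a randomly low baseline would let
intensity-dependent censoring hide the very effects they exist to carry.
CSF samples mix a plasma profile into a clean-CSF profile in proportion to
a per-sample Beta-distributed contamination fraction; heme is proportional
to that fraction with small log-normal noise; one dedicated subject
contributes a bloody/clean pair (fractions 0.8 and 0.02).

All randomness flows from a single seed through documented per-stage
substreams, so any block regenerates in isolation and two runs are
byte-identical. `fixture_small()` is the fixed-seed instance the test
suite uses.

What the generator does **not** emulate: batch effects (a single batch by
default, though the normalizer handles many), correlated metabolite
modules, adducts/in-source fragments, drift, censoring that depends on
anything but abundance, and real biological covariance between the plasma
and tumour programmes. Passing recovery tests therefore show the methods
are correct and well-calibrated under the stated generative assumptions -
not that real microdialysate satisfies those assumptions.

## Numerical and design choices

* Ceiling presence threshold; even-count medians as midpoint means.
* Fold-change ties by metabolite name; heme ties by sample id; running-sum
  extreme taken at the first position attaining the maximum magnitude.
* ES extremes only need evaluation just before and just after hits
  (the profile is linear in between), giving an O(hits) permutation inner
  loop that the suite verifies against the full O(N) profile to 1e-12.
* Doubled midranks make the signed-rank convolution exact in integer
  arithmetic; tail comparisons use a 1e-9 guard.
* Display floors (`<1e-05` for zero permutation estimates, p to 4
  decimals, z clipped at +-6) are applied at presentation only; raw
  values are retained everywhere.
* Reported problem sizes in the suite: enrichment oracle checks at
  N <= 200 over ~1000 instances, exhaustive signed-rank enumeration for
  n <= 12, Ward oracle at <= 8 samples, recovery simulations on the
  default 15-case cohort with 1000 permutations per cell and 20 seeds for
  the plasma-recovery rate, 10,000 replicates for the exact test's size.
  These sizes were chosen to make each check decisive at interactive
  runtimes.

## Limitations

* The exact test is the only inferential engine for differential tables;
  with n <= 9 pairs its resolution is bounded by the attainable p floors,
  so ranking metabolites *within* the significant class rests on fold
  change, not p.
* Metabolite-permutation nulls treat metabolites as exchangeable within a
  list; correlated metabolite families (e.g. acyl-carnitines) make the
  null slightly liberal, which the FDR across sets only partially absorbs.
* The pipeline starts from quantified, identified peak areas; nothing
  upstream (peak picking, identification, QC) is modelled.
* `mean_fc` (mean of per-case ratios) is Jensen-biased upward under
  multiplicative noise; it is reported because it is the field's
  convention for these tables, and `fc_of_means` is emitted alongside.
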