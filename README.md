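# microdialysR

Analysis of untargeted metabolomics from **intraoperative microdialysis**
of gliomas. During surgery, semi-permeable catheters sample the
extracellular fluid of radiographically distinct regions — contrast-
**e**nhancing tumour (E, disrupted blood–brain barrier),
**n**on-**e**nhancing tumour (NE), and adjacent **b**rain (B) — plus CSF
with variable blood contamination. LC–MS peak areas from such cohorts are
relative, sparse, and come from a handful of heterogeneous patients, so
every inference in this package is built on within-patient pairing and
rank-based cross-patient comparison.

The package is for analysts working with catheter- or compartment-paired
metabolomics who need the full path from a peak-area matrix to publishable
tables: normalization, presence filtering, paired fold-change ranked
lists, metabolite-set enrichment, exact paired tests, clustering, and a
plasma-contamination analysis — with a ground-truth simulator so every
stage is testable without patient data.

## Methods at the core

* **Weighted running-sum enrichment** (implemented here, not wrapped):
  walking a ranked list of N metabolites, a set member at position *i*
  adds |s_i|^p / N_R (N_R = Σ_hits |s_j|^p, default p = 1), a non-member
  subtracts 1/(N − N_H); the enrichment score ES is the signed
  maximum-magnitude deviation of the running sum. Significance comes from
  a metabolite-permutation null (no sample labels exist to permute for a
  single catheter pair): NES = ES / mean |same-sign null ES|, nominal p =
  same-sign exceedance fraction, and FDR q = (pooled-null tail
  fraction)/(observed tail fraction) at each |NES|, monotonized within
  sign family. Zero permutation estimates display as `<1e-05`.
* **Exact Wilcoxon signed-rank test**: zeros discarded, midranks for
  ties, p from the exact distribution of the signed-rank sum over all 2^n
  sign assignments (integer convolution over doubled midranks); two-sided
  p = 2 × smaller tail. At n = 9 concordant pairs the attainable minimum
  is 2/2⁹ = 0.0039; at n = 7, 2/2⁷ = 0.0156.
* **Paired fold-change ranked lists**: FC = E/B per case on
  median-normalized peak areas (median = 1 per metabolite per batch),
  rank 1 = most tumour-associated; signatures = top/bottom 35.
* **Bloodiness reference lists** from paired (bloody/clean) or pooled
  (heme-ranked quartile) CSF, queried against each case's E-vs-NE list to
  quantify plasma influx through the disrupted barrier.
* **Synthetic cohorts**: multiplicative log-normal model
  y = exp(μ_m + u_mc + β_m,loc + ε) with metabolite classes
  (plasma-derived, tumour-produced, brain-associated, IDH-restricted
  oncometabolite, background), intensity-dependent missingness, and a
  contamination-graded CSF block, all with ground truth.

## Worked example

```r
library(microdialysR)

cohort <- generate_cohort(default_generator_config(seed = 11L))
norm   <- median_normalize(cohort$matrix)
filt   <- presence_filter(norm, 0.90)
filt$matrix
#> peak_matrix: 180 metabolites x 37 samples (layer=normalized, 1 batch, 3.0% missing)
```

180 of 200 simulated metabolites are present in at least
`ceiling(0.9 × 37) = 34` catheters and form the analyzable universe.

```r
eb <- paired_contrast_table(filt$matrix, cohort$annotation, "E", "B")
eb
#> differential table E/B (n = 9 cases): 47 up, 20 down, 113 ns (p <= 0.05, FC >= 2)
head(eb$table[order(eb$table$p_two_sided, -eb$table$mean_fc),
              c("metabolite", "n_pairs", "mean_fc", "p_two_sided", "class")], 5)
#>  metabolite n_pairs mean_fc p_two_sided class
#>    GAA_like       9 167.268    0.003906    up
#>      met046       9  14.555    0.003906    up
#>      met050       9  10.498    0.003906    up
#>      met044       9   9.747    0.003906    up
#>      met045       9   9.742    0.003906    up
```

47 metabolites are significantly elevated in enhancing tumour and 20 in
brain. The planted extreme tumour metabolite (`GAA_like`, true effect
×128) tops the table at the nine-pair p-value floor 0.0039 — the smallest
p an exact paired test can produce at this cohort size.

```r
rl   <- make_ranked_list(filt$matrix, "case01_E", "case01_B",
                         annotation = cohort$annotation)
rl
#> ranked_list 'case01_E_vs_case01_B': 171 metabolites (9 omitted)
#>   top:    GAA_like (FC 99.7)
#>   bottom: met063 (FC 0.0559)

sets <- build_sets_from_list(rl, k = 35)
rl2  <- make_ranked_list(filt$matrix, "case02_E", "case02_B",
                         annotation = cohort$annotation)
permutation_null(rl2, sets$top, p = 1, n_permutations = 1000, seed = 3L)
#> enrichment of 'case01_E_vs_case01_B_top35' in 'case02_E_vs_case02_B': ES 0.880, NES 2.530, p <1e-05
```

Patient 1's enhancing-tumour signature is strongly, positively enriched
at the tumour end of patient 2's ranked list: the enhancing extracellular
metabolome is conserved across patients. `cross_case_enrichment_matrix()`
runs this for all case pairs with a familywise permutation FDR, and
`plasma_enrichment()` asks the analogous question for bloody-vs-clean CSF
signatures. `run_pipeline(list(seed = 7L, simulate = TRUE), out_dir = "out")`
(or a YAML config naming real input files; see
`inst/scripts/run_pipeline.R` for the command-line wrapper) writes every
table with full provenance headers.

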