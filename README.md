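# ccrcctools

Analysis toolkit for transcriptome-driven characterization of clear cell
renal cell carcinoma (ccRCC) cohorts.  It is aimed at cancer-genomics
analysts who have bulk RNA-seq of a tumor cohort — expression matrices,
RNA-derived variant calls, limited matched normals, clinical follow-up —
and want the standard ccRCC workup as tested, composable R functions:

* **Somatic-variant filtering** from RNA-seq calls: a four-stage cascade
  (quality → population frequency → functional class → cancer-gene
  panel), optional matched-normal checking, per-sample mutation load and
  per-gene mutation frequencies.
* **Cross-cohort driver comparison**: integer counts reconstructed from
  published one-decimal percentages, per-gene two-sided Fisher exact
  tests (minimum-likelihood convention, exact hypergeometric sums).
* **Molecular subtyping**: consensus non-negative matrix factorization
  (NMF) over variable genes with cophenetic rank selection, compression
  to a 300-gene transferable signature, and `1 − Spearman` hierarchical
  transfer classification of external cohorts.
* **Immune phenotyping**: 66-marker clustering into
  active / tolerant / inactive tumor tiers anchored by normal samples,
  constrained least-squares deconvolution of bulk profiles into
  reference cell-type fractions, group-wise fraction comparison, and
  eTMB (somatic-call count) correlation.
* **Survival stratification**: Kaplan–Meier curves, median survival,
  multi-group log-rank tests, and joint class × phenotype strata.
* **A synthetic-cohort generator** with recorded ground truth (planted
  subtype programs, immune tiers, variant kinds, cell-type mixtures,
  group-dependent exponential survival), so the whole pipeline is
  testable end to end without patient data.

The core statistic of the subtyping is consensus NMF: the non-negative
fold of z-scored expression `V ≈ WH` is factorized from 50 random starts
per rank, samples are co-clustered by dominant coefficient, and the
stability of the consensus matrix — its cophenetic correlation — selects
the rank `k`.  Class-discriminating genes are then ranked one-vs-rest by
Welch *t* with Benjamini–Hochberg adjustment, and the top 300 form the
signature used to classify external cohorts by average-linkage
clustering of the `1 − ρ` (Spearman) distance.

## Worked example

Compare published driver-gene frequencies between a 55-patient Chinese
ccRCC cohort and the white TCGA KIRC patients with mutation data
(n = 451), reconstructing counts from the printed percentages:

```r
library(ccrcctools)
library(dplyr)

tab <- driver_frequency_table()
res <- compare_driver_frequencies(
  select(tab, gene_symbol, percent = percent_chinese), 55,
  select(tab, gene_symbol, percent = percent_tcga_white), 451)
res %>% filter(gene_symbol %in% c("VHL", "PBRM1", "NCOR2", "KDM5C"))
#>   gene_symbol percent_1 percent_2 count_1 count_2    p_value significant
#> 1 VHL              76.4      52.8      42     238  0.000862  TRUE
#> 2 NCOR2            12.7       1.4      NA      NA NA         FALSE
#> 3 PBRM1             9.1      33.7       5     152  0.0000838 TRUE
#> 4 KDM5C             0         6.9       0      31  0.0377    TRUE
```

`VHL` is mutated in 42/55 Chinese tumors versus 238/451 TCGA-white tumors
(p = 8.6e-4): substantially more frequent, while `PBRM1` (5/55 vs 152/451,
p = 8.4e-5) and `KDM5C` (0/55 vs 31/451, p = 0.038) run the other way.
`NCOR2`'s printed 1.4% is inconsistent with an n = 451 denominator — no
integer count prints as 1.4% — so the row carries an explanatory note
instead of a fabricated count.

Subtype a (here: synthetic) cohort and inspect the fit:

```r
sim <- simulate_expression_cohort(
  cohort_config(n_tumor = 30, n_normal = 0, n_genes = 600,
                n_class_genes = 60, seed = 35))
fit <- fit_subtypes(sim$expression, n_genes = 300, ranks = 2:4,
                    n_runs = 15, top_n = 60, seed = 35)
fit
#> Consensus-NMF subtype model: k = 3 (cophenetic 1.000), 30 samples
#> signature: 60 genes, recall of full clustering = 1.000
glance(fit)
#>       k cophenetic n_samples n_selected_genes n_signature_genes recall
#> 1     3          1        30              300                60      1
```

The rank survey picked `k = 3` (the planted class count) with a perfectly
stable consensus, and the 60-gene signature reproduces the full
clustering exactly (`recall = 1`).  `tidy(fit)` returns per-sample class
labels; `autoplot(fit)` draws the cophenetic profile;
`transfer_classify()` carries the signature to an external cohort.

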