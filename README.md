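# epistrat

Tumors of a single cancer type often split into subgroups with different
clinical outcomes based on the expression of **epifactors** — the writers,
erasers and readers of DNA and histone marks, and the chromatin remodelers.
`epistrat` is an R package for researchers who want to perform that
stratification end to end on bulk RNA-seq cohorts with clinical follow-up,
and to carry the resulting signatures into validation cohorts and
single-cell data.

The workflow:

1. **Preprocess** — median-of-ratios size factors, log2 transformation,
   purity-based sample filtering, and selection of variable epifactor genes
   by an automatic standard-deviation cutoff targeting 500–600 genes.
2. **Stratify** — consensus non-negative matrix factorization: `V ≈ WH`
   with nonnegative factors, minimizing the generalized Kullback–Leibler
   divergence `D(V‖WH)` by multiplicative updates (C++ kernel), repeated
   from seeded restarts into a consensus matrix. Rank `k ∈ {2,3,4}` is
   chosen by majority vote of the cophenetic coefficient, mean silhouette
   width and the connectivity index.
3. **Signatures** — cluster-specific genes by the Kim–Park score
   `1 + (1/log2 k) Σ p log2 p` over normalized basis loadings, thresholded
   at mean + 3 sd; clusters labeled "poor"/"better" by Kaplan–Meier
   survival.
4. **Survival** — log-rank tests and age/sex-adjusted Cox models per
   endpoint (PFI/DSS/OS); a per-gene prognostic screen using maximally
   selected log-rank cutpoints with BH correction; a meta-PCNA
   proliferation covariate (top 1% of genes correlated with PCNA) to test
   proliferation independence; prognostic residuals `N − M` across cohorts
   with exact sign tests.
5. **Enrichment** — protein-complex over-representation among signature
   genes by odds ratio with a 10,000-iteration permutation null;
   alteration-frequency comparisons between clusters by Fisher's exact
   test with a 10% frequency filter; hypergeometric overlap tests.
6. **Validation & single cell** — rank-based single-sample enrichment
   scores classify new samples by the higher-scoring signature; per-cell
   module scores with expression-matched control genes assign cells to
   poor/better/both/none groups, with one-vs-rest Wilcoxon DE.

A synthetic-cohort generator (`generate_cohort()`, `generate_single_cell()`,
`generate_alterations()`) plants known expression programs, a
PCNA-anchored proliferation module, program-dependent hazards and
annotations, so every stage is verified against ground truth.

## Worked example

```r
library(epistrat)

cohort <- generate_cohort(cohort_config(seed = 1))   # 3000 genes x 200 tumors
norm   <- normalize_log2(cohort$counts)
sel    <- select_variable_epifactors(norm, cohort$annotation)
length(sel$genes)
#> [1] 500

cc <- consensus_cluster(norm$values[sel$genes, ], k = 2, n_runs = 10,
                        seed = 11, tol = 1e-4)
cc
#> Consensus NMF result: k = 2, 200 samples, 10 runs
#>   cophenetic = 0.998, silhouette = 0.191, connectivity = 0.00
#> cluster
#>   1   2
#> 100 100

label_clusters_by_outcome(cc$labels, cohort$clinical)
#>        1        2
#>   "poor" "better"

cmp <- compare_clusters(cc$labels, cohort$clinical)
cmp$pfi$cox
#> Cox fit (converged), partial loglik -554.29
#>       term    coef      se    hr hr_lo hr_hi        p
#> 1 cluster2 -0.8813 0.18725 0.414 0.287 0.598 2.52e-06
#> 2      age  0.0111 0.00936 1.011 0.993 1.030 2.35e-01
#> 3     sexM -0.1808 0.18157 0.835 0.585 1.191 3.19e-01
```

Reading the output: the automatic cutoff kept 500 of the 720 annotated
epifactors; the consensus matrix is almost perfectly stable (cophenetic
0.998) and splits the 200 tumors 100/100, exactly recovering the two
planted expression programs. Cluster 1 is the poor-outcome cluster:
belonging to cluster 2 multiplies the progression hazard by 0.414
(95% CI 0.287–0.598, Wald p ≈ 2.5e-06) after adjusting for age and sex —
the generator planted a log hazard ratio of 0.7 for the program
corresponding to cluster 1, i.e. a hazard ratio of 2.01 ≈ 1/0.414 in the
other direction.

`run_pipeline()` chains all stages (simulate → preprocess → stratify →
survive → screen → enrich → validate → sc-score) from one YAML/JSON or list
configuration, writes every output as TSV/JSON, and records a manifest with
per-file md5 digests so identical seeds reproduce identical runs.

## Further reading

The methods vignette (`vignettes/epifactor-stratification.Rmd`) documents
the model, every tunable parameter with its default and rationale, the
synthetic generator's assumptions and their limits, numerical edge-case
handling, and known limitations (including the calibration caveat for the
optimal-cutpoint prognostic screen).
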