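# psiclust

Intron-retention subtyping of tumor cohorts from splice-event PSI profiles.

Bulk RNA-seq cohorts can be stratified not only by gene expression but by
how efficiently tumors remove introns. `psiclust` implements that analysis
as a tested, reusable R pipeline for computational biologists working with
splice-event count tables: from inclusion/exclusion read counts to
percent-spliced-in (PSI) matrices, NMF consensus clusters, cluster-validity
and asymmetry statistics, a differential-splicing filter cascade,
cancer-gene enrichment, RNA-binding-protein (RBP) correlation discovery,
and survival comparisons. A synthetic-cohort generator with planted ground
truth makes every stage testable without access to controlled patient data.

## The method

**PSI quantification.** For each splice event and sample,
`PSI = inclusion / (inclusion + exclusion)`; events with fewer than 10
total spliced reads in a sample are treated as missing (`NA`), and events
missing in any sample are excluded from clustering.

**Clustering.** The most variable events (sample s.d. > 0.1 for intron
retention) form a non-negative events × samples matrix `X`. Repeated NMF
factorizations `X ≈ WH` (multiplicative updates minimizing ‖X − WH‖²_F,
seeded random initializations) give per-run sample assignments
(argmax over columns of `H`); their co-clustering frequencies form the
consensus matrix, cut by average-linkage hierarchical clustering. Stability
is summarized by the cophenetic correlation coefficient, which also drives
rank selection. Cluster-defining events come from the Kim–Park
basis-specificity score on `W`. Partitions are compared with k-means and
hierarchical comparators via AMI/ARI, and validated with RMSSTD, R² and
the SD validity index.

**Asymmetry.** For two clusters, each top event's
`ΔPSI_mean = mean PSI(cluster 1) − mean PSI(cluster 2)` is computed; the
pattern is *asymmetric* when strictly more than 70% of top events have
their higher mean PSI in the same cluster — the signature that
distinguishes intron-retention subtypes from the balanced patterns of
other splicing types.

**Differential cascade.** Per-event two-tailed Mann–Whitney U tests with
Benjamini–Hochberg adjustment (keep q < 0.05), then removal of events with
≥ 10% missing values overall, removal of events whose per-cluster missing
fractions differ by ≥ 5%, and finally selection of events with
`|ΔPSI_mean| > 0.1`.

**Downstream.** Fisher/hypergeometric enrichment of the selected events in
oncogene/tumor-suppressor and intron-location categories; a median-of-ratios
normalized, Welch-on-log differential-expression stand-in (a deliberate,
documented replacement for a negative-binomial Wald model — the interface
accepts externally computed size factors if you prefer another engine);
Pearson RBP-event correlation discovery (report r ≥ 0.7, q < 0.05); and
survival analysis per cluster (Kaplan–Meier, Mantel–Cox log-rank,
multivariate Cox with Efron ties, maximally selected cutpoints for
continuous markers).

## Worked example

```r
library(psiclust)

cfg    <- simulation_config(seed = 7)   # 40+40 samples, 600 IR events,
cohort <- simulate_cohort(cfg)          # 30% shifted up by 0.2 in cluster 2
bundle <- run_pipeline(pipeline_config(seed = 7), cohort)
print(bundle)
#> report_bundle
#>   partition: k=2 (40+40), cophenetic=1.0000
#>   asymmetry: fraction_positive=0.000, asymmetric=TRUE
#>   differential cascade: 180 selected of 600 tested
#>   Cox HR (cluster 2 vs 1): 0.588

adjusted_mutual_information(bundle$partition, cohort$truth$cluster)
#> [1] 1
```

Reading the output: the consensus partition reproduces the planted
two-cluster structure exactly (AMI = 1) with a perfectly stable consensus
(cophenetic 1.0). Every top clustering event has its higher mean PSI in
cluster 2 (`fraction_positive = 0` means all `ΔPSI_mean` are negative), so
the asymmetry flag is set: cluster 2 is the high-retention subtype. The
filter cascade selects exactly the 180 planted events, and the multivariate
Cox model estimates a hazard ratio of 0.59 for cluster 2 relative to
cluster 1 (the generator's true value is 0.49; an 80-sample cohort
estimates it with this much noise), i.e. membership in the high-retention
cluster is associated with a lower hazard.

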