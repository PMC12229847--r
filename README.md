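# metabhub

Discovery of signed metabolic gene signatures from tumor expression
cohorts, for computational biologists studying how metabolic reprogramming
tracks tumor aggressiveness.

Given a gene-by-sample expression matrix, clinical annotations, a metabolic
gene catalog and an interaction network, the package:

1. **Scores aggressiveness** per patient as the sum of expression Z-scores
   over an EMT (epithelial-to-mesenchymal transition) program, and splits
   the cohort into low / intermediate / high tertiles.
2. **Filters metabolic targets** by three simultaneous criteria: strictly
   monotone expression across the tertiles with one-way ANOVA BH-FDR
   q < 0.05; differential expression between early and advanced stage
   (Student's t, BH-FDR q < 0.05, direction concordant with the trend); and
   an optimal-cutpoint log-rank survival association (p < 0.05).
3. **Prioritizes network hubs** among the selected targets by an
   equal-energy random walk: every node starts with energy 1, repeatedly
   keeps half and sends half split equally among its neighbours, and at
   equilibrium the retained energy is the RW score

   $$e_\infty(v) = |C|\,\frac{\deg(v)}{\sum_{u\in C}\deg(u)}$$

   on each connected component $C$. Nodes with RW score ≥ 2 (twice the
   network-average energy) are the hubs.
4. **Builds the signed signature**: up-trending hubs are oncogenic,
   down-trending hubs suppressors, and each patient's signature score is
   $\sum_{\text{up}} z_g - \sum_{\text{down}} z_g$. The score is associated
   with survival (optimal-cutpoint log-rank), with gene-set enrichment
   between low/high score groups (a self-contained permutation GSEA
   engine), and with DNA methylation via per-gene Pearson correlation
   (genes with r < −0.50 are flagged as methylation-silenced candidates).

A synthetic multi-omics cohort generator (`simulate_cohort()`) plants a
known latent aggressiveness axis, oncogenic/suppressor hub genes, a weak
co-regulated tier, survival hazard, stage labels, methylation
anticorrelation and a hub-structured network, so the whole pipeline can be
validated against ground truth. A fixed signature can be re-scored on an
independent cohort with `validate_signature()` (no re-selection).

## Worked example

```r
library(metabhub)

co  <- simulate_cohort(sim_config(seed = 11))     # 300 samples, 500-gene catalog
fit <- discover_signature(co$expression, co$clinical, co$edges,
                          co$emt_genes, co$metab_genes,
                          methylation = co$methylation, seed = 11)
fit
#> Metabolic signature discovery
#>   catalog genes tested:   500
#>   selected targets:       46 (24 up, 22 down)
#>   network:                43 nodes, 79 edges (3 isolated removed)
#>   hubs (RW score >= 2):  7
#>   signature up (oncogenic):   ONCO4, ONCO5, ONCO2, ONCO1, ONCO3
#>   signature down (suppressor): TSG2, TSG1
#>   signature log-rank: chi2 = 61.5, p = 4.35e-15 (high_worse)
```

The cohort planted five oncogenic (`ONCO*`) and two suppressor (`TSG*`)
hub genes; the discovery funnel — 500 catalog genes, 46 selected targets,
43 networked, 7 hubs — recovers exactly those seven with the correct
polarity. The signature's high-score group has significantly worse survival
(log-rank chi-square 61.5), and `summary(fit)` additionally shows that the
two suppressor hubs (and only they) are flagged by the
methylation–expression classifier:

```r
summary(fit)
#> ...
#> Methylation-expression correlation of signature genes:
#>    gene   pearson_r n_pairs flagged
#> ...
#> 6  TSG2 -0.61667031     300    TRUE
#> 7  TSG1 -0.57769875     300    TRUE
```

Individual stages are exported for use on real data: `read_expression()`,
`read_gmt()`, `read_edges()`, `zscore_rows()`, `geneset_score()`,
`tertile_groups()`, `select_targets()`, `build_network()`,
`random_walk_scores()`, `select_hubs()`, `signed_signature_score()`,
`optimal_cutoff()`, `km_curve()`, `logrank()`, `permutation_test()`,
`meth_expr_correlation()`, `run_report()` / `write_run_report()`.

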