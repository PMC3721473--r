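# ovca

Molecular subtyping and functional screen analysis for epithelial ovarian
cancer (EOC) expression data.

Epithelial ovarian cancer is markedly heterogeneous: tumours with the same
histology diverge in prognosis and treatment response. `ovca` implements a
complete, tested pipeline for dissecting that heterogeneity from bulk
expression data and for connecting the resulting molecular subtypes to
growth-essential genes measured in pooled shRNA screens. It is aimed at
computational biologists who want each stage of such a workflow as an
auditable, reusable function rather than a chain of one-off tools.

The pipeline stages, and the statistic or model at the core of each:

| Stage | Function(s) | Core method |
|---|---|---|
| Batch compilation | `combat_adjust()` | parametric empirical-Bayes location/scale adjustment: $y_{bgj} = \alpha_g + X\beta_g + \gamma_{bg} + \delta_{bg}\epsilon_{bgj}$, with $\gamma^*,\delta^*$ shrunk toward moment-matched batch priors |
| Gene selection | `variance_filter()`, `center_genes()` | SD > 1.05 across samples; per-gene median centering |
| Subtype discovery | `consensus_cluster()`, `select_k()` | consensus matrix $M_{ij}$ = co-clustering rate over 1000 subsamples (ratio 0.8) of average-linkage (UPGMA) Euclidean clusterings; PAC / CDF-area / purity diagnostics |
| Cluster validation | `silhouette_widths()`, `sigclust_test()` | SW $=(b-a)/\max(a,b)$ with SW > 0 defining core samples; Gaussian-null cluster-index test with Ledoit–Wolf-regularized spectrum |
| Pathway activity | `ssgsea_score()` | single-sample GSEA: integrated difference of weighted in-set ECDF (weights $r^\alpha$, $\alpha=0.25$) and out-of-set ECDF over each sample's gene ranking |
| Subtype gene sets | `select_subtype_sets()` | one-vs-rest SAM statistic $d=(\bar x_1-\bar x_0)/(s+s_0)$ at permutation FDR $q\le 0$, AND ROC AUC > 0.85 |
| Subtype prediction | `one_vs_rest()`, `cross_validate()` | Bayesian probit regression on SVD metagenes of the top-50-core-sample signature (Albert–Chib Gibbs sampling), argmax assignment, k-fold / three-way-split CV |
| Screen quantification | `count_hairpins()`, `normalize_counts()`, `combine_screens()` | perfect-match counting, total-count scaling, cross-screen batch adjustment |
| Essential genes | `signal_to_noise()`, `riger_gene_scores()`, `riger_permutation_fdr()`, `call_subtype_genes()` | signal-to-noise hairpin metric $(\bar x_A-\bar x_B)/(s_A+s_B)$, weighted Kolmogorov–Smirnov gene enrichment, 1000-permutation null, BH FDR, calls at $q<0.005$ with hairpin score $\ge 0.2$ |
| Clinical statistics | `km_estimate()`, `logrank_test()`, `cox_fit()`, `fisher_exact()`, `mann_whitney_u()`, `spearman_matrix()`, `gi50()` | Kaplan–Meier, k-group log-rank, Breslow Cox PH (HR, 95% CI), exact tests, GI50 from four-parameter logistic dose-response fits |
| Synthetic data | `simulate_cohort()`, `simulate_gene_sets()`, `simulate_survival()`, `simulate_screen()`, `simulate_dose_response()` | generators planting exactly the structure each stage assumes, for fully offline testing |

See `vignettes/ovca-methods.Rmd` for the models, parameter defaults and
numerical choices in detail.

## Worked example

Simulate a two-batch cohort with three planted subtypes, then run the full
discovery pipeline:

```r
library(ovca)

sim <- simulate_cohort(cohort_sim_config(
  n_genes = 400, n_samples = 150, k_subtypes = 3, genes_per_signature = 40,
  signature_effect = 1.8, n_batches = 2, noise_sd = 1, seed = 42))

adj  <- combat_adjust(sim$expr, sim$batch, covariates = sim$subtype)$expr
expr <- center_genes(variance_filter(adj, 1.05), "median")

cc  <- consensus_cluster(expr, k_range = 2:5, n_iter = 200, seed = 7)
sel <- select_k(cc)
labels <- cc[[paste0("k", sel$recommended_k)]]$labels
asg <- silhouette_widths(as.matrix(dist(t(expr))), labels)

sets <- simulate_gene_sets(sim$signature_genes, rownames(sim$expr),
                           n_decoy_sets = 10, set_size = 20, seed = 8)
es     <- ssgsea_score(adj, sets)
selset <- select_subtype_sets(es, labels, q_max = 0, auc_min = 0.85, seed = 9)

ovr  <- one_vs_rest(adj, asg, n_per_subtype = 30, seed = 10)
surv <- simulate_survival(labels, baseline_hazard = 0.03,
                          hazard_ratio = c("2" = 2.2), censoring_rate = 0.3,
                          seed = 11)
lr <- logrank_test(surv$os_time, surv$os_event, surv$subtype)
cx <- cox_fit(surv$os_time, surv$os_event,
              data.frame(subtype2 = as.numeric(surv$subtype == "2")))
```

Output printed by this run:

```
genes kept by SD > 1.05 filter: 123 of 400
  k cdf_area   pac purity delta_area
1 2    0.452 0.447  0.861      0.452
2 3    0.674 0.000  1.000      0.491
3 4    0.680 0.013  0.992      0.008
4 5    0.686 0.018  0.986      0.010
recommended k: 3
ARI vs planted truth: 1
core samples (SW > 0): 150 / 150
       set subtype q auc
1  TRUE_S1       1 0   1
14 TRUE_S2       2 0   1
27 TRUE_S3       3 0   1
held-out assignment accuracy: 100 %
log-rank chi-square = 14.68 (df = 2), p = 0.00065
subtype-2 HR = 2.20 (95% CI 1.46-3.33), p = 0.000185
```

Reading the output: the SD filter keeps mostly the 120 planted signature
genes; PAC drops to 0 at k = 3 (every consensus entry is 0 or 1), so 3 is
recommended and the labels match the planted truth exactly (ARI 1); all
150 samples have positive silhouette width; exactly the three planted
gene sets (and no decoys) pass q = 0 / AUC > 0.85 for their own subtype;
held-out samples are assigned to the right subtype by the probit
metagene models; and the survival layer recovers the hazard ratio planted
for subtype 2 (true HR 2.2) with a significant log-rank separation.

For the screen arm, see `?simulate_screen`, `?riger_gene_scores` and the
acceptance suite (`tests/testthat/test-acceptance.R`), which recovers
≥80% of planted essential genes at q < 0.03 with empirical FDR ≤ 10% on a
2,000-gene, 5-hairpins-per-gene, 5-vs-9-cell-line screen.

## Command line

An `ovca` executable (installed under `exec/`) wraps the pipeline:

```sh
ovca io validate expr.tsv --format expr
ovca simulate cohort --config cohort.json --out sim/
ovca preprocess --expr sim/expression.tsv --batches batches.tsv \
     --sd-threshold 1.05 --center median --out adj.tsv
ovca subtype discover --expr adj.tsv --kmax 6 --iters 1000 --seed 7 --out subtypes/
ovca ssgsea --expr adj.tsv --gmt sets.gmt --out es.tsv
ovca select-sets --es es.tsv --labels subtypes/subtypes.tsv --qmax 0 --aucmin 0.85 --out sel.tsv
ovca screen count --reads reads.fastq --library lib.tsv --out counts.tsv
ovca screen riger --counts counts.tsv --library lib.tsv --groups groups.tsv \
     --perms 1000 --qmax 0.005 --hairpin-min 0.2 --seed 7 --out riger/
ovca survival logrank --clinical clin.tsv --labels subtypes.tsv
ovca gi50 --doses doses.tsv
```

Simulator configs are JSON files whose keys mirror the
`cohort_sim_config()` / `screen_sim_config()` fields.

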