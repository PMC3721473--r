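---
title: "Methods: subtype discovery and functional screen analysis with ovca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype discovery and functional screen analysis with ovca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`ovca` re-implements, as a tested and reusable pipeline, a classification
and functional-genomics workflow for epithelial ovarian cancer (EOC):
molecular subtypes are discovered from compiled log2 expression cohorts by
consensus clustering, characterized by single-sample gene set enrichment,
made portable by Bayesian probit metagene predictors, and linked to
growth-essential genes through pooled shRNA screens scored by
ranked-hairpin enrichment. A synthetic-data module generates inputs with
exactly the statistical structure each stage assumes, so the whole pipeline
is testable offline. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic world does and does not establish.

# Preprocessing: batch adjustment, gene filtering, centering

Compiled multi-cohort expression data carry strong site/platform batch
effects. `combat_adjust()` implements the parametric empirical-Bayes
location/scale model: for gene $g$ in batch $b$,
$y_{bgj} = \alpha_g + X\beta_g + \gamma_{bg} + \delta_{bg}\,\epsilon_{bgj}$.
Genes are standardized against a least-squares fit of batch (and optional
protected biological covariates), per-(batch, gene) location and scale
effects are estimated, shrunk toward moment-matched batch-level priors
(normal for $\gamma$, inverse-gamma for $\delta$) by the usual iterative
posterior solution, and the data are back-transformed. Only the parametric
prior is provided: it is deterministic, testable, and the synthetic
generator plants exactly this location/scale structure, so adjustment is
identifiable by construction.

Choices where the published recipe is underspecified:

* **Covariate protection.** Whether the original analysis protected
  subtype labels in the design is unknown; `covariates` is an optional
  argument (recommended when labels exist, since unbalanced batches
  otherwise absorb biology).
* **Gene filtering.** `variance_filter()` retains genes with
  across-sample SD (n−1 denominator) strictly greater than the threshold;
  the published cutoff 1.05 (on the compiled log2 matrix) is the default.
* **Centering.** "Normalized and centred" pre-clustering is interpreted
  as per-gene median centering with optional unit-SD scaling
  (`center_genes()`, both configurable); the exact recipe was not stated.

# Consensus clustering and cluster validation

`consensus_cluster()` follows the resampled-consensus scheme: in each of
`n_iter` iterations (published setting 1000) a fraction `subsample`
(published 0.8) of samples is drawn without replacement and clustered by
average-linkage (UPGMA) hierarchical clustering of Euclidean distances
(1 − Pearson offered as an option); the consensus entry for a sample pair
is the fraction of co-sampled iterations in which they co-clustered.
Subsampling draws samples only, matching the defaults of the GenePattern
implementation for the options the paper names. Final labels cut the
average-linkage tree of 1 − consensus.

`select_k()` reports, per k, the consensus CDF area, its relative
increments, the proportion of ambiguous clustering (PAC: entries strictly
between 0.1 and 0.9) and mean within-cluster consensus ("purity"). The
*recommended* k is the PAC minimizer. The naive "argmax of the delta-area"
rule is almost always k = 2 on real consensus curves, which contradicts
the behaviour the contract itself expects on planted data; PAC is the
accepted modern repair and recovers the planted k in the tests. The
recommendation is advisory only: the original workflow clustered at
K_max = 18 and merged clusters by biological annotation, a step that is
not algorithmically specified; `relabel_small_clusters()` reproduces the
"Others" residue rule (clusters below 2% of samples, configurable).

`silhouette_widths()` computes SW(i) = (b − a)/max(a, b); samples with
SW > 0 are "core" samples, the training material of the predictors.
Singleton clusters are assigned SW = 0 with a warning.

`sigclust_test()` asks whether a 2-cluster split exceeds single-Gaussian
structure: the cluster index (within-cluster SS over total SS of the best
2-means) is compared to its parametric-bootstrap distribution under a
Gaussian with diagonal covariance from the data's eigenvalue spectrum.
Two regularizations matter numerically. First, raw sample eigenvalues are
overdispersed, which makes the naive bootstrap so conservative that its
type-I rate is ~0; the spectrum is therefore shrunk toward its isotropic
mean with the Ledoit–Wolf intensity before simulation. Under an isotropic
null the intensity approaches 1, restoring calibration (the cluster index
is scale-invariant); strong signal directions are barely shrunk, so power
is retained. Second, eigenvalues are floored at a MAD-based background
noise variance (the "soft" variant), which matters when genes outnumber
samples and the sample spectrum is rank-deficient.

# Single-sample enrichment and subtype-specific gene sets

`ssgsea_score()` ranks each sample's genes by expression (descending,
ties broken by ascending gene id — deterministic across platforms) and
integrates the difference between the weighted in-set ECDF (weights
$r^\alpha$ on the expression ranks, normalized within the set) and the
unweighted out-of-set ECDF over the whole ranked list. $\alpha$ defaults
to 0.25, the convention of the single-sample lineage this scheme follows;
the source publication does not state it. Scores are not normalized by
gene count by default (a `normalize` flag divides by N for cross-set
comparability). With $\alpha = 0$ the score depends on ranks only and is
invariant to monotone transforms of a sample's values, a property the
tests exercise.

Subtype-specific sets are selected one-vs-rest (`select_subtype_sets()`)
by the conjunction of a SAM-style moderated difference statistic at
permutation FDR q ≤ 0 and ROC AUC > 0.85 (both published thresholds), with
overexpression required (d > 0) and results ordered by descending AUC.
Two deliberate simplifications of SAM: the exchangeability constant $s_0$
is the median of the per-row standard errors rather than the original
percentile search, and q-values use the *expected* (mean over
permutations) count of permuted statistics beyond each observed cutoff,
rather than the classic median count. The mean variant is what makes
"q = 0" a meaningful selection rule: q = 0 states that no permuted
statistic anywhere in the matrix reached the observed cutoff. With the
median variant the most extreme null row attains q = 0 roughly half the
time by exchangeability, and a q = 0 threshold could not control false
selections even approximately.

# Probit metagene subtype predictors

For each subtype, a one-vs-rest binary probit regression on metagenes
(`one_vs_rest()`): the top `n_per_subtype = 50` core samples per subtype
(highest SW, ties broken by sample id) form the training set; genes are
ranked by absolute Pearson correlation with the binary phenotype
(`n_genes = 100` kept); the centered signature submatrix is decomposed by
SVD, each basis vector oriented to a non-negative loading sum, and samples
are projected onto the top `n_metagenes = 2` components; coefficients are
sampled by Albert–Chib truncated-normal data augmentation under a vague
normal prior (`n_mcmc = 2000`, `burn_in = 500`). The original tool's exact
parameter choices live in unavailable supplements; these defaults are
deliberately modest, configurable, and tunable via the three-way-split
scheme in `cross_validate()`. Prediction projects new samples onto the
stored basis and applies the probit link at the posterior-mean
coefficients; per-dataset gene-wise standardization (default on) is the
cross-study shift correction, making predictions invariant to gene-wise
affine rescaling of the new cohort. Samples are assigned by argmax
probability with no floor — the published assignment rule is unstated —
and flagged low-confidence when the maximum is below 0.5. Perfect
separation does not break the sampler but lets the posterior drift; it is
detected and flagged, and the ranking of probabilities remains usable.

# Pooled shRNA screen analysis

Reads are counted by perfect match to the library sequences after a
constant 5' trim (`count_hairpins()`); no quality-aware alignment is
attempted, per the counting rule the screen itself used. Counts are
scaled to a common column total (`normalize_counts()`), screens are
compiled on their hairpin intersection, log2(x + 1) transformed, and
standardized across screens with the same empirical-Bayes batch model
(`combine_screens()`).

The per-hairpin differential metric is the signal-to-noise ratio
(mean difference over the sum of group SDs), with each SD floored at
max(sd, 0.2·|mean|, 0.2) — the GenePattern convention that prevents
division blow-ups on near-constant hairpins. This metric is also the
"hairpin score" used for display filtering (≥ 0.2), a quantity the source
never defines; defining it as the ranking metric itself is the natural
reading and is documented prominently here.

`riger_gene_scores()` converts ranked hairpins to gene scores by a
weighted Kolmogorov–Smirnov running sum (hits add normalized
|metric|^p, p = 1 by default; misses subtract 1/(N − n_gene)), run
separately from the amplified (high-metric) and depleted (low-metric)
ends — two one-sided analyses, since whether the original used one shared
list is unknown. Ties in the metric are broken by a deterministic string
hash of hairpin ids: libraries list a gene's hairpins consecutively, so
breaking ties by file order would fabricate gene-level enrichment whenever
metrics tie (e.g. all-equal metrics must yield no calls).

The permutation null of `riger_permutation_fdr()` reassigns hairpins to
genes preserving the hairpins-per-gene multiset. Under this null the
ranked metric list is fixed, so a gene's null score depends only on its
hairpin count; the null is therefore sampled once per distinct count
(`n_perm = 1000` subsets), which is the same distribution at a fraction of
the cost. p-values carry the +1 correction so they are never exactly 0
and BH is well defined; the reported dominant-direction p is doubled
(two one-sided tests) and capped at 1, keeping it super-uniform under the
null; q-values are Benjamini–Hochberg within direction. Calls use
q < 0.005 (discovery) or q < 0.03 (validation screening), the published
thresholds. `cohens_d()` and `sirna_validation_call()` (pass iff ≥ 20%
suppression on the target line, p < 0.001, and ≥ 20 points more
suppression than on reference lines) complete the downstream rules.

# Survival and clinical statistics

`km_estimate()` is the product-limit estimator; `logrank_test()` is the
k-group observed-minus-expected test with hypergeometric variance
(df = k − 1), unstratified — whether the original stratified by cohort is
unknown. `cox_fit()` wraps the field-standard Newton–Raphson Breslow
partial-likelihood fit (Efron ties are not offered; simulated times are
continuous) and reports HR, 95% Wald intervals and p-values; monotone
likelihood is flagged rather than silently reported. Binary encodings of
age (≥ 55), stage (III/IV), grade (≥ 2) and metastasis mirror the
published table and are user-configurable. `fisher_exact()` uses the
probability-mass two-sided rule; `mann_whitney_u()` enumerates exactly
for small samples and otherwise applies the tie- and continuity-corrected
normal approximation; `spearman_matrix()` is Pearson on midranks with the
t approximation for p.

`gi50()` estimates the 50% growth-inhibition concentration from a
twofold dilution series by a four-parameter logistic fit on log
concentration, falling back to log-linear interpolation between the
bracketing doses when the fit fails; a response that never crosses 50% is
reported censored ("> max dose" or "< min dose") rather than
extrapolated.

# The synthetic world

Generators are pure functions of (config, seed); defaults state the world
once:

* **Cohorts** (`simulate_cohort()`): Gaussian log2 noise (sd 1), k
  subtype signature blocks shifted by δ (default 1.5 = 1.5 noise SDs, the
  planted-recovery regime of the contract), batch location shifts and
  multiplicative residual scales — exactly the ComBat model, so
  adjustment is identifiable, and a green batch test establishes
  correctness of the estimator, not robustness to model misspecification.
* **Gene sets** (`simulate_gene_sets()`): one true subset of each
  signature block plus uniform decoys, whose overlap with signatures is
  hypergeometric by construction.
* **Survival** (`simulate_survival()`): exponential times with
  subtype-proportional hazards and independent uniform censoring solved to
  hit the requested censoring fraction in expectation. Proportional
  hazards hold exactly; Cox recovery tests validate the estimator, not the
  PH assumption.
* **Screens** (`simulate_screen()`): Gaussian hairpin log2 abundances,
  per-hairpin depletion N(1.5, 0.5²) applied to essential genes in the
  target group only, per-(hairpin, sample) replicate noise (sd 0.5 log2 —
  typical replicate scatter in pooled screens; the overdispersion beyond
  counting noise), and multinomial sampling at fixed depth, mirroring
  sequencing of a pooled PCR product. Default design: 2,000 genes × 5
  hairpins, 5 target vs 9 reference lines, depth 5 × 10⁶.
* **Dose-response** (`simulate_dose_response()`): the Hill curve
  100/(1 + (c/GI50)^h) with optional Gaussian noise; nine twofold
  dilutions by default (an eight-step/128-fold series is equally
  accepted).

What the synthetic world does **not** emulate: probe-level structure,
pathway cross-talk, non-Gaussian expression tails, sequencing error,
copy-number confounding of hairpin abundance, and informative censoring.
Green tests establish that the estimators recover the structure they
assume, at the stated sizes and effect magnitudes — not performance on any
particular clinical cohort.

# Known limitations

* Gene identifiers are opaque strings; probe-to-gene collapsing is out of
  scope (the original probe list is unavailable).
* The consolidation of many consensus clusters into named subtypes is a
  biological, not algorithmic, step; the package exposes the machinery
  (tree cuts, small-cluster relabeling) but not the annotation.
* Exact numerical reproduction of the original BinReg 2.0 and RIGER
  binaries is not attempted; contracts are implemented from their stated
  definitions with the documented choices above.
* The CLI consumes JSON (not YAML) configuration files.
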