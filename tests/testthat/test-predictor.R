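fake_assignment <- function(labels, sw) {
  data.frame(sample = names(labels), label = unname(labels), sw = sw,
             core = sw > 0, stringsAsFactors = FALSE)
}

test_that("core training selection takes top silhouette widths", {
  set.seed(21)
  labels <- setNames(rep(c("A", "B"), c(60, 30)), sprintf("s%03d", 1:90))
  sw <- c(seq(0.9, 0.01, length.out = 60), seq(0.5, 0.01, length.out = 30))
  asg <- fake_assignment(labels, sw)
  expect_warning(picked <- pick_core_training(asg, 50), "only 30")
  expect_length(picked, 80)
  a_picked <- intersect(picked, names(labels)[labels == "A"])
  expect_setequal(a_picked, asg$sample[asg$label == "A"][order(-asg$sw[asg$label == "A"])][1:50])

  # deterministic tie-break by sample id
  asg2 <- fake_assignment(setNames(rep("A", 3), c("s3", "s1", "s2")),
                          c(0.5, 0.5, 0.9))
  expect_identical(pick_core_training(asg2, 2), c("s2", "s1"))

  asg3 <- fake_assignment(setNames(c("A", "B"), c("s1", "s2")), c(0.5, -0.1))
  expect_error(pick_core_training(asg3, 1), "zero core")
})

test_that("signature gene ranking follows |correlation|", {
  set.seed(22)
  labels <- rep(c(0, 1), each = 20)
  e <- random_expr(50, 40, seed = 22)
  e["g01", ] <- labels          # identical to the label
  e <- tiny_expr(e, genes = rownames(e))
  sig <- select_signature_genes(e, labels, n_genes = 5)
  expect_identical(sig$gene[1], "g01")
  expect_equal(abs(sig$score[1]), 1)
  # independent genes have |r| bounded by ~4/sqrt(n)
  expect_lt(abs(sig$score[5]), 1)
  expect_warning(select_signature_genes(e, labels, n_genes = 100), "using all")
})

test_that("metagene decomposition is an SVD with oriented basis", {
  e <- random_expr(10, 12, seed = 23)
  dec <- metagene_decompose(e, n_metagenes = 3)
  expect_equal(crossprod(dec$basis), diag(3), tolerance = 1e-10)
  expect_true(all(colSums(dec$basis) >= 0))

  rank1 <- tiny_expr(outer(1:6, seq(0.5, 3, length.out = 8)))
  d1 <- metagene_decompose(rank1, n_metagenes = 3)
  expect_equal(ncol(d1$basis), 1)  # only one non-null component

  # full reconstruction from all components
  full <- metagene_decompose(e, n_metagenes = 12)
  rec <- full$basis %*% full$scores + full$gene_means
  expect_equal(unname(rec), unname(unclass(e)), tolerance = 1e-8)
})

test_that("probit Gibbs sampler respects symmetry and monotonicity", {
  set.seed(24)
  labels <- rep(c(0, 1), each = 30)
  zero_fit <- probit_fit(rep(0, 60), labels, n_mcmc = 1500, burn_in = 300,
                         seed = 1)
  expect_lt(abs(pnorm(zero_fit$coef_mean[1]) - 0.5), 0.07)

  x <- c(rnorm(30, -0.8), rnorm(30, 0.8))
  fit <- probit_fit(x, labels, n_mcmc = 3000, burn_in = 500, seed = 2)
  expect_gt(fit$coef_mean[2], 0)
  # training probabilities ordered with the scores
  p_train <- pnorm(fit$coef_mean[1] + fit$coef_mean[2] * x)
  expect_gt(cor(p_train, x, method = "spearman"), 0.999)
  flip <- probit_fit(x, 1 - labels, n_mcmc = 3000, burn_in = 500, seed = 2)
  expect_lt(flip$coef_mean[2], 0)
  expect_lt(abs(fit$coef_mean[2] + flip$coef_mean[2]), 0.3)
})

test_that("prediction is deterministic and uses the probit closed form", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 120, n_samples = 80, k_subtypes = 2, genes_per_signature = 30,
    signature_effect = 2, noise_sd = 0.7, seed = 25))
  labels <- as.numeric(sim$subtype == "S1")
  model <- train_signature_model(sim$expr, labels, n_genes = 40,
                                 n_metagenes = 2, n_mcmc = 800,
                                 burn_in = 200, seed = 3)
  p <- predict_probability(model, sim$expr)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p > 0.5) == (labels == 1)), 0.9)

  # duplicated sample gets an identical probability
  dup <- expression_matrix(sim$expr[, c(1, 1, 2)],
                           sample_ids = c("d1", "d2", "d3"))
  pd <- predict_probability(model, dup)
  expect_equal(pd[["d1"]], pd[["d2"]])

  # a sample at the metagene origin scores Phi(intercept)
  origin <- expression_matrix(
    matrix(model$gene_means, ncol = 2, nrow = length(model$gene_means),
           dimnames = list(names(model$gene_means), c("o1", "o2"))))
  po <- predict_probability(model, origin)
  expect_equal(unname(po[1]), pnorm(model$coef_mean[1]), tolerance = 1e-10)

  tiny <- expression_matrix(sim$expr[1:10, 1:3])
  expect_error(predict_probability(model, tiny), "80%")
})

test_that("one-vs-rest recovers planted subtypes on held-out samples", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 200, n_samples = 150, k_subtypes = 3, genes_per_signature = 40,
    signature_effect = 1.5, noise_sd = 1, seed = 26))
  d <- as.matrix(dist(t(sim$expr)))
  asg <- silhouette_widths(d, sim$subtype)
  ovr <- one_vs_rest(sim$expr, asg, n_per_subtype = 25, n_genes = 60,
                     n_metagenes = 2, n_mcmc = 800, burn_in = 200, seed = 4)
  expect_length(ovr$models, 3)
  pred <- ovr$prediction
  truth <- sim$subtype[pred$sample]
  expect_gt(mean(pred$assigned == truth) * 100, 85)
  expect_true(all(c("assigned", "low_confidence") %in% colnames(pred)))
})

test_that("cross-validation is deterministic and sane on separable data", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 120, n_samples = 90, k_subtypes = 3, genes_per_signature = 30,
    signature_effect = 3, noise_sd = 0.5, seed = 27))
  d <- as.matrix(dist(t(sim$expr)))
  asg <- silhouette_widths(d, sim$subtype)
  cv <- cross_validate(sim$expr, asg, scheme = "kfold", k = 3,
                       n_per_subtype = 20, n_genes = 40, n_metagenes = 2,
                       n_mcmc = 600, burn_in = 150, seed = 5)
  expect_gt(cv$mean_concordance, 95)
  cv2 <- cross_validate(sim$expr, asg, scheme = "kfold", k = 3,
                        n_per_subtype = 20, n_genes = 40, n_metagenes = 2,
                        n_mcmc = 600, burn_in = 150, seed = 5)
  expect_identical(cv$folds, cv2$folds)
  expect_error(cross_validate(sim$expr, asg, scheme = "kfold", k = 60),
               "smallest class")
})
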