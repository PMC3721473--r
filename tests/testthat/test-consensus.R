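test_that("average linkage clusters simple 1-D configurations correctly", {
  d <- as.matrix(dist(c(0, 1, 10)))
  fit <- hierarchical_average_linkage(d, k = 2)
  expect_equal(unname(fit$labels[1]), unname(fit$labels[2]))
  expect_false(fit$labels[3] == fit$labels[1])

  fit_n <- hierarchical_average_linkage(d, k = 3)
  expect_length(unique(fit_n$labels), 3)

  dd <- as.matrix(dist(c(5, 5, 9)))
  tree <- hierarchical_average_linkage(dd)$tree
  expect_equal(min(tree$height), 0)  # duplicated points merge at height 0

  dbad <- d; dbad[1, 2] <- dbad[2, 1] <- NaN
  expect_error(hierarchical_average_linkage(dbad), "NA")
})

test_that("consensus matrix reflects resampled co-clustering", {
  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 60, n_samples = 45, k_subtypes = 3, genes_per_signature = 20,
    signature_effect = 3, noise_sd = 0.3, seed = 7))
  cc <- consensus_cluster(sim$expr, k_range = 3, n_iter = 100, seed = 11)
  M <- cc$k3$consensus
  expect_true(isSymmetric(unname(M)))
  expect_true(all(diag(M) == 1))
  same <- outer(sim$subtype, sim$subtype, "==")
  expect_gt(min(M[same & upper.tri(M)]), 0.9)
  expect_lt(max(M[!same & upper.tri(M)]), 0.1)
  expect_equal(adjusted_rand_index(cc$k3$labels, sim$subtype), 1)

  # no resampling variation: subsample = 1 makes every entry 0 or 1
  cc1 <- consensus_cluster(sim$expr, k_range = 3, n_iter = 5, subsample = 1,
                           seed = 2)
  expect_true(all(cc1$k3$consensus %in% c(0, 1)))

  # two identical samples always co-cluster
  e <- random_expr(20, 8, seed = 3)
  e[, 2] <- e[, 1]
  e <- tiny_expr(e)
  cci <- consensus_cluster(e, k_range = 2, n_iter = 60, seed = 4)
  expect_equal(cci$k2$consensus[1, 2], 1)
})

test_that("select_k metrics behave at the extremes and find planted k", {
  block <- function(sizes) {
    M <- matrix(0, sum(sizes), sum(sizes))
    start <- cumsum(c(1, sizes))
    for (i in seq_along(sizes)) {
      ix <- start[i]:(start[i + 1] - 1)
      M[ix, ix] <- 1
    }
    M
  }
  mk <- function(M, k) list(k = k, consensus = M,
                            labels = rep(seq_len(k), length.out = nrow(M)))
  Mb <- block(c(5, 5, 5))
  res <- list(k2 = mk(Mb, 2),
              k3 = list(k = 3, consensus = Mb,
                        labels = rep(1:3, each = 5)))
  sel <- select_k(res)
  expect_equal(sel$metrics$pac[sel$metrics$k == 3], 0)
  expect_equal(sel$metrics$purity[sel$metrics$k == 3], 1)

  Mamb <- matrix(0.5, 12, 12); diag(Mamb) <- 1
  res2 <- list(k2 = mk(Mamb, 2), k3 = mk(Mamb, 3))
  expect_equal(select_k(res2)$metrics$pac, c(1, 1))

  sim <- simulate_cohort(cohort_sim_config(
    n_genes = 150, n_samples = 100, k_subtypes = 5, genes_per_signature = 25,
    signature_effect = 2.5, noise_sd = 0.5, seed = 13))
  cc <- consensus_cluster(sim$expr, k_range = 2:7, n_iter = 80, seed = 5)
  expect_equal(select_k(cc)$recommended_k, 5)
})

test_that("silhouette widths match hand values and the brute-force oracle", {
  d <- as.matrix(dist(c(0, 0, 10, 10)))
  sw <- silhouette_widths(d, c(1, 1, 2, 2))
  expect_equal(sw$sw, rep(1, 4))
  expect_true(all(sw$core))

  # a == b boundary: equidistant point (cluster 2 is a singleton -> warning)
  d2 <- as.matrix(dist(c(0, 2, 4)))
  expect_warning(sw2 <- silhouette_widths(d2, c(1, 1, 2)), "singleton")
  expect_equal(sw2$sw[2], 0)  # a = b = 2 for the middle point

  set.seed(6)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    x <- matrix(rnorm(n * 4), n)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    d <- as.matrix(dist(x))
    got <- suppressWarnings(silhouette_widths(d, labels)$sw)
    expect_equal(got, silhouette_oracle(d, labels), tolerance = 1e-12)
  }

  # random labels on structureless data: mean SW near zero
  set.seed(7)
  means <- replicate(30, {
    x <- matrix(rnorm(40 * 5), 40)
    mean(suppressWarnings(
      silhouette_widths(as.matrix(dist(x)), sample(1:3, 40, TRUE))$sw))
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("sigclust separates real clusters and respects duplication", {
  x <- cbind(matrix(rnorm(20 * 12, 0, 0.5), 20), matrix(rnorm(20 * 12, 3, 0.5), 20))
  dimnames(x) <- list(paste0("g", 1:20), paste0("s", 1:24))
  res <- sigclust_test(expression_matrix(x), n_sim = 400, seed = 1)
  expect_lt(res$p_value, 0.005)

  dup <- expression_matrix(cbind(x, x), sample_ids = paste0("t", 1:48))
  res_dup <- sigclust_test(dup, n_sim = 400, seed = 1)
  expect_lt(abs(res_dup$p_value - res$p_value), 0.05)
  expect_error(sigclust_test(expression_matrix(x[, 1:3, drop = FALSE])), ">= 4")
})

test_that("concordance counts agreement after optimal matching", {
  a <- setNames(c("x", "x", "y", "y"), paste0("s", 1:4))
  expect_equal(concordance(a, a)$percent_agreement, 100)
  expect_equal(concordance(a, a)$ari, 1)

  b <- a; b[4] <- "x"
  expect_equal(concordance(a, b)$percent_agreement, 75)

  set.seed(8)
  a5 <- sample(paste0("C", 1:5), 500, TRUE)
  b5 <- sample(paste0("C", 1:5), 500, TRUE)
  res <- concordance(a5, b5)
  expect_lt(abs(res$percent_agreement - 20), 8)
  expect_lt(abs(res$ari), 0.05)
  expect_error(concordance(setNames(a5[1:3], paste0("p", 1:3)),
                           setNames(b5[1:3], paste0("q", 1:3))), "no samples")
})

test_that("tiny clusters are relabeled Other", {
  labels <- c(rep("A", 60), rep("B", 39), "C")
  out <- relabel_small_clusters(labels, min_fraction = 0.02)
  expect_equal(sum(out == "Other"), 1)
  expect_equal(sort(unique(out)), c("A", "B", "Other"))
})
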