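test_that("hairpin counting is exact-match only", {
  lib <- tiny_library(n_genes = 2, hairpins_per_gene = 2, seed = 31)
  reads <- c(lib$sequence[1], lib$sequence[1], lib$sequence[2],
             sub("A", "T", sub("^.", "N", lib$sequence[3])))  # mismatch
  counts <- count_hairpins(reads, lib)
  expect_equal(unname(counts[1:3]), c(2L, 1L, 0L))
  expect_equal(attr(counts, "n_unmatched"), 1L)

  # trimming: reads carry a 3-base 5' adapter
  counts2 <- count_hairpins(paste0("TTT", lib$sequence), lib, trim5 = 3)
  expect_equal(as.vector(counts2), rep(1L, 4))

  # FASTA file input
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1", lib$sequence[1], ">r2", lib$sequence[4]), fa)
  counts3 <- count_hairpins(fa, lib)
  expect_equal(unname(counts3[c(1, 4)]), c(1L, 1L))
  expect_error(count_hairpins(character(), lib), "no reads")
})

test_that("normalization scales columns and preserves proportions", {
  m <- matrix(c(2, 2, 1, 3), 2, 2,
              dimnames = list(c("h1", "h2"), c("a", "b")))
  norm <- normalize_counts(m, scale = 1e6)
  expect_equal(norm[, "a"], c(h1 = 5e5, h2 = 5e5))
  expect_equal(colSums(norm), c(a = 1e6, b = 1e6))
  expect_equal(normalize_counts(norm, 1e6), norm)  # idempotent
  expect_equal(norm["h2", "b"] / norm["h1", "b"], 3)
  m0 <- m; m0[, 1] <- 0
  expect_error(normalize_counts(m0), "zero-total")
})

test_that("combining screens intersects hairpins and removes screen offsets", {
  set.seed(32)
  base <- matrix(rpois(200 * 4, 400), 200, 4,
                 dimnames = list(sprintf("h%03d", 1:200), paste0("a", 1:4)))
  shifted <- matrix(rpois(200 * 4, 800), 200, 4,
                    dimnames = list(sprintf("h%03d", 1:200), paste0("b", 1:4)))
  extra <- rbind(shifted, matrix(5, 3, 4, dimnames = list(c("x1", "x2", "x3"),
                                                          paste0("b", 1:4))))
  res <- combine_screens(list(s1 = base, s2 = extra))
  expect_setequal(res$excluded, c("x1", "x2", "x3"))
  expect_equal(nrow(res$expr), 200)
  # planted ~1 log2 offset between screens removed to within 5%
  gap <- mean(rowMeans(res$expr[, 1:4]) - rowMeans(res$expr[, 5:8]))
  expect_lt(abs(gap), 0.05)

  single <- combine_screens(list(only = base))
  expect_equal(single$expr,
               normalize_counts(base, log2_transform = TRUE))
})

test_that("signal-to-noise matches hand arithmetic and is antisymmetric", {
  a <- matrix(c(0, 2), 1); b <- matrix(c(-2, 0), 1)
  expect_equal(signal_to_noise(a, b, floor_min = 0), 2 / (2 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(signal_to_noise(a, a), 0)
  set.seed(33)
  x <- matrix(rnorm(40), 4); y <- matrix(rnorm(40, 1), 4)
  expect_equal(signal_to_noise(x, y), -signal_to_noise(y, x))
  expect_error(signal_to_noise(matrix(1), matrix(1:2, 1)), ">= 2")
})

test_that("gene enrichment scores match hand values and the brute-force oracle", {
  lib <- tiny_library(n_genes = 20, hairpins_per_gene = 5, seed = 34)
  metrics <- setNames(seq(10, 0.1, length.out = 100), lib$hairpin_id)
  res <- riger_gene_scores(metrics, lib, weight_exponent = 0)
  expect_equal(res$es_amplified[res$gene == "G01"], 1)  # ranks 1-5 of 100

  # single-hairpin gene at the very bottom
  lib1 <- rbind(lib, data.frame(hairpin_id = "hp999", gene = "G99",
                                sequence = paste(rep("A", 21), collapse = "")))
  m1 <- c(metrics, hp999 = 0.01)
  res1 <- riger_gene_scores(m1, lib1, weight_exponent = 0)
  expect_equal(res1$direction[res1$gene == "G99"], "depleted")
  expect_gt(res1$es_depleted[res1$gene == "G99"], 0.99)

  # uniformly spread hairpins give small |ES|
  spread <- lib[lib$gene == "G01", ]
  spread_metrics <- metrics
  spread_pos <- c(10, 30, 50, 70, 90)
  nm <- names(sort(spread_metrics, decreasing = TRUE))
  reassigned <- lib
  reassigned$gene[match(nm[spread_pos], reassigned$hairpin_id)] <- "GS"
  res_s <- riger_gene_scores(spread_metrics, reassigned, weight_exponent = 0)
  expect_lt(res_s$es_amplified[res_s$gene == "GS"], 0.3)

  # oracle equality on random instances, both weightings
  set.seed(35)
  for (rep in 1:10) {
    libx <- tiny_library(n_genes = 12, hairpins_per_gene = sample(2:5, 1),
                         seed = 100 + rep)
    mx <- setNames(rnorm(nrow(libx)), libx$hairpin_id)
    for (p in c(0, 1)) {
      got <- riger_gene_scores(mx, libx, weight_exponent = p)
      ord_hi <- order(-mx)
      pos_hi <- integer(length(mx)); pos_hi[ord_hi] <- seq_along(mx)
      for (g in unique(libx$gene)) {
        ix <- which(libx$gene == g)
        pos <- sort(pos_hi[ix])
        w <- abs(mx[ix])[order(pos_hi[ix])]^p
        expect_equal(got$es_amplified[got$gene == g],
                     ks_oracle(pos, w, length(mx)), tolerance = 1e-12)
      }
    }
  }
})

test_that("permutation p-values and BH q-values are correct and directional", {
  expect_equal(ovca:::.bh_adjust(c(0.01, 0.02, 0.03, 1.0)),
               c(0.04, 0.04, 0.04, 1.0))
  set.seed(36)
  for (rep in 1:5) {
    p <- runif(sample(5:40, 1))
    expect_equal(ovca:::.bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }

  # tied metrics carry no signal: with the pseudo-random tie scatter no gene
  # should look enriched (the observed ES is a typical null draw)
  lib <- tiny_library(n_genes = 30, hairpins_per_gene = 4, seed = 37)
  flat <- setNames(rep(1, nrow(lib)), lib$hairpin_id)
  res_flat <- riger_permutation_fdr(riger_gene_scores(flat, lib), flat, lib,
                                    n_perm = 200, seed = 1)
  expect_gt(min(res_flat$q), 0.2)
  expect_gt(mean(res_flat$p), 0.3)

  # direction consistency: negating metrics swaps depleted and amplified
  set.seed(38)
  mx <- setNames(rnorm(nrow(lib)), lib$hairpin_id)
  r_pos <- riger_gene_scores(mx, lib)
  r_neg <- riger_gene_scores(-mx, lib)
  expect_equal(r_pos$es_amplified, r_neg$es_depleted, tolerance = 1e-12)
  expect_equal(r_pos$es_depleted, r_neg$es_amplified, tolerance = 1e-12)
})

test_that("gene calling applies the q and hairpin-score thresholds", {
  riger <- data.frame(gene = c("A", "B", "C"),
                      es = c(-0.9, -0.8, 0.7),
                      direction = c("depleted", "depleted", "amplified"),
                      q = c(0.004, 0.006, 0.001), stringsAsFactors = FALSE)
  lib <- data.frame(hairpin_id = paste0("h", 1:6),
                    gene = rep(c("A", "B", "C"), each = 2),
                    sequence = ovca:::.random_unique_seqs(6),
                    stringsAsFactors = FALSE)
  metrics <- setNames(c(-0.25, -0.1, -0.3, -0.3, 0.5, 0.15), lib$hairpin_id)
  calls <- call_subtype_genes(riger, metrics, lib, q_max = 0.005,
                              hairpin_score_min = 0.2)
  expect_identical(calls$depleted$gene, "A")      # B fails q < 0.005
  expect_identical(calls$depleted$hairpins, "h1") # h2 fails |score| >= 0.2
  expect_identical(calls$amplified$gene, "C")

  # monotonicity: a looser q admits a superset
  loose <- call_subtype_genes(riger, metrics, lib, q_max = 0.03)
  expect_true(all(calls$depleted$gene %in% loose$depleted$gene))
  expect_true("B" %in% loose$depleted$gene)
})

test_that("effect size and siRNA decision rules match the stated conventions", {
  # means 1 vs 0 with unit pooled SD (two-point groups with var 1)
  expect_equal(cohens_d(1 + c(-1, 1) * sqrt(2) / 2,
                        0 + c(-1, 1) * sqrt(2) / 2), 1, tolerance = 1e-12)
  expect_equal(cohens_d(1:4, 1:4), 0)
  expect_equal(cohens_d(2 * c(1, 3, 5), 2 * c(2, 4, 6)),
               cohens_d(c(1, 3, 5), c(2, 4, 6)))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")

  expect_true(sirna_validation_call(25, 1e-4, 2))
  expect_false(sirna_validation_call(25, 1e-4, 10))   # differential only 15
  expect_false(sirna_validation_call(15, 1e-9, 0))    # below 20% suppression
  expect_false(sirna_validation_call(25, 0.01, 0))    # p too large
  expect_error(sirna_validation_call(25, NA, 2), "p-value")
})
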