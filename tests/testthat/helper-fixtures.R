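# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except through temporary files created
# here.

tiny_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, genes, samples)
}

random_expr <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  tiny_expr(matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_library <- function(n_genes = 4, hairpins_per_gene = 3, seed = 1) {
  set.seed(seed)
  h <- n_genes * hairpins_per_gene
  data.frame(
    hairpin_id = sprintf("hp%03d", seq_len(h)),
    gene = rep(sprintf("G%02d", seq_len(n_genes)), each = hairpins_per_gene),
    sequence = ovca:::.random_unique_seqs(h, width = 21L),
    stringsAsFactors = FALSE)
}

# Independent brute-force oracles ------------------------------------------

# ssGSEA: explicit walk down the full ranked list.
ssgsea_oracle <- function(v, genes, set, alpha) {
  ord <- order(-v, genes, method = "radix")
  N <- length(v)
  inset <- genes[ord] %in% set
  w <- (N - seq_len(N) + 1)^alpha
  w[!inset] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (N - sum(inset))
  sum(p_in - p_out)
}

# Weighted-KS enrichment: explicit running sum over every position.
ks_oracle <- function(positions, weights, N) {
  w <- if (sum(weights) > 0) weights / sum(weights) else
    rep(1 / length(positions), length(positions))
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    j <- match(i, positions)
    if (!is.na(j)) run <- run + w[[j]] else run <- run - 1 / (N - length(positions))
    best <- max(best, run)
  }
  best
}

# Silhouette widths: literal per-sample double loop.
silhouette_oracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[[i]]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[[i]]), function(l) {
      mean(d[i, labels == l])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
}

# Fisher exact p: enumerate every assignment of row membership.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  count_ways <- choose(m, support) * choose(n, k - support)
  probs <- count_ways / choose(m + n, k)
  sum(probs[probs <= probs[support == tab[1, 1]] * (1 + 1e-7)])
}

# BH q-value as its definition: the minimal estimated FDR (m * t / #{p <= t})
# over all rejection thresholds t that still include hypothesis i.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- p[p >= p[[i]] - 1e-15]
    min(1, vapply(cand, function(t) m * t / sum(p <= t + 1e-15), 0))
  }, 0)
}
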