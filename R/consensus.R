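# Subtype discovery by resampled consensus of average-linkage hierarchical
# clusterings, with silhouette-width core-sample calling, a Gaussian-null
# two-cluster significance test, and label concordance utilities.

#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#'
#' Thin wrapper over agglomerative average linkage returning both the merge
#' tree and, optionally, cut-to-k labels. Deterministic given the input.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @param k optional number of clusters to cut to.
#' @return list with `tree` (an `hclust`) and `labels` (integer vector, or
#'   `NULL` when `k` is missing).
#' @export
hierarchical_average_linkage <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    .assert(!anyNA(d), "distance matrix contains NA")
    .assert(isSymmetric(unname(d)), "distance matrix must be symmetric")
    .assert(all(diag(d) == 0), "distance matrix must have a zero diagonal")
    .assert(all(d >= 0), "distances must be non-negative")
    d <- stats::as.dist(d)
  }
  .assert(!anyNA(d), "distance matrix contains NA")
  tree <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  list(tree = tree, labels = labels)
}

#' Consensus clustering over random sample subsamples
#'
#' For each iteration, a fraction `subsample` of samples is drawn without
#' replacement, clustered by average-linkage hierarchical clustering of the
#' chosen distance, and cut to k. The consensus matrix entry M\[i, j\] is
#' the fraction of co-sampled runs in which i and j co-clustered. Final
#' labels come from average-linkage clustering of 1 - M.
#'
#' @param expr genes x samples matrix (samples are clustered).
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_iter resampling iterations (published setting: 1000).
#' @param subsample sample fraction per iteration (published setting: 0.8).
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson correlation).
#' @param seed RNG seed.
#' @return named list (one element per k) with `k`, `consensus` (samples x
#'   samples), `cosample_counts`, `labels`, `tree`.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, n_iter = 1000,
                              subsample = 0.8,
                              distance = c("euclidean", "pearson"),
                              seed = 1L) {
  distance <- match.arg(distance)
  expr <- expression_matrix(expr)
  .assert(n_iter >= 1, "n_iter must be >= 1")
  .assert(subsample > 0 && subsample <= 1, "subsample must be in (0, 1]")
  n <- ncol(expr)
  m <- max(2L, floor(subsample * n))
  set.seed(seed)
  draws <- lapply(seq_len(n_iter), function(i) sort(sample.int(n, m)))
  dists <- lapply(draws, function(idx) .sample_dist(expr[, idx, drop = FALSE], distance))
  cosample <- matrix(0, n, n)
  for (idx in draws) cosample[idx, idx] <- cosample[idx, idx] + 1
  out <- lapply(k_range, function(k) {
    cocluster <- matrix(0, n, n)
    for (b in seq_len(n_iter)) {
      idx <- draws[[b]]
      lab <- stats::cutree(stats::hclust(dists[[b]], method = "average"), k = k)
      for (cl in unique(lab)) {
        members <- idx[lab == cl]
        cocluster[members, members] <- cocluster[members, members] + 1
      }
    }
    M <- cocluster / pmax(cosample, 1)
    never <- cosample == 0 & upper.tri(cosample)
    if (any(never)) {
      warning(sprintf("%d sample pair(s) never co-sampled; consensus imputed 0",
                      sum(never)), call. = FALSE)
    }
    diag(M) <- 1
    dimnames(M) <- list(colnames(expr), colnames(expr))
    fit <- hierarchical_average_linkage(1 - M, k = k)
    list(k = k, consensus = M, cosample_counts = cosample,
         labels = stats::setNames(fit$labels, colnames(expr)), tree = fit$tree)
  })
  names(out) <- paste0("k", k_range)
  out
}

.sample_dist <- function(expr, distance) {
  if (distance == "euclidean") {
    stats::dist(t(expr))
  } else {
    stats::as.dist(1 - stats::cor(expr))
  }
}

#' Per-k consensus metrics and an advisory choice of k
#'
#' Reports, per k: the empirical CDF area of the consensus entries, the
#' relative delta area, the proportion of ambiguous clustering
#' (PAC; entries in (0.1, 0.9)), and mean within-cluster consensus
#' ("purity"). The recommended k is the PAC minimizer (ties to the
#' smallest k) — advisory only; biological relabeling/merging is left to
#' the analyst.
#'
#' @param results list returned by [consensus_cluster()] over >= 2 values
#'   of k.
#' @param pac_lower,pac_upper PAC ambiguity window bounds.
#' @return list with `metrics` (data.frame) and `recommended_k`.
#' @export
select_k <- function(results, pac_lower = 0.1, pac_upper = 0.9) {
  .assert(length(results) >= 2, "need consensus results for >= 2 values of k")
  rows <- lapply(results, function(res) {
    M <- res$consensus
    v <- M[upper.tri(M)]
    grid <- seq(0, 1, by = 0.01)
    cdf <- stats::ecdf(v)(grid)
    area <- sum(diff(grid) * cdf[-1L])
    pac <- mean(v > pac_lower & v < pac_upper)
    purity <- mean(unlist(lapply(split(seq_along(res$labels), res$labels),
                                 function(ix) {
                                   if (length(ix) < 2) return(1)
                                   sub <- M[ix, ix]
                                   sub[upper.tri(sub)]
                                 })))
    data.frame(k = res$k, cdf_area = area, pac = pac, purity = purity)
  })
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  metrics <- metrics[order(metrics$k), ]
  metrics$delta_area <- c(metrics$cdf_area[[1L]],
                          diff(metrics$cdf_area) /
                            pmax(metrics$cdf_area[-nrow(metrics)], 1e-12))
  list(metrics = metrics,
       recommended_k = metrics$k[[which.min(metrics$pac)]])
}

#' Silhouette widths and core-sample mask
#'
#' SW(i) = (b - a) / max(a, b), with a = mean distance to own cluster and
#' b = the smallest mean distance to another cluster. Samples in singleton
#' clusters get SW = 0 with a warning. Core samples are those with SW > 0.
#'
#' @param d samples x samples distance matrix (or `dist`).
#' @param labels cluster label per sample (>= 2 non-empty clusters).
#' @return data.frame with `sample`, `label`, `sw`, `core`.
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  .assert(length(labels) == n, "one label per sample required")
  labels <- as.character(labels)
  levs <- unique(labels)
  .assert(length(levs) >= 2, "need >= 2 clusters")
  sizes <- table(labels)
  if (any(sizes == 1)) {
    warning("singleton cluster(s); their samples get SW = 0", call. = FALSE)
  }
  # Mean distance from every sample to every cluster, in one pass.
  member <- vapply(levs, function(l) as.numeric(labels == l), numeric(n))
  sums <- d %*% member                       # n x k total distance to cluster
  counts <- matrix(sizes[levs], n, length(levs), byrow = TRUE)
  own <- member == 1
  a_counts <- counts - own                    # exclude self from own cluster
  means <- sums / pmax(counts, 1)
  a <- rowSums((sums * own)) / pmax(rowSums(a_counts * own), 1)
  means_other <- means
  means_other[own == 1] <- Inf
  b <- apply(means_other, 1L, min)
  sw <- (b - a) / pmax(a, b)
  sw[labels %in% names(sizes)[sizes == 1]] <- 0
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(sample = ids, label = labels, sw = sw, core = sw > 0,
             stringsAsFactors = FALSE)
}

#' Gaussian-null significance test for a two-cluster split
#'
#' The cluster index CI = within-cluster SS / total SS of the best 2-means
#' partition is compared to its distribution under a single multivariate
#' Gaussian null with diagonal covariance given by the data's eigenvalue
#' spectrum. Raw sample eigenvalues are overdispersed (which makes the raw
#' parametric bootstrap severely conservative), so the spectrum is
#' regularized by Ledoit-Wolf shrinkage toward its isotropic mean and then
#' floored at a MAD-based background-noise variance (the soft
#' background-noise variant).
#'
#' @param expr genes x samples matrix restricted to the two clusters under
#'   test (>= 4 samples).
#' @param n_sim null simulations (published SigClust lineage uses 1000).
#' @param seed RNG seed.
#' @param nstart 2-means restarts.
#' @return list with `p_value`, `ci_observed`, `ci_null`.
#' @export
sigclust_test <- function(expr, n_sim = 1000, seed = 1L, nstart = 5L) {
  expr <- expression_matrix(expr)
  n <- ncol(expr)
  .assert(n >= 4, "sigclust_test needs >= 4 samples")
  x <- t(expr)                      # samples x genes
  xc <- scale(x, center = TRUE, scale = FALSE)
  set.seed(seed)
  ci_obs <- .cluster_index_2means(xc, nstart)
  sv <- svd(xc, nu = 0, nv = 0)$d
  eig <- numeric(ncol(xc))
  eig[seq_along(sv)] <- sv^2 / (n - 1)
  eig <- .lw_shrink_eigenvalues(xc, eig)
  sigma2_bg <- (stats::mad(xc))^2
  eig <- pmax(eig, sigma2_bg)
  ci_null <- vapply(seq_len(n_sim), function(b) {
    sim <- matrix(stats::rnorm(n * length(eig)), n) *
      matrix(sqrt(eig), n, length(eig), byrow = TRUE)
    .cluster_index_2means(sim, nstart)
  }, 0)
  p <- mean(ci_null <= ci_obs)
  list(p_value = p, ci_observed = ci_obs, ci_null = ci_null)
}

# Ledoit-Wolf (2004) shrinkage of the covariance spectrum toward mu * I.
# Under an isotropic null the intensity approaches 1, undoing the
# overdispersion of sample eigenvalues; strong signal directions are left
# nearly untouched, preserving power.
.lw_shrink_eigenvalues <- function(xc, eig) {
  n <- nrow(xc); p <- ncol(xc)
  mu <- mean(eig)
  d2 <- sum((eig - mu)^2) / p
  if (d2 == 0) return(eig)
  xn <- sum(rowSums(xc^2)^2) / n^2
  b2 <- min((xn - sum(eig^2) * (n - 1)^2 / n^2 / n) / p, d2)
  b2 <- max(b2, 0)
  rho <- b2 / d2
  rho * mu + (1 - rho) * eig
}

.cluster_index_2means <- function(x, nstart) {
  km <- stats::kmeans(x, centers = 2L, nstart = nstart)
  km$tot.withinss / km$totss
}

#' Agreement between two labelings
#'
#' Percent agreement after optimal one-to-one label matching (exact
#' assignment for <= 8 labels), or after an explicit mapping, plus the
#' adjusted Rand index.
#'
#' @param labels_a,labels_b named label vectors over the same samples.
#' @param mapping `"bestmatch"` (optimal one-to-one matching of
#'   `labels_a` levels onto `labels_b` levels) or a named character vector
#'   mapping a-levels to b-levels.
#' @return list with `percent_agreement`, `ari`, `mapping`.
#' @export
concordance <- function(labels_a, labels_b, mapping = "bestmatch") {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    shared <- intersect(names(labels_a), names(labels_b))
    .assert(length(shared) > 0, "label vectors share no samples")
    labels_a <- labels_a[shared]
    labels_b <- labels_b[shared]
  } else {
    .assert(length(labels_a) == length(labels_b),
            "unnamed label vectors must have equal length")
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (identical(mapping, "bestmatch")) {
    tab <- table(labels_a, labels_b)
    map <- .best_label_map(tab)
  } else {
    .assert(!is.null(names(mapping)), "explicit mapping must be named")
    map <- mapping
  }
  mapped <- unname(map[labels_a])
  agree <- mean(!is.na(mapped) & mapped == labels_b) * 100
  list(percent_agreement = agree,
       ari = adjusted_rand_index(labels_a, labels_b), mapping = map)
}

#' Relabel tiny consensus clusters as "Other"
#'
#' Clusters holding fewer than `min_fraction` of samples are relabeled
#' `"Other"`, mirroring the unclassified residue of the published scheme.
#'
#' @param labels cluster labels.
#' @param min_fraction minimum cluster size as a fraction of samples.
#' @return relabeled character vector.
#' @export
relabel_small_clusters <- function(labels, min_fraction = 0.02) {
  labels <- as.character(labels)
  sizes <- table(labels) / length(labels)
  small <- names(sizes)[sizes < min_fraction]
  labels[labels %in% small] <- "Other"
  labels
}
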