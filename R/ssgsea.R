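# Per-sample pathway activity scoring (single-sample gene set enrichment)
# and subtype-specific gene set selection by a moderated difference
# statistic with a permutation FDR plus an ROC-AUC cutoff.

#' Single-sample gene set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' ascending gene id, deterministic across platforms). For a gene set, the
#' enrichment score is the sum over ranked positions of the difference
#' between the weighted in-set ECDF (weights `rank^alpha`, normalized to 1
#' over the set) and the unweighted out-of-set ECDF — the integrated
#' running-sum statistic, not its extremum.
#'
#' @param expr genes x samples matrix.
#' @param sets gene set collection (named list of gene vectors).
#' @param alpha rank weighting exponent (0 = pure ECDF difference;
#'   default 0.25, the convention of the single-sample lineage).
#' @param min_overlap sets with fewer overlapping genes are skipped with a
#'   warning; sets covering every gene (empty complement) likewise.
#' @param normalize divide each score by the number of genes (off by
#'   default; for cross-set comparability only).
#' @return sets x samples matrix of enrichment scores.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, min_overlap = 1L,
                         normalize = FALSE) {
  expr <- expression_matrix(expr)
  .assert(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  genes <- rownames(expr)
  n <- length(genes)
  members <- lapply(sets, function(s) which(genes %in% s))
  usable <- vapply(members, function(ix) {
    length(ix) >= min_overlap && length(ix) < n
  }, TRUE)
  if (!all(usable)) {
    warning(sprintf("skipping %d set(s) with too small overlap or empty complement: %s",
                    sum(!usable),
                    paste(names(sets)[!usable], collapse = ", ")), call. = FALSE)
  }
  .assert(any(usable), "no gene set overlaps the expression matrix")
  members <- members[usable]
  gene_order_tiebreak <- order(genes)  # precomputed id tie-break
  es <- matrix(NA_real_, length(members), ncol(expr),
               dimnames = list(names(members), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    ord <- order(-v, genes, method = "radix")     # value desc, id asc
    pos_of_gene <- integer(n)
    pos_of_gene[ord] <- seq_len(n)
    w_all <- (n - seq_len(n) + 1)^alpha            # weight at ranked position
    for (k in seq_along(members)) {
      pos <- sort(pos_of_gene[members[[k]]])
      es[k, j] <- .ssgsea_es(pos, w_all, n)
    }
  }
  if (normalize) es <- es / n
  es
}

# Integrated difference of in-set weighted ECDF and out-of-set ECDF over
# the full ranked list, using only the hit positions (O(|set|) per set).
.ssgsea_es <- function(pos, w_all, n) {
  m <- length(pos)
  w <- w_all[pos]
  cw <- cumsum(w) / sum(w)
  n_out <- n - m
  # Between hit k (inclusive) and the position before hit k+1, P_in = cw[k]
  # and P_out ramps linearly; summing the difference segment by segment.
  bounds <- c(pos, n + 1L)
  total <- 0
  out_before <- pos[[1L]] - 1L   # out-of-set genes ranked above the first hit
  for (k in seq_len(m)) {
    len <- bounds[[k + 1L]] - bounds[[k]]          # positions in segment k
    # out-of-set positions in this segment: all but the hit itself
    outs <- seq_len(len) - 1L
    total <- total + sum(cw[[k]] - (out_before + outs) / n_out)
    out_before <- out_before + len - 1L
  }
  # positions before the first hit contribute P_in = 0 minus running P_out
  lead <- pos[[1L]] - 1L
  if (lead > 0) total <- total - sum(seq_len(lead)) / n_out
  total
}

#' Two-class moderated difference statistic with permutation q-values
#'
#' d_i = (mean1 - mean0) / (s_i + s0), with s_i the pooled standard error
#' and s0 the exchangeability constant (median of the s_i). q-values follow
#' the order-statistic permutation procedure: for each observed |d| cutoff,
#' the false-call estimate is the expected (mean over permutations) count
#' of permuted |d*| values at or beyond the cutoff, divided by the observed
#' call count, made monotone. A q of exactly 0 therefore means no permuted
#' statistic anywhere reached the cutoff.
#'
#' @param scores rows x samples matrix (rows are gene sets or genes).
#' @param labels binary 0/1 (or logical) class labels, >= 2 samples each.
#' @param n_perm label permutations.
#' @param seed RNG seed.
#' @return data.frame with `d`, `q` per row.
#' @export
sam_two_class <- function(scores, labels, n_perm = 200, seed = 1L) {
  scores <- as.matrix(scores)
  labels <- as.numeric(labels)
  .assert(all(labels %in% c(0, 1)), "labels must be binary 0/1")
  .assert(sum(labels == 1) >= 2 && sum(labels == 0) >= 2,
          "each class needs >= 2 samples")
  d_obs <- .sam_d(scores, labels)
  set.seed(seed)
  n <- length(labels)
  abs_obs <- abs(d_obs)
  ord <- order(-abs_obs)
  exceed <- matrix(0L, n_perm, nrow(scores))
  for (b in seq_len(n_perm)) {
    d_perm <- .sam_d(scores, labels[sample.int(n)])
    # count of permuted |d*| >= each observed |d| cutoff (sorted desc)
    exceed[b, ] <- length(d_perm) -
      findInterval(abs_obs[ord] - 1e-12, sort(abs(d_perm)))
  }
  mean_false <- colMeans(exceed)
  called <- seq_along(ord)
  fdr <- pmin(mean_false / called, 1)
  fdr <- rev(cummin(rev(fdr)))                   # monotone step-up
  q <- numeric(length(d_obs))
  q[ord] <- fdr
  data.frame(d = d_obs, q = q, row.names = rownames(scores))
}

.sam_d <- function(scores, labels) {
  i1 <- labels == 1; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(scores[, i1, drop = FALSE])
  m0 <- rowMeans(scores[, i0, drop = FALSE])
  ss1 <- rowSums((scores[, i1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((scores[, i0, drop = FALSE] - m0)^2)
  s <- sqrt((1 / n1 + 1 / n0) * (ss1 + ss0) / (n1 + n0 - 2))
  s0 <- stats::median(s)
  (m1 - m0) / (s + s0)
}

#' Area under the ROC curve (rank statistic)
#'
#' AUC = Mann-Whitney U / (n1 * n0), with ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (1 = positive), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  .assert(all(labels %in% c(0, 1)), "labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  .assert(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)                               # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select subtype-specific gene sets by SAM q-value and ROC AUC
#'
#' For every subtype, a one-vs-rest comparison of enrichment scores:
#' a set is selected for a subtype when its q-value is <= `q_max`, its
#' AUC exceeds `auc_min` and it is overexpressed there (d > 0). The
#' published thresholds are q = 0 and AUC > 0.85; selected sets are
#' reported in descending AUC.
#'
#' @param enrichment sets x samples enrichment matrix.
#' @param labels subtype label per sample (>= 2 subtypes).
#' @param q_max,auc_min selection thresholds.
#' @param n_perm,seed passed to [sam_two_class()].
#' @return data.frame with one row per (set, subtype): `d`, `q`, `auc`,
#'   `selected`, ordered by subtype then descending AUC.
#' @export
select_subtype_sets <- function(enrichment, labels, q_max = 0,
                                auc_min = 0.85, n_perm = 200, seed = 1L) {
  enrichment <- as.matrix(enrichment)
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  .assert(length(levs) >= 2, "need >= 2 subtypes")
  out <- lapply(seq_along(levs), function(i) {
    s <- levs[[i]]
    bin <- as.numeric(labels == s)
    sam <- sam_two_class(enrichment, bin, n_perm = n_perm, seed = seed + i)
    auc <- apply(enrichment, 1L, roc_auc, labels = bin)
    df <- data.frame(set = rownames(enrichment), subtype = s,
                     d = sam$d, q = sam$q, auc = auc,
                     stringsAsFactors = FALSE)
    df$selected <- df$q <= q_max & df$auc > auc_min & df$d > 0
    df[order(-df$auc), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean enrichment across a subset of gene sets
#'
#' The per-sample arithmetic mean of the enrichment scores of the named
#' sets — e.g. a microtubule-activity score averaging the scores of the
#' microtubule-related sets.
#'
#' @param enrichment sets x samples matrix.
#' @param set_names non-empty subset of rownames.
#' @return named per-sample mean vector.
#' @export
mean_set_activity <- function(enrichment, set_names) {
  .assert(length(set_names) >= 1, "set subset must be non-empty")
  missing <- setdiff(set_names, rownames(enrichment))
  .assert(length(missing) == 0, "unknown set name(s): %s",
          paste(missing, collapse = ", "))
  colMeans(enrichment[set_names, , drop = FALSE])
}
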