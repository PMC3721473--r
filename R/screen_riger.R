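# Pooled shRNA screen quantification and subtype-specific essential-gene
# calling: exact-match read counting, total-count normalization,
# cross-screen compilation with batch adjustment, the per-hairpin
# signal-to-noise metric, weighted Kolmogorov-Smirnov gene enrichment with
# a hairpins-per-gene-preserving permutation null and BH FDR, and the
# downstream decision rules.

#' Count hairpins by exact sequence match
#'
#' Reads are trimmed to the hairpin-length window at a constant 5' offset
#' and matched exactly against the library sequences (perfect match only);
#' every matching read increments its hairpin by one.
#'
#' @param reads character vector of read sequences, or a FASTA/FASTQ path
#'   (read via Biostrings when installed, else a plain-text fallback).
#' @param library hairpin library data.frame (see
#'   [read_hairpin_library()]).
#' @param trim5 constant 5' trim before the hairpin window.
#' @return integer vector of counts named by hairpin id, with attribute
#'   `n_unmatched`.
#' @export
count_hairpins <- function(reads, library, trim5 = 0L) {
  library <- hairpin_library(library)
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- .read_sequences(reads)
  }
  .assert(length(reads) > 0, "no reads supplied")
  width <- nchar(library$sequence[[1L]])
  window <- substr(toupper(reads), trim5 + 1L, trim5 + width)
  hit <- match(window, library$sequence)
  counts <- tabulate(hit, nbins = nrow(library))
  names(counts) <- library$hairpin_id
  attr(counts, "n_unmatched") <- sum(is.na(hit))
  counts
}

.read_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(path, format = fmt)))
  }
  lines <- readLines(path)
  .assert(length(lines) > 0, "empty read file: %s", path)
  if (startsWith(lines[[1L]], "@")) {
    lines[seq(2L, length(lines), by = 4L)]
  } else {
    lines[!startsWith(lines, ">")]
  }
}

#' Scale columns of a count matrix to a common total
#'
#' Each sample's counts are scaled so the column sum equals `scale`
#' (total-read normalization); optionally log2(x + 1) transformed for
#' downstream metrics.
#'
#' @param counts hairpins x samples matrix with positive column totals.
#' @param scale target column sum (default 1e6, counts per million).
#' @param log2_transform apply log2(x + 1) after scaling.
#' @return normalized matrix.
#' @export
normalize_counts <- function(counts, scale = 1e6, log2_transform = FALSE) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  .assert(all(tot > 0), "zero-total column(s): %s",
          paste(colnames(counts)[tot == 0], collapse = ", "))
  out <- sweep(counts, 2L, tot / scale, "/")
  if (log2_transform) out <- log2(out + 1)
  out
}

#' Compile screens on a shared hairpin universe with batch adjustment
#'
#' Takes the hairpin intersection across screens, total-count normalizes,
#' log2(x + 1) transforms, and removes the screen batch effect with the
#' empirical-Bayes location/scale adjustment.
#'
#' @param count_list named list of hairpins x samples raw count matrices
#'   (one per screen).
#' @param scale normalization scale.
#' @return list with `expr` (adjusted log2 matrix), `batch` (screen label
#'   per sample), `excluded` (hairpins absent from some screen).
#' @export
combine_screens <- function(count_list, scale = 1e6) {
  .assert(is.list(count_list) && length(count_list) >= 1, "need >= 1 screen")
  if (is.null(names(count_list))) {
    names(count_list) <- sprintf("screen%d", seq_along(count_list))
  }
  shared <- Reduce(intersect, lapply(count_list, rownames))
  .assert(length(shared) > 0, "screens share no hairpins")
  all_ids <- unique(unlist(lapply(count_list, rownames)))
  excluded <- setdiff(all_ids, shared)
  norm <- lapply(count_list, function(m) {
    normalize_counts(m[shared, , drop = FALSE], scale = scale,
                     log2_transform = TRUE)
  })
  expr <- do.call(cbind, norm)
  batch <- rep(names(count_list), vapply(count_list, ncol, 0L))
  names(batch) <- colnames(expr)
  if (length(count_list) == 1L) {
    return(list(expr = expr, batch = batch, excluded = excluded))
  }
  adj <- combat_adjust(expression_matrix(expr), batch)
  list(expr = adj$expr, batch = batch, excluded = excluded,
       model = adj$model)
}

#' Signal-to-noise differential metric per hairpin
#'
#' (mean_A - mean_B) / (sd_A + sd_B), with each group sd floored at
#' `max(sd, sd_frac * |group mean|, floor_min)` — the GenePattern
#' convention preventing division blow-ups on near-constant hairpins.
#'
#' @param values_a,values_b numeric matrices (hairpins x samples) or
#'   vectors, >= 2 samples per group.
#' @param sd_frac,floor_min sd floor parameters.
#' @return numeric metric per hairpin (positive = higher in group A).
#' @export
signal_to_noise <- function(values_a, values_b, sd_frac = 0.2,
                            floor_min = 0.2) {
  if (is.null(dim(values_a))) values_a <- matrix(values_a, nrow = 1L)
  if (is.null(dim(values_b))) values_b <- matrix(values_b, nrow = 1L)
  .assert(ncol(values_a) >= 2 && ncol(values_b) >= 2,
          "each group needs >= 2 samples")
  floor_sd <- function(s, m) pmax(s, sd_frac * abs(m), floor_min)
  m_a <- rowMeans(values_a); m_b <- rowMeans(values_b)
  s_a <- floor_sd(apply(values_a, 1L, stats::sd), m_a)
  s_b <- floor_sd(apply(values_b, 1L, stats::sd), m_b)
  as.numeric((m_a - m_b) / (s_a + s_b))
}

#' Weighted Kolmogorov-Smirnov gene enrichment scores from ranked hairpins
#'
#' Hairpins are ranked by the differential metric; per gene, a weighted
#' running sum walks the ranked list (hits increment by `|metric|^p`
#' normalized over the gene's hairpins, misses decrement by 1/(N - n_gene))
#' and the enrichment score is its maximal deviation toward each end:
#' `es_amplified` scans from the high-metric end, `es_depleted` from the
#' low-metric end. Both are reported per gene together with the dominant
#' signed `es`.
#'
#' @param metrics named per-hairpin metric vector.
#' @param library hairpin library (maps hairpins to genes). Hairpins
#'   missing from `metrics` are ignored; genes with no scored hairpins are
#'   skipped with a warning.
#' @param weight_exponent 0 (unweighted KS) or 1 (metric-weighted,
#'   the default RIGER-style setting).
#' @return data.frame per gene: `gene`, `n_hairpins`, `es_amplified`,
#'   `es_depleted`, `es` (signed; negative = depleted), `direction`.
#' @export
riger_gene_scores <- function(metrics, library, weight_exponent = 1) {
  .assert(weight_exponent %in% c(0, 1), "weight_exponent must be 0 or 1")
  library <- hairpin_library(library)
  .assert(!is.null(names(metrics)), "metrics must be named by hairpin id")
  scored <- intersect(library$hairpin_id, names(metrics))
  missing_genes <- setdiff(library$gene,
                           library$gene[library$hairpin_id %in% scored])
  if (length(missing_genes) > 0) {
    warning(sprintf("%d gene(s) with no scored hairpins skipped",
                    length(missing_genes)), call. = FALSE)
  }
  lib <- library[library$hairpin_id %in% scored, ]
  v <- metrics[lib$hairpin_id]
  n <- length(v)
  ord_hi <- order(-v, .string_hash(lib$hairpin_id))  # amplified end first
  pos_hi <- integer(n); pos_hi[ord_hi] <- seq_len(n)
  genes <- split(seq_len(n), lib$gene)
  w_abs <- abs(v)^weight_exponent
  es_amp <- vapply(genes, function(ix) {
    .ks_es(sort(pos_hi[ix]), w_abs[ix][order(pos_hi[ix])], n)
  }, 0)
  pos_lo <- n + 1L - pos_hi           # depleted end first
  es_dep <- vapply(genes, function(ix) {
    .ks_es(sort(pos_lo[ix]), w_abs[ix][order(pos_lo[ix])], n)
  }, 0)
  dominant <- ifelse(es_dep >= es_amp, -es_dep, es_amp)
  data.frame(gene = names(genes),
             n_hairpins = lengths(genes),
             es_amplified = es_amp, es_depleted = es_dep,
             es = dominant,
             direction = ifelse(es_dep >= es_amp, "depleted", "amplified"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic pseudo-random ordering for metric ties. Hairpin libraries
# typically list a gene's hairpins consecutively, so breaking ties by file
# order would fabricate gene-level enrichment whenever metrics tie; a string
# hash scatters tied hairpins reproducibly instead.
.string_hash <- function(x) {
  base <- vapply(x, function(s) {
    h <- 5381
    for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483648
    h
  }, 0)
  # three multiplicative scrambling rounds (exact in doubles): sequential
  # ids like hp0001/hp0002 hash to nearby values, and one round is still
  # order-preserving over short runs
  for (i in 1:3) base <- (base * 69069 + 1) %% 2147483648
  base
}

# Maximal positive deviation of the weighted KS running sum, evaluated at
# hit positions (the maximum over the full walk occurs just after a hit).
.ks_es <- function(pos, w, n) {
  m <- length(pos)
  tw <- sum(w)
  w <- if (tw > 0) w / tw else rep(1 / m, m)
  hit_cum <- cumsum(w)
  miss_cum <- (pos - seq_len(m)) / (n - m)
  max(c(hit_cum - miss_cum, 0))
}

#' Permutation p-values and BH q-values for gene enrichment scores
#'
#' The null permutes the hairpin-to-gene assignment while preserving the
#' hairpins-per-gene multiset. Because the ranked metric list is fixed
#' under this null, a gene's null enrichment score depends only on its
#' hairpin count, so the null is sampled once per distinct count:
#' `n_perm` random hairpin subsets of that size. Per-direction p-values
#' carry the +1 correction (never exactly zero); the reported `p` is the
#' dominant direction's p doubled (two one-sided tests), capped at 1, and
#' `q` is Benjamini-Hochberg within each direction.
#'
#' @param scores data.frame from [riger_gene_scores()].
#' @param metrics,library,weight_exponent as for [riger_gene_scores()].
#' @param n_perm permutations (>= 100; published setting 1000).
#' @param seed RNG seed.
#' @return `scores` with `p_amplified`, `p_depleted`, `p`, `q` columns
#'   (`p`/`q` follow each gene's dominant direction).
#' @export
riger_permutation_fdr <- function(scores, metrics, library, n_perm = 1000,
                                  weight_exponent = 1, seed = 1L) {
  .assert(n_perm >= 100, "n_perm must be >= 100")
  library <- hairpin_library(library)
  scored <- intersect(library$hairpin_id, names(metrics))
  lib <- library[library$hairpin_id %in% scored, ]
  v <- metrics[lib$hairpin_id]
  n <- length(v)
  ord_hi <- order(-v, .string_hash(lib$hairpin_id))
  pos_hi <- integer(n); pos_hi[ord_hi] <- seq_len(n)
  pos_lo <- n + 1L - pos_hi
  w_abs <- abs(v)^weight_exponent
  set.seed(seed)
  counts <- sort(unique(scores$n_hairpins))
  null_amp <- null_dep <- vector("list", length(counts))
  names(null_amp) <- names(null_dep) <- as.character(counts)
  for (h in counts) {
    amp <- dep <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      ix <- sample.int(n, h)
      amp[[b]] <- .ks_es(sort(pos_hi[ix]), w_abs[ix][order(pos_hi[ix])], n)
      dep[[b]] <- .ks_es(sort(pos_lo[ix]), w_abs[ix][order(pos_lo[ix])], n)
    }
    null_amp[[as.character(h)]] <- sort(amp)
    null_dep[[as.character(h)]] <- sort(dep)
  }
  p_from_null <- function(obs, nulls) {
    vapply(seq_along(obs), function(i) {
      nv <- nulls[[as.character(scores$n_hairpins[[i]])]]
      (1 + length(nv) - findInterval(obs[[i]] - 1e-12, nv)) / (n_perm + 1)
    }, 0)
  }
  scores$p_amplified <- p_from_null(scores$es_amplified, null_amp)
  scores$p_depleted <- p_from_null(scores$es_depleted, null_dep)
  # dominant-direction p with the usual two-one-sided-tests correction so
  # the reported p stays super-uniform under the null
  scores$p <- pmin(1, 2 * pmin(scores$p_depleted, scores$p_amplified))
  scores$q <- NA_real_
  for (dir in c("depleted", "amplified")) {
    sel <- scores$direction == dir
    if (any(sel)) scores$q[sel] <- .bh_adjust(scores$p[sel])
  }
  scores
}

#' Call subtype-specific depleted and amplified genes
#'
#' Genes pass at `q < q_max`; the supporting hairpins reported for display
#' are restricted to `|hairpin score| >= hairpin_score_min` (the hairpin
#' score is the hairpin's signal-to-noise metric). Published thresholds:
#' q < 0.005 and hairpin score >= 0.2.
#'
#' @param riger data.frame from [riger_permutation_fdr()].
#' @param metrics named per-hairpin metric vector (hairpin scores).
#' @param library hairpin library.
#' @param q_max q-value cutoff.
#' @param hairpin_score_min display cutoff for supporting hairpins.
#' @return list with `depleted` and `amplified` data.frames (`gene`, `es`,
#'   `q`, `hairpins` — semicolon-joined supporting hairpin ids).
#' @export
call_subtype_genes <- function(riger, metrics, library, q_max = 0.005,
                               hairpin_score_min = 0.2) {
  library <- hairpin_library(library)
  pick <- function(dir) {
    hits <- riger[riger$direction == dir & riger$q < q_max, , drop = FALSE]
    if (nrow(hits) == 0) {
      return(data.frame(gene = character(), es = numeric(), q = numeric(),
                        hairpins = character(), stringsAsFactors = FALSE))
    }
    hp <- vapply(hits$gene, function(g) {
      ids <- library$hairpin_id[library$gene == g]
      ids <- ids[ids %in% names(metrics)]
      keep <- ids[abs(metrics[ids]) >= hairpin_score_min]
      paste(keep, collapse = ";")
    }, "")
    data.frame(gene = hits$gene, es = hits$es, q = hits$q, hairpins = hp,
               stringsAsFactors = FALSE)[order(hits$q), ]
  }
  list(depleted = pick("depleted"), amplified = pick("amplified"))
}

#' Cohen's d effect size
#'
#' (mean_A - mean_B) / pooled SD, pooled with n-1 weights.
#'
#' @param values_a,values_b numeric vectors, >= 2 each.
#' @return standardized mean difference.
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  .assert(na >= 2 && nb >= 2, "each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  .assert(sp2 > 0, "zero pooled SD")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

#' siRNA validation decision rule
#'
#' A gene passes when knockdown gives at least 20% growth suppression on
#' the target line with p < 0.001 against control, and at least 20
#' percentage points more suppression on the target line than on the
#' reference lines.
#'
#' @param target_suppression percent growth suppression on the target line.
#' @param p_value t-test p-value vs the negative control.
#' @param reference_suppression percent suppression on the reference
#'   line(s) (maximum is used if several).
#' @param min_suppression,max_p,min_differential rule thresholds.
#' @return logical pass/fail.
#' @export
sirna_validation_call <- function(target_suppression, p_value,
                                  reference_suppression,
                                  min_suppression = 20, max_p = 0.001,
                                  min_differential = 20) {
  .assert(!is.null(p_value) && !is.na(p_value), "missing p-value")
  .assert(all(abs(c(target_suppression, reference_suppression)) <= 100),
          "suppression percentages must lie in [-100, 100]")
  target_suppression >= min_suppression && p_value < max_p &&
    (target_suppression - max(reference_suppression)) >= min_differential
}
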