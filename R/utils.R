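#' @keywords internal
"_PACKAGE"

# Shared argument checking helpers. All stop() messages name the offending
# argument so CLI users see actionable errors.

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors over the same samples.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Optimal one-to-one matching of cluster labels maximizing agreement.
# Exact over permutations for k <= 8, greedy beyond that.
.best_label_map <- function(tab) {
  k_a <- nrow(tab); k_b <- ncol(tab)
  k <- max(k_a, k_b)
  sq <- matrix(0L, k, k)
  sq[seq_len(k_a), seq_len(k_b)] <- tab
  if (k <= 8L) {
    perms <- .permutations(k)
    agree <- apply(perms, 1L, function(p) sum(sq[cbind(seq_len(k), p)]))
    p <- perms[which.max(agree), ]
  } else {
    p <- integer(k)
    taken <- rep(FALSE, k)
    for (i in order(-apply(sq, 1L, max))) {
      j <- which.max(ifelse(taken, -Inf, sq[i, ]))
      p[i] <- j; taken[j] <- TRUE
    }
  }
  stats::setNames(colnames(tab)[p[seq_len(k_a)]], rownames(tab))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

# Benjamini-Hochberg step-up q-values (monotone in ranked p).
.bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
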