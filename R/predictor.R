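# One-vs-rest Bayesian probit metagene subtype predictors: core-sample
# training selection, correlation-based signature genes, SVD metagenes,
# latent-variable Gibbs probit regression, prediction on new cohorts, and
# cross-validation.

#' Pick top core samples per subtype for training
#'
#' Per subtype, the `n_per_subtype` core samples (SW > 0) with the largest
#' silhouette widths; ties broken by lexicographically smaller sample id.
#' Subtypes with fewer cores contribute all of them, with a warning.
#'
#' @param assignment data.frame with `sample`, `label`, `sw`, `core`
#'   columns (as from [silhouette_widths()]).
#' @param n_per_subtype training samples per subtype (published rule: 50).
#' @return character vector of training sample ids.
#' @export
pick_core_training <- function(assignment, n_per_subtype = 50) {
  .assert(all(c("sample", "label", "sw", "core") %in% colnames(assignment)),
          "assignment needs columns sample, label, sw, core")
  core <- assignment[assignment$core, ]
  n_core <- table(core$label)
  missing <- setdiff(unique(assignment$label), names(n_core))
  .assert(length(missing) == 0, "subtype(s) with zero core samples: %s",
          paste(missing, collapse = ", "))
  picked <- lapply(split(core, core$label), function(df) {
    df <- df[order(-df$sw, df$sample), ]
    if (nrow(df) < n_per_subtype) {
      warning(sprintf("subtype '%s' has only %d core samples (< %d); using all",
                      df$label[[1L]], nrow(df), n_per_subtype), call. = FALSE)
    }
    df$sample[seq_len(min(n_per_subtype, nrow(df)))]
  })
  unname(unlist(picked))
}

#' Rank genes by absolute correlation with a binary phenotype
#'
#' @param expr genes x samples matrix.
#' @param labels binary 0/1 labels (both classes present).
#' @param n_genes how many top genes to return (capped at the gene count
#'   with a warning).
#' @return data.frame of `gene` and signed Pearson `score`, ranked by
#'   decreasing |score|; constant genes score 0.
#' @export
select_signature_genes <- function(expr, labels, n_genes = 100) {
  expr <- expression_matrix(expr)
  labels <- as.numeric(labels)
  .assert(all(labels %in% c(0, 1)) && length(unique(labels)) == 2,
          "labels must be binary with both classes present")
  sds <- apply(expr, 1L, stats::sd)
  r <- rep(0, nrow(expr))
  ok <- sds > 0
  r[ok] <- suppressWarnings(as.numeric(stats::cor(t(expr[ok, , drop = FALSE]),
                                                  labels)))
  if (n_genes > nrow(expr)) {
    warning(sprintf("n_genes (%d) > available genes (%d); using all",
                    n_genes, nrow(expr)), call. = FALSE)
    n_genes <- nrow(expr)
  }
  ord <- order(-abs(r), rownames(expr))
  top <- ord[seq_len(n_genes)]
  data.frame(gene = rownames(expr)[top], score = r[top],
             stringsAsFactors = FALSE)
}

#' Metagene decomposition of a signature submatrix
#'
#' SVD of the gene-centered signature submatrix. Metagene scores are the
#' projections of samples onto the top left singular vectors; each basis
#' vector is oriented so its loading sum is non-negative.
#'
#' @param expr signature genes x samples matrix (>= 2 of each).
#' @param n_metagenes number of components to keep.
#' @return list with `basis` (genes x m, orthonormal columns), `d`
#'   (singular values), `scores` (m x samples), `gene_means`.
#' @export
metagene_decompose <- function(expr, n_metagenes = 2) {
  expr <- expression_matrix(expr)
  .assert(nrow(expr) >= 2 && ncol(expr) >= 2, "need >= 2 genes and samples")
  mu <- rowMeans(expr)
  xc <- expr - mu
  sv <- svd(xc)
  .assert(sv$d[[1L]] > 0, "signature submatrix has rank 0")
  m <- min(n_metagenes, sum(sv$d > sv$d[[1L]] * 1e-12))
  U <- sv$u[, seq_len(m), drop = FALSE]
  flip <- ifelse(colSums(U) < 0, -1, 1)
  U <- U * rep(flip, each = nrow(U))
  rownames(U) <- rownames(expr)
  scores <- t(U) %*% xc
  list(basis = U, d = sv$d[seq_len(m)], scores = scores, gene_means = mu)
}

#' Bayesian probit regression by truncated-normal data augmentation
#'
#' Albert-Chib Gibbs sampling of a probit model under a vague normal prior
#' N(0, `prior_var` I) on the coefficients (intercept included).
#' Perfect separation does not break the sampler but lets the posterior
#' drift; it is detected and flagged.
#'
#' @param scores m x samples metagene score matrix (or vector).
#' @param labels binary 0/1 labels, both classes present.
#' @param n_mcmc,burn_in Gibbs iterations and burn-in (n_mcmc > burn_in).
#' @param prior_var prior variance of coefficients.
#' @param seed RNG seed.
#' @return list with `coef_mean`, `coef_sd` (intercept first), `separable`
#'   flag, and the retained `draws`.
#' @export
probit_fit <- function(scores, labels, n_mcmc = 2000, burn_in = 500,
                       prior_var = 100, seed = 1L) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  labels <- as.numeric(labels)
  .assert(all(labels %in% c(0, 1)) && length(unique(labels)) == 2,
          "labels must be binary with both classes present")
  .assert(n_mcmc > burn_in, "n_mcmc must exceed burn_in")
  X <- cbind(1, t(scores))
  n <- nrow(X); p <- ncol(X)
  V <- solve(crossprod(X) + diag(1 / prior_var, p))
  R <- chol(V)
  set.seed(seed)
  beta <- rep(0, p)
  keep <- matrix(NA_real_, n_mcmc - burn_in, p)
  pos <- labels == 1
  for (it in seq_len(n_mcmc)) {
    eta <- as.numeric(X %*% beta)
    u <- stats::runif(n)
    # z | beta: truncated normal above/below 0 via inverse-CDF
    lo <- stats::pnorm(0, eta, 1)
    z <- numeric(n)
    z[pos] <- stats::qnorm(lo[pos] + u[pos] * (1 - lo[pos]), eta[pos], 1)
    z[!pos] <- stats::qnorm(u[!pos] * lo[!pos], eta[!pos], 1)
    z[!is.finite(z)] <- eta[!is.finite(z)]      # guard extreme tails
    mu_b <- V %*% crossprod(X, z)
    beta <- as.numeric(mu_b + t(R) %*% stats::rnorm(p))
    if (it > burn_in) keep[it - burn_in, ] <- beta
  }
  coef_mean <- colMeans(keep)
  coef_sd <- apply(keep, 2L, stats::sd)
  fitted <- stats::pnorm(as.numeric(X %*% coef_mean))
  separable <- all(fitted[pos] > 0.5) && all(fitted[!pos] < 0.5) &&
    max(abs(coef_mean[-1L])) > 3 * sqrt(prior_var) / 4
  list(coef_mean = coef_mean, coef_sd = coef_sd, separable = separable,
       draws = keep)
}

#' Train a one-subtype-vs-rest signature model
#'
#' @param expr genes x samples training matrix.
#' @param labels binary 0/1 (1 = target subtype).
#' @param n_genes,n_metagenes,n_mcmc,burn_in,seed model parameters.
#' @param standardize gene-wise z-score the training matrix first
#'   (repeated independently on any new dataset at prediction time, the
#'   cross-study shift correction).
#' @return a `signature_model` list.
#' @export
train_signature_model <- function(expr, labels, n_genes = 100,
                                  n_metagenes = 2, n_mcmc = 2000,
                                  burn_in = 500, standardize = TRUE,
                                  seed = 1L) {
  expr <- expression_matrix(expr)
  if (standardize) expr <- .genewise_z(expr)
  sig <- select_signature_genes(expr, labels, n_genes = n_genes)
  dec <- metagene_decompose(expr[sig$gene, , drop = FALSE],
                            n_metagenes = n_metagenes)
  fit <- probit_fit(dec$scores, labels, n_mcmc = n_mcmc, burn_in = burn_in,
                    seed = seed)
  structure(list(signature = sig, basis = dec$basis, d = dec$d,
                 gene_means = dec$gene_means, coef_mean = fit$coef_mean,
                 coef_sd = fit$coef_sd, separable = fit$separable,
                 standardize = standardize,
                 training_samples = colnames(expr)),
            class = "signature_model")
}

.genewise_z <- function(expr) {
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  s[s == 0] <- 1
  (expr - mu) / s
}

#' Predict subtype probability from a signature model
#'
#' New samples are (optionally) gene-wise standardized within their own
#' dataset, projected onto the stored metagene basis, and pushed through
#' the probit link at the posterior-mean coefficients. At least 80% of the
#' signature genes must be present; missing ones are imputed at the
#' training mean (zero on the centered scale) with a warning.
#'
#' @param model a `signature_model`.
#' @param expr genes x samples matrix of new data.
#' @return named vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, expr) {
  .assert(inherits(model, "signature_model"), "model must be a signature_model")
  expr <- expression_matrix(expr)
  if (model$standardize && ncol(expr) > 1L) expr <- .genewise_z(expr)
  genes <- model$signature$gene
  present <- genes %in% rownames(expr)
  .assert(mean(present) >= 0.8,
          "only %.0f%% of signature genes present (>= 80%% required)",
          100 * mean(present))
  if (!all(present)) {
    warning(sprintf("%d signature gene(s) missing; imputed at training mean",
                    sum(!present)), call. = FALSE)
  }
  xc <- matrix(0, length(genes), ncol(expr),
               dimnames = list(genes, colnames(expr)))
  xc[present, ] <- expr[genes[present], , drop = FALSE] -
    model$gene_means[genes[present]]
  scores <- t(model$basis) %*% xc
  eta <- model$coef_mean[[1L]] +
    as.numeric(t(scores) %*% model$coef_mean[-1L])
  stats::setNames(stats::pnorm(eta), colnames(expr))
}

#' One-vs-rest subtype predictor suite
#'
#' Per subtype: pick top core training samples, rank signature genes,
#' decompose into metagenes, fit the probit model; then score every
#' non-training sample against all models and assign by argmax
#' probability (low-confidence flag when the maximum is below 0.5).
#'
#' @param expr genes x samples matrix.
#' @param assignment silhouette assignment data.frame (see
#'   [pick_core_training()]).
#' @param n_per_subtype,n_genes,n_metagenes,n_mcmc,burn_in,standardize,seed
#'   model parameters.
#' @return list with `models` (per subtype), `prediction` (data.frame of
#'   per-model probabilities, `assigned`, `low_confidence` for held-out
#'   samples), `training_samples`.
#' @export
one_vs_rest <- function(expr, assignment, n_per_subtype = 50, n_genes = 100,
                        n_metagenes = 2, n_mcmc = 2000, burn_in = 500,
                        standardize = TRUE, seed = 1L) {
  expr <- expression_matrix(expr)
  subtypes <- sort(unique(assignment$label))
  .assert(length(subtypes) >= 2, "need >= 2 subtypes")
  train_ids <- pick_core_training(assignment, n_per_subtype)
  train_expr <- expr[, train_ids, drop = FALSE]
  train_labels <- assignment$label[match(train_ids, assignment$sample)]
  models <- lapply(seq_along(subtypes), function(i) {
    train_signature_model(train_expr,
                          as.numeric(train_labels == subtypes[[i]]),
                          n_genes = n_genes, n_metagenes = n_metagenes,
                          n_mcmc = n_mcmc, burn_in = burn_in,
                          standardize = standardize, seed = seed + i)
  })
  names(models) <- subtypes
  heldout <- setdiff(colnames(expr), train_ids)
  prediction <- NULL
  if (length(heldout) > 0) {
    prediction <- predict_subtype(models, expr[, heldout, drop = FALSE])
  }
  list(models = models, prediction = prediction, training_samples = train_ids)
}

#' Apply a suite of one-vs-rest models to samples
#'
#' @param models named list of `signature_model`s (one per subtype).
#' @param expr genes x samples matrix.
#' @return data.frame with one probability column per subtype, plus
#'   `assigned` (argmax) and `low_confidence` (max probability < 0.5).
#' @export
predict_subtype <- function(models, expr) {
  probs <- vapply(models, predict_probability, numeric(ncol(expr)),
                  expr = expr)
  if (ncol(expr) == 1L) probs <- matrix(probs, 1L, length(models),
                                        dimnames = list(colnames(expr),
                                                        names(models)))
  assigned <- names(models)[max.col(probs, ties.method = "first")]
  data.frame(sample = colnames(expr), probs,
             assigned = assigned,
             low_confidence = apply(probs, 1L, max) < 0.5,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Cross-validate the one-vs-rest predictor
#'
#' `kfold`: stratified k-fold; per fold, models are trained on the other
#' folds (core selection restricted to training samples) and held-out
#' samples are assigned by argmax. `three_way_split`: stratified
#' train/tune/test split, with the tune partition used to pick
#' (`n_genes`, `n_metagenes`) over a small grid before scoring the test
#' partition once.
#'
#' @param expr genes x samples matrix.
#' @param assignment silhouette assignment data.frame.
#' @param scheme `"kfold"` or `"three_way_split"`.
#' @param k folds for `kfold`.
#' @param n_per_subtype,n_genes,n_metagenes,n_mcmc,burn_in model settings
#'   (`n_genes`/`n_metagenes` may be vectors for the tuning grid in
#'   `three_way_split`).
#' @param seed RNG seed (controls fold assignment and samplers).
#' @return list with per-fold concordance (`folds`), `mean_concordance`,
#'   and for three-way split the chosen parameters.
#' @export
cross_validate <- function(expr, assignment,
                           scheme = c("kfold", "three_way_split"), k = 10,
                           n_per_subtype = 50, n_genes = 100, n_metagenes = 2,
                           n_mcmc = 2000, burn_in = 500, seed = 1L) {
  scheme <- match.arg(scheme)
  expr <- expression_matrix(expr)
  assignment <- assignment[match(colnames(expr), assignment$sample), ]
  labels <- stats::setNames(assignment$label, assignment$sample)
  set.seed(seed)
  if (scheme == "kfold") {
    .assert(k <= min(table(labels)), "k exceeds the smallest class size")
    fold <- stats::setNames(integer(length(labels)), names(labels))
    for (ix in split(seq_along(labels), labels)) {
      fold[ix] <- sample(rep_len(sample.int(k), length(ix)))
    }
    acc <- vapply(seq_len(k), function(f) {
      tr <- names(labels)[fold != f]
      te <- names(labels)[fold == f]
      ovr <- one_vs_rest(expr[, tr, drop = FALSE],
                         assignment[assignment$sample %in% tr, ],
                         n_per_subtype = n_per_subtype, n_genes = n_genes,
                         n_metagenes = n_metagenes, n_mcmc = n_mcmc,
                         burn_in = burn_in, seed = seed + f)
      pred <- predict_subtype(ovr$models, expr[, te, drop = FALSE])
      mean(pred$assigned == labels[te]) * 100
    }, 0)
    return(list(folds = data.frame(fold = seq_len(k), concordance = acc),
                mean_concordance = mean(acc)))
  }
  # three-way split: 50% train / 25% tune / 25% test, stratified
  part <- stats::setNames(character(length(labels)), names(labels))
  for (ids in split(names(labels), labels)) {
    ids <- sample(ids)
    n <- length(ids)
    part[ids] <- c(rep("train", ceiling(n / 2)),
                   rep("tune", ceiling(n / 4)),
                   rep("test", n - ceiling(n / 2) - ceiling(n / 4)))
  }
  grid <- expand.grid(n_genes = n_genes, n_metagenes = n_metagenes)
  tune_score <- vapply(seq_len(nrow(grid)), function(gi) {
    ovr <- one_vs_rest(expr[, part == "train", drop = FALSE],
                       assignment[part[assignment$sample] == "train", ],
                       n_per_subtype = n_per_subtype,
                       n_genes = grid$n_genes[[gi]],
                       n_metagenes = grid$n_metagenes[[gi]],
                       n_mcmc = n_mcmc, burn_in = burn_in, seed = seed + gi)
    pred <- predict_subtype(ovr$models, expr[, part == "tune", drop = FALSE])
    mean(pred$assigned == labels[part == "tune"]) * 100
  }, 0)
  best <- which.max(tune_score)
  ovr <- one_vs_rest(expr[, part != "test", drop = FALSE],
                     assignment[part[assignment$sample] != "test", ],
                     n_per_subtype = n_per_subtype,
                     n_genes = grid$n_genes[[best]],
                     n_metagenes = grid$n_metagenes[[best]],
                     n_mcmc = n_mcmc, burn_in = burn_in, seed = seed)
  pred <- predict_subtype(ovr$models, expr[, part == "test", drop = FALSE])
  acc <- mean(pred$assigned == labels[part == "test"]) * 100
  list(folds = data.frame(fold = "test", concordance = acc),
       mean_concordance = acc,
       chosen = grid[best, , drop = FALSE], tune_scores = tune_score)
}
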