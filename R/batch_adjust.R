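# Compilation of multi-batch expression data: parametric empirical-Bayes
# location/scale batch adjustment, the across-sample SD gene filter, and
# per-gene centering/scaling ahead of clustering.

#' Empirical-Bayes batch adjustment (location/scale model)
#'
#' Parametric adjustment of per-batch location and scale effects. Genes are
#' standardized against a batch-free design fit, per-(batch, gene) location
#' (`gamma`) and scale (`delta`) effects are estimated and shrunk toward
#' moment-matched batch priors (normal for `gamma`, inverse-gamma for
#' `delta`), and the data are back-transformed. Optional biological group
#' labels are protected in the design so real subtype structure is not
#' removed along with the batch effect.
#'
#' @param expr genes x samples log2 matrix.
#' @param batches batch label per sample (>= 2 samples per batch).
#' @param covariates optional biological group label per sample.
#' @return list with `expr` (adjusted matrix, same dimensions) and `model`
#'   (per-batch shrunk `gamma_star`/`delta_star` matrices plus prior
#'   hyperparameters).
#' @export
combat_adjust <- function(expr, batches, covariates = NULL) {
  expr <- expression_matrix(expr)
  .assert(length(batches) == ncol(expr), "one batch label per sample required")
  batches <- factor(batches)
  n_per <- table(batches)
  .assert(all(n_per >= 2), "batch with a single sample: %s",
          paste(names(n_per)[n_per < 2], collapse = ", "))
  if (nlevels(batches) == 1L) {
    return(list(expr = expr, model = list(note = "single batch; no adjustment")))
  }
  zero_var <- apply(expr, 1L, stats::sd) == 0
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene(s) passed through unadjusted",
                    sum(zero_var)), call. = FALSE)
  }
  n <- ncol(expr)
  batch_design <- stats::model.matrix(~ 0 + batches)
  design <- batch_design
  if (!is.null(covariates)) {
    .assert(length(covariates) == ncol(expr), "one covariate label per sample")
    design <- cbind(batch_design,
                    stats::model.matrix(~ factor(covariates))[, -1L, drop = FALSE])
  }
  # Gene-wise least squares for batch + covariate effects.
  B_hat <- solve(crossprod(design), t(design) %*% t(expr))  # coef x genes
  nb <- nlevels(batches)
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(nb), , drop = FALSE])
  stand_mean <- matrix(grand_mean, nrow(expr), n, dimnames = dimnames(expr))
  if (ncol(design) > nb) {
    extra <- design[, -seq_len(nb), drop = FALSE]
    stand_mean <- stand_mean +
      t(extra %*% B_hat[-seq_len(nb), , drop = FALSE])
  }
  var_pooled <- rowSums((expr - t(design %*% B_hat))^2) / n
  var_pooled[var_pooled == 0] <- 1  # zero-variance genes: pass-through
  z <- (expr - stand_mean) / sqrt(var_pooled)

  lev <- levels(batches)
  gamma_hat <- t(vapply(lev, function(b) rowMeans(z[, batches == b, drop = FALSE]),
                        numeric(nrow(expr))))
  delta_hat <- t(vapply(lev, function(b) apply(z[, batches == b, drop = FALSE], 1L, stats::var),
                        numeric(nrow(expr))))
  # Moment-matched priors per batch: gamma ~ N(gbar, t2); delta ~ InvGamma.
  gbar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) (2 * stats::var(d) + mean(d)^2) / stats::var(d))
  b_prior <- apply(delta_hat, 1L, function(d) (mean(d) * stats::var(d) + mean(d)^3) / stats::var(d))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  z_adj <- z
  for (i in seq_along(lev)) {
    sel <- batches == lev[[i]]
    n_b <- sum(sel)
    gs <- gamma_hat[i, ]; ds <- delta_hat[i, ]
    # Iterative EB solution for the posterior-mode pair (gamma*, delta*).
    for (iter in seq_len(100L)) {
      g_new <- (t2[[i]] * n_b * gamma_hat[i, ] + ds * gbar[[i]]) /
        (t2[[i]] * n_b + ds)
      sum2 <- rowSums((z[, sel, drop = FALSE] -
                         matrix(g_new, nrow(expr), n_b))^2)
      d_new <- (0.5 * sum2 + b_prior[[i]]) / (n_b / 2 + a_prior[[i]] - 1)
      change <- max(abs(g_new - gs) / pmax(abs(gs), 1e-8),
                    abs(d_new - ds) / pmax(ds, 1e-8))
      gs <- g_new; ds <- d_new
      if (change < 1e-4) break
    }
    gamma_star[i, ] <- gs
    delta_star[i, ] <- ds
    z_adj[, sel] <- (z[, sel, drop = FALSE] -
                       matrix(gs, nrow(expr), n_b)) /
      matrix(sqrt(ds), nrow(expr), n_b)
  }
  adj <- z_adj * sqrt(var_pooled) + stand_mean
  adj[zero_var, ] <- expr[zero_var, ]
  model <- list(gamma_star = gamma_star, delta_star = delta_star,
                gamma_prior_mean = gbar, gamma_prior_var = t2,
                delta_prior_shape = a_prior, delta_prior_scale = b_prior,
                grand_mean = as.numeric(grand_mean), batches = lev)
  list(expr = expression_matrix(adj), model = model)
}

#' Filter genes by across-sample standard deviation
#'
#' Retains exactly the genes whose sample SD (n-1 denominator) is strictly
#' greater than `sd_threshold`. The published analysis used 1.05 on the
#' compiled log2 matrix.
#'
#' @param expr genes x samples matrix.
#' @param sd_threshold non-negative SD cutoff (default 1.05).
#' @return the filtered matrix.
#' @export
variance_filter <- function(expr, sd_threshold = 1.05) {
  expr <- expression_matrix(expr)
  .assert(ncol(expr) >= 2, "need >= 2 samples to compute an SD")
  .assert(sd_threshold >= 0, "sd_threshold must be >= 0")
  keep <- apply(expr, 1L, stats::sd) > sd_threshold
  expr[keep, , drop = FALSE]
}

#' Center (and optionally scale) genes
#'
#' Subtracts a per-gene location (mean or median) and optionally divides by
#' the per-gene SD, the usual pre-clustering normalization.
#'
#' @param expr genes x samples matrix.
#' @param method `"mean"` or `"median"` location.
#' @param scale `"none"` or `"unit"` (divide by per-gene SD).
#' @return the centered matrix.
#' @export
center_genes <- function(expr, method = c("median", "mean"),
                         scale = c("none", "unit")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  expr <- expression_matrix(expr)
  loc <- if (method == "mean") rowMeans(expr) else apply(expr, 1L, stats::median)
  out <- expr - loc
  if (scale == "unit") {
    s <- apply(out, 1L, stats::sd)
    s[s == 0] <- 1
    out <- out / s
  }
  expression_matrix(out)
}
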