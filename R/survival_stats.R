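# Clinical statistics layer: Kaplan-Meier curves, the k-group log-rank
# test, Cox proportional-hazards regression (Breslow ties, via the survival
# package), Fisher's exact test, Mann-Whitney U, Spearman correlation
# matrices, and GI50 estimation from dilution-series viability curves.

#' Kaplan-Meier product-limit estimate per group
#'
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param group optional group label per subject (default: one group).
#' @return named list of per-group data.frames with `time`, `n_risk`,
#'   `n_event`, `surv` (step function values; S(0) = 1 implicitly).
#' @export
km_estimate <- function(time, event, group = NULL) {
  .assert(length(time) == length(event), "time/event length mismatch")
  .assert(all(time > 0), "times must be > 0")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  .assert(all(table(group) > 0), "empty group")
  lapply(split(data.frame(time, event), group), function(df) {
    ts <- sort(unique(df$time[df$event == 1]))
    surv <- 1
    out <- lapply(ts, function(tt) {
      n_risk <- sum(df$time >= tt)
      n_event <- sum(df$time == tt & df$event == 1)
      data.frame(time = tt, n_risk = n_risk, n_event = n_event)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      return(data.frame(time = numeric(), n_risk = integer(),
                        n_event = integer(), surv = numeric()))
    }
    out$surv <- cumprod(1 - out$n_event / out$n_risk)
    out
  })
}

#' k-group log-rank test
#'
#' Standard observed-minus-expected log-rank with hypergeometric variance,
#' generalized to k groups (df = k - 1) via the generalized inverse of the
#' covariance of the first k - 1 groups.
#'
#' @param time,event survival data (>= 1 event overall).
#' @param group group label per subject (>= 2 groups).
#' @return list with `chisq`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  .assert(all(time > 0), "times must be > 0")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  group <- factor(group)
  .assert(nlevels(group) >= 2, "need >= 2 groups")
  .assert(all(table(group) > 0), "group with no subjects")
  .assert(sum(event) >= 1, "need >= 1 event")
  k <- nlevels(group)
  ts <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    d <- sum(event == 1 & time == tt)
    d_g <- vapply(levels(group), function(g) {
      sum(event == 1 & time == tt & group == g)
    }, 0)
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      # multivariate hypergeometric covariance of the group event counts
      frac <- n_g / n
      Vt <- d * (n - d) / (n - 1) * (diag(frac) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1L)
  diff <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- as.numeric(t(diff) %*% solve(Vi, diff))
  p <- stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  list(chisq = chisq, df = k - 1L, p_value = p,
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)),
       variance = V)
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Fits the Breslow partial likelihood by Newton-Raphson (via
#' `survival::coxph`) and reports hazard ratios with 95% Wald intervals.
#' Supports univariate and multivariate designs; covariates constant
#' across subjects are rejected, and monotone-likelihood (complete
#' separation) fits are flagged.
#'
#' @param time,event survival data.
#' @param covariates data.frame or matrix of numeric/binary covariates.
#' @param max_iter Newton-Raphson iteration cap.
#' @return data.frame per covariate: `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`, `coef`, `se`; attribute `separation` flags suspect fits.
#' @export
cox_fit <- function(time, event, covariates, max_iter = 100) {
  covariates <- as.data.frame(covariates)
  .assert(ncol(covariates) >= 1, "need >= 1 covariate")
  const <- vapply(covariates, function(x) length(unique(x)) == 1L, TRUE)
  .assert(!any(const), "constant covariate(s): %s",
          paste(colnames(covariates)[const], collapse = ", "))
  .assert(sum(event) >= ncol(covariates),
          "fewer events than covariates")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .,
                    data = covariates, ties = "breslow",
                    control = survival::coxph.control(iter.max = max_iter)),
    warning = function(w) {
      if (grepl("infinite|converge|ran out of iterations",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  .assert(!is.null(stats::coef(fit)),
          "Cox fit failed to converge in %d iterations", max_iter)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(
    covariate = names(beta),
    coef = as.numeric(beta), se = se,
    hr = exp(as.numeric(beta)),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "separation") <- separation || any(abs(beta) > 15)
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. The odds ratio is the sample cross-product ratio
#' (infinite when b*c = 0).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  .assert(all(dim(tab) == c(2L, 2L)), "table must be 2x2")
  .assert(all(tab >= 0) && all(tab == round(tab)),
          "cells must be non-negative integers")
  .assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
          "both margins must be positive")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (tab[1, 2] * tab[2, 1] == 0) {
    if (tab[1, 1] * tab[2, 2] == 0) NaN else Inf
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration of group assignments for small
#' samples (combined n below `exact_below` * 2 and no ties across the
#' exact path), otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_below use exact enumeration when both groups are smaller
#'   than this (and the combined size is tractable).
#' @return list with `u` (U statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_below = 20) {
  .assert(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # #{x > y} + ties/2
  small <- nx < exact_below && ny < exact_below && choose(nx + ny, nx) <= 2e5
  if (small) {
    combos <- utils::combn(nx + ny, nx)
    u_null <- apply(combos, 2L, function(ix) {
      sum(r[ix]) - nx * (nx + 1) / 2
    })
    mid <- nx * ny / 2
    p <- mean(abs(u_null - mid) >= abs(u - mid) - 1e-9)
    return(list(u = u, p_value = p, method = "exact enumeration"))
  }
  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
  sigma <- sqrt(nx * ny / 12 * ((nx + ny + 1) - tie_term))
  z <- (abs(u - mu) - 0.5) / sigma
  list(u = u, p_value = 2 * stats::pnorm(-max(z, 0)),
       method = "normal approximation")
}

#' Spearman correlation matrix with per-pair p-values
#'
#' Pearson correlation of midranked data between all column pairs of A and
#' B; p-values from the t approximation. Constant columns yield NA.
#'
#' @param a,b numeric matrices with matching row counts (observations in
#'   rows); `b` defaults to `a`.
#' @return list with `rho` and `p_value` matrices.
#' @export
spearman_matrix <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  .assert(nrow(a) == nrow(b) && nrow(a) >= 3, "need >= 3 paired observations")
  ra <- apply(a, 2L, rank)
  rb <- apply(b, 2L, rank)
  const_a <- apply(a, 2L, function(x) length(unique(x)) == 1L)
  const_b <- apply(b, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(ra, rb))
  rho[const_a, ] <- NA
  rho[, const_b] <- NA
  n <- nrow(a)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12 & !is.na(rho)] <- 0
  list(rho = rho, p_value = p)
}

#' GI50 from a dilution-series viability curve
#'
#' Default model is a four-parameter logistic on log concentration
#' (least squares), with log-linear interpolation between the bracketing
#' doses as the fallback. When viability never falls below 50%, the result
#' is right-censored at the maximum dose ("> max dose"); never crossing
#' from above yields the symmetric left-censored result.
#'
#' @param dose_response data.frame with `concentration` (positive,
#'   increasing) and `viability` (percent).
#' @param model `"fourPL"` or `"loglinear"`.
#' @param monotone_tol warn when the response rises by more than this many
#'   percentage points against the overall trend.
#' @return list with `gi50`, `censored` (`"none"`, `">max"`, `"<min"`),
#'   `model` actually used.
#' @export
gi50 <- function(dose_response, model = c("fourPL", "loglinear"),
                 monotone_tol = 15) {
  model <- match.arg(model)
  conc <- dose_response$concentration
  viab <- dose_response$viability
  .assert(length(conc) >= 4, "need >= 4 concentrations")
  .assert(all(conc > 0), "concentrations must be positive")
  .assert(all(is.finite(viab)), "viability must be finite")
  if (max(diff(viab)) > monotone_tol) {
    warning("non-monotone dose-response beyond tolerance", call. = FALSE)
  }
  if (all(viab > 50)) {
    return(list(gi50 = Inf, censored = ">max", model = "none"))
  }
  if (all(viab < 50)) {
    return(list(gi50 = 0, censored = "<min", model = "none"))
  }
  interp <- function() {
    below <- which(viab <= 50)[1L]
    above <- max(which(viab[seq_len(below)] > 50))
    lx <- log(conc[c(above, below)])
    ly <- viab[c(above, below)]
    exp(lx[1L] + (50 - ly[1L]) * diff(lx) / diff(ly))
  }
  if (model == "loglinear") {
    return(list(gi50 = interp(), censored = "none", model = "loglinear"))
  }
  start <- list(top = max(viab), bottom = min(0, min(viab)),
                lg = log(interp()), hill = 1)
  fit <- tryCatch(
    stats::nls(viab ~ bottom + (top - bottom) / (1 + exp(hill * (log(conc) - lg))),
               start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(gi50 = interp(), censored = "none",
                model = "loglinear (fourPL fallback)"))
  }
  cf <- stats::coef(fit)
  # concentration where the fitted curve crosses 50%
  g <- if (cf[["top"]] > 50 && cf[["bottom"]] < 50) {
    exp(cf[["lg"]] + log((cf[["top"]] - 50) / (50 - cf[["bottom"]])) / cf[["hill"]])
  } else {
    interp()
  }
  list(gi50 = unname(g), censored = "none", model = "fourPL")
}
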