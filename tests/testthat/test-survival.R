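test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- km_estimate(c(1, 2), c(1, 1))$all
  expect_equal(km$surv, c(0.5, 0))

  cens <- km_estimate(c(3, 5, 9), c(0, 0, 0))$all
  expect_equal(nrow(cens), 0)  # S stays at 1 throughout

  # doubling every record leaves the curve unchanged
  t1 <- c(1, 2, 3, 5); e1 <- c(1, 0, 1, 1)
  a <- km_estimate(t1, e1)$all
  b <- km_estimate(rep(t1, 2), rep(e1, 2))$all
  expect_equal(a$surv, b$surv)
})

test_that("log-rank matches the hand-computed toy and null symmetry", {
  lr <- logrank_test(c(1, 2), c(1, 1), c("A", "B"))
  expect_equal(lr$chisq, 1.0, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, 0.3173105, tolerance = 1e-6)
  expect_equal(unname(lr$observed["A"] - lr$expected["A"]), 0.5)

  # identical groups: statistic exactly zero
  tt <- c(1, 3, 4, 7); ee <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(tt, tt), c(ee, ee), rep(c("A", "B"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-10)
  expect_equal(lr0$p_value, 1)

  # df = 1 identity: chi-square equals squared standardized O-E
  set.seed(41)
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.8); g2 <- rep(c("A", "B"), 20)
  lr2 <- logrank_test(t2, e2, g2)
  z2 <- (lr2$observed["A"] - lr2$expected["A"])^2 / lr2$variance[1, 1]
  expect_equal(lr2$chisq, unname(z2), tolerance = 1e-10)

  # k-group version agrees with survival::survdiff
  g3 <- rep(c("A", "B", "C"), length.out = 60)
  set.seed(42)
  t3 <- rexp(60, ifelse(g3 == "C", 2, 1)); e3 <- rbinom(60, 1, 0.7)
  lr3 <- logrank_test(t3, e3, g3)
  sd3 <- survival::survdiff(survival::Surv(t3, e3) ~ g3)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-8)
  expect_equal(lr3$df, 2)
})

test_that("Cox regression reports HR, CI and flags bad designs", {
  set.seed(43)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.05 * 2^x)
  cc <- runif(n, 0, 40)
  fit <- cox_fit(pmin(t0, cc), as.numeric(t0 <= cc), data.frame(arm = x))
  expect_lt(abs(fit$hr - 2) / 2, 0.25)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  # duplicating the data leaves the estimate unchanged, SE shrinks ~ sqrt(2)
  fit2 <- cox_fit(rep(pmin(t0, cc), 2), rep(as.numeric(t0 <= cc), 2),
                  data.frame(arm = rep(x, 2)))
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-6)
  expect_equal(fit2$se * sqrt(2), fit$se, tolerance = 1e-3)

  expect_error(cox_fit(1:4, c(1, 1, 0, 1), data.frame(z = rep(1, 4))),
               "constant")

  # multivariate design runs and returns one row per covariate
  fitm <- cox_fit(pmin(t0, cc), as.numeric(t0 <= cc),
                  data.frame(arm = x, age = rnorm(n)))
  expect_equal(nrow(fitm), 2)
})

test_that("Fisher exact matches enumeration for all small tables", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(10, 3, 2, 15), 2))$odds_ratio, 25)
  eq <- fisher_exact(matrix(c(3, 3, 2, 2), 2))
  expect_equal(eq$p_value, 1)

  set.seed(44)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-10)
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Mann-Whitney exact and approximate paths are sound", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$u, 0)
  expect_equal(r1$p_value, 0.1)
  r2 <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_equal(r2$u, 2)
  expect_equal(r2$p_value, 1)
  # large-sample path approximates the exact one
  set.seed(45)
  x <- rnorm(50); y <- rnorm(60, 0.4)
  approx_p <- mann_whitney_u(x, y)$p_value
  expect_lt(abs(approx_p - wilcox.test(x, y, exact = FALSE)$p.value), 0.02)
})

test_that("Spearman matrices use midranks and flag constants", {
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  res <- spearman_matrix(cbind(x), cbind(y))
  expect_equal(res$rho[1, 1], cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(res$rho[1, 1], 4.5 / sqrt(4.5 * 5), tolerance = 1e-12)

  up <- 1:10
  expect_equal(unname(spearman_matrix(cbind(up), cbind(exp(up)))$rho[1, 1]), 1)
  expect_equal(unname(spearman_matrix(cbind(up), cbind(rev(up)))$rho[1, 1]), -1)
  cst <- spearman_matrix(cbind(rep(1, 5)), cbind(1:5))
  expect_true(is.na(cst$rho[1, 1]))
})

test_that("GI50 recovers the analytic midpoint and honors censoring", {
  dr <- simulate_dose_response(10, hill_slope = 1)
  g <- gi50(dr)
  expect_lt(abs(g$gi50 - 10) / 10, 0.01)
  g2 <- gi50(dr, model = "loglinear")
  expect_lt(abs(g2$gi50 - 10) / 10, 0.05)

  high <- simulate_dose_response(1e6, hill_slope = 1,
                                 concentrations = 2^(0:8))
  expect_identical(gi50(high)$censored, ">max")

  # uniformly higher viability never lowers the GI50
  lower <- dr; lower$viability <- pmin(dr$viability + 10, 100)
  g3 <- gi50(lower, model = "loglinear")
  expect_gte(g3$gi50, g2$gi50)

  # noisy recovery
  set.seed(46)
  errs <- replicate(40, {
    drn <- simulate_dose_response(10, 1, noise_sd = 3, seed = sample(1e6, 1))
    gi50(drn)$gi50
  })
  expect_lt(abs(median(errs) - 10) / 10, 0.1)
})
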