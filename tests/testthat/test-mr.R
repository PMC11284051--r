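test_that("Wald ratio arithmetic and error handling", {
  i1 <- make_instruments(bx = 1, by = 0.5, sy = 0.1)
  r1 <- wald_ratio(i1)
  expect_equal(r1$beta, 0.5)
  expect_equal(r1$se, 0.1)
  i2 <- make_instruments(bx = 0.7, by = 0, sy = 0.1)
  r2 <- wald_ratio(i2)
  expect_equal(r2$beta, 0)
  expect_equal(r2$odds_ratio, 1)
  i3 <- make_instruments(bx = 0.5, by = -0.1, sy = 0.05)
  r3 <- wald_ratio(i3)
  expect_equal(r3$beta, -0.2)
  expect_equal(r3$se, 0.1)
  expect_error(wald_ratio(make_instruments(0, 0.1, 0.1)), "zero")
})

test_that("IVW equals the Wald ratio for duplicated instruments", {
  inst <- make_instruments(bx = c(0.4, 0.4), by = c(0.12, 0.12),
                           sy = c(0.05, 0.05))
  fit <- ivw(inst)
  expect_equal(fit$beta, 0.12 / 0.4)
  expect_error(ivw(inst[1, ]), "at least 2")
})

test_that("an infinitely noisy instrument contributes nothing to IVW", {
  inst <- make_instruments(bx = c(0.3, 0.5, 0.2), by = c(0.1, 0.2, 0.05),
                           sy = c(0.04, 0.07, 1e9))
  with_it <- ivw(inst)
  without <- ivw(inst[1:2, ])
  expect_equal(with_it$beta, without$beta, tolerance = 1e-10)
  expect_equal(with_it$se, without$se, tolerance = 1e-6)
})

test_that("IVW matches a weighted-least-squares oracle to 1e-10", {
  set.seed(61)
  bx <- runif(5, 0.1, 0.5)
  by <- 0.3 * bx + rnorm(5, 0, 0.02)
  sy <- runif(5, 0.02, 0.08)
  inst <- make_instruments(bx, by, sy)
  fit <- ivw(inst)
  w <- 1 / sy^2
  # oracle: explicit zero-intercept normal equations
  beta_o <- solve(t(bx * w) %*% bx, t(bx * w) %*% by)[1, 1]
  se_o <- sqrt(solve(t(bx * w) %*% bx)[1, 1])
  expect_equal(fit$beta, beta_o, tolerance = 1e-10)
  expect_equal(fit$se, se_o, tolerance = 1e-10)
  # and the lm route agrees on the point estimate
  expect_equal(fit$beta, unname(coef(lm(by ~ 0 + bx, weights = w))),
               tolerance = 1e-10)
})

test_that("IVW is the precision-weighted average of Wald ratios", {
  set.seed(62)
  bx <- runif(8, 0.1, 0.6) * sample(c(-1, 1), 8, TRUE)
  by <- 0.25 * bx + rnorm(8, 0, 0.03)
  sy <- runif(8, 0.02, 0.1)
  inst <- make_instruments(bx, by, sy)
  ratios <- by / bx
  w <- bx^2 / sy^2
  expect_equal(ivw(inst)$beta, sum(w * ratios) / sum(w), tolerance = 1e-10)
})

test_that("estimators are equivariant under exposure rescaling", {
  set.seed(63)
  bx <- runif(10, 0.1, 0.4)
  by <- 0.4 * bx + rnorm(10, 0, 0.02)
  sy <- runif(10, 0.03, 0.08)
  inst <- make_instruments(bx, by, sy)
  scaled <- inst
  scaled$beta_exposure <- 2.5 * scaled$beta_exposure
  scaled$se_exposure <- 2.5 * scaled$se_exposure
  expect_equal(ivw(scaled)$beta, ivw(inst)$beta / 2.5, tolerance = 1e-12)
  expect_equal(mr_egger(scaled)$result$beta, mr_egger(inst)$result$beta / 2.5,
               tolerance = 1e-12)
  expect_equal(weighted_median(scaled, n_boot = 50, seed = 1)$beta,
               weighted_median(inst, n_boot = 50, seed = 1)$beta / 2.5,
               tolerance = 1e-12)
})

test_that("fixed-effect IVW SE never grows as instruments are added", {
  set.seed(64)
  bx <- runif(12, 0.1, 0.5)
  by <- 0.3 * bx + rnorm(12, 0, 0.02)
  sy <- runif(12, 0.02, 0.1)
  inst <- make_instruments(bx, by, sy)
  ses <- vapply(2:12, function(k) ivw(inst[1:k, ])$se, numeric(1))
  expect_true(all(diff(ses) <= 1e-12))
})

test_that("Egger slope and intercept match the closed-form WLS oracle", {
  bx <- c(0.1, 0.3, 0.5)
  by <- 0.02 + 0.4 * bx           # exactly collinear
  sy <- c(0.05, 0.04, 0.06)
  inst <- make_instruments(bx, by, sy)
  fit <- mr_egger(inst)
  X <- cbind(1, bx); W <- diag(1 / sy^2)
  coef_o <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  expect_equal(fit$intercept, unname(coef_o[1, 1]), tolerance = 1e-10)
  expect_equal(fit$result$beta, unname(coef_o[2, 1]), tolerance = 1e-10)
  # collinear data: residual scale is ~0, SE floors at the fixed-effect level
  cov_o <- solve(t(X) %*% W %*% X)
  expect_equal(fit$result$se, sqrt(cov_o[2, 2]), tolerance = 1e-8)
})

test_that("Egger intercept is well calibrated without pleiotropy", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_mr_instruments(20, 0.3, pleiotropy_sd = 0, seed = s)
    fit <- mr_egger(sim$instruments)
    hits <- hits + (abs(fit$intercept) <= 2 * fit$intercept_se)
  }
  expect_gte(hits, 93L)
})

test_that("directional pleiotropy surfaces in the Egger intercept", {
  sim <- simulate_mr_instruments(200, 0.3, pleiotropy_sd = 0.01,
                                 pleiotropy_mean = 0.05,
                                 exposure_n = 1e6, outcome_n = 1e6, seed = 9)
  fit <- mr_egger(sim$instruments)
  expect_gt(fit$intercept / fit$intercept_se, 3)
  expect_lt(fit$intercept_pval, 0.01)
})

test_that("weighted median reduces to the ordinary median and is robust", {
  inst <- make_instruments(bx = rep(1, 5), by = c(1, 2, 3, 4, 5),
                           sy = rep(0.1, 5))
  fit <- weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 3)
  # constant ratios give that constant under any weights
  inst2 <- make_instruments(bx = c(0.2, 0.5, 1), by = 0.7 * c(0.2, 0.5, 1),
                            sy = c(0.01, 0.3, 0.07))
  expect_equal(weighted_median(inst2, n_boot = 50, seed = 1)$beta, 0.7)
})

test_that("weighted median resists a minority of invalid instruments", {
  set.seed(65)
  bx <- runif(14, 0.2, 0.5)
  ratio <- c(rep(0.3, 10), rep(2.0, 4))
  sy <- c(rep(0.02, 10), rep(0.03, 4))
  by <- ratio * bx
  inst <- make_instruments(bx, by, sy)
  fit <- weighted_median(inst, n_boot = 200, seed = 2)
  expect_equal(fit$beta, 0.3, tolerance = 0.05)
  # IVW, by contrast, is dragged away by the invalid minority
  expect_gt(ivw(inst)$beta, 0.5)
})

test_that("Cochran's Q vanishes for identical ratios and matches arithmetic", {
  inst <- make_instruments(bx = c(0.2, 0.4, 0.8), by = 0.5 * c(0.2, 0.4, 0.8),
                           sy = c(0.03, 0.05, 0.06))
  expect_equal(cochran_q(inst)$cochran_q, 0, tolerance = 1e-20)
  # hand-computed three-instrument fixture
  bx <- c(0.5, 0.25, 1); by <- c(0.10, 0.10, 0.30); sy <- c(0.1, 0.05, 0.2)
  inst2 <- make_instruments(bx, by, sy)
  ratios <- by / bx                      # 0.2, 0.4, 0.3
  w <- bx^2 / sy^2                       # 25, 25, 25
  b_ivw <- sum(w * ratios) / sum(w)      # 0.3
  q_hand <- sum(w * (ratios - b_ivw)^2)  # 25*(0.01+0.01) = 0.5
  out <- cochran_q(inst2)
  expect_equal(out$cochran_q, q_hand, tolerance = 1e-12)
  expect_equal(out$q_df, 2L)
  expect_equal(out$q_pval, pchisq(q_hand, 2, lower.tail = FALSE))
})

test_that("Q p-values are uniform under homogeneity", {
  pvals <- vapply(1:200, function(s) {
    sim <- simulate_mr_instruments(10, 0.3, pleiotropy_sd = 0,
                                   exposure_n = 1e7, outcome_n = 5e4,
                                   seed = s)
    cochran_q(sim$instruments)$q_pval
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("odds-ratio conversion is exact in the null case", {
  out <- beta_to_or(0, 0.1)
  expect_equal(out$odds_ratio, 1)
  expect_equal(out$ci_low * out$ci_high, 1)   # symmetric on the log scale
  expect_equal(out$pval, 1)
})

test_that("run_mr dispatches by instrument count", {
  i1 <- make_instruments(0.5, 0.2, 0.05)
  expect_equal(run_mr(i1)$method, "wald_ratio")
  i2 <- make_instruments(c(0.5, 0.3), c(0.2, 0.1), c(0.05, 0.04))
  r2 <- run_mr(i2)
  expect_equal(r2$method, "ivw")
  expect_null(r2$sensitivity$egger)       # no Egger with two instruments
  expect_false(is.null(r2$sensitivity$cochran_q))
  i3 <- make_instruments(c(0.5, 0.3, 0.4), c(0.2, 0.1, 0.15),
                         c(0.05, 0.04, 0.05))
  r3 <- run_mr(i3, n_boot = 50)
  expect_equal(r3$method, "ivw")
  expect_s3_class(r3$sensitivity$egger, "mr_result")
  expect_s3_class(r3$sensitivity$weighted_median, "mr_result")
})

test_that("recovered causal effect lies within 2 SE at scale", {
  sim <- simulate_mr_instruments(20, 0.4, exposure_n = 20000,
                                 outcome_n = 20000, seed = 17)
  fit <- run_mr(sim$instruments, n_boot = 100)
  expect_lt(abs(fit$beta - 0.4), 2 * fit$se)
})

test_that("mr_result methods expose the estimate coherently", {
  inst <- make_instruments(c(0.5, 0.3, 0.4), c(0.2, 0.1, 0.15),
                           c(0.05, 0.04, 0.05))
  fit <- run_mr(inst, n_boot = 50)
  expect_equal(unname(coef(fit)), fit$beta)
  ci <- confint(fit)
  expect_lt(ci[1], fit$beta)
  expect_gt(ci[2], fit$beta)
  expect_equal(exp(ci[1]), fit$ci_low, tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.mr_result")
  expect_equal(s$method, c("ivw", "egger", "weighted_median"))
  expect_output(print(fit), "Two-sample MR")
})
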