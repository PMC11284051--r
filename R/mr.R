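# Two-sample Mendelian randomization estimators on a harmonized instrument
# set: Wald ratio, fixed-effect inverse-variance weighted (IVW), MR-Egger,
# weighted median, and Cochran's Q heterogeneity, plus the log-odds ->
# odds-ratio report conversion. run_mr() dispatches by instrument count and
# returns a classed S3 object with the usual model-object methods.

P_FLOOR <- 1e-300

check_instruments <- function(x, min_n, fn) {
  req <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
           "se_outcome")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stopf("instrument set is missing column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(x$snp)) stopf("duplicate instrument snp ids")
  if (nrow(x) < min_n)
    stopf("%s requires at least %d instrument(s), got %d", fn, min_n, nrow(x))
  if (any(x$se_outcome <= 0) || any(x$se_exposure < 0))
    stopf("instrument SEs must be positive")
  invisible(x)
}

two_sided_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), P_FLOOR)

mk_mr_result <- function(method, n_snps, beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(method = method, n_snps = n_snps, beta = beta, se = se,
                 pval = two_sided_p(beta / se),
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 level = level),
            class = "mr_result")
}

#' Wald ratio causal estimate from a single instrument
#'
#' beta = beta_outcome / beta_exposure, with the first-order standard error
#' se_outcome / |beta_exposure| (exposure-side uncertainty ignored; the
#' second-order delta-method SE, which adds the exposure term, is available
#' via `second_order = TRUE`).
#'
#' @param instrument one harmonized instrument record (one row)
#' @param second_order use the second-order delta-method SE
#' @return an `mr_result`
#' @export
wald_ratio <- function(instrument, second_order = FALSE) {
  check_instruments(instrument, 1L, "wald_ratio")
  if (nrow(instrument) != 1L) stopf("wald_ratio takes exactly one instrument")
  bx <- instrument$beta_exposure
  by <- instrument$beta_outcome
  if (bx == 0) stopf("Wald ratio undefined: exposure beta is zero")
  beta <- by / bx
  se <- instrument$se_outcome / abs(bx)
  if (second_order)
    se <- sqrt(instrument$se_outcome^2 / bx^2 +
                 by^2 * instrument$se_exposure^2 / bx^4)
  mk_mr_result("wald_ratio", 1L, beta, se)
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' Pools the instruments with weights 1/se_outcome^2:
#' beta = sum(w bx by) / sum(w bx^2), se = sqrt(1 / sum(w bx^2)) -- the
#' zero-intercept weighted least-squares regression of outcome betas on
#' exposure betas with the residual variance fixed at 1 (fixed-effect
#' model). With `random_effects = TRUE` the SE is inflated by the
#' multiplicative overdispersion factor max(1, sqrt(Q / (n - 1))).
#'
#' @param instruments harmonized instrument records (>= 2 rows)
#' @param random_effects multiplicative random-effects SE
#' @return an `mr_result`
#' @export
ivw <- function(instruments, random_effects = FALSE) {
  check_instruments(instruments, 2L, "ivw")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se <- sqrt(1 / denom)
  if (random_effects) {
    q <- sum(w * (by - beta * bx)^2)
    se <- se * max(1, sqrt(q / (nrow(instruments) - 1L)))
  }
  mk_mr_result(if (random_effects) "ivw_mre" else "ivw",
               nrow(instruments), beta, se)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept and weights 1/se_outcome^2. The slope is the pleiotropy-robust
#' causal estimate; a nonzero intercept indicates directional pleiotropy.
#' Standard errors use the estimated residual scale floored at 1
#' (multiplicative random-effects convention), with normal-approximation
#' p-values.
#'
#' @param instruments harmonized instrument records (>= 3 rows)
#' @return list with `result` (slope `mr_result`) and `intercept`,
#'   `intercept_se`, `intercept_pval`
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 3L, "mr_egger")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- max(sm$sigma, 1)          # never deflate below the FE model
  co <- sm$coefficients
  slope <- co["bx", "Estimate"]
  slope_se <- co["bx", "Std. Error"] / sm$sigma * sigma
  inter <- co["(Intercept)", "Estimate"]
  inter_se <- co["(Intercept)", "Std. Error"] / sm$sigma * sigma
  list(result = mk_mr_result("egger", nrow(instruments), slope, slope_se),
       intercept = inter, intercept_se = inter_se,
       intercept_pval = two_sided_p(inter / inter_se))
}

weighted_median_point <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; ws <- w[o] / sum(w)
  cw <- cumsum(ws) - ws / 2           # mid-point cumulative weights
  below <- max(which(cw < 0.5), 1L)
  if (cw[below] >= 0.5) return(r[1])
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1L] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

#' Weighted-median causal estimate
#'
#' The inverse-variance-weighted median of the per-instrument Wald ratios;
#' consistent when at least half the weight comes from valid instruments.
#' The standard error is obtained by parametric bootstrap: instrument betas
#' are resampled from normal distributions at their stated SEs and the
#' weighted median recomputed.
#'
#' @param instruments harmonized instrument records (>= 3 rows)
#' @param n_boot bootstrap draws for the SE
#' @param seed integer seed for the bootstrap
#' @return an `mr_result`
#' @export
weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 3L, "weighted_median")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  ratios <- by / bx
  w <- 1 / (sy^2 / bx^2)              # first-order ratio precision
  est <- weighted_median_point(ratios, w)
  set.seed(seed)
  k <- length(bx)
  boot <- vapply(seq_len(n_boot), function(b) {
    bxb <- stats::rnorm(k, bx, sx)
    byb <- stats::rnorm(k, by, sy)
    rb <- byb / bxb
    wb <- bxb^2 / sy^2
    weighted_median_point(rb, wb)
  }, numeric(1))
  mk_mr_result("weighted_median", k, est, stats::sd(boot))
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over instruments of w_j (ratio_j - beta_ivw)^2 with
#' w_j = beta_exposure_j^2 / se_outcome_j^2 (the first-order inverse
#' variance of the Wald ratio); under homogeneity Q is chi-square with
#' n_snps - 1 degrees of freedom. beta_ivw is the fixed-effect IVW
#' estimate, i.e. the precision-weighted mean of the ratios.
#'
#' @param instruments harmonized instrument records (>= 2 rows)
#' @return list with `cochran_q`, `q_df`, `q_pval`
#' @export
cochran_q <- function(instruments) {
  check_instruments(instruments, 2L, "cochran_q")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  ratios <- by / bx
  w <- bx^2 / instruments$se_outcome^2
  beta_ivw <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - beta_ivw)^2)
  df <- nrow(instruments) - 1L
  list(cochran_q = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Convert a log-odds effect to an odds ratio with confidence interval
#'
#' OR = exp(beta), CI = exp(beta +/- z se) with z the two-sided normal
#' quantile at `level`, and a two-sided normal p-value. This is the
#' conversion used to report MR results for a case-control outcome.
#'
#' @param beta log-odds effect estimate
#' @param se its standard error (> 0)
#' @param level confidence level (default 0.95)
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `pval`
#' @export
beta_to_or <- function(beta, se, level = 0.95) {
  check_number(se, "se", lower = 0, strict_lower = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(odds_ratio = exp(beta),
       ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se),
       pval = two_sided_p(beta / se))
}

#' Run two-sample MR with the count-based dispatch rule
#'
#' With a single instrument the Wald ratio is used; with two or more, the
#' fixed-effect IVW estimate. When three or more instruments are available
#' the MR-Egger slope and intercept, the weighted-median estimate and
#' Cochran's Q are attached as sensitivity analyses (Q alone when exactly
#' two).
#'
#' @param instruments harmonized instrument records (>= 1 row)
#' @param n_boot,seed bootstrap settings for the weighted-median SE
#' @return an `mr_result`; sensitivity analyses, when available, are in
#'   `$sensitivity` (fields cochran_q, q_df, q_pval, egger_intercept,
#'   egger_intercept_pval, egger, weighted_median)
#' @export
run_mr <- function(instruments, n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 1L, "run_mr")
  k <- nrow(instruments)
  res <- if (k == 1L) wald_ratio(instruments) else ivw(instruments)
  if (k >= 2L) {
    q <- cochran_q(instruments)
    res$sensitivity <- q
    if (k >= 3L) {
      eg <- mr_egger(instruments)
      wm <- weighted_median(instruments, n_boot = n_boot, seed = seed)
      res$sensitivity <- c(q, list(
        egger_intercept = eg$intercept,
        egger_intercept_se = eg$intercept_se,
        egger_intercept_pval = eg$intercept_pval,
        egger = eg$result, weighted_median = wm))
    }
  }
  res$instruments <- instruments
  res
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR (%s), %d instrument(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.*f  se = %.*f  p = %s\n", digits, x$beta, digits,
              x$se, format.pval(x$pval, digits = digits)))
  cat(sprintf("  OR = %.2f (%.0f%% CI %.2f-%.2f)\n", x$odds_ratio,
              100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
summary.mr_result <- function(object, ...) {
  rows <- list(data.frame(
    method = object$method, n_snps = object$n_snps, beta = object$beta,
    se = object$se, pval = object$pval, odds_ratio = object$odds_ratio,
    ci_low = object$ci_low, ci_high = object$ci_high,
    stringsAsFactors = FALSE))
  s <- object$sensitivity
  for (extra in list(s$egger, s$weighted_median)) {
    if (!is.null(extra))
      rows[[length(rows) + 1L]] <- data.frame(
        method = extra$method, n_snps = extra$n_snps, beta = extra$beta,
        se = extra$se, pval = extra$pval, odds_ratio = extra$odds_ratio,
        ci_low = extra$ci_low, ci_high = extra$ci_high,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "heterogeneity") <-
    if (!is.null(s)) s[c("cochran_q", "q_df", "q_pval")] else NULL
  attr(out, "egger_intercept") <-
    if (!is.null(s$egger_intercept))
      s[c("egger_intercept", "egger_intercept_se", "egger_intercept_pval")]
    else NULL
  class(out) <- c("summary.mr_result", "data.frame")
  out
}

#' @export
print.summary.mr_result <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  h <- attr(x, "heterogeneity")
  if (!is.null(h))
    cat(sprintf("Cochran's Q = %.3f on %d df, p = %s\n", h$cochran_q,
                h$q_df, format.pval(h$q_pval, digits = 3)))
  e <- attr(x, "egger_intercept")
  if (!is.null(e))
    cat(sprintf("Egger intercept = %.4f (se %.4f), p = %s\n",
                e$egger_intercept, e$egger_intercept_se,
                format.pval(e$egger_intercept_pval, digits = 3)))
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list(object$method,
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}
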