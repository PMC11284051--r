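# Internal numeric helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' log(exp(a) - exp(b)) for a >= b, stable
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a < b) stop("logdiffexp requires a >= b")
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside its allowed range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Per-variant marginal linear regression (closed form)
#'
#' Regress a quantitative phenotype on each dosage column separately,
#' returning effect, SE and two-sided p for every variant.
#' @keywords internal
marginal_linear <- function(G, y) {
  n <- length(y)
  gm <- colMeans(G)
  Gc <- sweep(G, 2L, gm)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- as.numeric(crossprod(Gc, yc))
  beta <- sxy / sxx
  # residual variance per variant
  syy <- sum(yc^2)
  rss <- syy - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  list(beta = beta, se = se,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Single-covariate logistic regression via IRLS
#'
#' Small hand-rolled Newton solver (intercept + one dosage) so that
#' thousands of per-variant fits stay cheap in simulations.
#' @keywords internal
logistic_fit1 <- function(g, y, max_iter = 25L, tol = 1e-8) {
  b0 <- log(mean(y) / (1 - mean(y)))
  b1 <- 0
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * g
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    # 2x2 weighted normal equations
    sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g * g)
    u0 <- sum(r); u1 <- sum(r * g)
    det <- sw * swgg - swg * swg
    if (det <= 0) break
    d0 <- (swgg * u0 - swg * u1) / det
    d1 <- (sw * u1 - swg * u0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- b0 + b1 * g
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g * g)
  det <- sw * swgg - swg * swg
  se <- sqrt(sw / det)
  z <- b1 / se
  list(beta = b1, se = se, pval = 2 * stats::pnorm(-abs(z)))
}

#' Per-variant marginal logistic regression
#' @keywords internal
marginal_logistic <- function(G, y) {
  m <- ncol(G)
  beta <- se <- pval <- numeric(m)
  for (j in seq_len(m)) {
    fit <- logistic_fit1(G[, j], y)
    beta[j] <- fit$beta; se[j] <- fit$se; pval[j] <- fit$pval
  }
  list(beta = beta, se = se, pval = pval)
}
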