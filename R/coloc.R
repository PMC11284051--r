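# Bayesian colocalization of two association signals in a cis region under
# the single-causal-variant approximate-Bayes-factor model: per-variant
# Wakefield log Bayes factors, hypothesis sums H0-H4 accumulated in log
# space, and posterior probabilities PP0-PP4.

#' Extract an aligned two-trait cis region around an anchor position
#'
#' Intersects the variants present in both traits within
#' `|pos - anchor_pos| <= flank_kb * 1000`, harmonizes the outcome (trait 2)
#' to the exposure's effect-allele orientation via [harmonize()], and
#' returns the paired per-variant effects in a common order.
#'
#' @param trait1,trait2 summary-statistics data frames (columns snp, chr,
#'   pos, ea, oa, eaf, beta, se, pval, n)
#' @param anchor_pos anchor base-pair position (e.g. the index pQTL)
#' @param flank_kb flank half-width in kb (default 500)
#' @param trait_types character length-2, each "quantitative" or
#'   "case_control"
#' @param palindromic_eaf_limit passed to [harmonize()]
#' @return object of class `coloc_region`: list with `snp`, `pos`,
#'   `beta1`, `se1`, `beta2`, `se2`, `trait_types`, `n_snps`
#' @export
extract_region <- function(trait1, trait2, anchor_pos, flank_kb = 500,
                           trait_types = c("quantitative", "case_control"),
                           palindromic_eaf_limit = 0.42) {
  validate_sumstats(trait1, "trait1")
  validate_sumstats(trait2, "trait2")
  check_number(flank_kb, "flank_kb", lower = 0)
  trait_types <- match.arg(trait_types,
                           c("quantitative", "case_control"),
                           several.ok = TRUE)
  if (length(trait_types) != 2L)
    stopf("trait_types must have length 2")
  in1 <- abs(trait1$pos - anchor_pos) <= flank_kb * 1000
  t1 <- trait1[in1, , drop = FALSE]
  shared <- intersect(t1$snp, trait2$snp)
  if (!length(shared))
    stopf("no shared variants between the two traits within the region")
  t1 <- t1[match(shared, t1$snp), , drop = FALSE]
  h <- harmonize(t1, trait2, palindromic_eaf_limit = palindromic_eaf_limit)
  if (!nrow(h))
    stopf("no variants remain after harmonization in the region")
  keep <- match(h$snp, t1$snp)
  structure(list(snp = h$snp, pos = t1$pos[keep],
                 beta1 = h$beta_exposure, se1 = h$se_exposure,
                 beta2 = h$beta_outcome, se2 = h$se_outcome,
                 trait_types = trait_types, n_snps = nrow(h)),
            class = "coloc_region")
}

#' Wakefield approximate log Bayes factor
#'
#' For an estimate beta with standard error se and a zero-centered normal
#' effect prior with SD `prior_sd`: with z = beta/se and
#' r = prior_sd^2 / (prior_sd^2 + se^2),
#' log ABF = 0.5 * (log(1 - r) + r z^2), the evidence for a nonzero effect
#' relative to the point null. Vectorized over beta/se.
#'
#' @param beta effect estimate(s)
#' @param se standard error(s), > 0
#' @param prior_sd prior effect SD; the conventional defaults are 0.15 for a
#'   quantitative trait (per SD units) and 0.2 for a case-control trait
#'   (log-odds)
#' @return log Bayes factor(s)
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stopf("se must be positive")
  check_number(prior_sd, "prior_sd", lower = 0, strict_lower = TRUE)
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z2)
}

default_prior_sd <- function(trait_type) {
  if (trait_type == "case_control") 0.2 else 0.15
}

#' Colocalization posteriors under the five-hypothesis ABF model
#'
#' Computes per-variant Wakefield log Bayes factors for each trait and the
#' posterior probability of the five mutually exclusive hypotheses: H0
#' (neither trait has a causal variant in the region), H1/H2 (only trait
#' 1/2), H3 (both, distinct variants), H4 (both, one shared variant). All
#' sums are accumulated in log space with log-sum-exp; PP3 is exactly zero
#' for a single-variant region, where no distinct-variant pair exists.
#'
#' @param region a `coloc_region`
#' @param p1,p2 per-variant prior probability of a trait-1-only /
#'   trait-2-only causal variant (default 1e-4)
#' @param p12 per-variant prior probability of a shared causal variant
#'   (default 1e-5)
#' @param prior_sd1,prior_sd2 effect-prior SDs per trait; defaults follow
#'   the trait types (0.15 quantitative, 0.2 case-control)
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `priors`, `n_snps`, `top_shared_variant` (id maximizing
#'   the per-variant shared term), and `lbf1`, `lbf2`
#' @export
coloc_abf <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(region, "coloc_region"))
  for (nm in c("p1", "p2", "p12"))
    check_number(get(nm), nm, lower = 0, upper = 1, strict_lower = TRUE,
                 strict_upper = TRUE)
  if (region$n_snps * (p1 + p2 + p12) >= 1)
    stopf("priors too large for region size: n * (p1+p2+p12) must be < 1")
  sd1 <- prior_sd1 %||% default_prior_sd(region$trait_types[1])
  sd2 <- prior_sd2 %||% default_prior_sd(region$trait_types[2])

  lbf1 <- log_abf(region$beta1, region$se1, sd1)
  lbf2 <- log_abf(region$beta2, region$se2, sd2)

  l1 <- logsumexp(lbf1)                 # sum_j BF1_j
  l2 <- logsumexp(lbf2)                 # sum_j BF2_j
  l12 <- logsumexp(lbf1 + lbf2)         # sum_j BF1_j BF2_j
  # sum over distinct pairs: (sum_i BF1_i)(sum_j BF2_j) - sum_j BF1_j BF2_j
  l3 <- if (region$n_snps < 2L) -Inf else logdiffexp(l1 + l2, l12)

  lh <- c(H0 = 0,
          H1 = log(p1) + l1,
          H2 = log(p2) + l2,
          H3 = log(p1) + log(p2) + l3,
          H4 = log(p12) + l12)
  m <- max(lh)
  pp <- exp(lh - m) / sum(exp(lh - m))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(trait1 = sd1, trait2 = sd2),
                 n_snps = region$n_snps,
                 top_shared_variant = region$snp[which.max(lbf1 + lbf2)],
                 lbf1 = stats::setNames(lbf1, region$snp),
                 lbf2 = stats::setNames(lbf2, region$snp)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 3, ...) {
  cat(sprintf("Colocalization over %d variants (p1=%g, p2=%g, p12=%g)\n",
              x$n_snps, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, digits))
  cat(sprintf("  top shared variant: %s\n", x$top_shared_variant))
  cat(sprintf("  shared-variant decision (PP4 > 0.8): %s\n",
              coloc_decision(x)))
  invisible(x)
}

#' Shared-causal-variant decision
#'
#' TRUE iff the posterior probability of a shared causal variant (PP4)
#' strictly exceeds the threshold. The boundary is strict: PP4 exactly
#' equal to the threshold returns FALSE.
#'
#' @param result a `coloc_result`
#' @param threshold decision threshold on PP4 (default 0.8)
#' @return logical
#' @export
coloc_decision <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "coloc_result"))
  unname(result$pp["PP4"] > threshold)
}
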