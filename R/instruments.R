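# Instrument selection from QTL summary statistics: p-value thresholding,
# greedy LD clumping against a correlation reference, and allele
# harmonization of exposure instruments with outcome summary statistics.

SUMSTATS_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                   "pval", "n")

validate_sumstats <- function(x, name = "sumstats") {
  miss <- setdiff(SUMSTATS_COLS, names(x))
  if (length(miss))
    stopf("%s is missing column(s): %s", name, paste(miss, collapse = ", "))
  if (anyDuplicated(x$snp)) stopf("%s has duplicate snp ids", name)
  if (any(x$se <= 0, na.rm = TRUE)) stopf("%s has non-positive SEs", name)
  if (any(x$pval <= 0 | x$pval > 1, na.rm = TRUE))
    stopf("%s has p-values outside (0, 1]", name)
  if (any(toupper(x$ea) == toupper(x$oa)))
    stopf("%s has records with identical effect and other allele", name)
  invisible(x)
}

#' Select candidate instruments by association p-value
#'
#' Returns the variants associated with the exposure below the significance
#' threshold (strict inequality), sorted ascending by p-value with ties
#' broken by (chromosome, position).
#'
#' @param sumstats summary-statistics data frame (columns snp, chr, pos, ea,
#'   oa, eaf, beta, se, pval, n)
#' @param p_threshold significance threshold (default 5e-8, genome-wide)
#' @return the qualifying rows of `sumstats`, re-sorted
#' @export
select_instruments <- function(sumstats, p_threshold = 5e-8) {
  validate_sumstats(sumstats)
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  hits <- sumstats[sumstats$pval < p_threshold, , drop = FALSE]
  hits <- hits[order(hits$pval, hits$chr, hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining candidate with the lowest p-value as an
#' index variant and discards every remaining candidate lying within
#' `window_kb` of it (base-pair distance <= window_kb * 1000) whose squared
#' correlation with it is at least `r2_threshold`. Candidates absent from
#' the LD reference cannot be certified independent and are conservatively
#' discarded (and reported in the `dropped` attribute).
#'
#' @param candidates summary-statistics rows, typically from
#'   [select_instruments()]
#' @param ld list with `snp_ids` and correlation matrix `r`, or a matrix
#'   with dimnames
#' @param r2_threshold squared-correlation threshold (discard at r2 >=
#'   threshold); 0.001 is the convention for eQTL instruments, 0.01 the
#'   relaxed pQTL panel setting
#' @param window_kb clumping window half-width in kb
#' @return the retained index variants in selection order, with attribute
#'   `dropped` (data frame: snp, reason)
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001,
                     window_kb = 10000) {
  validate_sumstats(candidates, "candidates")
  if (is.matrix(ld)) ld <- list(snp_ids = rownames(ld), r = ld)
  r <- ld$r
  ids <- ld$snp_ids %||% rownames(r)
  if (is.null(ids)) stopf("LD matrix has no snp ids")
  dimnames(r) <- list(ids, ids)

  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  known <- candidates$snp %in% ids
  if (any(!known)) {
    dropped <- rbind(dropped, data.frame(
      snp = candidates$snp[!known], reason = "missing_from_ld_reference",
      stringsAsFactors = FALSE))
    candidates <- candidates[known, , drop = FALSE]
  }
  candidates <- candidates[order(candidates$pval, candidates$chr,
                                 candidates$pos), , drop = FALSE]
  keep <- integer()
  remaining <- seq_len(nrow(candidates))
  while (length(remaining)) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    same_chr <- candidates$chr[remaining] == candidates$chr[idx]
    near <- same_chr &
      abs(candidates$pos[remaining] - candidates$pos[idx]) <= window_kb * 1000
    r2 <- r[candidates$snp[idx], candidates$snp[remaining]]^2
    clash <- near & r2 >= r2_threshold
    if (any(clash)) {
      dropped <- rbind(dropped, data.frame(
        snp = candidates$snp[remaining[clash]],
        reason = sprintf("r2 >= %g with index %s", r2_threshold,
                         candidates$snp[idx]),
        stringsAsFactors = FALSE))
      remaining <- remaining[!clash]
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

is_palindromic <- function(ea, oa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  toupper(oa) == comp[toupper(ea)]
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each exposure instrument with the outcome record for the same
#' variant on a common effect-allele orientation: when the outcome's alleles
#' are swapped relative to the exposure, the outcome beta is sign-flipped
#' and its effect-allele frequency complemented. Palindromic variants (A/T
#' or C/G) whose effect-allele frequency lies inside the ambiguity band
#' `(palindromic_eaf_limit, 1 - palindromic_eaf_limit)` -- or is missing --
#' cannot be oriented reliably and are excluded, as are variants absent
#' from the outcome or with mismatching allele pairs. Exclusions are
#' recorded with reasons.
#'
#' Harmonizing an already harmonized set is a no-op.
#'
#' @param exposure exposure summary-statistics rows (the instruments)
#' @param outcome outcome summary-statistics data frame
#' @param palindromic_eaf_limit half-width of the allowed frequency band for
#'   palindromic variants (default 0.42: frequencies in (0.42, 0.58) are
#'   ambiguous)
#' @return data frame of class `harmonized_instruments` with columns snp,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome, eaf, flipped;
#'   excluded records are in attribute `excluded` (snp, reason)
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  validate_sumstats(exposure, "exposure")
  validate_sumstats(outcome, "outcome")
  check_number(palindromic_eaf_limit, "palindromic_eaf_limit",
               lower = 0, upper = 0.5)

  excl <- list()
  rows <- list()
  om <- outcome[match(exposure$snp, outcome$snp), , drop = FALSE]
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    o <- om[i, ]
    if (is.na(o$snp)) {
      excl[[length(excl) + 1L]] <- c(e$snp, "absent_from_outcome"); next
    }
    ea <- toupper(e$ea); oa <- toupper(e$oa)
    oea <- toupper(o$ea); ooa <- toupper(o$oa)
    if (is_palindromic(ea, oa)) {
      f <- e$eaf
      ambiguous <- is.na(f) ||
        (f > palindromic_eaf_limit & f < 1 - palindromic_eaf_limit)
      if (ambiguous) {
        excl[[length(excl) + 1L]] <- c(e$snp, "palindromic_ambiguous_eaf")
        next
      }
    }
    if (oea == ea && ooa == oa) {
      flip <- FALSE
    } else if (oea == oa && ooa == ea) {
      flip <- TRUE
    } else {
      excl[[length(excl) + 1L]] <- c(e$snp, "allele_mismatch"); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = e$snp,
      beta_exposure = e$beta, se_exposure = e$se,
      beta_outcome = if (flip) -o$beta else o$beta,
      se_outcome = o$se,
      eaf = e$eaf,
      flipped = flip, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), beta_exposure = numeric(),
               se_exposure = numeric(), beta_outcome = numeric(),
               se_outcome = numeric(), eaf = numeric(), flipped = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harmonized_instruments", "data.frame")
  attr(out, "excluded") <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(snp = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(snp = character(), reason = character(),
                    stringsAsFactors = FALSE)
  out
}
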