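# Phenome-wide pleiotropy screen: threshold a multi-trait association table
# for one target and decide whether any off-target association survives.

#' Screen a target across a phenome-wide association table
#'
#' Returns the target's records with p-value strictly below `alpha`, sorted
#' ascending by p-value. A record at exactly `alpha` is excluded.
#'
#' @param table phenome-wide association data frame with columns gene,
#'   trait, trait_class, pval (effect optional)
#' @param target gene id to screen
#' @param alpha significance threshold (default 2e-8, the portal-style
#'   multiplicity-corrected cutoff)
#' @return the significant rows, sorted by p-value
#' @export
phewas_screen <- function(table, target, alpha = 2e-8) {
  req <- c("gene", "trait", "trait_class", "pval")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stopf("phewas table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(table$pval <= 0 | table$pval > 1))
    stopf("phewas p-values must be in (0, 1]")
  if (anyDuplicated(table[c("gene", "trait")]))
    stopf("duplicate (gene, trait) pairs in phewas table")
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  hits <- table[table$gene == target & table$pval < alpha, , drop = FALSE]
  hits <- hits[order(hits$pval), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Pleiotropy verdict from a screen result
#'
#' "clean" iff no significant off-target trait remains after excluding the
#' disease under study itself (case-insensitive substring match on the
#' trait name); otherwise "flagged".
#'
#' @param significant data frame of significant records from
#'   [phewas_screen()]
#' @param disease_trait trait-name substring identifying the study disease
#'   (default "multiple sclerosis")
#' @return "clean" or "flagged"
#' @export
pleiotropy_verdict <- function(significant,
                               disease_trait = "multiple sclerosis") {
  if (!nrow(significant)) return("clean")
  off_target <- !grepl(disease_trait, significant$trait, ignore.case = TRUE,
                       fixed = FALSE)
  if (any(off_target)) "flagged" else "clean"
}
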