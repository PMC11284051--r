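# Plain-text interchange: summary statistics and PheWAS tables as TSV, LD
# matrices as TSV with an id header, cell-by-gene counts as MatrixMarket
# triplets with genes/barcodes/metadata sidecars, ground truth as JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write / read GWAS or QTL summary statistics as TSV
#'
#' Tab-separated with header columns snp, chr, pos, ea, oa, eaf, beta, se,
#' pval, n.
#'
#' @param sumstats summary-statistics data frame
#' @param path file path
#' @return the path (write) or the validated data frame (read)
#' @export
write_sumstats <- function(sumstats, path) {
  validate_sumstats(sumstats)
  write_tsv(sumstats[SUMSTATS_COLS], path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- read_tsv(path)
  x$chr <- as.character(x$chr)
  validate_sumstats(x, basename(path))
  x
}

#' Write / read an LD correlation matrix as TSV
#'
#' Square matrix with variant ids as both header row and first column.
#'
#' @param ld list with `snp_ids` and matrix `r`, or a named matrix
#' @param path file path
#' @return the path (write) or a list with `snp_ids`, `r` (read)
#' @export
write_ld_matrix <- function(ld, path) {
  if (is.matrix(ld)) ld <- list(snp_ids = rownames(ld), r = ld)
  m <- as.data.frame(ld$r)
  names(m) <- ld$snp_ids
  m <- cbind(snp = ld$snp_ids, m)
  write_tsv(m, path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  x <- read_tsv(path)
  ids <- as.character(x[[1]])
  r <- as.matrix(x[, -1, drop = FALSE])
  dimnames(r) <- list(ids, ids)
  if (max(abs(r - t(r))) > 1e-8) stopf("LD matrix is not symmetric")
  list(snp_ids = ids, r = r)
}

#' Write / read a cell-by-gene count matrix as MatrixMarket + sidecars
#'
#' Writes `<prefix>.mtx` (genes x cells triplets), `<prefix>.genes.tsv`,
#' `<prefix>.barcodes.tsv`, and `<prefix>.metadata.tsv` (cell, donor,
#' condition).
#'
#' @param x a `cell_matrix`
#' @param prefix path prefix for the four files
#' @param mito_prefix gene-name prefix flagging mitochondrial genes on read
#' @return the prefix (write) or a `cell_matrix` (read)
#' @export
write_cell_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "cell_matrix"))
  Matrix::writeMM(x$counts, paste0(prefix, ".mtx"))
  writeLines(x$gene_ids, paste0(prefix, ".genes.tsv"))
  writeLines(x$cell_ids, paste0(prefix, ".barcodes.tsv"))
  write_tsv(x$cell_meta, paste0(prefix, ".metadata.tsv"))
  invisible(prefix)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(prefix, mito_prefix = "MT-") {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")),
                        "CsparseMatrix")
  genes <- readLines(paste0(prefix, ".genes.tsv"))
  cells <- readLines(paste0(prefix, ".barcodes.tsv"))
  meta <- read_tsv(paste0(prefix, ".metadata.tsv"))
  cell_matrix(counts, genes, cells, meta, mito_prefix = mito_prefix)
}

#' Write / read a ground-truth record as JSON
#'
#' @param truth a `ground_truth`
#' @param path file path
#' @return the path (write) or a `ground_truth` (read)
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- unclass(truth)
  # named numeric vectors must become objects, not bare arrays
  out$de_genes <- lapply(out$de_genes, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- ground_truth(
    scenario = if (is.null(x$scenario)) NA_character_ else x$scenario,
    causal_variant_ids = list(
      trait1 = as.character(x$causal_variant_ids$trait1 %||% character()),
      trait2 = as.character(x$causal_variant_ids$trait2 %||% character())),
    causal_effect = x$causal_effect %||% 0,
    de_genes = lapply(x$de_genes %||% list(), function(g) unlist(g)))
  extra <- setdiff(names(x), names(gt))
  for (nm in extra) gt[[nm]] <- x[[nm]]
  gt
}

#' Write a phenome-wide association table as TSV
#' @param table phewas data frame
#' @param path file path
#' @export
write_phewas_table <- function(table, path) write_tsv(table, path)

#' @rdname write_phewas_table
#' @export
read_phewas_table <- function(path) read_tsv(path)
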