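# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# minimal summary-statistics table on a 1 kb-spaced synthetic chromosome
make_sumstats <- function(n, beta = NULL, se = NULL, pval = NULL,
                          ea = "A", oa = "C", eaf = 0.3, chr = "1") {
  data.frame(
    snp = sprintf("snp%04d", seq_len(n)),
    chr = chr, pos = seq_len(n) * 1000L,
    ea = rep_len(ea, n), oa = rep_len(oa, n),
    eaf = rep_len(eaf, n),
    beta = beta %||% rep(0, n),
    se = se %||% rep(0.1, n),
    pval = pval %||% rep(0.5, n),
    n = 1000L, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_instruments <- function(bx, by, sy, sx = rep(0.01, length(bx))) {
  data.frame(snp = sprintf("iv%03d", seq_along(bx)),
             beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy,
             eaf = 0.3, flipped = FALSE, stringsAsFactors = FALSE)
}

# dense toy count matrix wrapped as a cell_matrix
make_cell_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                             condition = NULL, mito_genes = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  gene_ids <- gene_ids %||% sprintf("G%03d", seq_len(ng))
  cell_ids <- cell_ids %||% sprintf("c%03d", seq_len(nc))
  condition <- condition %||% rep_len(c("case", "control"), nc)
  meta <- data.frame(cell = cell_ids,
                     donor = rep_len(c("d1", "d2", "d3", "d4"), nc),
                     condition = condition, stringsAsFactors = FALSE)
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE), gene_ids, cell_ids,
              meta, mito_genes = mito_genes)
}

# adjusted Rand index (independent implementation for cluster checks)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
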