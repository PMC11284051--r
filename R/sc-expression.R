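# Single-cell expression stage: container, QC, normalization, PCA,
# graph clustering, marker-based annotation, and case-vs-control
# differential expression within cell types.

#' Cell-by-gene count container
#'
#' Thin validated container around a sparse genes x cells integer count
#' matrix with per-cell metadata (donor, condition) and a per-gene
#' mitochondrial flag.
#'
#' @param counts sparse non-negative integer matrix, genes in rows, cells in
#'   columns
#' @param gene_ids,cell_ids unique identifiers for rows / columns
#' @param cell_meta data frame with columns `cell`, `donor`, `condition`
#'   (`condition` in case/control), one row per cell in column order
#' @param mito_genes logical per-gene flag (default: gene id starts with
#'   `mito_prefix`)
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#' @return object of class `cell_matrix`
#' @export
cell_matrix <- function(counts, gene_ids, cell_ids, cell_meta,
                        mito_genes = NULL, mito_prefix = "MT-") {
  counts <- methods::as(counts, "CsparseMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    stopf("counts dimensions do not match gene/cell ids")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("counts must be non-negative integers")
  if (!all(c("cell", "donor", "condition") %in% names(cell_meta)))
    stopf("cell_meta needs columns cell, donor, condition")
  if (!identical(cell_meta$cell, as.character(cell_ids)))
    stopf("cell_meta rows must match cell_ids in order")
  bad <- setdiff(unique(cell_meta$condition), c("case", "control"))
  if (length(bad)) stopf("condition must be case/control, found: %s",
                         paste(bad, collapse = ", "))
  if (is.null(mito_genes)) mito_genes <- startsWith(gene_ids, mito_prefix)
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, mito_genes = mito_genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              length(x$gene_ids), length(x$cell_ids), sum(x$mito_genes)))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$cell_meta$condition)),
                            table(x$cell_meta$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

subset_cell_matrix <- function(x, genes = NULL, cells = NULL) {
  gi <- genes %||% seq_along(x$gene_ids)
  ci <- cells %||% seq_along(x$cell_ids)
  cell_matrix(x$counts[gi, ci, drop = FALSE],
              x$gene_ids[gi], x$cell_ids[ci],
              x$cell_meta[ci, , drop = FALSE],
              mito_genes = x$mito_genes[gi])
}

#' Quality-control filtering of cells and genes
#'
#' Removes genes detected (count > 0) in fewer than `min_cells_per_gene`
#' cells, then cells with fewer than `min_genes_per_cell` detected genes or
#' with a mitochondrial count fraction at or above `max_mito_fraction`.
#' The gene filter is applied before the cell filters, and the pair is
#' iterated to a fixed point so that the result always satisfies both
#' constraints simultaneously (which also makes the filter idempotent).
#'
#' Boundaries follow the "less than" convention: a cell with exactly
#' `min_genes_per_cell` detected genes is retained, one with
#' `min_genes_per_cell - 1` is removed; a gene detected in exactly
#' `min_cells_per_gene` cells is retained.
#'
#' @param x a `cell_matrix`
#' @param min_cells_per_gene genes must be detected in at least this many
#'   cells
#' @param min_genes_per_cell cells must have at least this many detected
#'   genes
#' @param max_mito_fraction cells with mitochondrial fraction >= this are
#'   removed
#' @return the filtered `cell_matrix`
#' @export
qc_filter <- function(x, min_cells_per_gene = 3L, min_genes_per_cell = 250L,
                      max_mito_fraction = 0.10) {
  stopifnot(inherits(x, "cell_matrix"))
  repeat {
    det <- x$counts > 0
    keep_g <- Matrix::rowSums(det) >= min_cells_per_gene
    if (any(!keep_g)) {
      x <- subset_cell_matrix(x, genes = which(keep_g))
      det <- x$counts > 0
    }
    genes_per_cell <- Matrix::colSums(det)
    tot <- Matrix::colSums(x$counts)
    mito_tot <- if (any(x$mito_genes))
      Matrix::colSums(x$counts[x$mito_genes, , drop = FALSE]) else 0
    mito_frac <- ifelse(tot > 0, mito_tot / tot, 0)
    keep_c <- genes_per_cell >= min_genes_per_cell & mito_frac < max_mito_fraction
    if (all(keep_g) && all(keep_c)) break
    if (!any(keep_c))
      stopf("no cells survive QC (thresholds: >= %d genes, mito < %g)",
            min_genes_per_cell, max_mito_fraction)
    x <- subset_cell_matrix(x, cells = which(keep_c))
  }
  if (length(x$gene_ids) == 0L) stopf("no genes survive QC")
  x
}

#' Log-normalize counts
#'
#' value = ln(1 + scale_factor * count / cell_total), the standard
#' library-size normalization followed by a log1p transform. Zero counts map
#' to zero, so the sparsity pattern is preserved.
#'
#' @param x a `cell_matrix`
#' @param scale_factor target library size (default 1e4)
#' @return sparse real-valued genes x cells matrix with dimnames
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  tot <- Matrix::colSums(x$counts)
  if (any(tot == 0)) stopf("all-zero cells must be removed before normalization")
  m <- x$counts
  # scale columns in the sparse slots directly
  m@x <- log1p(scale_factor * m@x / rep.int(tot, diff(m@p)))
  m
}

scale_rows <- function(m) {
  # dense per-gene standardization (center + unit variance)
  d <- as.matrix(m)
  mu <- rowMeans(d)
  sdev <- apply(d, 1L, stats::sd)
  sdev[sdev == 0] <- 1
  (d - mu) / sdev
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion (variance/mean of the normalized
#' values, z-scored within mean bins) and keeps the top `n_hvg`.
#'
#' @param normalized genes x cells normalized matrix
#' @param n_hvg number of genes to keep (capped at the number available)
#' @return character vector of gene ids
#' @export
select_hvg <- function(normalized, n_hvg = 2000L) {
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- pmax(ex2 - mu^2, 0)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, seq(0, 1, 0.05))),
              include.lowest = TRUE)
  zd <- stats::ave(disp, bins, FUN = function(z) {
    s <- stats::sd(z); if (is.na(s) || s == 0) s <- 1
    (z - mean(z)) / s
  })
  ord <- order(zd, decreasing = TRUE)
  rownames(normalized)[ord[seq_len(min(n_hvg, length(ord)))]]
}

#' Principal component analysis of normalized expression
#'
#' Computes PCA on per-gene standardized normalized values (cells as
#' observations), returning component scores ordered by decreasing explained
#' variance. Component signs are fixed so the loading of largest magnitude
#' is positive.
#'
#' @param normalized genes x cells normalized matrix (typically restricted
#'   to highly variable genes)
#' @param n_components number of components (capped at min(cells, genes))
#' @return list with `scores` (cells x components), `sdev` (component
#'   standard deviations) and `var_explained` (fractions)
#' @export
run_pca <- function(normalized, n_components = 31L) {
  z <- scale_rows(normalized)          # genes x cells
  k <- min(n_components, nrow(z), ncol(z))
  p <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = k)
  # deterministic sign convention
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       sdev = p$sdev[seq_len(k)],
       var_explained = p$sdev[seq_len(k)]^2 / sum(p$sdev^2))
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph in PC space, reweights edges by the
#' Jaccard overlap of neighborhoods (shared nearest neighbors), prunes weak
#' edges, and partitions the graph by Louvain community detection at the
#' given resolution. Deterministic for a fixed seed.
#'
#' @param scores cells x components PCA score matrix
#' @param n_neighbors neighborhood size k
#' @param resolution Louvain resolution; higher gives more clusters
#' @param seed integer seed
#' @param prune Jaccard weight below which edges are dropped
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer per cell) and `cell_type` (per-cluster annotation,
#'   initially NA)
#' @export
cluster_cells <- function(scores, n_neighbors = 20L, resolution = 1,
                          seed = 1L, prune = 1 / 15) {
  n <- nrow(scores)
  k <- min(n_neighbors, n - 1L)
  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  # shared-nearest-neighbor Jaccard weights on the kNN edge set
  nbr <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  ei <- rep(seq_len(n), each = k)
  ej <- as.integer(t(nn))
  keep <- ei < ej
  pairs <- unique(cbind(pmin(ei, ej), pmax(ei, ej)))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nbr[[pairs[r, 1]]]; b <- nbr[[pairs[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  sel <- w >= prune
  g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[sel]
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cl <- igraph::membership(comm)
  cl <- as.integer(factor(cl))         # compact 1..K labels
  names(cl) <- rownames(scores)
  structure(list(cluster = cl,
                 cell_type = rep(NA_character_, max(cl))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- max(x$cluster)
  cat(sprintf("cluster_assignment: %d cells in %d clusters\n",
              length(x$cluster), k))
  for (i in seq_len(k))
    cat(sprintf("  cluster %d: %d cells%s\n", i, sum(x$cluster == i),
                if (!is.na(x$cell_type[i])) paste0(" [", x$cell_type[i], "]")
                else ""))
  invisible(x)
}

#' Annotate clusters with cell types from marker gene sets
#'
#' Scores each cluster against each marker set by the mean per-gene
#' standardized (z-scored) expression of the set's markers in that cluster;
#' the cluster is labeled with the best-scoring type, or left "unassigned"
#' when the margin between best and runner-up falls below `min_margin`.
#'
#' @param assignment a `cluster_assignment`
#' @param normalized genes x cells normalized matrix
#' @param marker_sets named list: cell type -> character vector of marker
#'   gene ids (empty sets are never assigned)
#' @param min_margin minimum score margin between best and second-best type
#' @return the `cluster_assignment` with `cell_type` filled in
#' @export
annotate_clusters <- function(assignment, normalized, marker_sets,
                              min_margin = 0.05) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!length(marker_sets)) stopf("marker_sets must be non-empty")
  z <- scale_rows(normalized)
  cl <- assignment$cluster[colnames(normalized)]
  kk <- max(assignment$cluster)
  types <- names(marker_sets)
  score <- matrix(-Inf, nrow = kk, ncol = length(types),
                  dimnames = list(NULL, types))
  for (ty in types) {
    mk <- intersect(marker_sets[[ty]], rownames(z))
    if (!length(mk)) next                      # empty set: never assigned
    for (i in seq_len(kk)) {
      cells <- which(cl == i)
      score[i, ty] <- mean(z[mk, cells, drop = FALSE])
    }
  }
  for (i in seq_len(kk)) {
    s <- sort(score[i, ], decreasing = TRUE)
    if (!is.finite(s[1])) { assignment$cell_type[i] <- "unassigned"; next }
    margin <- if (length(s) > 1L && is.finite(s[2])) s[1] - s[2] else Inf
    assignment$cell_type[i] <-
      if (margin >= min_margin) names(s)[1] else "unassigned"
  }
  assignment
}

# Shared differential-expression engine: Wilcoxon rank-sum per gene between
# two cell groups on normalized values, with Seurat-convention fold changes
# log2((mean(expm1 x) + 1 + eps) / (mean(expm1 y) + 1 + eps)).
de_table <- function(normalized, cells1, cells2, pseudo = 1e-9) {
  x1 <- normalized[, cells1, drop = FALSE]
  x2 <- normalized[, cells2, drop = FALSE]
  m1 <- Matrix::rowMeans(expm1(x1))
  m2 <- Matrix::rowMeans(expm1(x2))
  log2fc <- log2((m1 + 1 + pseudo) / (m2 + 1 + pseudo))
  pct1 <- Matrix::rowMeans(x1 > 0)
  pct2 <- Matrix::rowMeans(x2 > 0)
  pval <- vapply(seq_len(nrow(normalized)), function(g) {
    a <- x1[g, ]; b <- x2[g, ]
    if (all(a == a[1]) && all(b == a[1])) return(1)
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  }, numeric(1))
  data.frame(gene = rownames(normalized), log2fc = log2fc,
             pct_group1 = pct1, pct_group2 = pct2, pval = pval,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find cluster marker genes (one-vs-rest)
#'
#' For each cluster, compares its cells against all remaining cells with a
#' two-sided Wilcoxon rank-sum test per gene. A gene is reported for a
#' cluster only if its absolute log2 fold change is at least
#' `min_abs_log2fc` and it is detected in at least `min_pct` of cells in
#' either group. P-values are Benjamini-Hochberg adjusted within each
#' cluster.
#'
#' @param normalized genes x cells normalized matrix
#' @param assignment a `cluster_assignment`
#' @param min_abs_log2fc minimum |log2FC| (inclusive)
#' @param min_pct minimum detection fraction in either group (inclusive)
#' @return data frame of DEG records: gene, cluster, cell_type, log2fc,
#'   pct_group1, pct_group2, pval, padj
#' @export
find_all_markers <- function(normalized, assignment,
                             min_abs_log2fc = 0.25, min_pct = 0.25) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- assignment$cluster[colnames(normalized)]
  out <- list()
  for (i in sort(unique(cl))) {
    tab <- de_table(normalized, which(cl == i), which(cl != i))
    tab$cluster <- i
    tab$cell_type <- assignment$cell_type[i]
    keep <- abs(tab$log2fc) >= min_abs_log2fc &
      pmax(tab$pct_group1, tab$pct_group2) >= min_pct
    tab <- tab[keep, , drop = FALSE]
    tab$padj <- stats::p.adjust(tab$pval, method = "BH")
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$padj, res$gene),
      c("gene", "cluster", "cell_type", "log2fc", "pct_group1",
        "pct_group2", "pval", "padj")]
}

#' Case-vs-control differential expression within cell types
#'
#' Within each annotated cell type, compares case cells against control
#' cells with a two-sided Wilcoxon rank-sum test per gene. Records must pass
#' strict thresholds on |log2FC| and detection fraction, and a
#' Benjamini-Hochberg adjusted p-value cutoff; adjustment is performed
#' within each cell type over the genes passing the effect-size filters.
#'
#' @param normalized genes x cells normalized matrix
#' @param assignment an annotated `cluster_assignment` (cell types filled)
#' @param conditions named character vector per cell, values case/control
#' @param min_abs_log2fc strict minimum |log2FC| (records at the threshold
#'   are excluded)
#' @param min_pct strict minimum detection fraction in either group
#' @param max_padj maximum adjusted p-value (inclusive)
#' @param min_cells_per_arm cell types with fewer cells in either condition
#'   are skipped
#' @return data frame of DEG records: gene, cell_type, log2fc, pct_group1
#'   (case), pct_group2 (control), pval, padj
#' @export
find_degs <- function(normalized, assignment, conditions,
                      min_abs_log2fc = 0.3, min_pct = 0.25,
                      max_padj = 0.05, min_cells_per_arm = 3L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cells <- colnames(normalized)
  cl <- assignment$cluster[cells]
  ctype <- assignment$cell_type[cl]
  cond <- conditions[cells]
  out <- list()
  for (ty in setdiff(unique(ctype), c(NA, "unassigned"))) {
    i_case <- which(ctype == ty & cond == "case")
    i_ctrl <- which(ctype == ty & cond == "control")
    if (length(i_case) < min_cells_per_arm ||
        length(i_ctrl) < min_cells_per_arm) next
    tab <- de_table(normalized, i_case, i_ctrl)
    keep <- abs(tab$log2fc) > min_abs_log2fc &
      pmax(tab$pct_group1, tab$pct_group2) > min_pct
    tab <- tab[keep, , drop = FALSE]
    if (!nrow(tab)) next
    tab$padj <- stats::p.adjust(tab$pval, method = "BH")
    tab <- tab[tab$padj <= max_padj, , drop = FALSE]
    if (!nrow(tab)) next
    tab$cell_type <- ty
    out[[length(out) + 1L]] <- tab
  }
  if (!length(out))
    return(data.frame(gene = character(), cell_type = character(),
                      log2fc = numeric(), pct_group1 = numeric(),
                      pct_group2 = numeric(), pval = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$cell_type, res$padj, res$gene),
             c("gene", "cell_type", "log2fc", "pct_group1", "pct_group2",
               "pval", "padj")]
  rownames(res) <- NULL
  res
}
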