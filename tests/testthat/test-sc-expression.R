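test_that("QC cell boundary: exactly min_genes detected is retained", {
  ng <- 300
  # cell 1: 250 detected genes; cell 2: 249; cells 3-6: all genes detected
  counts <- matrix(1L, nrow = ng, ncol = 6)
  counts[251:ng, 1] <- 0L
  counts[250:ng, 2] <- 0L
  m <- make_cell_matrix(counts)
  qc <- qc_filter(m, min_cells_per_gene = 1, min_genes_per_cell = 250)
  expect_true("c001" %in% qc$cell_ids)
  expect_false("c002" %in% qc$cell_ids)
})

test_that("QC gene boundary: detected in exactly 3 cells is retained", {
  counts <- matrix(5L, nrow = 10, ncol = 6)
  counts[1, 4:6] <- 0L   # gene 1 detected in 3 cells
  counts[2, 3:6] <- 0L   # gene 2 detected in 2 cells
  m <- make_cell_matrix(counts)
  qc <- qc_filter(m, min_cells_per_gene = 3, min_genes_per_cell = 1,
                  max_mito_fraction = 1)
  expect_true("G001" %in% qc$gene_ids)
  expect_false("G002" %in% qc$gene_ids)
})

test_that("QC removes the high-mito cell of the 6x6 toy matrix", {
  # six genes (one mitochondrial), six cells; every gene detected in all
  # cells except that cell 1 puts 50% of its counts on the mito gene
  counts <- matrix(2L, nrow = 6, ncol = 6)
  counts[1, 1] <- 10L   # mito gene: 10 of 20 counts in cell 1
  m <- make_cell_matrix(counts, gene_ids = c("MT-1", sprintf("G%03d", 2:6)),
                        mito_genes = c(TRUE, rep(FALSE, 5)))
  # hand enumeration: cell 1 puts 10 of its 20 counts on MT-1, mito
  # fraction 0.5; the other cells carry 2 of 12 counts on MT-1 (0.167),
  # so a toy threshold of 0.2 isolates exactly the planted cell
  qc2 <- qc_filter(m, min_cells_per_gene = 3, min_genes_per_cell = 2,
                   max_mito_fraction = 0.2)
  expect_equal(dim(qc2$counts), c(6L, 5L))
  expect_false("c001" %in% qc2$cell_ids)
})

test_that("qc_filter is idempotent", {
  sc <- simulate_sc_counts(c(A = 80, B = 80), n_genes = 400, seed = 21,
                           lowq_cell_fraction = 0.15)
  once <- qc_filter(sc$matrix)
  twice <- qc_filter(once)
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
  expect_identical(once$cell_ids, twice$cell_ids)
})

test_that("log-normalization matches its closed form and keeps zeros", {
  counts <- matrix(0L, nrow = 4, ncol = 2)
  counts[, 1] <- c(2L, 98L, 0L, 0L)     # total 100
  counts[, 2] <- c(7L, 0L, 7L, 0L)      # total 14
  m <- make_cell_matrix(counts)
  norm <- log_normalize(m, scale_factor = 1e4)
  expect_equal(norm[1, 1], log(1 + 1e4 * 2 / 100))   # ln(201)
  expect_equal(norm[3, 1], 0)
  expect_equal(as.vector(norm == 0), as.vector(m$counts == 0))
  # count equal to the cell total at scale factor 1 gives ln 2
  m2 <- make_cell_matrix(matrix(c(5L, 0L, 3L, 1L), nrow = 2))
  norm2 <- log_normalize(m2, scale_factor = 1)
  expect_equal(norm2[1, 1], log(2))
})

test_that("PCA recovers a rank-1 structure and orthogonal scores", {
  set.seed(31)
  u <- rnorm(30); v <- rnorm(40)
  x <- outer(u, v) + matrix(rnorm(1200, sd = 1e-3), 30, 40)
  rownames(x) <- sprintf("G%02d", 1:30)
  p <- run_pca(x, n_components = 5)
  expect_gt(p$var_explained[1], 0.99)
  cv <- stats::cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6 * max(diag(cv)))
})

test_that("PCA agrees with a dense eigendecomposition oracle", {
  set.seed(32)
  x <- matrix(rnorm(600), nrow = 30, ncol = 20)  # 30 genes x 20 cells
  rownames(x) <- sprintf("G%02d", 1:30)
  p <- run_pca(x, n_components = 5)
  # oracle: eigenvectors of the cell covariance of standardized genes
  z <- t(scale(t(x)))
  zc <- scale(t(z), scale = FALSE)
  ev <- eigen(stats::cov(zc))
  oracle_scores <- zc %*% ev$vectors[, 1:5]
  for (j in 1:5)
    expect_gt(abs(stats::cor(p$scores[, j], oracle_scores[, j])), 0.999)
})

test_that("clustering separates two well-separated blobs perfectly", {
  set.seed(41)
  scores <- rbind(matrix(rnorm(200, mean = 0), ncol = 2),
                  matrix(rnorm(200, mean = 20), ncol = 2))
  rownames(scores) <- sprintf("c%03d", 1:200)
  cl <- cluster_cells(scores, n_neighbors = 25, resolution = 0.1, seed = 1)
  truth <- rep(1:2, each = 100)
  expect_equal(max(cl$cluster), 2L)
  expect_equal(ari(cl$cluster, truth), 1)
})

test_that("a single blob at low resolution stays one cluster", {
  set.seed(42)
  scores <- matrix(rnorm(300), ncol = 3)
  rownames(scores) <- sprintf("c%03d", 1:100)
  cl <- cluster_cells(scores, resolution = 0.05, seed = 1)
  expect_equal(max(cl$cluster), 1L)
})

test_that("clustering recovers planted cell types on generated counts", {
  sc <- simulate_sc_counts(c(A = 200, B = 200), n_genes = 500, seed = 7,
                           markers = list(A = c("G0001", "G0002"),
                                          B = c("G0003", "G0004")))
  norm <- log_normalize(qc_filter(sc$matrix))
  pca <- run_pca(norm[select_hvg(norm, 2000), , drop = FALSE], 20)
  cl <- cluster_cells(pca$scores, seed = 7)
  truth <- sc$truth$cell_type[colnames(norm)]
  expect_gt(ari(cl$cluster, truth), 0.9)
  # determinism for a fixed seed
  cl2 <- cluster_cells(pca$scores, seed = 7)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("marker-set annotation labels clusters and honors empty sets", {
  # two clusters; genes 1-2 are A markers expressed only in cluster 1
  norm <- matrix(0.1, nrow = 6, ncol = 40,
                 dimnames = list(sprintf("G%03d", 1:6),
                                 sprintf("c%03d", 1:40)))
  norm[1:2, 1:20] <- 3
  norm[3:4, 21:40] <- 3
  cl <- structure(list(cluster = stats::setNames(rep(1:2, each = 20),
                                                 colnames(norm)),
                       cell_type = rep(NA_character_, 2)),
                  class = "cluster_assignment")
  ann <- annotate_clusters(cl, norm,
                           list(A = c("G001", "G002"),
                                B = c("G003", "G004"),
                                Never = character()))
  expect_equal(ann$cell_type, c("A", "B"))
  # empty marker set can never win
  ann2 <- annotate_clusters(cl, norm, list(Never = character(),
                                           A = c("G001", "G002")))
  expect_false("Never" %in% ann2$cell_type)
})

test_that("one-vs-rest markers require both effect and detection", {
  set.seed(51)
  norm <- matrix(rpois(8 * 60, 2) * 0.5, nrow = 8, ncol = 60,
                 dimnames = list(sprintf("G%03d", 1:8),
                                 sprintf("c%03d", 1:60)))
  norm[1, ] <- 1.0                        # identical everywhere
  norm[2, 1:30] <- 4; norm[2, 31:60] <- 0 # exclusive to cluster 1
  cl <- structure(list(cluster = stats::setNames(rep(1:2, each = 30),
                                                 colnames(norm)),
                       cell_type = c("A", "B")),
                  class = "cluster_assignment")
  mk <- find_all_markers(norm, cl)
  expect_false("G001" %in% mk$gene)
  expect_true("G002" %in% mk$gene[mk$cluster == 1])
})

test_that("planted markers are fully recovered from generated data", {
  markers <- list(A = c("G0001", "G0002", "G0003"),
                  B = c("G0004", "G0005"))
  sc <- simulate_sc_counts(c(A = 150, B = 150), n_genes = 400, seed = 52,
                           markers = markers)
  norm <- log_normalize(qc_filter(sc$matrix))
  pca <- run_pca(norm[select_hvg(norm, 2000), , drop = FALSE], 15)
  cl <- cluster_cells(pca$scores, seed = 1, resolution = 0.3)
  cl <- annotate_clusters(cl, norm, markers)
  mk <- find_all_markers(norm, cl)
  for (ty in names(markers)) {
    found <- mk$gene[mk$cell_type == ty & mk$log2fc > 0]
    expect_true(all(markers[[ty]] %in% found),
                label = sprintf("all %s markers recovered", ty))
  }
})

test_that("a gene at log2FC 0.29 is never a DEG regardless of p-value", {
  # construct normalized data with an enormous but sub-threshold shift
  n <- 200
  norm <- matrix(0.5, nrow = 3, ncol = n,
                 dimnames = list(c("Ga", "Gb", "Gc"),
                                 sprintf("c%03d", 1:n)))
  case <- 1:(n / 2); ctrl <- (n / 2 + 1):n
  # solve for means giving log2((m1+1)/(m0+1)) = 0.29 exactly, zero noise
  base <- expm1(0.8)
  target <- (base + 1) * 2^0.29 - 1
  norm["Ga", ctrl] <- 0.8
  norm["Ga", case] <- log1p(target)
  # Gb is a genuine DEG (log2fc ~ 1.2) so the result set is non-empty
  norm["Gb", ctrl] <- 0.2
  norm["Gb", case] <- 2.0
  cl <- structure(list(cluster = stats::setNames(rep(1L, n), colnames(norm)),
                       cell_type = "T"),
                  class = "cluster_assignment")
  cond <- stats::setNames(rep(c("case", "control"), each = n / 2),
                          colnames(norm))
  degs <- find_degs(norm, cl, cond, min_abs_log2fc = 0.3)
  expect_false("Ga" %in% degs$gene)
  expect_true("Gb" %in% degs$gene)
})

test_that("planted DE genes are detected at log2FC 1.5", {
  de <- list(A = c(G0010 = 1.5), B = c(G0011 = -1.5))
  sc <- simulate_sc_counts(c(A = 400, B = 400), n_genes = 400, seed = 53,
                           markers = list(A = "G0001", B = "G0002"),
                           de_genes = de)
  norm <- log_normalize(qc_filter(sc$matrix))
  pca <- run_pca(norm[select_hvg(norm, 2000), , drop = FALSE], 15)
  cl <- cluster_cells(pca$scores, seed = 1, resolution = 0.3)
  cl <- annotate_clusters(cl, norm, list(A = "G0001", B = "G0002"))
  cond <- stats::setNames(sc$matrix$cell_meta$condition,
                          sc$matrix$cell_meta$cell)
  degs <- find_degs(norm, cl, cond)
  expect_true("G0010" %in% degs$gene[degs$cell_type == "A"])
  expect_true("G0011" %in% degs$gene[degs$cell_type == "B"])
  expect_lt(degs$log2fc[degs$gene == "G0011"][1], 0)
})

test_that("permuted condition labels yield almost no DEG calls", {
  sc <- simulate_sc_counts(c(A = 200, B = 200), n_genes = 300, seed = 54)
  norm <- log_normalize(qc_filter(sc$matrix))
  cl <- structure(list(cluster = stats::setNames(
    as.integer(factor(sc$truth$cell_type[colnames(norm)])), colnames(norm)),
    cell_type = levels(factor(sc$truth$cell_type))),
    class = "cluster_assignment")
  total_calls <- 0
  for (s in 1:3) {
    set.seed(s)
    cond <- stats::setNames(sample(rep_len(c("case", "control"),
                                           ncol(norm))), colnames(norm))
    total_calls <- total_calls + nrow(find_degs(norm, cl, cond))
  }
  # FDR control: false calls stay below 5% of tested genes per run
  expect_lte(total_calls / 3, 0.05 * nrow(norm))
})

test_that("DEG output is invariant to gene and cell permutations", {
  sc <- simulate_sc_counts(c(A = 100, B = 100), n_genes = 200, seed = 55,
                           de_genes = list(A = c(G0020 = 1.5)))
  norm <- as.matrix(log_normalize(qc_filter(sc$matrix,
                                            min_genes_per_cell = 80)))
  cl <- structure(list(cluster = stats::setNames(
    as.integer(factor(sc$truth$cell_type[colnames(norm)])), colnames(norm)),
    cell_type = levels(factor(sc$truth$cell_type))),
    class = "cluster_assignment")
  cond <- stats::setNames(sc$matrix$cell_meta$condition,
                          sc$matrix$cell_meta$cell)
  base <- find_degs(norm, cl, cond)
  set.seed(56)
  gperm <- sample(nrow(norm)); cperm <- sample(ncol(norm))
  shuf <- find_degs(norm[gperm, cperm], cl, cond)
  expect_equal(base[order(base$cell_type, base$gene), ],
               shuf[order(shuf$cell_type, shuf$gene), ],
               ignore_attr = TRUE)
})

test_that("cell matrix round-trips through MatrixMarket files", {
  sc <- simulate_sc_counts(c(A = 30, B = 30), n_genes = 80, seed = 57)
  prefix <- file.path(tempdir(), "scio")
  write_cell_matrix(sc$matrix, prefix)
  back <- read_cell_matrix(prefix)
  expect_identical(as.matrix(back$counts), as.matrix(sc$matrix$counts))
  expect_identical(back$cell_meta, sc$matrix$cell_meta)
  expect_identical(back$mito_genes, sc$matrix$mito_genes)
})
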