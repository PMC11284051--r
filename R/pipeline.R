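# Pipeline orchestration: a flat YAML config, file-based stages
# (simulate -> sc-deg -> eQTL MR -> pQTL MR -> coloc -> phewas -> report),
# and the final target-prioritization report. Every stage reads and writes
# the plain-text interchange formats, so each is independently re-runnable,
# and a run log records every filter decision with its threshold and the
# observed value.

pipeline_defaults <- function() list(
  seed = 1L,
  synthetic = TRUE,
  # single-cell QC / normalization / clustering
  qc_min_cells_per_gene = 3, qc_min_genes_per_cell = 250,
  qc_max_mito_fraction = 0.10,
  norm_scale_factor = 1e4, n_hvg = 2000, pca_components = 31,
  cluster_neighbors = 20, cluster_resolution = 1.0,
  annotate_min_margin = 0.05,
  marker_min_abs_log2fc = 0.25, marker_min_pct = 0.25,
  # case-vs-control DEG thresholds
  deg_min_abs_log2fc = 0.3, deg_min_pct = 0.25, deg_max_padj = 0.05,
  # instrument selection / clumping (per QTL class)
  eqtl_p_threshold = 5e-8, eqtl_r2_threshold = 0.001,
  pqtl_p_threshold = 5e-8, pqtl_r2_threshold = 0.01,
  clump_window_kb = 10000, palindromic_eaf_limit = 0.42,
  # MR
  mr_significance = 0.05, mr_n_boot = 1000,
  # colocalization
  coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
  coloc_flank_kb = 500, coloc_pp4_threshold = 0.8,
  # phenome-wide screen
  phewas_alpha = 2e-8, disease_trait = "multiple sclerosis",
  require_eqtl_support = TRUE,
  # synthetic demo scenario
  sc_cells_per_type = 150, sc_n_genes = 600, sc_nb_dispersion = 0.4,
  sc_mito_gene_fraction = 0.05, sc_lowq_cell_fraction = 0.06,
  sc_donors_per_condition = 5,
  qtl_n_individuals = 10000, qtl_n_variants = 200, ld_decay = 0.95,
  qtl_maf_range = c(0.2, 0.5),
  qtl_effect = 0.6, outcome_effect = -0.35, case_fraction = 0.4,
  phewas_n_traits = 500
)

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (each stage default equals its
#' documented convention: QC at >= 250 genes and mito < 10%, DEG at
#' |log2FC| > 0.3 / minPct > 0.25 / Padj <= 0.05, instruments at p < 5e-8
#' clumped at r2 < 0.001 (eQTL) or < 0.01 (pQTL) over 10,000 kb windows,
#' MR gate p < 0.05, coloc priors (1e-4, 1e-4, 1e-5) with a +/- 500 kb
#' region and PP4 > 0.8, PheWAS at 2e-8) and overrides them from a flat
#' YAML file or a named list. Unknown keys are rejected.
#'
#' @param config path to a YAML file, a named list of overrides, or NULL
#'   for pure defaults
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- pipeline_defaults()
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    if (!is.list(config)) stopf("config must be a file path or a named list")
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
      stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
  }
  check_number(cfg$qc_max_mito_fraction, "qc_max_mito_fraction", 0, 1)
  check_number(cfg$mr_significance, "mr_significance", 0, 1,
               strict_lower = TRUE)
  check_number(cfg$coloc_pp4_threshold, "coloc_pp4_threshold", 0, 1)
  structure(cfg, class = c("pipeline_config", class(cfg)))
}

run_log_new <- function() data.frame(stage = character(), item = character(),
                                     message = character(),
                                     stringsAsFactors = FALSE)

log_add <- function(log, stage, item, message) {
  rbind(log, data.frame(stage = stage, item = item, message = message,
                        stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# Demo scenario: three candidate proteins planted as DEGs with QTL support.
#   - the true target: shared causal variant (H4) in both QTL stages,
#     protective effect, clean phenome-wide screen -> sole top-tier row
#   - an H3 decoy: distinct (but correlated) causal variants for protein
#     and disease, so MR looks nominally significant yet coloc must fail
#   - a PheWAS decoy: genuine H4 colocalization but a planted off-target
#     association -> demoted at the final screen
demo_candidates <- function() list(
  true_target  = list(gene = "G0101", cell_type = "B_cell",  log2fc = 1.5,
                      pqtl_scenario = "H4"),
  h3_decoy     = list(gene = "G0102", cell_type = "B_cell",  log2fc = 1.4,
                      pqtl_scenario = "H3"),
  phewas_decoy = list(gene = "G0103", cell_type = "T_cell",  log2fc = 1.5,
                      pqtl_scenario = "H4"))

demo_marker_sets <- function() list(
  B_cell   = sprintf("G%04d", 10:14),
  T_cell   = sprintf("G%04d", 20:24),
  Monocyte = sprintf("G%04d", 30:34))

#' Generate the bundled synthetic demo inputs
#'
#' Writes every input the cascade consumes to `out_dir/inputs`: a
#' cell-by-gene count matrix with three planted cell types and planted
#' case-vs-control DEGs; per-candidate eQTL and pQTL summary-statistic
#' panels paired with a simulated case-control disease GWAS on a shared LD
#' panel (shared causal variant for the true target, distinct correlated
#' variants for the H3 decoy); an LD reference per panel; and a
#' phenome-wide association table per candidate (one with a planted
#' off-target hit). Ground truth is stored as JSON alongside.
#'
#' @param config a `pipeline_config` (or anything [pipeline_config()]
#'   accepts)
#' @param out_dir output directory
#' @return (invisibly) the input directory path
#' @export
stage_simulate <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  inp <- file.path(out_dir, "inputs")
  cands <- demo_candidates()
  markers <- demo_marker_sets()

  de <- list(
    B_cell = c(G0101 = cands$true_target$log2fc,
               G0102 = cands$h3_decoy$log2fc),
    T_cell = c(G0103 = cands$phewas_decoy$log2fc, G0104 = -1.2))
  sc <- simulate_sc_counts(
    cells_per_type = c(B_cell = cfg$sc_cells_per_type,
                       T_cell = cfg$sc_cells_per_type,
                       Monocyte = cfg$sc_cells_per_type),
    n_genes = cfg$sc_n_genes, markers = markers, de_genes = de,
    nb_dispersion = cfg$sc_nb_dispersion,
    mito_gene_fraction = cfg$sc_mito_gene_fraction,
    lowq_cell_fraction = cfg$sc_lowq_cell_fraction,
    donors_per_condition = cfg$sc_donors_per_condition,
    seed = cfg$seed)
  write_cell_matrix(sc$matrix, file.path(inp, "sc"))
  write_ground_truth(sc$truth, file.path(inp, "sc.truth.json"))
  jsonlite::write_json(markers, file.path(inp, "marker_sets.json"),
                       auto_unbox = FALSE, pretty = TRUE)

  m <- cfg$qtl_n_variants
  panel_seed <- cfg$seed * 101L
  for (i in seq_along(cands)) {
    cand <- cands[[i]]
    g <- cand$gene
    for (class_i in c("eqtl", "pqtl")) {
      sd <- panel_seed + 10L * i + (class_i == "pqtl")
      geno <- simulate_ld_genotypes(cfg$qtl_n_individuals, m,
                                    decay = cfg$ld_decay,
                                    maf_range = cfg$qtl_maf_range, seed = sd)
      scen <- if (class_i == "pqtl") cand$pqtl_scenario else "H4"
      ce <- m %/% 2L + 1L
      sim <- simulate_two_trait_sumstats(
        geno, scenario = scen,
        exposure_effect = cfg$qtl_effect,
        outcome_effect = cfg$outcome_effect,
        outcome_type = "case_control", seed = sd + 1L,
        causal_exposure = ce,
        causal_outcome = if (scen == "H3") ce - 8L else NULL,
        case_fraction = cfg$case_fraction)
      pre <- file.path(inp, sprintf("%s_%s", class_i, g))
      write_sumstats(sim$exposure, paste0(pre, ".exposure.tsv"))
      write_sumstats(sim$outcome, paste0(pre, ".outcome.tsv"))
      write_ld_matrix(list(snp_ids = geno$variants$snp, r = geno$ld),
                      paste0(pre, ".ld.tsv"))
      write_ground_truth(sim$truth, paste0(pre, ".truth.json"))
    }
    planted <- if (names(cands)[i] == "phewas_decoy")
      c("essential hypertension" = 1e-9) else NULL
    pw <- simulate_phewas_table(g, cfg$phewas_n_traits, planted = planted,
                                seed = panel_seed + 100L + i)
    write_phewas_table(pw, file.path(inp, sprintf("phewas_%s.tsv", g)))
  }
  writeLines(jsonlite::toJSON(lapply(cands, `[[`, "gene"),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(inp, "candidates.json"))
  invisible(inp)
}

#' Single-cell stage: QC, normalization, clustering, annotation, DEGs
#'
#' Reads the cell-by-gene matrix and marker sets from `out_dir/inputs`,
#' runs QC filtering, log-normalization, highly-variable-gene selection,
#' PCA, shared-nearest-neighbor Louvain clustering, marker-based cluster
#' annotation, and case-vs-control differential expression within each
#' annotated cell type. Writes `clusters.tsv`, `markers.tsv` and
#' `degs.tsv` to `out_dir`.
#'
#' @inheritParams stage_simulate
#' @return (invisibly) the DEG data frame
#' @export
stage_sc_deg <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  inp <- file.path(out_dir, "inputs")
  mat <- read_cell_matrix(file.path(inp, "sc"))
  marker_sets <- lapply(
    jsonlite::read_json(file.path(inp, "marker_sets.json"),
                        simplifyVector = TRUE), as.character)
  log <- run_log_new()
  n0 <- dim(mat)
  qc <- qc_filter(mat, cfg$qc_min_cells_per_gene, cfg$qc_min_genes_per_cell,
                  cfg$qc_max_mito_fraction)
  log <- log_add(log, "qc", "cells",
                 sprintf("retained %d of %d cells (>= %d genes, mito < %g)",
                         ncol(qc$counts), n0[2], cfg$qc_min_genes_per_cell,
                         cfg$qc_max_mito_fraction))
  log <- log_add(log, "qc", "genes",
                 sprintf("retained %d of %d genes (detected in >= %d cells)",
                         nrow(qc$counts), n0[1], cfg$qc_min_cells_per_gene))
  norm <- log_normalize(qc, cfg$norm_scale_factor)
  hvg <- select_hvg(norm, cfg$n_hvg)
  pca <- run_pca(norm[hvg, , drop = FALSE], cfg$pca_components)
  cl <- cluster_cells(pca$scores, cfg$cluster_neighbors,
                      cfg$cluster_resolution, seed = cfg$seed)
  cl <- annotate_clusters(cl, norm, marker_sets, cfg$annotate_min_margin)
  log <- log_add(log, "cluster", "assignment",
                 sprintf("%d clusters annotated as: %s", max(cl$cluster),
                         paste(cl$cell_type, collapse = ", ")))
  mk <- find_all_markers(norm, cl, cfg$marker_min_abs_log2fc,
                         cfg$marker_min_pct)
  cond <- stats::setNames(qc$cell_meta$condition, qc$cell_meta$cell)
  degs <- find_degs(norm, cl, cond, cfg$deg_min_abs_log2fc,
                    cfg$deg_min_pct, cfg$deg_max_padj)
  log <- log_add(log, "deg", "count",
                 sprintf("%d DEGs at |log2FC| > %g, pct > %g, padj <= %g",
                         nrow(degs), cfg$deg_min_abs_log2fc,
                         cfg$deg_min_pct, cfg$deg_max_padj))
  write_tsv(data.frame(cell = names(cl$cluster), cluster = cl$cluster,
                       cell_type = cl$cell_type[cl$cluster],
                       stringsAsFactors = FALSE),
            file.path(out_dir, "clusters.tsv"))
  write_tsv(mk, file.path(out_dir, "markers.tsv"))
  write_tsv(degs, file.path(out_dir, "degs.tsv"))
  append_run_log(log, out_dir)
  invisible(degs)
}

append_run_log <- function(log, out_dir) {
  path <- file.path(out_dir, "run_log.tsv")
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
  invisible(path)
}

mr_for_gene <- function(gene, inp, class, cfg, log) {
  pre <- file.path(inp, sprintf("%s_%s", class, gene))
  if (!file.exists(paste0(pre, ".exposure.tsv")))
    return(list(res = NULL, log = log_add(log, class, gene,
                                          "no QTL panel available")))
  exposure <- read_sumstats(paste0(pre, ".exposure.tsv"))
  outcome <- read_sumstats(paste0(pre, ".outcome.tsv"))
  ld <- read_ld_matrix(paste0(pre, ".ld.tsv"))
  p_thr <- if (class == "eqtl") cfg$eqtl_p_threshold else cfg$pqtl_p_threshold
  r2_thr <- if (class == "eqtl") cfg$eqtl_r2_threshold else
    cfg$pqtl_r2_threshold
  cand <- select_instruments(exposure, p_thr)
  log <- log_add(log, class, gene,
                 sprintf("%d candidate instruments at p < %g", nrow(cand),
                         p_thr))
  if (!nrow(cand)) return(list(res = NULL, log = log))
  clumped <- ld_clump(cand, ld, r2_thr, cfg$clump_window_kb)
  log <- log_add(log, class, gene,
                 sprintf("%d instruments after clumping at r2 < %g, %g kb",
                         nrow(clumped), r2_thr, cfg$clump_window_kb))
  h <- harmonize(clumped, outcome, cfg$palindromic_eaf_limit)
  if (!nrow(h)) return(list(res = NULL, log = log_add(log, class, gene,
                            "no instruments survive harmonization")))
  res <- run_mr(h, n_boot = cfg$mr_n_boot, seed = cfg$seed)
  log <- log_add(log, class, gene,
                 sprintf("MR (%s, %d snps): beta=%.4f se=%.4f p=%.3g",
                         res$method, res$n_snps, res$beta, res$se, res$pval))
  list(res = res, log = log, exposure = exposure, outcome = outcome)
}

mr_row <- function(gene, res) data.frame(
  gene = gene, method = res$method, nsnp = res$n_snps, beta = res$beta,
  se = res$se, pval = res$pval, or = res$odds_ratio, ci_low = res$ci_low,
  ci_high = res$ci_high, stringsAsFactors = FALSE)

#' MR stage for one instrument class
#'
#' For each candidate gene with a QTL panel of the requested class, selects
#' instruments below the class p-value threshold, clumps them against the
#' panel's LD reference at the class r-squared threshold (0.001 for eQTL,
#' 0.01 for pQTL by default, both over 10,000 kb windows), harmonizes them
#' with the disease GWAS, and runs the count-dispatched MR. Writes
#' `mr_<class>.tsv`.
#'
#' @inheritParams stage_simulate
#' @param instrument_class "eqtl" or "pqtl"
#' @param genes candidate gene ids; default: DEG genes from `degs.tsv`
#'   (intersected with eQTL-MR-significant genes for the pqtl class when
#'   `require_eqtl_support` is set)
#' @return (invisibly) the MR results data frame
#' @export
stage_mr <- function(config = NULL, out_dir,
                     instrument_class = c("eqtl", "pqtl"), genes = NULL) {
  cfg <- pipeline_config(config)
  class <- match.arg(instrument_class)
  inp <- file.path(out_dir, "inputs")
  log <- run_log_new()
  if (is.null(genes)) {
    degs <- read_tsv(file.path(out_dir, "degs.tsv"))
    genes <- unique(degs$gene)
    if (class == "pqtl" && cfg$require_eqtl_support) {
      emr <- read_tsv(file.path(out_dir, "mr_eqtl.tsv"))
      sig <- emr$gene[emr$pval < cfg$mr_significance]
      log <- log_add(log, "pqtl", "gate",
                     sprintf("%d of %d DEG genes pass eQTL MR at p < %g",
                             length(intersect(genes, sig)), length(genes),
                             cfg$mr_significance))
      genes <- intersect(genes, sig)
    }
  }
  rows <- list()
  for (g in genes) {
    fit <- mr_for_gene(g, inp, class, cfg, log)
    log <- fit$log
    if (!is.null(fit$res)) rows[[g]] <- mr_row(g, fit$res)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    mr_row("x", mk_mr_result("ivw", 0L, 0, 1))[0, ]
  rownames(out) <- NULL
  write_tsv(out, file.path(out_dir, sprintf("mr_%s.tsv", class)))
  append_run_log(log, out_dir)
  invisible(out)
}

#' Colocalization stage
#'
#' For each protein whose pQTL MR reached the significance gate, extracts
#' the cis region around the index pQTL (the exposure's minimum-p variant),
#' computes the five-hypothesis posteriors, and applies the PP4 decision.
#' Writes `coloc.tsv`.
#'
#' @inheritParams stage_simulate
#' @return (invisibly) the coloc results data frame
#' @export
stage_coloc <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  inp <- file.path(out_dir, "inputs")
  pmr <- read_tsv(file.path(out_dir, "mr_pqtl.tsv"))
  log <- run_log_new()
  rows <- list()
  for (g in pmr$gene[pmr$pval < cfg$mr_significance]) {
    exposure <- read_sumstats(file.path(inp, sprintf("pqtl_%s.exposure.tsv", g)))
    outcome <- read_sumstats(file.path(inp, sprintf("pqtl_%s.outcome.tsv", g)))
    anchor <- exposure$pos[which.min(exposure$pval)]
    region <- extract_region(exposure, outcome, anchor, cfg$coloc_flank_kb,
                             trait_types = c("quantitative", "case_control"),
                             palindromic_eaf_limit = cfg$palindromic_eaf_limit)
    res <- coloc_abf(region, cfg$coloc_p1, cfg$coloc_p2, cfg$coloc_p12)
    pass <- coloc_decision(res, cfg$coloc_pp4_threshold)
    log <- log_add(log, "coloc", g,
                   sprintf("PP4=%.4f over %d snps -> %s (threshold %g)",
                           res$pp["PP4"], res$n_snps,
                           if (pass) "colocalizes" else "fails",
                           cfg$coloc_pp4_threshold))
    rows[[g]] <- data.frame(
      gene = g, n_snps = res$n_snps,
      pp0 = res$pp["PP0"], pp1 = res$pp["PP1"], pp2 = res$pp["PP2"],
      pp3 = res$pp["PP3"], pp4 = res$pp["PP4"],
      top_shared_variant = res$top_shared_variant, pass = pass,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), n_snps = integer(), pp0 = numeric(),
               pp1 = numeric(), pp2 = numeric(), pp3 = numeric(),
               pp4 = numeric(), top_shared_variant = character(),
               pass = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  write_tsv(out, file.path(out_dir, "coloc.tsv"))
  append_run_log(log, out_dir)
  invisible(out)
}

#' Phenome-wide screen stage
#'
#' Screens every protein that reached the pQTL MR stage against its
#' phenome-wide association table at the configured threshold and issues a
#' clean/flagged pleiotropy verdict (the study disease itself never flags).
#' Writes `phewas_hits.tsv` and `phewas_verdicts.tsv`.
#'
#' @inheritParams stage_simulate
#' @return (invisibly) the verdicts data frame
#' @export
stage_phewas <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  inp <- file.path(out_dir, "inputs")
  pmr <- read_tsv(file.path(out_dir, "mr_pqtl.tsv"))
  log <- run_log_new()
  hits <- list(); verd <- list()
  for (g in pmr$gene) {
    path <- file.path(inp, sprintf("phewas_%s.tsv", g))
    if (!file.exists(path)) {
      log <- log_add(log, "phewas", g, "no phewas table; verdict clean")
      verd[[g]] <- data.frame(gene = g, n_significant = 0L,
                              verdict = "clean", stringsAsFactors = FALSE)
      next
    }
    tab <- read_phewas_table(path)
    sig <- phewas_screen(tab, g, cfg$phewas_alpha)
    v <- pleiotropy_verdict(sig, cfg$disease_trait)
    log <- log_add(log, "phewas", g,
                   sprintf("%d association(s) at p < %g -> %s", nrow(sig),
                           cfg$phewas_alpha, v))
    if (nrow(sig)) hits[[g]] <- sig
    verd[[g]] <- data.frame(gene = g, n_significant = nrow(sig), verdict = v,
                            stringsAsFactors = FALSE)
  }
  hit_df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(), trait = character(),
               trait_class = character(), pval = numeric(),
               effect = numeric(), stringsAsFactors = FALSE)
  verd_df <- do.call(rbind, c(verd, list(make.row.names = FALSE)))
  rownames(hit_df) <- NULL
  write_tsv(hit_df, file.path(out_dir, "phewas_hits.tsv"))
  write_tsv(verd_df, file.path(out_dir, "phewas_verdicts.tsv"))
  append_run_log(log, out_dir)
  invisible(verd_df)
}

#' Assemble the target-prioritization report
#'
#' Joins the DEG, eQTL-MR, pQTL-MR, colocalization and PheWAS outputs into
#' one row per candidate gene/protein. A candidate reaches the `top` tier
#' iff its pQTL MR p-value is below the significance gate AND the
#' colocalization decision is true AND the PheWAS verdict is clean;
#' otherwise the tier names the first stage at which it failed. Writes
#' `report.tsv` and a human-readable `summary.txt`.
#'
#' @inheritParams stage_simulate
#' @return (invisibly) the report data frame
#' @export
stage_report <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  degs <- read_tsv(file.path(out_dir, "degs.tsv"))
  emr <- read_tsv(file.path(out_dir, "mr_eqtl.tsv"))
  pmr <- read_tsv(file.path(out_dir, "mr_pqtl.tsv"))
  col <- read_tsv(file.path(out_dir, "coloc.tsv"))
  verd <- read_tsv(file.path(out_dir, "phewas_verdicts.tsv"))

  genes <- unique(degs$gene[degs$gene %in% emr$gene |
                              degs$gene %in% pmr$gene])
  rows <- lapply(genes, function(g) {
    dg <- degs[degs$gene == g, , drop = FALSE]
    dg <- dg[which.min(dg$padj), , drop = FALSE]
    e <- emr[emr$gene == g, , drop = FALSE]
    p <- pmr[pmr$gene == g, , drop = FALSE]
    cc <- col[col$gene == g, , drop = FALSE]
    v <- verd[verd$gene == g, , drop = FALSE]
    e_sig <- nrow(e) == 1L && e$pval < cfg$mr_significance
    p_sig <- nrow(p) == 1L && p$pval < cfg$mr_significance
    c_pass <- nrow(cc) == 1L && isTRUE(as.logical(cc$pass))
    clean <- nrow(v) == 1L && v$verdict == "clean"
    tier <-
      if (!e_sig) "fails_eqtl_mr"
      else if (nrow(p) == 0L) "no_pqtl_instruments"
      else if (!p_sig) "fails_pqtl_mr"
      else if (!c_pass) "fails_coloc"
      else if (!clean) "fails_phewas"
      else "top"
    data.frame(
      gene = g, cell_type = dg$cell_type, deg_log2fc = dg$log2fc,
      deg_padj = dg$padj,
      eqtl_method = if (nrow(e)) e$method else NA_character_,
      eqtl_nsnp = if (nrow(e)) e$nsnp else NA_integer_,
      eqtl_beta = if (nrow(e)) e$beta else NA_real_,
      eqtl_pval = if (nrow(e)) e$pval else NA_real_,
      pqtl_method = if (nrow(p)) p$method else NA_character_,
      pqtl_nsnp = if (nrow(p)) p$nsnp else NA_integer_,
      pqtl_beta = if (nrow(p)) p$beta else NA_real_,
      pqtl_se = if (nrow(p)) p$se else NA_real_,
      pqtl_pval = if (nrow(p)) p$pval else NA_real_,
      pqtl_or = if (nrow(p)) p$or else NA_real_,
      pqtl_ci_low = if (nrow(p)) p$ci_low else NA_real_,
      pqtl_ci_high = if (nrow(p)) p$ci_high else NA_real_,
      coloc_pp4 = if (nrow(cc)) cc$pp4 else NA_real_,
      coloc_pass = if (nrow(cc)) as.logical(cc$pass) else NA,
      phewas_verdict = if (nrow(v)) v$verdict else NA_character_,
      tier = tier, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  tier_rank <- c(top = 0, fails_phewas = 1, fails_coloc = 2,
                 fails_pqtl_mr = 3, no_pqtl_instruments = 4,
                 fails_eqtl_mr = 5)
  report <- report[order(tier_rank[report$tier], report$pqtl_pval), ,
                   drop = FALSE]
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "report.tsv"))

  lines <- c("Target prioritization report", "============================",
             sprintf("candidates assessed: %d", nrow(report)),
             sprintf("top tier (pQTL MR p < %g, PP4 > %g, PheWAS clean): %s",
                     cfg$mr_significance, cfg$coloc_pp4_threshold,
                     paste(report$gene[report$tier == "top"],
                           collapse = ", ")),
             "")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "%s [%s]: DEG log2FC %.2f (padj %.2g); pQTL MR %s OR %.2f (%.2f-%.2f) p=%.3g; PP4 %s; PheWAS %s -> %s",
      r$gene, r$cell_type, r$deg_log2fc, r$deg_padj,
      r$pqtl_method %||% "-",
      r$pqtl_or, r$pqtl_ci_low, r$pqtl_ci_high, r$pqtl_pval,
      ifelse(is.na(r$coloc_pp4), "-", sprintf("%.3f", r$coloc_pp4)),
      r$phewas_verdict %||% "-", r$tier))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(report)
}

#' Run the full target-discovery cascade
#'
#' Executes the stages in order -- synthetic input generation (when
#' `synthetic` is set), single-cell DEG discovery, eQTL MR, pQTL MR,
#' colocalization, phenome-wide screen, and report assembly -- leaving
#' every intermediate table, the run log and the final report in
#' `out_dir`. Re-running with the same config and seed reproduces all
#' outputs bit-identically.
#'
#' @inheritParams stage_simulate
#' @return the target report data frame
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "run_log.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_used.yaml"))
  if (isTRUE(cfg$synthetic)) stage_simulate(cfg, out_dir)
  stage_sc_deg(cfg, out_dir)
  stage_mr(cfg, out_dir, "eqtl")
  stage_mr(cfg, out_dir, "pqtl")
  stage_coloc(cfg, out_dir)
  stage_phewas(cfg, out_dir)
  stage_report(cfg, out_dir)
}
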