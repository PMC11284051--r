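# Seeded generators for every input the cascade consumes: LD-correlated
# genotype panels, two-trait QTL/GWAS summary statistics under the five
# colocalization hypotheses, independent MR instrument sets, negative-binomial
# single-cell counts with planted cell types / markers / DEGs, and
# multi-trait PheWAS tables. All generators are bit-reproducible given
# (parameters, seed) and return a ground-truth record alongside the data.

NON_PALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Ground-truth record for a simulated dataset
#'
#' Captures what was planted by a generator: the colocalization scenario
#' (H0..H4), the causal variant id(s) per trait, the true causal effect of
#' the exposure on the outcome (log-odds per unit exposure), and any planted
#' differentially expressed genes per cell type.
#'
#' @param scenario one of "H0".."H4" (or NA for generators without a
#'   colocalization scenario)
#' @param causal_variant_ids named list with `trait1` and `trait2` character
#'   vectors of causal variant ids
#' @param causal_effect true causal effect of exposure on outcome
#' @param de_genes named list: cell type -> named numeric vector of true
#'   log2 fold changes
#' @return an object of class `ground_truth`
#' @export
ground_truth <- function(scenario = NA_character_,
                         causal_variant_ids = list(trait1 = character(),
                                                   trait2 = character()),
                         causal_effect = 0,
                         de_genes = list()) {
  if (!is.na(scenario)) {
    if (!scenario %in% paste0("H", 0:4))
      stopf("scenario must be one of H0..H4, got '%s'", scenario)
    t1 <- causal_variant_ids$trait1
    t2 <- causal_variant_ids$trait2
    if (scenario == "H0" && (length(t1) || length(t2)))
      stopf("H0 ground truth must have no causal variants")
    if (scenario == "H4" &&
        !(length(t1) == 1L && identical(t1, t2)))
      stopf("H4 ground truth must share exactly one causal variant")
    if (scenario == "H3" && length(intersect(t1, t2)))
      stopf("H3 ground truth requires distinct causal variants")
  }
  structure(list(scenario = scenario,
                 causal_variant_ids = causal_variant_ids,
                 causal_effect = causal_effect,
                 de_genes = de_genes),
            class = "ground_truth")
}

#' Simulate an LD-correlated genotype panel
#'
#' Haplotypes arise from a first-order autoregressive latent Gaussian process
#' along the chromosome, thresholded to alleles at each variant's minor
#' allele frequency; dosages are the sum of two independent haplotypes, so
#' the correlation between variants decays monotonically with distance at a
#' rate set by `decay`. Positions are laid out on a single synthetic
#' chromosome at fixed 1 kb spacing (1-based), and alleles are drawn from
#' non-palindromic base pairs so downstream harmonization never drops a
#' planted variant as strand-ambiguous.
#'
#' @param n_individuals number of diploid individuals (>= 2)
#' @param n_variants number of variants (>= 1)
#' @param decay adjacent-variant latent correlation, in [0, 1)
#' @param maf_range length-2 interval within (0, 0.5) for minor allele
#'   frequencies
#' @param seed integer seed; the panel is bit-reproducible given it
#' @return an object of class `ld_genotypes`: list with `dosages`
#'   (individuals x variants 0/1/2 matrix), `ld` (variant correlation
#'   matrix), and `variants` (data frame: snp, chr, pos, ea, oa, eaf)
#' @export
simulate_ld_genotypes <- function(n_individuals, n_variants, decay = 0.9,
                                  maf_range = c(0.05, 0.5), seed = 1L) {
  n <- check_count(n_individuals, "n_individuals", min = 2L)
  m <- check_count(n_variants, "n_variants", min = 1L)
  check_number(decay, "decay", lower = 0, upper = 1, strict_upper = TRUE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an interval within (0, 0.5]")
  set.seed(seed)

  maf <- stats::runif(m, maf_range[1], maf_range[2])
  thr <- stats::qnorm(maf)

  sim_haplo <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (decay > 0 && m > 1L) {
      sd_innov <- sqrt(1 - decay^2)
      for (j in 2:m) z[, j] <- decay * z[, j - 1L] + sd_innov * z[, j]
    }
    # allele 1 carries the (minor) effect allele
    sweep(z, 2L, thr, `<`) * 1L
  }
  G <- sim_haplo() + sim_haplo()

  snp <- sprintf("snp%04d", seq_len(m))
  colnames(G) <- snp
  alleles <- NON_PALINDROMIC_PAIRS[
    sample.int(nrow(NON_PALINDROMIC_PAIRS), m, replace = TRUE), , drop = FALSE]
  variants <- data.frame(
    snp = snp, chr = "1", pos = seq_len(m) * 1000L,
    ea = alleles[, 1], oa = alleles[, 2],
    eaf = colMeans(G) / 2,
    stringsAsFactors = FALSE
  )
  sds <- apply(G, 2L, stats::sd)
  if (any(sds == 0))
    warning("monomorphic variants in panel; their LD entries are set to 0")
  ld <- suppressWarnings(stats::cor(G))
  ld[!is.finite(ld)] <- 0
  diag(ld) <- 1
  structure(list(dosages = G, ld = ld, variants = variants),
            class = "ld_genotypes")
}

#' @export
print.ld_genotypes <- function(x, ...) {
  cat(sprintf("LD genotype panel: %d individuals x %d variants (chr %s, 1 kb spacing)\n",
              nrow(x$dosages), ncol(x$dosages), x$variants$chr[1]))
  invisible(x)
}

#' Simulate exposure and outcome summary statistics under a colocalization
#' scenario
#'
#' Realizes one of the five mutually exclusive colocalization hypotheses on a
#' shared genotype panel: H0 (no causal variant in either trait), H1/H2
#' (causal variant in one trait only), H3 (distinct causal variants), H4 (one
#' shared causal variant). The panel is split into disjoint halves so the
#' two traits form a genuine two-sample design; per-variant effects are
#' marginal single-variant regressions -- linear for a quantitative trait,
#' logistic (log-odds scale) for a case-control trait.
#'
#' @param genotypes an `ld_genotypes` panel
#' @param scenario one of "H0".."H4"
#' @param exposure_effect per-allele effect of the exposure's causal variant
#'   on the (quantitative, unit-variance residual) exposure; must be 0 for
#'   H0/H2
#' @param outcome_effect per-allele effect of the outcome's causal variant
#'   (log-odds for case-control); must be 0 for H0/H1
#' @param outcome_type "case_control" or "quantitative"
#' @param seed integer seed
#' @param causal_exposure,causal_outcome optional variant indices; defaults
#'   place the shared/exposure variant mid-panel and, under H3, the outcome
#'   variant a quarter-panel away
#' @param case_fraction expected case fraction for a case-control outcome
#' @return list with `exposure` and `outcome` summary-statistic data frames
#'   (columns snp, chr, pos, ea, oa, eaf, beta, se, pval, n) and `truth`
#'   (a `ground_truth`)
#' @export
simulate_two_trait_sumstats <- function(genotypes, scenario, exposure_effect,
                                        outcome_effect,
                                        outcome_type = c("case_control",
                                                         "quantitative"),
                                        seed = 1L,
                                        causal_exposure = NULL,
                                        causal_outcome = NULL,
                                        case_fraction = 0.4) {
  stopifnot(inherits(genotypes, "ld_genotypes"))
  outcome_type <- match.arg(outcome_type)
  if (!scenario %in% paste0("H", 0:4))
    stopf("scenario must be one of H0..H4")
  exp_has <- scenario %in% c("H1", "H3", "H4")
  out_has <- scenario %in% c("H2", "H3", "H4")
  if (exp_has && exposure_effect == 0)
    stopf("%s requires a nonzero exposure_effect", scenario)
  if (!exp_has && exposure_effect != 0)
    stopf("%s requires exposure_effect = 0", scenario)
  if (out_has && outcome_effect == 0)
    stopf("%s requires a nonzero outcome_effect", scenario)
  if (!out_has && outcome_effect != 0)
    stopf("%s requires outcome_effect = 0", scenario)

  G <- genotypes$dosages
  v <- genotypes$variants
  n <- nrow(G); m <- ncol(G)
  if (n < 4L) stopf("panel too small to split into two samples")

  ce <- causal_exposure %||% (m %/% 2L + 1L)
  co <- causal_outcome %||%
    if (scenario == "H3") max(1L, ce - max(1L, m %/% 4L)) else ce
  if (ce > m || co > m) stopf("causal variant index outside the panel")
  if (scenario == "H3" && ce == co)
    stopf("H3 requires distinct causal variants")
  if (scenario == "H4") co <- ce

  set.seed(seed)
  half <- n %/% 2L
  i1 <- seq_len(half); i2 <- (half + 1L):n
  G1 <- G[i1, , drop = FALSE]; G2 <- G[i2, , drop = FALSE]

  y1 <- stats::rnorm(length(i1))
  if (exp_has) y1 <- y1 + exposure_effect * G1[, ce]
  s1 <- marginal_linear(G1, y1)

  if (out_has) eta <- outcome_effect * (G2[, co] - mean(G2[, co])) else
    eta <- rep(0, length(i2))
  if (outcome_type == "case_control") {
    eta <- eta + stats::qlogis(case_fraction)
    y2 <- stats::rbinom(length(i2), 1L, stats::plogis(eta))
    s2 <- marginal_logistic(G2, y2)
  } else {
    y2 <- eta + stats::rnorm(length(i2))
    s2 <- marginal_linear(G2, y2)
  }

  mk <- function(idx, s, Gh) data.frame(
    snp = v$snp, chr = v$chr, pos = v$pos, ea = v$ea, oa = v$oa,
    eaf = colMeans(Gh) / 2, beta = s$beta, se = s$se, pval = s$pval,
    n = length(idx), stringsAsFactors = FALSE)

  truth <- ground_truth(
    scenario = scenario,
    causal_variant_ids = list(
      trait1 = if (exp_has) v$snp[ce] else character(),
      trait2 = if (out_has) v$snp[co] else character()),
    causal_effect = if (scenario == "H4") outcome_effect / exposure_effect
                    else 0)
  list(exposure = mk(i1, s1, G1), outcome = mk(i2, s2, G2), truth = truth)
}

#' Simulate a harmonized instrument set with known causal effect
#'
#' A test bed for the MR estimators: mutually independent variants with true
#' exposure effects drawn away from zero, noisy observed exposure betas, and
#' outcome betas equal to `causal_beta` times the true exposure effect plus
#' an optional pleiotropic shift plus sampling noise at the stated standard
#' errors. `pleiotropy_sd = 0` (and `pleiotropy_mean = 0`) is the
#' valid-instrument setting.
#'
#' @param n_instruments number of independent instruments (>= 1)
#' @param causal_beta true causal effect of exposure on outcome
#' @param pleiotropy_sd SD of per-instrument pleiotropic effects (>= 0)
#' @param exposure_n,outcome_n sample sizes governing the standard errors
#'   (per-allele SE for a unit-variance trait, 1/sqrt(2 f (1-f) n))
#' @param seed integer seed
#' @param pleiotropy_mean mean pleiotropic shift (directional pleiotropy)
#' @param exposure_beta_range magnitude range for true exposure effects
#' @return list with `instruments` (a harmonized instrument data frame) and
#'   `truth`
#' @export
simulate_mr_instruments <- function(n_instruments, causal_beta,
                                    pleiotropy_sd = 0,
                                    exposure_n = 20000, outcome_n = 20000,
                                    seed = 1L, pleiotropy_mean = 0,
                                    exposure_beta_range = c(0.1, 0.3)) {
  k <- check_count(n_instruments, "n_instruments", min = 1L)
  check_number(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_count(exposure_n, "exposure_n", min = 2L)
  check_count(outcome_n, "outcome_n", min = 2L)
  set.seed(seed)
  maf <- stats::runif(k, 0.1, 0.5)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * exposure_n)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * outcome_n)
  bx_true <- sample(c(-1, 1), k, replace = TRUE) *
    stats::runif(k, exposure_beta_range[1], exposure_beta_range[2])
  bx <- bx_true + stats::rnorm(k, 0, se_x)
  alpha <- stats::rnorm(k, pleiotropy_mean, pleiotropy_sd)
  by <- causal_beta * bx_true + alpha + stats::rnorm(k, 0, se_y)
  inst <- data.frame(
    snp = sprintf("iv%03d", seq_len(k)),
    beta_exposure = bx, se_exposure = se_x,
    beta_outcome = by, se_outcome = se_y,
    eaf = maf, flipped = FALSE, stringsAsFactors = FALSE)
  truth <- ground_truth(causal_effect = causal_beta)
  truth$pleiotropy <- alpha
  list(instruments = inst, truth = truth)
}

#' Simulate a cell-by-gene count matrix with planted structure
#'
#' Negative-binomial counts with cell-type-specific mean profiles: marker
#' genes are elevated in their own type, differentially expressed genes are
#' shifted between case and control within their type by a stated log2 fold
#' change, and a configurable fraction of cells is made low quality (fewer
#' than `lowq_detected` detected genes, or a mitochondrial count share above
#' 10%) so the QC stage has real work to do. Cells are split evenly between
#' the case and control conditions and across donors within condition.
#'
#' Gene ids are `G0001`, `G0002`, ... followed by
#' `round(mito_gene_fraction * n_genes)` mitochondrial ids `MT-1`, `MT-2`,
#' ... (n_genes ids in total); marker and DE specifications must reference
#' these ids.
#'
#' @param cells_per_type named integer vector: cell type -> number of cells
#'   (>= 2 types)
#' @param n_genes total number of genes
#' @param markers named list: cell type -> character vector of marker gene
#'   ids (elevated `marker_boost`-fold in that type)
#' @param de_genes named list: cell type -> named numeric vector of log2
#'   fold changes (case vs control) planted within that type
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi mu^2)
#' @param mito_gene_fraction fraction of genes that are mitochondrial
#' @param lowq_cell_fraction fraction of cells rendered low quality
#' @param seed integer seed
#' @param donors_per_condition donors per condition (>= 2); cells are
#'   assigned round-robin within condition
#' @param target_library_size expected total counts per healthy cell
#' @param marker_boost fold elevation of a marker gene in its own type
#' @param type_profile_sd SD (log scale) of the per-type lognormal
#'   perturbation of the shared baseline profile; controls how separable
#'   the planted cell types are
#' @param de_base_boost baseline-expression multiplier applied (in both
#'   conditions) to planted DE genes, so their fold change is identifiable
#'   at single-cell sequencing depth
#' @return list with `matrix` (a `cell_matrix`) and `truth` (a
#'   `ground_truth` whose `de_genes` records the plant; `truth$cell_type`
#'   and `truth$lowq` give per-cell labels)
#' @export
simulate_sc_counts <- function(cells_per_type, n_genes,
                               markers = list(), de_genes = list(),
                               nb_dispersion = 0.5,
                               mito_gene_fraction = 0.05,
                               lowq_cell_fraction = 0.05,
                               seed = 1L,
                               donors_per_condition = 5L,
                               target_library_size = 2500,
                               marker_boost = 6,
                               type_profile_sd = 0.6,
                               de_base_boost = 3) {
  if (length(cells_per_type) < 2L || is.null(names(cells_per_type)))
    stopf("cells_per_type must be a named vector with >= 2 cell types")
  ng <- check_count(n_genes, "n_genes", min = 10L)
  check_number(nb_dispersion, "nb_dispersion", lower = 0, strict_lower = TRUE)
  check_number(mito_gene_fraction, "mito_gene_fraction", lower = 0, upper = 0.5)
  check_number(lowq_cell_fraction, "lowq_cell_fraction", lower = 0, upper = 1)
  dpc <- check_count(donors_per_condition, "donors_per_condition", min = 2L)

  n_mito <- round(mito_gene_fraction * ng)
  gene_ids <- c(sprintf("G%04d", seq_len(ng - n_mito)),
                if (n_mito > 0L) sprintf("MT-%d", seq_len(n_mito)))
  mito <- startsWith(gene_ids, "MT-")

  types <- names(cells_per_type)
  for (ty in names(markers))
    if (!ty %in% types) stopf("marker set for unknown cell type '%s'", ty)
  for (ty in names(de_genes)) {
    if (!ty %in% types) stopf("DE spec for unknown cell type '%s'", ty)
    bad <- setdiff(names(de_genes[[ty]]), gene_ids)
    if (length(bad))
      stopf("DE gene(s) not in gene list: %s", paste(bad, collapse = ", "))
  }
  for (ty in names(markers)) {
    bad <- setdiff(markers[[ty]], gene_ids)
    if (length(bad))
      stopf("marker gene(s) not in gene list: %s", paste(bad, collapse = ", "))
  }

  set.seed(seed)
  # baseline relative expression, shared across types
  base_w <- stats::rgamma(ng, shape = 0.8, rate = 1) + 0.02
  # mitochondrial genes get a healthy ~5% share of the library
  if (n_mito > 0L)
    base_w[mito] <- sum(base_w[!mito]) * 0.05 / n_mito
  de_ids <- unique(unlist(lapply(de_genes, names)))
  if (length(de_ids))
    base_w[match(de_ids, gene_ids)] <- base_w[match(de_ids, gene_ids)] *
      de_base_boost

  type_profiles <- lapply(types, function(ty) {
    # each type has its own expression program on top of the shared baseline
    w <- base_w * stats::rlnorm(ng, 0, type_profile_sd)
    # pin the mitochondrial share back to its healthy level per type
    if (n_mito > 0L)
      w[mito] <- sum(w[!mito]) * 0.05 / n_mito
    mk <- markers[[ty]]
    if (length(mk)) w[match(mk, gene_ids)] <- w[match(mk, gene_ids)] * marker_boost
    # suppress other types' markers in this type
    other_mk <- setdiff(unlist(markers[setdiff(names(markers), ty)]), mk)
    if (length(other_mk))
      w[match(other_mk, gene_ids)] <- w[match(other_mk, gene_ids)] * 0.1
    w
  })
  names(type_profiles) <- types

  n_cells <- sum(cells_per_type)
  cell_type <- rep(types, cells_per_type)
  # alternate conditions within each type so both are always represented
  condition <- unlist(lapply(cells_per_type, function(k)
    rep_len(c("case", "control"), k)), use.names = FALSE)
  donor_idx <- stats::ave(seq_len(n_cells), condition,
                          FUN = function(i) rep_len(seq_len(dpc), length(i)))
  donor <- paste0(ifelse(condition == "case", "MS", "CTRL"), donor_idx)

  size <- 1 / nb_dispersion
  lib <- stats::rlnorm(n_cells, log(target_library_size), 0.2)

  n_lowq <- round(lowq_cell_fraction * n_cells)
  lowq <- rep(FALSE, n_cells)
  if (n_lowq > 0L) {
    pick <- sample.int(n_cells, n_lowq)
    lowq[pick] <- TRUE
  }
  lowq_kind <- ifelse(lowq, rep_len(c("few_genes", "high_mito"), n_cells), "none")

  counts <- matrix(0L, nrow = ng, ncol = n_cells)
  for (i in seq_len(n_cells)) {
    w <- type_profiles[[cell_type[i]]]
    de <- de_genes[[cell_type[i]]]
    if (length(de) && condition[i] == "case") {
      j <- match(names(de), gene_ids)
      w[j] <- w[j] * 2^de
    }
    li <- lib[i]
    if (lowq[i] && lowq_kind[i] == "few_genes") li <- li * 0.08
    if (lowq[i] && lowq_kind[i] == "high_mito" && n_mito > 0L)
      w[mito] <- sum(w[!mito]) * 0.35 / n_mito
    mu <- li * w / sum(w)
    counts[, i] <- stats::rnbinom(ng, size = size, mu = mu)
  }

  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  mat <- cell_matrix(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    gene_ids = gene_ids, cell_ids = cell_ids,
    cell_meta = data.frame(cell = cell_ids, donor = donor,
                           condition = condition, stringsAsFactors = FALSE),
    mito_genes = mito)

  truth <- ground_truth(de_genes = de_genes)
  truth$cell_type <- stats::setNames(cell_type, cell_ids)
  truth$lowq <- stats::setNames(lowq, cell_ids)
  truth$markers <- markers
  list(matrix = mat, truth = truth)
}

#' Simulate a phenome-wide association table for one gene
#'
#' Background traits receive p-values drawn uniformly on
#' `(background_p_floor, 1)`; planted associations are inserted verbatim.
#'
#' @param gene gene id the table screens
#' @param n_traits number of background traits
#' @param planted named numeric vector: trait name -> exact p-value to plant
#' @param background_p_floor lower bound of the background p-value draw
#' @param seed integer seed
#' @return data frame with columns gene, trait, trait_class, pval, effect
#' @export
simulate_phewas_table <- function(gene, n_traits, planted = NULL,
                                  background_p_floor = 1e-6, seed = 1L) {
  nt <- check_count(n_traits, "n_traits", min = 0L)
  check_number(background_p_floor, "background_p_floor",
               lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.null(planted)) {
    if (is.null(names(planted)) || !is.numeric(planted))
      stopf("planted must be a named numeric vector of p-values")
    if (any(planted <= 0))
      stopf("planted p-values must be > 0")
  }
  set.seed(seed)
  traits <- sprintf("trait_%04d", seq_len(nt))
  pv <- stats::runif(nt, background_p_floor, 1)
  cls <- sample(c("binary", "quantitative"), nt, replace = TRUE,
                prob = c(0.92, 0.08))
  tab <- data.frame(gene = gene, trait = traits, trait_class = cls,
                    pval = pv, effect = stats::rnorm(nt, 0, 0.05),
                    stringsAsFactors = FALSE)
  if (length(planted)) {
    tab <- rbind(tab, data.frame(
      gene = gene, trait = names(planted), trait_class = "binary",
      pval = unname(planted), effect = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  tab
}
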