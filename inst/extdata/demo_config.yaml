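# Bundled demo configuration for the synthetic end-to-end run.
# All values equal the package defaults; they are spelled out here so a run
# is fully described by its config file.

seed: 1
synthetic: true

# single-cell QC / normalization / clustering
qc_min_cells_per_gene: 3
qc_min_genes_per_cell: 250
qc_max_mito_fraction: 0.10
norm_scale_factor: 10000
n_hvg: 2000
pca_components: 31
cluster_neighbors: 20
cluster_resolution: 1.0
annotate_min_margin: 0.05

# marker discovery and case-vs-control DEG thresholds
marker_min_abs_log2fc: 0.25
marker_min_pct: 0.25
deg_min_abs_log2fc: 0.3
deg_min_pct: 0.25
deg_max_padj: 0.05

# instrument selection and LD clumping, per QTL class
eqtl_p_threshold: 5.0e-8
eqtl_r2_threshold: 0.001
pqtl_p_threshold: 5.0e-8
pqtl_r2_threshold: 0.01
clump_window_kb: 10000
palindromic_eaf_limit: 0.42

# Mendelian randomization
mr_significance: 0.05
mr_n_boot: 1000

# colocalization
coloc_p1: 1.0e-4
coloc_p2: 1.0e-4
coloc_p12: 1.0e-5
coloc_flank_kb: 500
coloc_pp4_threshold: 0.8

# phenome-wide screen
phewas_alpha: 2.0e-8
disease_trait: "multiple sclerosis"
require_eqtl_support: true

# synthetic demo scenario
sc_cells_per_type: 150
sc_n_genes: 600
sc_nb_dispersion: 0.4
sc_mito_gene_fraction: 0.05
sc_lowq_cell_fraction: 0.06
sc_donors_per_condition: 5
qtl_n_individuals: 10000
qtl_n_variants: 200
ld_decay: 0.95
qtl_maf_range: [0.2, 0.5]
qtl_effect: 0.6
outcome_effect: -0.35
case_fraction: 0.4
phewas_n_traits: 500
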