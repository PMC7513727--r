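#' Configuration for the synthetic two-ecotype dataset generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' study conditions of a two-ecotype rice landrace panel: 40 upland and
#' 50 lowland genotypes, a 2,000-gene panel, a minority of highly
#' differentiated genes, a subset of genes under directional expression
#' selection organised into four co-expression modules, drought-responsive
#' genes, promoter SNPs that create/destroy planted cis-element motifs,
#' and traits built from module latent factors with an RWC/NT trade-off.
#'
#' Allele frequencies follow a Balding-Nichols model within ecotype.
#' The F parameters are calibrated so the *realized* estimates match
#' typical two-ecotype panels: `fst_intergenic = 0.11` yields a mean
#' per-SNP neutral Hudson F_ST of ~0.093 (the mean-of-ratios estimator
#' sits slightly below the model F), `fst_genic = 0.2` yields a
#' per-gene genomic mean of ~0.26 once the planted highly
#' differentiated, sweep and TDSG classes are mixed in, and
#' `fst_tdsg = 0.4` couples transcriptionally selected genes to
#' elevated sequence differentiation (realized mean ~0.41). Planted HDGs get ecotype frequencies near
#' `hdg_p_upland` / `hdg_p_lowland` (differential 0.8).
#'
#' @param seed integer; fixes all outputs bit-for-bit.
#' @param n_upland,n_lowland samples per ecotype (>= 2 each).
#' @param n_genes number of genes in the panel.
#' @param n_intergenic_snps SNPs in intergenic space (neutral F_ST baseline).
#' @param snps_per_gene SNPs per gene region (3 land in the upstream 2 kb).
#' @param frac_hdg fraction of genes planted as highly differentiated.
#' @param frac_tdsg fraction planted under directional expression selection.
#' @param frac_drg fraction planted drought-responsive.
#' @param frac_motif_altering fraction of genes given a planted
#'   cis-element-altering promoter SNP.
#' @param frac_sweep fraction planted as selective-sweep genes, per ecotype
#'   (within-ecotype diversity deflated ~10x).
#' @param effect_tdsg between-ecotype mean shift of planted TDSGs, in units
#'   of their within-ecotype SD (log2 scale).
#' @param drought_log2fc planted log2 fold change of DRGs under drought.
#' @param trait_noise_sd residual SD of simulated traits (standardised scale).
#' @param tradeoff_strength real in [-1, 1]; scales both the opposing
#'   RWC-DT / NT-CK factor loadings of the designated trade-off gene set and
#'   the (negative) ecotype offset of tiller number. 0 disables the planted
#'   trade-off entirely.
#' @param n_modules number of planted co-expression modules among
#'   drought-responsive TDSGs.
#' @param frac_tdsg_drought fraction of planted TDSGs that are also
#'   drought-responsive (these carry the module structure).
#' @param frac_cis_in_tdsg fraction of motif-altering genes drawn from the
#'   planted TDSG set (couples cis variation to transcriptional selection).
#' @param module_cor target within-module expression correlation.
#' @param tdsg_noise_sd residual within-ecotype SD of planted TDSGs
#'   (log2 scale), before the module factor.
#' @param noise_meanlog,noise_sdlog log-normal parameters of per-gene
#'   within-ecotype SD for unselected genes (log2 expression scale).
#' @param genotype_noise_frac fraction of each gene's residual variance
#'   that is genotype-intrinsic and therefore shared between the CK and
#'   DT measurements of the same genotype (the rest is
#'   condition-specific residual noise).
#' @param origin_effect_sd SD of the random origin (geographic) effect.
#' @param n_origins_per_ecotype origin levels nested within each ecotype.
#' @param neutral_expr_drift_sd SD of a random between-ecotype expression
#'   offset on unselected genes, in units of each gene's within-ecotype SD.
#'   0 (default) = stabilising baseline; set to the drift-matched value to
#'   emulate neutrally drifting expression.
#' @param fst_intergenic,fst_genic,fst_tdsg Balding-Nichols F for
#'   intergenic SNPs, neutral genic SNPs and planted-TDSG genes.
#' @param hdg_p_upland,hdg_p_lowland mean ecotype allele frequencies at
#'   planted HDG SNPs.
#' @param sweep_deflation factor by which sweep genes' within-ecotype
#'   allele frequencies are pushed toward fixation (~10x diversity loss).
#' @param gene_body_length,gene_spacing,flank gene model geometry in bp;
#'   each gene region is upstream `flank` + body + downstream `flank`.
#' @param baseline_meanlog2,baseline_sdlog2 per-gene baseline mean
#'   log2(FPKM + 1) distribution.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_upland = 40L, n_lowland = 50L,
                       n_genes = 2000L,
                       n_intergenic_snps = 2000L,
                       snps_per_gene = 10L,
                       frac_hdg = 0.05,
                       frac_tdsg = 0.2,
                       frac_drg = 0.25,
                       frac_motif_altering = 0.2,
                       frac_sweep = 0.04,
                       effect_tdsg = 2.8,
                       drought_log2fc = 2,
                       trait_noise_sd = 0.5,
                       tradeoff_strength = 0.8,
                       n_modules = 4L,
                       frac_tdsg_drought = 0.6,
                       frac_cis_in_tdsg = 0.5,
                       module_cor = 0.8,
                       tdsg_noise_sd = 0.2,
                       noise_meanlog = log(0.5),
                       noise_sdlog = 0.35,
                       genotype_noise_frac = 0.7,
                       origin_effect_sd = 0.02,
                       n_origins_per_ecotype = 4L,
                       neutral_expr_drift_sd = 0,
                       fst_intergenic = 0.11,
                       fst_genic = 0.2,
                       fst_tdsg = 0.4,
                       hdg_p_upland = 0.9,
                       hdg_p_lowland = 0.1,
                       sweep_deflation = 10,
                       gene_body_length = 2000L,
                       gene_spacing = 10000L,
                       flank = 2000L,
                       baseline_meanlog2 = 5,
                       baseline_sdlog2 = 1.5) {
  for (nm in c("frac_hdg", "frac_tdsg", "frac_drg", "frac_motif_altering",
               "frac_sweep", "frac_tdsg_drought", "frac_cis_in_tdsg",
               "module_cor")) {
    check_fraction(get(nm), nm)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  if (n_upland < 2 || n_lowland < 2)
    stop("need at least 2 samples per ecotype")
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (snps_per_gene < 4)
    stop("'snps_per_gene' must be >= 4 (3 upstream + >=1 in the gene body)")
  if (abs(tradeoff_strength) > 1)
    stop("'tradeoff_strength' must lie in [-1, 1]")
  check_fraction(genotype_noise_frac, "genotype_noise_frac")
  if (gene_spacing < gene_body_length + 2L * flank + 1000L)
    stop("'gene_spacing' too small for gene regions plus intergenic space")
  cfg <- mget(names(formals(sim_config)))
  for (nm in c("seed", "n_upland", "n_lowland", "n_genes", "n_intergenic_snps",
               "snps_per_gene", "n_modules", "n_origins_per_ecotype",
               "gene_body_length", "gene_spacing", "flank"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_upland, "upland +", x$n_lowland, "lowland samples,",
      x$n_genes, "genes,", x$snps_per_gene, "SNPs/gene,",
      x$n_intergenic_snps, "intergenic SNPs\n")
  cat("  planted fractions: hdg", x$frac_hdg, "| tdsg", x$frac_tdsg,
      "| drg", x$frac_drg, "| motif", x$frac_motif_altering,
      "| sweep", x$frac_sweep, "\n")
  cat("  effects: tdsg", x$effect_tdsg, "SD | drought log2FC",
      x$drought_log2fc, "| tradeoff", x$tradeoff_strength,
      "| seed", x$seed, "\n")
  invisible(x)
}
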