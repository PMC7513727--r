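#' Generate a complete synthetic dataset
#'
#' Runs the genotype, promoter/motif, expression and trait generators
#' in order and assembles the full bundle with its ground truth. All
#' outputs are fixed bit-for-bit by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `geno`, `sites`, `regions`,
#'   `meta`, `promoters`, `motifs`, `promoter_snps`, `expr_ck`,
#'   `expr_dt`, `traits`, `truth` (gene-level flags), `truth_snps`
#'   (planted motif gain/loss records), `genome_length`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  g <- simulate_genotypes(cfg)
  pr <- simulate_promoters(cfg, g)
  ex <- simulate_expression(cfg, g$truth)
  tr <- simulate_traits(cfg, ex$ck, ex$dt, ex$meta, g$truth)
  structure(list(
    geno = g$geno, sites = pr$sites, regions = g$regions, meta = g$meta,
    promoters = pr$promoters, motifs = pr$motifs,
    promoter_snps = pr$promoter_snps,
    expr_ck = ex$ck, expr_dt = ex$dt,
    traits = tr, truth = g$truth, truth_snps = pr$snp_truth,
    tdsg_sign = ex$tdsg_sign, drought_sign = ex$drought_sign,
    genome_length = g$genome_length, cfg = cfg
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$geno), "SNPs x", ncol(x$geno), "samples;",
      nrow(x$regions), "genes;",
      sum(x$truth$planted_tdsg), "planted TDSGs;",
      sum(x$truth$planted_hdg), "planted HDGs\n")
  invisible(x)
}

#' Write a synthetic dataset to interchange files
#'
#' VCF 4.2 (genotypes), GFF3 (gene models), FASTA (promoters) and TSVs
#' (motifs, expression, metadata, traits, ground truth) under `dir`.
#'
#' @param data a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vcf(data$geno, data$sites, p("genotypes.vcf"))
  write_gff3(data$regions, p("genes.gff3"))
  write_fasta(data$promoters, p("promoters.fa"))
  write_tsv(data$motifs, p("motifs.tsv"))
  write_expression(data$expr_ck, p("expression_ck.tsv"))
  write_expression(data$expr_dt, p("expression_dt.tsv"))
  write_tsv(data$meta, p("metadata.tsv"))
  write_tsv(data$traits, p("traits.tsv"))
  write_tsv(data$truth, p("truth_genes.tsv"))
  if (!is.null(data$truth_snps))
    write_tsv(data$truth_snps, p("truth_snps.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Rebuilds the analysis bundle from the interchange files; gene/zone
#' assignment of SNPs is recomputed from the annotation.
#'
#' @param dir dataset directory.
#' @param flank flank size used for the gene regions (default 2000).
#' @return list shaped like a `sim_dataset` (without ground truth
#'   unless the truth TSVs are present).
#' @export
read_dataset <- function(dir, flank = 2000L) {
  p <- function(f) file.path(dir, f)
  vcf <- read_vcf(p("genotypes.vcf"))
  regions <- read_annotation(p("genes.gff3"), flank = flank)
  sites <- assign_snps_to_regions(vcf$sites, regions)
  out <- list(
    geno = vcf$geno, sites = sites, regions = regions,
    meta = read_tsv(p("metadata.tsv")),
    promoters = read_fasta(p("promoters.fa")),
    motifs = read_motif_library(p("motifs.tsv")),
    expr_ck = read_expression(p("expression_ck.tsv")),
    expr_dt = read_expression(p("expression_dt.tsv")),
    traits = read_tsv(p("traits.tsv"))
  )
  out$promoter_snps <- promoter_snp_table(out$sites, regions, flank)
  if (file.exists(p("truth_genes.tsv")))
    out$truth <- read_tsv(p("truth_genes.tsv"))
  if (file.exists(p("truth_snps.tsv")))
    out$truth_snps <- read_tsv(p("truth_snps.tsv"))
  out$genome_length <- max(regions$end) + flank
  out
}
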