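## Per-site allele bookkeeping ----------------------------------------
##
## Diploid genotypes coded 0/1/2 (alt-allele dosage) are treated as 2n
## sampled alleles per site; missing genotypes (NA) are dropped per
## site. All statistics are per-site averages over a region's length.

## internal: per-site alt-allele frequency and allele count for a
## subset of samples
site_freq <- function(geno, samples) {
  g <- geno[, samples, drop = FALSE]
  n_al <- 2L * rowSums(!is.na(g))
  cnt <- rowSums(g, na.rm = TRUE)
  list(p = ifelse(n_al > 0, cnt / n_al, NA_real_), n = n_al)
}

## internal: per-site unbiased heterozygosity 2*p*q*n/(n-1) (the mean
## pairwise difference among the n sampled alleles at the site)
site_pi <- function(p, n) {
  ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
}

#' Nucleotide diversity of a genotype block
#'
#' Average pairwise per-site difference within a group across the
#' region's SNPs (monomorphic positions contribute zero), i.e.
#' `sum(2*p*q*n/(n-1)) / L` over sites, the unbiased frequency form of
#' pi, with `n` the number of sampled alleles and `L` the region length
#' in bp.
#'
#' @param geno integer site x sample matrix (0/1/2, NA = missing),
#'   restricted to the region's SNPs.
#' @param samples column names or indices of the group.
#' @param length region length in bp (per-site denominator).
#' @return per-site nucleotide diversity (numeric scalar).
#' @export
nucleotide_diversity <- function(geno, samples, length) {
  if (base::length(samples) == 0) stop("empty group: pi undefined")
  f <- site_freq(geno, samples)
  if (all(f$n < 2)) stop("fewer than 2 sampled alleles: pi undefined")
  sum(site_pi(f$p, f$n), na.rm = TRUE) / length
}

#' Between-group divergence D_xy
#'
#' Mean per-site difference over all between-group allele pairs,
#' divided by the region length: `sum(p1*(1-p2) + p2*(1-p1)) / L`.
#'
#' @inheritParams nucleotide_diversity
#' @param group_a,group_b sample subsets for the two groups.
#' @return per-site D_xy (numeric scalar).
#' @export
dxy <- function(geno, group_a, group_b, length) {
  fa <- site_freq(geno, group_a)
  fb <- site_freq(geno, group_b)
  sum(fa$p * (1 - fb$p) + fb$p * (1 - fa$p), na.rm = TRUE) / length
}

#' Hudson-type F_ST for a region (ratio of sums)
#'
#' `F_ST = 1 - sum(Hw) / sum(Hb)` aggregated over the region's SNPs,
#' where per site `Hw` is the average of the two within-group unbiased
#' heterozygosities and `Hb = p1*(1-p2) + p2*(1-p1)`. Ratio-of-sums
#' averaging; negative estimates clamped to 0, bounded above by 1.
#' Regions with no between-group heterozygosity are flagged missing
#' (`NA`) and are excluded from downstream quantiles.
#'
#' @inheritParams dxy
#' @return F_ST in [0, 1], or NA when undefined.
#' @export
hudson_fst <- function(geno, group_a, group_b) {
  fa <- site_freq(geno, group_a)
  fb <- site_freq(geno, group_b)
  hw <- (site_pi(fa$p, fa$n) + site_pi(fb$p, fb$n)) / 2
  hb <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  ok <- !is.na(hw) & !is.na(hb)
  if (!any(ok) || sum(hb[ok]) <= 0) return(NA_real_)
  min(max(1 - sum(hw[ok]) / sum(hb[ok]), 0), 1)
}

#' Neutral F_ST from intergenic SNPs
#'
#' Mean per-SNP Hudson F_ST over intergenic SNPs (each SNP's negative
#' estimate clamped to 0), with a bootstrap standard error over SNPs.
#'
#' @param geno genotype matrix restricted to intergenic SNPs.
#' @param group_a,group_b sample subsets for the two ecotypes.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with `mean`, `se`, `n_snps`, and the per-SNP values.
#' @export
neutral_fst <- function(geno, group_a, group_b, n_boot = 1000L, seed = 1L) {
  fa <- site_freq(geno, group_a)
  fb <- site_freq(geno, group_b)
  hw <- (site_pi(fa$p, fa$n) + site_pi(fb$p, fb$n)) / 2
  hb <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  ok <- !is.na(hw) & !is.na(hb) & hb > 0
  fst <- pmin(pmax(1 - hw[ok] / hb[ok], 0), 1)
  m <- length(fst)
  if (m == 0) stop("no polymorphic intergenic SNPs")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(fst[sample.int(m, m, replace = TRUE)]), numeric(1))
  list(mean = mean(fst), se = stats::sd(boot), n_snps = m, per_snp = fst)
}

#' Per-gene diversity/divergence scan
#'
#' Computes pi (upland, lowland, total), D_xy, Hudson F_ST and the
#' pi/D_xy ratios for every gene region (upstream flank + gene body +
#' downstream flank).
#'
#' @param geno full genotype matrix.
#' @param sites SNP table with `snp_id` and `gene_id` columns.
#' @param regions gene-model table with `gene_id` and `length`.
#' @param meta sample metadata with `sample` and `ecotype`.
#' @return data.frame (class `popgen_result`), one row per gene.
#' @export
popgen_scan <- function(geno, sites, regions, meta) {
  up <- meta$sample[meta$ecotype == "upland"]
  low <- meta$sample[meta$ecotype == "lowland"]
  f_up <- site_freq(geno, up)
  f_low <- site_freq(geno, low)
  f_tot <- site_freq(geno, meta$sample)
  pi_up_s <- site_pi(f_up$p, f_up$n)
  pi_low_s <- site_pi(f_low$p, f_low$n)
  pi_tot_s <- site_pi(f_tot$p, f_tot$n)
  hb_s <- f_up$p * (1 - f_low$p) + f_low$p * (1 - f_up$p)
  hw_s <- (pi_up_s + pi_low_s) / 2

  idx <- match(sites$gene_id, regions$gene_id)
  keep <- !is.na(idx)
  agg <- function(x) {
    v <- rep(0, nrow(regions))
    s <- tapply(x[keep], idx[keep], sum, na.rm = TRUE)
    v[as.integer(names(s))] <- s
    v
  }
  L <- regions$length
  sum_hw <- agg(hw_s); sum_hb <- agg(hb_s)
  fst <- ifelse(sum_hb > 0, pmin(pmax(1 - sum_hw / sum_hb, 0), 1), NA_real_)
  d <- agg(hb_s) / L
  out <- data.frame(
    gene_id = regions$gene_id,
    pi_upland = agg(pi_up_s) / L,
    pi_lowland = agg(pi_low_s) / L,
    pi_total = agg(pi_tot_s) / L,
    dxy = d,
    fst = fst,
    stringsAsFactors = FALSE
  )
  out$ratio_upland <- ifelse(out$dxy > 0, out$pi_upland / out$dxy, NA_real_)
  out$ratio_lowland <- ifelse(out$dxy > 0, out$pi_lowland / out$dxy, NA_real_)
  class(out) <- c("popgen_result", "data.frame")
  out
}

#' Call highly differentiated genes (HDGs)
#'
#' Threshold = empirical 95th percentile of the per-gene F_ST
#' distribution (genes with missing F_ST excluded); genes strictly above
#' the threshold are flagged.
#'
#' @param fst numeric vector of per-gene F_ST (NAs allowed).
#' @param probs quantile level (default 0.95).
#' @return list with logical `flag`, numeric `threshold`.
#' @export
call_hdg <- function(fst, probs = 0.95) {
  ok <- !is.na(fst)
  if (!any(ok)) stop("no defined F_ST values")
  thr <- stats::quantile(fst[ok], probs, names = FALSE)
  list(flag = !is.na(fst) & fst > thr, threshold = thr)
}

#' Directional-selection scan on the pi/D_xy ratio
#'
#' Genes whose within-ecotype polymorphism / between-ecotype divergence
#' ratio falls in the lowest 5% tail are flagged as under recent
#' directional selection in that ecotype. Genes with `dxy == 0`
#' (undefined ratio) are excluded from the ranking; exactly
#' `floor(tail * n_included)` genes are flagged, ties at the boundary
#' broken by gene-id order.
#'
#' @param ratio per-gene pi/D_xy values (NA = excluded).
#' @param gene_id gene identifiers (tie-break order).
#' @param tail tail fraction (default 0.05).
#' @return list with logical `flag`, the number excluded, and the
#'   realised ratio cutoff.
#' @export
pi_dxy_scan <- function(ratio, gene_id, tail = 0.05) {
  stopifnot(length(ratio) == length(gene_id))
  ok <- which(!is.na(ratio))
  k <- floor(tail * length(ok))
  flag <- logical(length(ratio))
  cutoff <- NA_real_
  if (k > 0) {
    ord <- ok[order(ratio[ok], gene_id[ok])]
    sel <- ord[seq_len(k)]
    flag[sel] <- TRUE
    cutoff <- ratio[ord[k]]
  }
  list(flag = flag, n_excluded = sum(is.na(ratio)), cutoff = cutoff)
}

#' Kolmogorov-Smirnov uniformity test of flagged-gene positions
#'
#' One-sample KS test of the genomic positions of a flag set against
#' the uniform distribution over the genome, asking whether gene
#' density is even across large (default 5,000 kb) windows.
#'
#' @param positions genomic positions (bp) of flagged genes.
#' @param genome_length total genome length in bp.
#' @param window window size in bp (reported binning context only; the
#'   test itself is on positions).
#' @return `htest` object from [stats::ks.test()].
#' @export
density_uniformity_test <- function(positions, genome_length, window = 5e6) {
  if (length(positions) == 0) stop("empty flag set")
  stopifnot(all(positions >= 0), all(positions <= genome_length))
  res <- suppressWarnings(
    stats::ks.test(positions, "punif", 0, genome_length))
  attr(res, "windows") <- ceiling(genome_length / window)
  res
}
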