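#' Sample metadata for a simulated panel
#'
#' Sample identifiers, ecotype, geographic origin (nested within ecotype,
#' `n_origins_per_ecotype` levels each) and the typical flag. The panel
#' emulates the *typical* genotypes of a two-ecotype landrace collection,
#' so all samples are flagged typical.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns sample, ecotype, origin, typical.
#' @export
sim_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- c(sprintf("U%02d", seq_len(cfg$n_upland)),
           sprintf("L%02d", seq_len(cfg$n_lowland)))
  eco <- rep(c("upland", "lowland"), c(cfg$n_upland, cfg$n_lowland))
  origin <- c(
    sprintf("U-or%d", 1L + (seq_len(cfg$n_upland) - 1L) %% cfg$n_origins_per_ecotype),
    sprintf("L-or%d", 1L + (seq_len(cfg$n_lowland) - 1L) %% cfg$n_origins_per_ecotype)
  )
  data.frame(sample = ids, ecotype = eco, origin = origin,
             typical = TRUE, stringsAsFactors = FALSE)
}

## internal: gene model geometry on one synthetic chromosome.
## Gene i occupies slot [(i-1)*spacing + 1, i*spacing]; the region
## (upstream flank + body + downstream flank) sits at the slot start,
## the remainder of the slot is intergenic space.
sim_regions <- function(cfg) {
  i <- seq_len(cfg$n_genes)
  slot0 <- (i - 1L) * cfg$gene_spacing
  region_len <- 2L * cfg$flank + cfg$gene_body_length
  start <- slot0 + 1L
  end <- slot0 + region_len
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  body_start <- start + cfg$flank
  body_end <- body_start + cfg$gene_body_length - 1L
  tss <- ifelse(strand == "+", body_start, body_end)
  data.frame(
    gene_id = sprintf("gene%04d", i),
    chrom = "chr1", strand = strand,
    start = start, end = end,
    body_start = body_start, body_end = body_end,
    tss = as.integer(tss), length = region_len,
    stringsAsFactors = FALSE
  )
}

## internal: planted gene-level ground-truth flags.  HDGs are placed in
## two contiguous genomic clusters (so the density-uniformity test has
## signal to find); everything else is sampled uniformly.  Counts follow
## round_half_up(fraction * n_genes) exactly.
sim_gene_truth <- function(cfg) {
  n <- cfg$n_genes
  set.seed(derive_seed(cfg$seed, 2L))
  k_hdg <- round_half_up(cfg$frac_hdg * n)
  k1 <- ceiling(k_hdg / 2)
  hdg_idx <- integer(0)
  if (k_hdg > 0) {
    c1 <- floor(0.2 * n) + 1L
    c2 <- floor(0.55 * n) + 1L
    hdg_idx <- unique(pmin(n, c(seq.int(c1, length.out = k1),
                                seq.int(c2, length.out = k_hdg - k1))))
    ## top up in the improbable case the clusters collide with the end
    while (length(hdg_idx) < k_hdg)
      hdg_idx <- unique(c(hdg_idx, sample.int(n, 1L)))
  }
  pool <- setdiff(seq_len(n), hdg_idx)
  k_sw <- round_half_up(cfg$frac_sweep * n)
  sweep_up <- sort(sample(pool, k_sw))
  sweep_low <- sort(sample(setdiff(pool, sweep_up), k_sw))
  k_tdsg <- round_half_up(cfg$frac_tdsg * n)
  tdsg_pool <- setdiff(seq_len(n), c(sweep_up, sweep_low))
  tdsg_idx <- sort(sample(tdsg_pool, min(k_tdsg, length(tdsg_pool))))
  ## drought-responsive TDSGs carry the planted module structure
  k_dr <- round_half_up(cfg$frac_tdsg_drought * length(tdsg_idx))
  dr_tdsg <- sort(sample(tdsg_idx, k_dr))
  module <- integer(n)
  if (cfg$n_modules > 0 && k_dr > 0)
    module[dr_tdsg] <- 1L + (seq_along(dr_tdsg) - 1L) %% cfg$n_modules
  k_drg <- round_half_up(cfg$frac_drg * n)
  drg_idx <- dr_tdsg
  if (k_drg > length(dr_tdsg)) {
    extra <- sample(setdiff(seq_len(n), dr_tdsg), k_drg - length(dr_tdsg))
    drg_idx <- sort(c(dr_tdsg, extra))
  } else if (k_drg < length(dr_tdsg)) {
    drg_idx <- sort(sample(dr_tdsg, k_drg))
  }
  k_cis <- round_half_up(cfg$frac_motif_altering * n)
  k_cis_t <- min(round_half_up(cfg$frac_cis_in_tdsg * k_cis), length(tdsg_idx))
  cis_idx <- sort(c(sample(tdsg_idx, k_cis_t),
                    sample(setdiff(seq_len(n), tdsg_idx),
                           min(k_cis - k_cis_t, n - length(tdsg_idx)))))
  flag <- function(idx) seq_len(n) %in% idx
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    planted_hdg = flag(hdg_idx),
    planted_tdsg = flag(tdsg_idx),
    planted_drg = flag(drg_idx),
    planted_sweep_upland = flag(sweep_up),
    planted_sweep_lowland = flag(sweep_low),
    planted_module = module,
    planted_tradeoff = module > 0L,
    planted_motif_altering = flag(cis_idx),
    stringsAsFactors = FALSE
  )
}

#' Simulate diploid genotypes for the two-ecotype panel
#'
#' Biallelic SNPs with ecotype allele frequencies drawn from a
#' Balding-Nichols model and diploid genotypes (coded 0/1/2) sampled
#' under Hardy-Weinberg within ecotype. Planted highly differentiated
#' genes get large frequency differentials (~0.9 vs ~0.1); planted
#' TDSG genes elevated differentiation (`fst_tdsg`); planted sweep genes
#' within-ecotype frequencies pushed toward fixation (diversity deflated
#' ~`sweep_deflation`-fold); intergenic SNPs low divergence
#' (`fst_intergenic`), forming the neutral F_ST baseline.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `geno` (integer site x sample matrix),
#'   `sites` (SNP table: snp_id, chrom, pos, ref, alt, gene_id, zone),
#'   `regions` (gene models), `meta` (sample metadata) and `truth`
#'   (gene-level planted flags plus `motif_snp` designations).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- sim_metadata(cfg)
  regions <- sim_regions(cfg)
  truth <- sim_gene_truth(cfg)
  n <- cfg$n_genes
  set.seed(derive_seed(cfg$seed, 3L))

  ## --- SNP positions ------------------------------------------------
  n_up <- max(1L, round_half_up(0.3 * cfg$snps_per_gene))
  n_down <- n_up
  n_body <- cfg$snps_per_gene - n_up - n_down
  stopifnot(n_body >= 1L)
  ## upstream offsets keep a margin so a planted motif always fits
  margin <- 15L
  draw_offsets <- function(k, pool) {
    m <- vapply(seq_len(n), function(i) sort(sample(pool, k)), integer(k))
    if (k == 1L) matrix(m, ncol = 1L) else t(m)
  }
  up_off <- draw_offsets(n_up, seq.int(margin, cfg$flank - margin))
  body_off <- draw_offsets(n_body, seq_len(cfg$gene_body_length))
  down_off <- draw_offsets(n_down, seq_len(cfg$flank - 1L))

  pos_list <- vector("list", n)
  zone_list <- vector("list", n)
  for (i in seq_len(n)) {
    r <- regions[i, ]
    if (r$strand == "+") {
      up_pos <- r$tss - cfg$flank + up_off[i, ] - 1L   # offsets 1..flank
      down_pos <- r$body_end + down_off[i, ]
    } else {
      up_pos <- r$tss + cfg$flank - up_off[i, ] + 1L
      down_pos <- r$body_start - down_off[i, ]
    }
    body_pos <- r$body_start + body_off[i, ] - 1L
    p <- c(up_pos, body_pos, down_pos)
    z <- rep(c("upstream", "body", "downstream"), c(n_up, n_body, n_down))
    o <- order(p)
    pos_list[[i]] <- p[o]
    zone_list[[i]] <- z[o]
  }
  genic_pos <- unlist(pos_list)
  genic_zone <- unlist(zone_list)
  genic_gene <- rep(regions$gene_id, each = cfg$snps_per_gene)

  ## intergenic positions: sampled without replacement from the
  ## complement of all gene regions
  region_len <- 2L * cfg$flank + cfg$gene_body_length
  gap_len <- cfg$gene_spacing - region_len
  ig_lin <- sort(sample.int(as.integer(n) * gap_len, cfg$n_intergenic_snps))
  ig_slot <- (ig_lin - 1L) %/% gap_len
  ig_pos <- ig_slot * cfg$gene_spacing + region_len + ((ig_lin - 1L) %% gap_len) + 1L

  pos <- c(genic_pos, ig_pos)
  gene_id <- c(genic_gene, rep(NA_character_, cfg$n_intergenic_snps))
  zone <- c(genic_zone, rep("intergenic", cfg$n_intergenic_snps))
  n_sites <- length(pos)

  ## ref/alt alleles (labels only; planted motif SNPs may be relabelled
  ## by the promoter generator to realise the motif gain/loss)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)

  ## --- ecotype allele frequencies ----------------------------------
  bn_draw <- function(p0, fst) {
    if (fst <= 0) return(rep(p0, length(p0)))
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    stats::rbeta(length(p0), a, b)
  }
  p0 <- stats::runif(n_sites, 0.1, 0.9)
  p_up <- numeric(n_sites)
  p_low <- numeric(n_sites)

  gene_class <- rep("intergenic", n_sites)
  gi <- match(gene_id, truth$gene_id)
  genic <- !is.na(gi)
  cls <- rep("neutral", sum(genic))
  cls[truth$planted_tdsg[gi[genic]]] <- "tdsg"
  cls[truth$planted_sweep_upland[gi[genic]]] <- "sweep_up"
  cls[truth$planted_sweep_lowland[gi[genic]]] <- "sweep_low"
  cls[truth$planted_hdg[gi[genic]]] <- "hdg"
  gene_class[genic] <- cls

  idx <- gene_class == "intergenic"
  p_up[idx] <- bn_draw(p0[idx], cfg$fst_intergenic)
  p_low[idx] <- bn_draw(p0[idx], cfg$fst_intergenic)
  idx <- gene_class == "neutral"
  p_up[idx] <- bn_draw(p0[idx], cfg$fst_genic)
  p_low[idx] <- bn_draw(p0[idx], cfg$fst_genic)
  idx <- gene_class == "tdsg"
  p_up[idx] <- bn_draw(p0[idx], cfg$fst_tdsg)
  p_low[idx] <- bn_draw(p0[idx], cfg$fst_tdsg)
  idx <- gene_class == "hdg"
  if (any(idx)) {
    m_up <- cfg$hdg_p_upland; m_low <- cfg$hdg_p_lowland
    p_up[idx] <- stats::rbeta(sum(idx), m_up * 50, (1 - m_up) * 50)
    p_low[idx] <- stats::rbeta(sum(idx), m_low * 50, (1 - m_low) * 50)
  }
  squash <- function(p, defl) ifelse(p <= 0.5, p / defl, 1 - (1 - p) / defl)
  idx <- gene_class == "sweep_up"
  if (any(idx)) {
    p_up[idx] <- squash(bn_draw(p0[idx], cfg$fst_genic), cfg$sweep_deflation)
    p_low[idx] <- bn_draw(p0[idx], cfg$fst_genic)
  }
  idx <- gene_class == "sweep_low"
  if (any(idx)) {
    p_up[idx] <- bn_draw(p0[idx], cfg$fst_genic)
    p_low[idx] <- squash(bn_draw(p0[idx], cfg$fst_genic), cfg$sweep_deflation)
  }

  ## --- diploid genotypes under HWE within ecotype -------------------
  nu <- cfg$n_upland; nl <- cfg$n_lowland
  g_up <- matrix(stats::rbinom(n_sites * nu, 2L, rep(p_up, nu)),
                 nrow = n_sites, ncol = nu)
  g_low <- matrix(stats::rbinom(n_sites * nl, 2L, rep(p_low, nl)),
                  nrow = n_sites, ncol = nl)
  geno <- cbind(g_up, g_low)
  colnames(geno) <- meta$sample
  snp_id <- sprintf("snp%06d", seq_len(n_sites))
  rownames(geno) <- snp_id

  sites <- data.frame(snp_id = snp_id, chrom = "chr1", pos = pos,
                      ref = ref, alt = alt, gene_id = gene_id, zone = zone,
                      stringsAsFactors = FALSE)

  ## designate the planted motif-altering SNP of each motif gene: its
  ## first upstream SNP (offsets were sampled with a margin, so a motif
  ## occurrence around the SNP always fits inside the window)
  motif_snp <- data.frame(gene_id = character(0), snp_id = character(0))
  cis_genes <- truth$gene_id[truth$planted_motif_altering]
  if (length(cis_genes)) {
    first_up <- vapply(cis_genes, function(g) {
      cand <- sites$snp_id[!is.na(sites$gene_id) & sites$gene_id == g &
                             sites$zone == "upstream"]
      cand[1L]
    }, character(1))
    motif_snp <- data.frame(gene_id = cis_genes, snp_id = unname(first_up),
                            stringsAsFactors = FALSE)
  }

  list(geno = geno, sites = sites, regions = regions, meta = meta,
       truth = truth, motif_snp = motif_snp,
       genome_length = as.numeric(cfg$n_genes) * cfg$gene_spacing)
}
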