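#' Scan a sequence for IUPAC motif occurrences
#'
#' All exact matches of each degenerate IUPAC pattern (via
#' `Biostrings::matchPattern(fixed = FALSE)`), on the forward strand
#' and, when `both_strands`, of the reverse complement pattern (hits
#' reported on the "-" strand over the same forward-coordinate
#' interval). Cis-element collections are typically strand-ambiguous,
#' so both strands are scanned by default.
#'
#' @param sequence single character string (A/C/G/T).
#' @param motifs motif library data.frame (`name`, `iupac`).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame with `motif`, `start` (0-based), `end`
#'   (exclusive), `strand`.
#' @export
scan_motifs <- function(sequence, motifs, both_strands = TRUE) {
  subj <- Biostrings::DNAString(sequence)
  out <- vector("list", nrow(motifs) * 2L)
  k <- 0L
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(motifs$iupac[i])
    strands <- if (both_strands) c("+", "-") else "+"
    for (s in strands) {
      p <- if (s == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      if (length(m)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          motif = motifs$name[i],
          start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m),
          strand = s, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$start, res$motif, res$strand), , drop = FALSE]
}

#' Classify promoter SNPs as cis-element-altering
#'
#' For each SNP, the reference-allele and alternate-allele sequences
#' are compared motif by motif on the occurrence sets overlapping the
#' SNP: an occurrence present only under the alternate allele is a
#' *gain*, only under the reference a *loss*; a motif matching under
#' both or neither alleles is not altered. Both strands are scanned by
#' default. Internally each SNP is examined in a window of width
#' `2L - 1` centred on it (L = motif length), inside which every
#' occurrence overlaps the SNP by construction, so the scan reduces to
#' one vectorised degenerate-pattern match per motif, strand and
#' allele; results are identical to comparing full-sequence occurrence
#' scans (the test-suite cross-checks against that route).
#'
#' @param promoters named character vector of promoter sequences
#'   (gene orientation, 5'->3').
#' @param snps data.frame with `snp_id`, `gene_id`, `offset` (1-based
#'   position within the promoter), `ref`, `alt` (gene-orientation
#'   alleles).
#' @param motifs motif library data.frame.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame of cis-altering records: `snp_id`, `gene_id`,
#'   `pos_rel` (position relative to the TSS, negative upstream),
#'   `ref`, `alt`, `motif`, `effect` ("gain"/"loss"), `strand`.
#' @export
classify_cis_snps <- function(promoters, snps, motifs, both_strands = TRUE) {
  if (!nrow(snps))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      pos_rel = integer(0), ref = character(0),
                      alt = character(0), motif = character(0),
                      effect = character(0), strand = character(0)))
  flank <- unique(nchar(promoters))
  stopifnot(length(flank) == 1)
  max_len <- max(nchar(motifs$iupac))
  lo0 <- pmax(1L, snps$offset - max_len + 1L)
  hi0 <- pmin(flank, snps$offset + max_len - 1L)
  centre0 <- snps$offset - lo0 + 1L
  seqs <- promoters[snps$gene_id]
  win_ref <- substr(seqs, lo0, hi0)
  win_alt <- win_ref
  substr(win_ref, centre0, centre0) <- snps$ref
  substr(win_alt, centre0, centre0) <- snps$alt

  recs <- vector("list", nrow(motifs))
  strands <- if (both_strands) c("+", "-") else "+"
  for (i in seq_len(nrow(motifs))) {
    L <- nchar(motifs$iupac[i])
    ## trim to width 2L-1 around the SNP: any match then overlaps it
    sub_lo <- pmax(1L, centre0 - L + 1L)
    sub_hi <- pmin(nchar(win_ref), centre0 + L - 1L)
    sref <- substr(win_ref, sub_lo, sub_hi)
    salt <- substr(win_alt, sub_lo, sub_hi)
    hit_ref <- hit_alt <- rep(FALSE, nrow(snps))
    strand_of <- rep(NA_character_, nrow(snps))
    for (s in strands) {
      pat <- if (s == "+") motifs$iupac[i] else revcomp(motifs$iupac[i])
      rx <- iupac_to_regex(pat)
      hr <- grepl(rx, sref, perl = TRUE)
      ha <- grepl(rx, salt, perl = TRUE)
      strand_of[is.na(strand_of) & (hr | ha)] <- s
      hit_ref <- hit_ref | hr
      hit_alt <- hit_alt | ha
    }
    gain <- hit_alt & !hit_ref
    loss <- hit_ref & !hit_alt
    sel <- which(gain | loss)
    if (length(sel)) {
      recs[[i]] <- data.frame(
        snp_id = snps$snp_id[sel], gene_id = snps$gene_id[sel],
        pos_rel = snps$offset[sel] - flank - 1L,
        ref = snps$ref[sel], alt = snps$alt[sel],
        motif = motifs$name[i],
        effect = ifelse(gain[sel], "gain", "loss"),
        strand = strand_of[sel], stringsAsFactors = FALSE
      )
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      pos_rel = integer(0), ref = character(0),
                      alt = character(0), motif = character(0),
                      effect = character(0), strand = character(0)))
  out <- do.call(rbind, recs)
  out <- out[order(out$gene_id, out$snp_id, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a single SNP (convenience wrapper)
#'
#' @param sequence promoter sequence (gene orientation).
#' @param offset 1-based SNP position within the sequence.
#' @param ref,alt alleles.
#' @inheritParams classify_cis_snps
#' @return data.frame of cis-altering records (possibly empty).
#' @export
classify_snp <- function(sequence, offset, ref, alt, motifs,
                         both_strands = TRUE) {
  classify_cis_snps(
    stats::setNames(sequence, "g"),
    data.frame(snp_id = "s", gene_id = "g", offset = offset,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    motifs, both_strands = both_strands
  )
}

#' Group samples into haplotypes over a gene's cis-altering SNPs
#'
#' Samples with identical (unphased) genotype vectors over the gene's
#' cis-altering SNPs form one haplotype group; heterozygous genotypes
#' are their own category and missing genotypes are labelled ".".
#'
#' @param geno genotype matrix restricted to the gene's cis-altering
#'   SNPs (sites x samples, 0/1/2/NA).
#' @return character vector of haplotype labels, one per sample.
#' @export
assign_haplotypes <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (nrow(geno) == 0) return(rep("h0", ncol(geno)))
  g <- geno
  g[is.na(g)] <- "."
  apply(g, 2, paste, collapse = "")
}

#' Haplotype-level vs ecotype-level expression divergence
#'
#' Q_ST of one gene's expression computed between haplotype groups and
#' between ecotypes. Haplotype groups with fewer than `min_group`
#' samples are excluded (count reported). The haplotype effect is
#' declared when the haplotype Q_ST exceeds the 95th percentile of
#' Q_ST values obtained by permuting haplotype labels *within*
#' ecotypes — the null that keeps the ecotype divergence intact, so a
#' haplotype grouping identical to the ecotype split is never flagged.
#'
#' @param x one gene's expression values (log2 scale recommended).
#' @param haplotype haplotype labels from [assign_haplotypes()].
#' @param ecotype ecotype labels.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param min_group minimum haplotype group size (default 3).
#' @return list with `qst_hap`, `qst_eco`, `q95_perm`, `flag`,
#'   `n_groups`, `n_excluded`, or NULL when fewer than two usable
#'   haplotype groups remain.
#' @export
haplotype_vs_ecotype_qst <- function(x, haplotype, ecotype,
                                     n_perm = 1000L, seed = 1L,
                                     min_group = 3L) {
  stopifnot(length(x) == length(haplotype), length(x) == length(ecotype))
  tab <- table(haplotype)
  keep_h <- names(tab)[tab >= min_group]
  keep <- haplotype %in% keep_h
  n_excluded <- sum(!keep)
  if (length(keep_h) < 2) return(NULL)
  xs <- x[keep]; hs <- haplotype[keep]; es <- ecotype[keep]
  q_hap <- qst(xs, hs, n_perm = 0)$qst
  q_eco <- qst(x, ecotype, n_perm = 0)$qst
  set.seed(seed)
  perm_q <- vapply(seq_len(n_perm), function(i) {
    hp <- hs
    for (e in unique(es)) {
      idx <- which(es == e)
      hp[idx] <- hp[idx[sample.int(length(idx))]]
    }
    qst(xs, hp, n_perm = 0)$qst
  }, numeric(1))
  q95 <- stats::quantile(perm_q, 0.95, names = FALSE)
  list(qst_hap = q_hap, qst_eco = q_eco, q95_perm = q95,
       flag = q_hap > q95, n_groups = length(keep_h),
       n_excluded = n_excluded)
}
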