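#' Read an IUPAC motif table
#'
#' Tab-separated, two columns: motif name and IUPAC degenerate string
#' (PLACE-style). Strings are validated against the IUPAC alphabet.
#'
#' @param path file path.
#' @return data.frame with columns `name`, `iupac`.
#' @export
read_motif_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "iupac") %in% names(df)))
    stop("motif table needs columns 'name' and 'iupac'")
  df$iupac <- toupper(df$iupac)
  if (any(nchar(df$iupac) == 0)) stop("empty motif string")
  ok <- vapply(df$iupac, function(m)
    all(strsplit(m, "")[[1]] %in% names(IUPAC_CODES)), logical(1))
  if (!all(ok))
    stop("invalid IUPAC strings: ", paste(df$name[!ok], collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicated motif names")
  df[, c("name", "iupac")]
}

#' The bundled synthetic cis-element library
#'
#' 102 synthetic plant-style IUPAC motifs (lengths 5-8, mixing concrete
#' and degenerate positions), shipped as a plain-text stand-in for a
#' curated stress/hormone-response cis-element collection.
#'
#' @return data.frame with columns `name`, `iupac`.
#' @export
default_motif_library <- function() {
  read_motif_library(system.file("extdata", "motifs_synthetic.tsv",
                                 package = "ecodiverge", mustWork = TRUE))
}

## internal: map genic upstream SNPs from chromosome space into promoter
## space (offset 1 = -flank, offset `flank` = position just before the
## TSS; alleles complemented on the minus strand).
promoter_snp_table <- function(sites, regions, flank) {
  up <- sites[!is.na(sites$gene_id) & sites$zone == "upstream", , drop = FALSE]
  if (!nrow(up)) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      offset = integer(0), ref = character(0),
                      alt = character(0)))
  }
  r <- regions[match(up$gene_id, regions$gene_id), ]
  plus <- r$strand == "+"
  offset <- ifelse(plus, up$pos - r$tss + flank + 1L, r$tss + flank - up$pos + 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(
    snp_id = up$snp_id, gene_id = up$gene_id, offset = as.integer(offset),
    ref = ifelse(plus, up$ref, comp[up$ref]),
    alt = ifelse(plus, up$alt, comp[up$alt]),
    stringsAsFactors = FALSE
  )
}

#' Simulate promoter sequences and plant motif-altering SNPs
#'
#' Random background sequence for each gene's upstream window
#' (`flank` nt, reported 5'->3' in gene orientation), made consistent
#' with the reference alleles of the upstream SNPs. For each planted
#' motif-altering SNP a motif occurrence is written around the SNP such
#' that exactly one allele completes it: for a *gain* the alternate
#' allele matches the motif position and the reference does not, for a
#' *loss* the reverse. The SNP's ref/alt labels in the site table are
#' re-drawn to realise this (genotype codes are unchanged), and each
#' planting is verified against a both-strand occurrence scan.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_genotypes()] from the same `cfg`.
#' @param motifs motif library data.frame; default the bundled one.
#' @return list with `promoters` (named character vector, one sequence
#'   per gene), `motifs`, updated `sites`, `promoter_snps` (promoter-space
#'   SNP table) and `snp_truth` (planted gain/loss records).
#' @export
simulate_promoters <- function(cfg, sim, motifs = default_motif_library()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (max(nchar(motifs$iupac)) >= cfg$flank)
    stop("motif longer than the upstream window")
  set.seed(derive_seed(cfg$seed, 6L))
  n <- cfg$n_genes
  flank <- cfg$flank
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  seq_mat <- matrix(sample(bases, n * flank, replace = TRUE), nrow = n)
  sites <- sim$sites

  ## overlay reference alleles of upstream SNPs (gene orientation)
  psnp <- promoter_snp_table(sites, sim$regions, flank)
  gi <- match(psnp$gene_id, sim$regions$gene_id)
  seq_mat[cbind(gi, psnp$offset)] <- psnp$ref

  ## plant motif gains/losses at the designated SNPs
  snp_truth <- NULL
  ms <- sim$motif_snp
  if (nrow(ms)) {
    eff <- rep_len(c("gain", "loss"), nrow(ms))
    rec <- vector("list", nrow(ms))
    for (k in seq_len(nrow(ms))) {
      gid <- ms$gene_id[k]
      g <- match(gid, sim$regions$gene_id)
      si <- match(ms$snp_id[k], sites$snp_id)
      o <- psnp$offset[match(ms$snp_id[k], psnp$snp_id)]
      planted <- FALSE
      for (try in 1:40) {
        mi <- sample.int(nrow(motifs), 1L)
        pat <- strsplit(motifs$iupac[mi], "")[[1]]
        L <- length(pat)
        cls <- lapply(pat, function(ch) strsplit(IUPAC_CODES[[ch]], "")[[1]])
        jcand <- which(vapply(cls, length, integer(1)) <= 3)
        if (!length(jcand)) next
        j <- if (length(jcand) == 1) jcand else sample(jcand, 1L)
        start <- o - (j - 1L)
        if (start < 1L || start + L - 1L > flank) next
        inb <- cls[[j]]
        outb <- setdiff(bases, inb)
        match_b <- if (length(inb) == 1) inb else sample(inb, 1L)
        miss_b <- if (length(outb) == 1) outb else sample(outb, 1L)
        if (eff[k] == "gain") { ref_b <- miss_b; alt_b <- match_b }
        else { ref_b <- match_b; alt_b <- miss_b }
        ## write a concrete instance of the motif, SNP position = ref
        inst <- vapply(cls, function(cb)
          if (length(cb) == 1) cb else sample(cb, 1L), character(1))
        old <- seq_mat[g, start:(start + L - 1L)]
        inst[j] <- ref_b
        seq_mat[g, start:(start + L - 1L)] <- inst
        ## verify: exactly one allele yields an occurrence overlapping o
        ctx <- max(1L, o - (L - 1L)):min(flank, o + L - 1L)
        mkseq <- function(b) {
          s <- seq_mat[g, ctx]; s[which(ctx == o)] <- b
          paste(s, collapse = "")
        }
        hit <- function(b) {
          s <- mkseq(b)
          rx <- iupac_to_regex(motifs$iupac[mi])
          grepl(rx, s) || grepl(rx, paste(comp[rev(strsplit(s, "")[[1]])],
                                          collapse = ""))
        }
        ok <- if (eff[k] == "gain") (!hit(ref_b)) && hit(alt_b)
              else hit(ref_b) && (!hit(alt_b))
        if (ok) {
          sites$ref[si] <- if (sim$regions$strand[g] == "+") ref_b else comp[[ref_b]]
          sites$alt[si] <- if (sim$regions$strand[g] == "+") alt_b else comp[[alt_b]]
          rec[[k]] <- data.frame(
            snp_id = ms$snp_id[k], gene_id = gid, motif = motifs$name[mi],
            planted_motif_gain = eff[k] == "gain",
            planted_motif_loss = eff[k] == "loss",
            offset = o, stringsAsFactors = FALSE
          )
          planted <- TRUE
          break
        }
        seq_mat[g, start:(start + L - 1L)] <- old  # undo and retry
      }
      if (!planted)
        stop("failed to plant a motif-altering SNP for ", gid)
    }
    snp_truth <- do.call(rbind, rec)
  }

  promoters <- apply(seq_mat, 1L, paste, collapse = "")
  names(promoters) <- sim$regions$gene_id
  list(promoters = promoters, motifs = motifs, sites = sites,
       promoter_snps = promoter_snp_table(sites, sim$regions, flank),
       snp_truth = snp_truth)
}
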