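## Interchange formats: VCF 4.2, GFF3, FASTA, TSV (tab, UTF-8, "." for
## missing). Readers lean on vcfR / rtracklayer / Biostrings; writers
## emit minimal deterministic plain text so repeated runs are
## byte-identical. Coordinates are 1-based inclusive throughout
## (VCF/GFF convention, kept internally as well).

#' Write genotypes to a minimal VCF 4.2 file
#'
#' GT-only, unphased; genotype codes 0/1/2 become 0/0, 0/1, 1/1 and NA
#' becomes ./..
#'
#' @param geno integer site x sample matrix.
#' @param sites site table (`snp_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, sites, path) {
  stopifnot(nrow(geno) == nrow(sites))
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt[is.na(geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ecodiverge",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(geno)), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, sites$snp_id, sites$ref,
                sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Biallelic records only (multi-allelic sites are skipped with a
#' warning); genotype = alt-allele dosage regardless of phasing
#' separator.
#'
#' @param path VCF path.
#' @return list with `geno` (integer site x sample matrix) and `sites`
#'   (snp_id, chrom, pos, ref, alt).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(geno = matrix(integer(0), 0, 0),
                sites = data.frame(snp_id = character(0),
                                   chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0))))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v)
  code <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (any(a == "." | is.na(a))) return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, integer(1))
  }
  geno <- apply(gt, 2, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(fix))
  id <- fix$ID
  if (any(is.na(id) | id == "."))
    id <- sprintf("%s_%s", fix$CHROM, fix$POS)
  rownames(geno) <- id
  colnames(geno) <- colnames(gt)
  list(geno = geno,
       sites = data.frame(snp_id = id, chrom = fix$CHROM,
                          pos = as.integer(fix$POS), ref = fix$REF,
                          alt = fix$ALT, stringsAsFactors = FALSE))
}

#' Write gene models to GFF3
#'
#' One `gene` feature per row (gene body coordinates; the analysis
#' flanks are derived at read time).
#'
#' @param regions region table (`gene_id`, `chrom`, `strand`,
#'   `body_start`, `body_end`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(regions, path) {
  lines <- paste(regions$chrom, "ecodiverge", "gene", regions$body_start,
                 regions$body_end, ".", regions$strand, ".",
                 paste0("ID=", regions$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene annotation and derive analysis regions
#'
#' Reads `gene` features from a GFF3 (via rtracklayer), derives the
#' strand-aware TSS and the upstream/downstream flanks, and clips
#' regions at position 1 and optionally at chromosome ends. Duplicate
#' gene IDs are an error.
#'
#' @param path GFF3 path.
#' @param flank flank size in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-clipping.
#' @return region table as used by [popgen_scan()].
#' @export
read_annotation <- function(path, flank = 2000L, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (anyDuplicated(ids)) stop("duplicated gene IDs in annotation")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("gene(s) without strand in annotation")
  body_start <- BiocGenerics::start(gr)
  body_end <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- pmax(body_start - flank, 1L)
  end <- body_end + flank
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[chrom]
    clipped <- !is.na(lim) & end > lim
    if (any(clipped))
      message(sum(clipped), " region(s) clipped at chromosome end")
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  if (any(start > body_start - flank))
    message(sum(start > body_start - flank),
            " region(s) clipped at chromosome start")
  data.frame(
    gene_id = ids, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    body_start = body_start, body_end = body_end,
    tss = as.integer(ifelse(strand == "+", body_start, body_end)),
    length = as.integer(end - start + 1L),
    stringsAsFactors = FALSE
  )
}

#' Assign SNPs to gene regions and zones
#'
#' Each SNP is assigned to the first overlapping gene region (upstream
#' flank / gene body / downstream flank, strand-aware) or to
#' "intergenic".
#'
#' @param sites site table (`chrom`, `pos`).
#' @param regions region table from [read_annotation()].
#' @return `sites` with `gene_id` and `zone` columns filled.
#' @export
assign_snps_to_regions <- function(sites, regions) {
  snp_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start,
                                                    regions$end))
  hit <- GenomicRanges::findOverlaps(snp_gr, reg_gr, select = "first")
  gene_id <- regions$gene_id[hit]
  zone <- rep("intergenic", nrow(sites))
  ok <- !is.na(hit)
  r <- regions[hit[ok], ]
  p <- sites$pos[ok]
  in_body <- p >= r$body_start & p <= r$body_end
  before <- p < r$body_start
  plus <- r$strand == "+"
  zone[ok] <- ifelse(in_body, "body",
                     ifelse(before == plus, "upstream", "downstream"))
  sites$gene_id <- gene_id
  sites$zone <- zone
  sites
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a data frame as TSV ("." for missing)
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an expression matrix as TSV (gene_id first column)
#' @param mat genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression TSV into a matrix
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
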