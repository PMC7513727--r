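mot <- function(...) {
  m <- c(...)
  data.frame(name = paste0("m", seq_along(m)), iupac = m,
             stringsAsFactors = FALSE)
}

test_that("motif scanning: direct match, palindrome, degenerate codes", {
  hits <- scan_motifs("TTCACGTGAA", mot("CACGTG"))
  ## palindromic motif: one interval, both strands
  expect_equal(nrow(hits), 2)
  expect_equal(unique(hits$start), 2)  # 0-based offset
  expect_equal(unique(hits$end), 8)
  expect_setequal(hits$strand, c("+", "-"))
  ## forward-only scan
  expect_equal(nrow(scan_motifs("TTCACGTGAA", mot("CACGTG"), FALSE)), 1)
  ## degenerate code R = A/G
  h2 <- scan_motifs("TTGACGTC", mot("GACRTC"), both_strands = FALSE)
  expect_equal(h2$start, 2)
  ## invalid IUPAC rejected upstream
  expect_error(iupac_to_regex("CAXGT"), "invalid IUPAC")
})

test_that("Biostrings scan equals the regex-expansion oracle on random sequences", {
  set.seed(51)
  lib <- default_motif_library()[1:25, ]
  for (r in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    got <- scan_motifs(s, lib)
    want <- oracle_scan(s, lib)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("SNP classification: planted gain, degenerate position, antisymmetry", {
  ## SNP completes a motif only under the alt allele -> gain
  s <- paste0(strrep("T", 20), "CAAGTG", strrep("T", 20))
  ## position 3 of CACGTG is at offset 23; ref A breaks it, alt C makes it
  r <- classify_snp(s, 23, "A", "C", mot("CACGTG"))
  expect_equal(r$effect, "gain")
  expect_equal(r$pos_rel, 23 - nchar(s) - 1)
  ## swapping ref and alt turns the gain into a loss
  r2 <- classify_snp(sub("CAAGTG", "CACGTG", s), 23, "C", "A", mot("CACGTG"))
  expect_equal(r2$effect, "loss")
  ## SNP at an N position matches under both alleles -> no record
  r3 <- classify_snp(s, 23, "A", "C", mot("CANGTG"))
  expect_equal(nrow(r3), 0)
})

test_that("classification equals the two-sequence scan oracle on random cases", {
  set.seed(52)
  lib <- default_motif_library()[seq(1, 102, by = 4), ]
  n_cases <- 400
  seqs <- vapply(seq_len(n_cases), function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1))
  ## half the cases get a motif instance planted near the SNP so that
  ## gains/losses are well represented
  off <- 30L
  for (i in seq(1, n_cases, by = 2)) {
    m <- sample(nrow(lib), 1)
    inst <- gsub("[RYSWKMBDHVN]", "A", lib$iupac[m])
    j <- sample(nchar(inst), 1)
    substr(seqs[i], off - j + 1, off - j + nchar(inst)) <- inst
  }
  alle <- t(vapply(seq_len(n_cases), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2)))
  snps <- data.frame(snp_id = sprintf("s%03d", 1:n_cases),
                     gene_id = sprintf("g%03d", 1:n_cases),
                     offset = off, ref = alle[, 1], alt = alle[, 2],
                     stringsAsFactors = FALSE)
  proms <- setNames(seqs, snps$gene_id)
  got <- classify_cis_snps(proms, snps, lib)
  for (i in seq_len(n_cases)) {
    want <- oracle_classify(seqs[i], off, alle[i, 1], alle[i, 2], lib)
    gi <- got[got$gene_id == snps$gene_id[i], c("motif", "effect")]
    rownames(gi) <- NULL
    expect_equal(gi[order(gi$motif), , drop = FALSE],
                 want[order(want$motif), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("planted motif-altering SNPs are all detected with the planted effect", {
  ds <- small_ds()
  cis <- classify_cis_snps(ds$promoters, ds$promoter_snps, ds$motifs)
  tru <- ds$truth_snps
  for (i in seq_len(nrow(tru))) {
    rec <- cis[cis$snp_id == tru$snp_id[i] & cis$motif == tru$motif[i], ]
    expect_equal(nrow(rec), 1)
    expect_equal(rec$effect,
                 if (tru$planted_motif_gain[i]) "gain" else "loss")
  }
})

test_that("haplotype assignment groups identical genotype vectors", {
  geno <- rbind(c(0, 0, 1, 2, 2, NA),
                c(2, 2, 1, 0, 0, 0))
  colnames(geno) <- paste0("s", 1:6)
  h <- unname(assign_haplotypes(geno))
  expect_equal(h[1], h[2])
  expect_false(h[1] == h[3])  # heterozygote is its own group
  expect_equal(length(unique(h)), 4)
  expect_match(h[6], "\\.")
  ## no cis-altering SNPs -> a single haplotype
  expect_equal(unique(assign_haplotypes(geno[0, , drop = FALSE])), "h0")
  ## 3 SNPs, all-distinct genotype vectors -> as many groups as samples
  g3 <- matrix(c(0,1,2, 1,0,2, 2,2,2, 0,0,0), nrow = 3)
  colnames(g3) <- paste0("t", 1:4)
  expect_equal(length(unique(assign_haplotypes(g3))), 4)
})

test_that("haplotype vs ecotype Q_ST flags haplotype-driven expression only", {
  set.seed(53)
  n <- 60
  eco <- rep(c("upland", "lowland"), each = n / 2)
  ## haplotypes split *within* ecotypes and drive expression
  hap <- rep(c("h1", "h2"), times = n / 2)
  x <- ifelse(hap == "h1", 10, 2) + rnorm(n, 0, 0.5)
  r <- haplotype_vs_ecotype_qst(x, hap, eco, n_perm = 300, seed = 1)
  expect_gt(r$qst_hap, r$qst_eco)
  expect_true(r$flag)
  ## haplotype identical to the ecotype partition -> never flagged
  x2 <- ifelse(eco == "upland", 8, 3) + rnorm(n, 0, 0.5)
  r2 <- haplotype_vs_ecotype_qst(x2, ifelse(eco == "upland", "hA", "hB"),
                                 eco, n_perm = 300, seed = 1)
  expect_equal(r2$qst_hap, r2$qst_eco)
  expect_false(r2$flag)
  ## singleton haplotype groups are excluded and counted
  hap3 <- hap; hap3[1] <- "rare"
  r3 <- haplotype_vs_ecotype_qst(x, hap3, eco, n_perm = 100, seed = 1)
  expect_equal(r3$n_excluded, 1)
  ## fewer than two usable groups -> NULL
  expect_null(haplotype_vs_ecotype_qst(x, rep("h1", n), eco, n_perm = 10))
})

test_that("cis-altering gene fraction rises with the planted fraction", {
  fr <- c(0, 0.3)
  frac_seen <- vapply(fr, function(f) {
    cfg <- sim_config(seed = 5, n_genes = 150, n_intergenic_snps = 100,
                      frac_motif_altering = f)
    g <- simulate_genotypes(cfg)
    pr <- simulate_promoters(cfg, g)
    cis <- classify_cis_snps(pr$promoters, pr$promoter_snps, pr$motifs)
    length(unique(cis$gene_id)) / 150
  }, numeric(1))
  expect_gt(frac_seen[2], frac_seen[1])
})
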