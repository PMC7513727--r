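test_that("pi, dxy and Hudson F_ST match brute-force allele-pool oracles", {
  set.seed(101)
  for (rep in 1:40) {
    ns <- sample(2:4, 1)
    nsnp <- sample(1:5, 1)
    geno <- matrix(sample(0:2, nsnp * 2 * ns, replace = TRUE),
                   nrow = nsnp,
                   dimnames = list(NULL, paste0("s", seq_len(2 * ns))))
    ga <- paste0("s", 1:ns); gb <- paste0("s", ns + 1:ns)
    L <- 100
    expect_equal(nucleotide_diversity(geno, ga, L), oracle_pi(geno, ga, L))
    expect_equal(dxy(geno, ga, gb, L), oracle_dxy(geno, ga, gb, L))
    expect_equal(hudson_fst(geno, ga, gb), oracle_hudson(geno, ga, gb))
  }
})

test_that("Hudson F_ST equals the oracle on all enumerable 2+2-sample 2-SNP instances", {
  ids <- paste0("s", 1:4)
  ga <- ids[1:2]; gb <- ids[3:4]
  combos <- as.matrix(expand.grid(rep(list(0:2), 8)))
  ## exhaustive over every genotype assignment of 2 SNPs x 4 samples
  got <- numeric(nrow(combos)); want <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    geno <- matrix(as.integer(combos[r, ]), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, ids))
    got[r] <- hudson_fst(geno, ga, gb)
    want[r] <- oracle_hudson(geno, ga, gb)
  }
  expect_identical(is.na(got), is.na(want))
  expect_equal(got, want)
})

test_that("pi and F_ST handle the textbook closed forms", {
  ids <- paste0("s", 1:4)
  ga <- ids[1:2]; gb <- ids[3:4]
  ## identical samples everywhere -> pi 0
  geno0 <- matrix(2L, nrow = 3, ncol = 4, dimnames = list(NULL, ids))
  expect_equal(nucleotide_diversity(geno0, ids, 100), 0)
  ## alternative fixation at every site -> F_ST 1
  genof <- matrix(rep(c(0L, 0L, 2L, 2L), each = 1), nrow = 1,
                  dimnames = list(NULL, ids))
  expect_equal(hudson_fst(genof, ga, gb), 1)
  ## equal allele frequencies in both groups -> 0 after clamping
  genoe <- matrix(c(0L, 2L, 0L, 2L), nrow = 1, dimnames = list(NULL, ids))
  expect_equal(hudson_fst(genoe, ga, gb), 0)
  ## groups fixed for different alleles at 1 of 10 sites -> dxy 0.1
  geno10 <- matrix(0L, nrow = 10, ncol = 4, dimnames = list(NULL, ids))
  geno10[1, 3:4] <- 2L
  expect_equal(dxy(geno10, ga, gb, 10), 0.1)
  ## dxy symmetric in group order and sample order
  expect_equal(dxy(geno10, gb, ga, 10), dxy(geno10, ga, gb, 10))
  expect_equal(dxy(geno10, sample(ga), sample(gb), 10),
               dxy(geno10, ga, gb, 10))
  ## empty group errors
  expect_error(nucleotide_diversity(geno0, character(0), 100), "empty")
})

test_that("pi estimator equals mean pairwise allele difference (unbiasedness form)", {
  ## one heterozygous sample pair differing at 1 of 100 sites: the
  ## per-site unbiased 2pq n/(n-1) equals the brute-force mean pairwise
  ## difference over the 2n alleles by construction
  ids <- c("a", "b")
  geno <- matrix(0L, nrow = 100, ncol = 2, dimnames = list(NULL, ids))
  geno[1, ] <- c(0L, 2L)
  expect_equal(nucleotide_diversity(geno, ids, 100),
               oracle_pi(geno, ids, 100))
})

test_that("neutral F_ST: zero divergence, bootstrap SE, degenerate single SNP", {
  ids <- paste0("s", 1:20)
  ga <- ids[1:10]; gb <- ids[11:20]
  ## equal allele frequencies at every SNP -> mean 0
  g <- matrix(rep(c(rep(0L, 5), rep(2L, 5)), 2), nrow = 1)
  g <- g[rep(1, 30), , drop = FALSE]
  colnames(g) <- ids
  nf <- neutral_fst(g, ga, gb, n_boot = 100, seed = 1)
  expect_equal(nf$mean, 0)
  ## bootstrap SE approximates the analytic SE of the mean at 10,000 SNPs
  set.seed(5)
  p_up <- rbeta(10000, 3, 3); p_low <- rbeta(10000, 3, 3)
  gu <- matrix(rbinom(10000 * 10, 2, rep(p_up, 10)), ncol = 10)
  gl <- matrix(rbinom(10000 * 10, 2, rep(p_low, 10)), ncol = 10)
  gg <- cbind(gu, gl); colnames(gg) <- ids
  nf2 <- neutral_fst(gg, ga, gb, n_boot = 1000, seed = 2)
  analytic <- sd(nf2$per_snp) / sqrt(length(nf2$per_snp))
  expect_lt(abs(nf2$se - analytic) / analytic, 0.1)
  ## single polymorphic SNP -> resamples identical -> SE 0
  g1 <- matrix(c(rep(0L, 10), rep(c(0L, 2L), 5)), nrow = 1,
               dimnames = list(NULL, ids))
  expect_equal(neutral_fst(g1, ga, gb, n_boot = 50, seed = 1)$se, 0)
})

test_that("HDG calling flags strictly above the 95th percentile", {
  set.seed(11)
  fst <- runif(1000)
  h <- call_hdg(fst)
  expect_lte(sum(h$flag), 50)
  expect_true(all(fst[h$flag] > h$threshold))
  ## degenerate: identical values -> none strictly above
  h2 <- call_hdg(rep(0.4, 50))
  expect_equal(sum(h2$flag), 0)
  expect_error(call_hdg(rep(NA_real_, 5)), "no defined")
})

test_that("pi/D_xy scan flags floor(tail*n) genes with documented tie-breaking", {
  set.seed(12)
  n <- 437
  ratio <- runif(n)
  ids <- sprintf("g%03d", seq_len(n))
  sc <- pi_dxy_scan(ratio, ids)
  expect_equal(sum(sc$flag), floor(0.05 * n))
  expect_equal(which(sc$flag), sort(order(ratio)[seq_len(floor(0.05 * n))]))
  ## a zero ratio always lands in the tail
  ratio[7] <- 0
  expect_true(pi_dxy_scan(ratio, ids)$flag[7])
  ## NA (dxy = 0) genes are excluded from the ranking
  ratio[1:40] <- NA
  sc2 <- pi_dxy_scan(ratio, ids)
  expect_equal(sc2$n_excluded, 40)
  expect_equal(sum(sc2$flag), floor(0.05 * (n - 40)))
  ## ties at the boundary break by gene id order
  r3 <- c(rep(0, 10), rep(1, 90))
  sc3 <- pi_dxy_scan(r3, sprintf("g%02d", 1:100))
  expect_equal(which(sc3$flag), 1:5)
})

test_that("density uniformity test: even spacing, clustering, empty input", {
  L <- 2e7
  even <- seq(L / 100, L, by = L / 100) - L / 200
  expect_gt(density_uniformity_test(even, L)$p.value, 0.9)
  clustered <- runif(50, 0, 5e6)  # all flags within one 5,000 kb window
  expect_lt(density_uniformity_test(clustered, L)$p.value, 0.001)
  expect_error(density_uniformity_test(numeric(0), L), "empty")
})

test_that("popgen_scan recovers planted structure on synthetic data", {
  ds <- small_ds()
  pg <- popgen_scan(ds$geno, ds$sites, ds$regions, ds$meta)
  tr <- ds$truth
  ## planted HDGs are recovered with sensitivity >= 0.9
  hdg <- call_hdg(pg$fst)
  expect_gte(mean(hdg$flag[tr$planted_hdg]), 0.9)
  ## planted sweep genes sit in the pi/D_xy lower tail, sensitivity >= 0.8
  scu <- pi_dxy_scan(pg$ratio_upland, pg$gene_id)
  expect_gte(mean(scu$flag[tr$planted_sweep_upland]), 0.8)
  ## per-gene values agree with the brute-force oracles on a spot check
  gid <- tr$gene_id[5]
  sel <- which(!is.na(ds$sites$gene_id) & ds$sites$gene_id == gid)
  L <- ds$regions$length[5]
  up <- ds$meta$sample[ds$meta$ecotype == "upland"]
  expect_equal(pg$pi_upland[5],
               oracle_pi(ds$geno[sel, , drop = FALSE], up, L))
  low <- ds$meta$sample[ds$meta$ecotype == "lowland"]
  expect_equal(pg$fst[5],
               oracle_hudson(ds$geno[sel, , drop = FALSE], up, low))
  expect_equal(pg$dxy[5],
               oracle_dxy(ds$geno[sel, , drop = FALSE], up, low, L))
})

test_that("pi and dxy are invariant to duplicating every sample", {
  set.seed(13)
  ids <- paste0("s", 1:6)
  geno <- matrix(sample(0:2, 30, TRUE), nrow = 5, dimnames = list(NULL, ids))
  ga <- ids[1:3]; gb <- ids[4:6]
  d1 <- dxy(geno, ga, gb, 50)
  geno2 <- cbind(geno, geno)
  colnames(geno2) <- c(ids, paste0(ids, "_dup"))
  expect_equal(dxy(geno2, c(ga, paste0(ga, "_dup")),
                   c(gb, paste0(gb, "_dup")), 50), d1)
})
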