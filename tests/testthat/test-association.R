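test_that("Fisher enrichment: hand odds ratio and exhaustive-tail oracle", {
  uni <- sprintf("g%03d", 1:200)
  ## 2x2 table (30, 70, 10, 90): OR = 30*90 / (70*10)
  set_a <- uni[1:100]                       # 30+70
  set_b <- uni[c(1:30, 101:110)]            # 30 in A, 10 outside
  fe <- fisher_enrichment(set_a, set_b, uni)
  expect_equal(fe$odds_ratio, (30 * 90) / (70 * 10))
  expect_equal(fe$p, oracle_fisher_p(30, 70, 10, 90), tolerance = 1e-9)
  ## proportional table -> OR 1, two-sided p 1
  fe2 <- fisher_enrichment(uni[1:100], uni[seq(1, 200, 2)], uni)
  expect_equal(fe2$odds_ratio, 1)
  expect_equal(fe2$p, 1)
  ## empty set A -> documented missing odds ratio
  fe3 <- fisher_enrichment(character(0), set_b, uni)
  expect_true(is.na(fe3$odds_ratio))
})

test_that("Fisher p equals the hypergeometric oracle on all tables with n <= 40", {
  got_two <- c(); want_two <- c(); got_gr <- c(); want_gr <- c()
  for (N in c(8L, 13L, 40L)) {
    margins <- expand.grid(m = 0:N, k = 0:N)
    margins <- margins[seq(1, nrow(margins), by = 3), ]  # thin the grid
    for (r in seq_len(nrow(margins))) {
      m <- margins$m[r]; k <- margins$k[r]
      for (n11 in max(0, m + k - N):min(m, k)) {
        uni <- as.character(seq_len(N))
        fe <- fisher_enrichment(uni[seq_len(m)],
                                uni[c(seq_len(n11),
                                      m + seq_len(k - n11))], uni)
        feg <- fisher_enrichment(uni[seq_len(m)],
                                 uni[c(seq_len(n11),
                                       m + seq_len(k - n11))], uni,
                                 alternative = "greater")
        got_two <- c(got_two, fe$p)
        want_two <- c(want_two, oracle_fisher_p(n11, m - n11, k - n11,
                                                N - m - k + n11))
        got_gr <- c(got_gr, feg$p)
        want_gr <- c(want_gr, oracle_fisher_p(n11, m - n11, k - n11,
                                              N - m - k + n11, "greater"))
      }
    }
  }
  expect_equal(got_two, want_two, tolerance = 1e-9)
  expect_equal(got_gr, want_gr, tolerance = 1e-9)
})

test_that("trait Q_ST profile flags planted divergent traits, not null ones", {
  ds <- small_ds()
  up <- ds$meta$ecotype == "upland"
  nf <- neutral_fst(ds$geno[ds$sites$zone == "intergenic", , drop = FALSE],
                    ds$meta$sample[up], ds$meta$sample[!up],
                    n_boot = 200, seed = 3)
  tq <- trait_qst_profile(ds$traits, ds$meta, nf, n_perm = 300, seed = 4)
  planted <- attr(ds$traits, "planted_divergent")
  expect_true(all(c("NT_CK", "FLW_DT", "RWC_DT") %in% planted))
  expect_true(all(tq$divergent[tq$trait %in% planted]))
  ## zero-ecotype-effect traits stay unflagged
  expect_false(any(tq$divergent[tq$trait %in% c("GW100_CK", "biomass_CK")]))
  ## Q_ST invariant to affine rescaling of a trait
  tr2 <- ds$traits
  tr2$RWC_DT <- 100 * tr2$RWC_DT + 3
  tq2 <- trait_qst_profile(tr2, ds$meta, nf, n_perm = 0)
  expect_equal(tq2$qst[tq2$trait == "RWC_DT"],
               tq$qst[tq$trait == "RWC_DT"])
})

test_that("trait-correlated gene sets behave at the exact and null extremes", {
  set.seed(71)
  meta <- data.frame(sample = sprintf("s%02d", 1:40),
                     ecotype = rep(c("upland", "lowland"), 20),
                     origin = "o1", typical = TRUE)
  expr <- matrix(rlnorm(300 * 40, 3, 0.5), 300, 40,
                 dimnames = list(sprintf("g%03d", 1:300), meta$sample))
  expr[300, ] <- 0  # constant gene
  traits <- data.frame(sample = meta$sample,
                       t_gene = expr[1, ],
                       t_null = rnorm(40))
  sets <- trait_correlated_genes(expr, traits, meta)
  tg <- sets[["t_gene"]]
  expect_equal(tg$r[1], 1)
  expect_true(tg$in_set[1])
  expect_true(is.na(tg$r[300]))       # constant gene excluded
  ## permuted/independent trait -> about 5% of genes by chance
  rate <- mean(sets[["t_null"]]$in_set, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("enrichment-ratio vs trait Q_ST correlation is positive under coupling", {
  ds <- small_ds()
  up <- ds$meta$ecotype == "upland"
  nf <- neutral_fst(ds$geno[ds$sites$zone == "intergenic", , drop = FALSE],
                    ds$meta$sample[up], ds$meta$sample[!up],
                    n_boot = 100, seed = 3)
  tq <- trait_qst_profile(ds$traits, ds$meta, nf, n_perm = 0)
  tn <- setdiff(names(ds$traits), "sample")
  ck <- grepl("_CK$", tn)
  sets <- c(trait_correlated_genes(ds$expr_ck,
                                   ds$traits[, c("sample", tn[ck])], ds$meta),
            trait_correlated_genes(ds$expr_dt,
                                   ds$traits[, c("sample", tn[!ck])], ds$meta))
  tdsg <- ds$truth$gene_id[ds$truth$planted_tdsg]
  rc <- ratio_vs_qst_correlation(sets, tdsg, tq)
  expect_true(all(rc$table$ratio >= 0 & rc$table$ratio <= 1))
  expect_gt(rc$r, 0)
  expect_lt(rc$p, 0.05)
  ## constant ratios -> missing correlation
  sets0 <- lapply(sets, function(s) { s$in_set <- FALSE; s })
  expect_true(is.na(ratio_vs_qst_correlation(sets0, tdsg, tq)$r))
  expect_error(ratio_vs_qst_correlation(sets, character(0), tq), "empty")
})

test_that("trade-off gene calling equals the direct filter oracle", {
  set.seed(72)
  n <- 200
  mk <- function(r, q) data.frame(gene_id = sprintf("g%03d", 1:n),
                                  r = r, p = q, q = q,
                                  in_set = q < 0.05)
  r1 <- runif(n, -1, 1); q1 <- runif(n)
  r2 <- runif(n, -1, 1); q2 <- runif(n)
  to <- tradeoff_genes(mk(r1, q1), mk(r2, q2))
  want <- sprintf("g%03d", which(q1 < .05 & q2 < .05 & sign(r1) == -sign(r2) &
                                   r1 != 0 & r2 != 0))
  expect_setequal(to$gene_id, want)
  ## both correlations positive are excluded even at tiny q
  both_pos <- tradeoff_genes(mk(abs(r1), rep(1e-6, n)),
                             mk(abs(r2), rep(1e-6, n)))
  expect_equal(nrow(both_pos), 0)
})

test_that("planted trade-off genes are recovered with high sensitivity", {
  ds <- small_ds()
  tn <- setdiff(names(ds$traits), "sample")
  sets_dt <- trait_correlated_genes(
    ds$expr_dt, ds$traits[, c("sample", tn[!grepl("_CK$", tn)])], ds$meta)
  sets_ck <- trait_correlated_genes(
    ds$expr_ck, ds$traits[, c("sample", tn[grepl("_CK$", tn)])], ds$meta)
  to <- tradeoff_genes(sets_dt[["RWC_DT"]], sets_ck[["NT_CK"]])
  planted <- ds$truth$gene_id[ds$truth$planted_tradeoff]
  expect_gte(mean(planted %in% to$gene_id), 0.8)
  ## opposite-sign pattern holds for >= 90% of planted genes
  m <- match(planted, sets_dt[["RWC_DT"]]$gene_id)
  sgn_ok <- sign(sets_dt[["RWC_DT"]]$r[m]) == -sign(sets_ck[["NT_CK"]]$r[m])
  expect_gte(mean(sgn_ok), 0.9)
})

test_that("trade-off null: strength 0 removes the opposite-sign structure", {
  cfg <- sim_config(seed = 23, n_genes = 200, n_intergenic_snps = 100,
                    tradeoff_strength = 0)
  ds <- simulate_dataset(cfg)
  tn <- setdiff(names(ds$traits), "sample")
  sets_dt <- trait_correlated_genes(
    ds$expr_dt, ds$traits[, c("sample", "RWC_DT")], ds$meta)
  sets_ck <- trait_correlated_genes(
    ds$expr_ck, ds$traits[, c("sample", "NT_CK")], ds$meta)
  planted <- ds$truth$gene_id[ds$truth$planted_tradeoff]
  m <- match(planted, sets_dt[["RWC_DT"]]$gene_id)
  both_sig <- sets_dt[["RWC_DT"]]$q[m] < .05 & sets_ck[["NT_CK"]]$q[m] < .05
  expect_lte(mean(both_sig, na.rm = TRUE), 0.1)
})

test_that("RWC direction consistency detects the planted adaptive coupling", {
  ds <- small_ds()
  tn <- setdiff(names(ds$traits), "sample")
  sets_dt <- trait_correlated_genes(
    ds$expr_dt, ds$traits[, c("sample", "RWC_DT")], ds$meta)
  rwc <- sets_dt[["RWC_DT"]]
  y <- log2(ds$expr_dt + 1)
  up <- ds$meta$ecotype == "upland"
  mu_up <- rowMeans(y[, up]); mu_low <- rowMeans(y[, !up])
  genes <- ds$truth$gene_id[ds$truth$planted_module > 0]
  rd <- rwc_direction_consistency(genes, rwc, mu_up, mu_low)
  expect_lt(rd$p, 1e-6)
  ## independent signs give a null association
  set.seed(73)
  rwc0 <- rwc
  rwc0$r <- rnorm(nrow(rwc0))
  rd0 <- rwc_direction_consistency(sample(rwc0$gene_id, 150), rwc0,
                                   mu_up, mu_low)
  expect_gt(rd0$p, 0.001)
})
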