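test_that("expression diversity E_d: hand value, nulls, scale invariance", {
  expect_equal(expression_diversity(c(1, 2, 3)), 0.5)  # sum|dev|=2, (n-1)Ep=4
  expect_equal(expression_diversity(rep(4, 10)), 0)
  x <- rgamma(20, 2, 1)
  expect_equal(expression_diversity(5 * x), expression_diversity(x))
  expect_true(is.na(expression_diversity(c(0, 0, 0))))
  expect_error(expression_diversity(3), "at least 2")
})

test_that("Q_ST variance-component closed forms and hand ANOVA oracle", {
  ## V_B = V_W by construction -> Q_ST = 1/3
  a <- c(0, 2); b <- c(sqrt(6), 2 + sqrt(6))
  q <- qst(c(a, b), rep(c("A", "B"), each = 2), n_perm = 0)
  expect_equal(q$qst, 1 / 3)
  expect_equal(q$vb, q$vw)
  ## identical group means -> V_B clamped, Q_ST 0
  q0 <- qst(c(1, 3, 1, 3), rep(c("A", "B"), each = 2), n_perm = 0)
  expect_equal(q0$qst, 0)
  ## toy 2x3 balanced design against a hand ANOVA decomposition
  x <- c(4, 6, 5, 10, 12, 14)
  g <- rep(c("A", "B"), each = 3)
  msw <- (sum((x[1:3] - 5)^2) + sum((x[4:6] - 12)^2)) / 4
  msb <- 3 * ((5 - 8.5)^2 + (12 - 8.5)^2) / 1
  vb <- (msb - msw) / 3
  qh <- qst(x, g, n_perm = 0)
  expect_equal(qh$vw, msw)
  expect_equal(qh$vb, vb)
  expect_equal(qh$qst, vb / (vb + 2 * msw))
  ## errors on degenerate grouping
  expect_error(qst(x, rep("A", 6)), "two groups")
  expect_error(qst(x, c("A", rep("B", 5))), ">= 2 samples")
})

test_that("Q_ST permutation p is reproducible and matrix version matches scalar", {
  set.seed(3)
  x <- rnorm(12)
  g <- rep(c("A", "B"), each = 6)
  p1 <- qst(x, g, n_perm = 200, seed = 9)
  p2 <- qst(x, g, n_perm = 200, seed = 9)
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0)
  expect_lte(p1$p, 1)
  X <- rbind(x, x + 1)
  qm <- qst_matrix(X, g, n_perm = 200, seed = 9)
  expect_equal(qm$qst[1], p1$qst)
  expect_equal(qm$p[1], p1$p)
  ## Q_ST invariant to affine rescaling
  expect_equal(qst(3 * x + 7, g, n_perm = 0)$qst, p1$qst)
})

test_that("DEG calling honours the strict fold-change boundary and thresholds", {
  ## identical values -> never a DEG
  expect_false(call_deg(c(10, 10), c(10, 10))$deg)
  ## fold change exactly 2 gives log2FC exactly 1, which fails strict > 1
  d <- call_deg(9, 19)  # (19+1)/(9+1) = 2
  expect_equal(d$log2fc, 1)
  expect_false(d$deg)
  ## a large shift with tiny p passes
  d2 <- call_deg(10, 200)
  expect_true(d2$deg)
  ## replicate route goes through the t-test
  d3 <- call_deg(c(10, 11, 9, 10), c(95, 100, 105, 102))
  expect_true(d3$deg)
})

test_that("matrix DEG p equals poisson.test's conditional binomial", {
  cases <- rbind(c(30, 70), c(5, 2), c(0, 0), c(12, 12), c(100, 45))
  p_mat <- call_deg_matrix(matrix(cases[, 1], ncol = 1),
                           matrix(cases[, 2], ncol = 1))$p
  for (i in seq_len(nrow(cases))) {
    want <- if (sum(cases[i, ]) == 0) 1 else
      poisson.test(c(cases[i, 2], cases[i, 1]))$p.value
    expect_equal(unname(p_mat[i, 1]), want, tolerance = 1e-10)
  }
})

test_that("DRG calling is the conjunction of per-genotype DEG and the paired t-test", {
  set.seed(21)
  n <- 30
  ck <- matrix(rlnorm(3 * n, 3, 0.2), nrow = 3)
  ## gene 1: DEG in several genotypes and consistent shift -> DRG
  dt <- ck
  dt[1, ] <- ck[1, ] * 5
  ## gene 2: one noisy genotype crosses the DEG threshold but the shift
  ## is not consistent -> paired t fails -> not a DRG
  dt[2, ] <- ck[2, ] * c(3, rep(1, n - 1)) * exp(rnorm(n, 0, 0.01))
  ## gene 3: consistent but tiny shift -> no DEG anywhere -> not a DRG
  dt[3, ] <- ck[3, ] * 1.1
  deg <- call_deg_matrix(ck, dt)
  drg <- call_drg(deg$deg, ck, dt)
  expect_true(drg$drg[1])
  expect_false(drg$drg[2])
  expect_false(drg$drg[3])
  expect_equal(drg$deg_count[3], 0)
})

test_that("planted DRGs are recovered and match the direct threshold oracle", {
  ds <- small_ds()
  deg <- call_deg_matrix(ds$expr_ck, ds$expr_dt)
  drg <- call_drg(deg$deg, ds$expr_ck, ds$expr_dt)
  expect_gte(mean(drg$drg[ds$truth$planted_drg]), 0.9)
  ## flag equals an independently coded threshold rule for a gene slice
  sel <- 1:40
  l2 <- log2((ds$expr_dt[sel, ] + 1) / (ds$expr_ck[sel, ] + 1))
  pp <- matrix(mapply(function(a, b) poisson.test(c(round(b), round(a)))$p.value,
                      ds$expr_ck[sel, ], ds$expr_dt[sel, ]), nrow = length(sel))
  expect_equal(unname(deg$deg[sel, ]), abs(l2) > 1 & pp < 0.05,
               ignore_attr = TRUE)
})

test_that("Q_ST-F_ST correlation handles exact and degenerate cases", {
  fst <- seq(0.1, 0.9, length.out = 20)
  qstv <- 0.3 + 0.5 * fst
  r <- qst_fst_correlation(qstv, fst)
  expect_equal(r$r, 1)
  expect_error(qst_fst_correlation(c(1, 2), c(1, 2)), ">= 3 genes")
  ## missing values dropped pairwise
  qstv[3] <- NA
  expect_equal(qst_fst_correlation(qstv, fst)$n, 19)
})

test_that("E_d and C.V. shrink when within-group variance shrinks", {
  set.seed(31)
  mu <- 50
  wide <- matrix(rlnorm(200 * 20, log(mu), 0.6), nrow = 200)
  narrow <- matrix(rlnorm(200 * 20, log(mu), 0.2), nrow = 200)
  ed_w <- apply(wide, 1, expression_diversity)
  ed_n <- apply(narrow, 1, expression_diversity)
  expect_gt(median(ed_w), median(ed_n))
  cv_w <- apply(wide, 1, expression_cv)
  cv_n <- apply(narrow, 1, expression_cv)
  expect_gt(median(cv_w), median(cv_n))
  ## the paired Wilcoxon reporting utility sees the difference
  expect_lt(compare_dispersion(ed_n, ed_w)$p.value, 1e-10)
})

test_that("expression_summary returns coherent per-gene statistics", {
  ds <- small_ds()
  es <- expression_summary(ds$expr_ck, ds$meta, n_perm = 100, seed = 1)
  expect_equal(nrow(es), nrow(ds$expr_ck))
  expect_true(all(es$ed_total >= 0, na.rm = TRUE))
  expect_true(all(es$qst_expr >= 0 & es$qst_expr <= 1))
  expect_true(all(es$qst_p > 0 & es$qst_p <= 1))
  ## planted TDSGs show elevated expression Q_ST
  expect_gt(median(es$qst_expr[ds$truth$planted_tdsg]),
            median(es$qst_expr[!ds$truth$planted_tdsg]))
})
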