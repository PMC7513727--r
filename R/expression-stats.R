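#' Expression diversity E_d
#'
#' `E_d = sum(|E_i - E_p|) / ((n - 1) * E_p)` with `E_p` the mean
#' expression over individuals: the mean absolute deviation scaled by
#' the mean. Dimensionless and invariant to positive rescaling.
#'
#' @param x numeric vector of FPKM values across individuals.
#' @return E_d, or NA for genes with zero mean expression.
#' @export
expression_diversity <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("E_d needs at least 2 individuals")
  ep <- mean(x)
  if (ep <= 0) return(NA_real_)
  sum(abs(x - ep)) / ((n - 1) * ep)
}

#' Coefficient of variation
#' @param x numeric vector.
#' @return sd(x)/mean(x), NA for zero-mean input.
#' @export
expression_cv <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

## internal: one-way method-of-moments variance components for one or
## many response rows. X: genes x samples matrix; g: factor.
## Returns list(vb, vw) with negative between-group components clamped
## to zero.
vc_oneway <- function(X, g) {
  g <- as.factor(g)
  k <- nlevels(g)
  N <- ncol(X)
  ind <- stats::model.matrix(~ g - 1)
  n_i <- colSums(ind)
  gs <- X %*% ind                      # group sums
  gm <- sweep(gs, 2, n_i, "/")         # group means
  tot <- rowSums(X)
  grand <- tot / N
  ssb <- rowSums(sweep(gm^2, 2, n_i, "*")) - N * grand^2
  sst <- rowSums(X^2) - N * grand^2
  ssw <- sst - ssb
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  ## `stat` is the continuous between/within ratio used to order
  ## permutations: the clamped Q_ST ties all no-signal genes at the
  ## zero boundary, which would make permutation p-values pile up at 1
  ## instead of being uniform under the null
  list(vb = pmax((msb - msw) / n0, 0), vw = msw,
       stat = ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0)))
}

#' Quantitative divergence Q_ST of a single variable
#'
#' `Q_ST = V_B / (V_B + 2 V_W)` with between- and within-group variance
#' components from one-way ANOVA method of moments (negative `V_B`
#' clamped to 0). The permutation p-value is the fraction of label
#' permutations whose divergence statistic reaches the observed one,
#' with add-one correction, so p is in (0, 1]; permutations are
#' ordered on the continuous between/within mean-square ratio (which
#' orders identically to the unclamped Q_ST), because the clamped
#' Q_ST ties every no-signal gene at the zero boundary and would
#' destroy the uniformity of null p-values.
#'
#' @param x numeric vector (trait values or one gene's expression).
#' @param groups group labels (2 or more groups, >= 2 samples each).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `qst`, `p`, `vb`, `vw`.
#' @export
qst <- function(x, groups, n_perm = 1000L, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("Q_ST needs at least two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  X <- matrix(x, nrow = 1)
  vc <- vc_oneway(X, groups)
  q_obs <- qst_from_vc(vc$vb, vc$vw)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      vp <- vc_oneway(X, sample(groups))
      if (vp$stat >= vc$stat) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(qst = q_obs, p = p, vb = vc$vb[1], vw = vc$vw[1])
}

## internal: Q_ST from variance components, 0 when totally degenerate
qst_from_vc <- function(vb, vw) {
  denom <- vb + 2 * vw
  ifelse(denom > 0, vb / denom, 0)
}

#' Q_ST and permutation p for every row of an expression matrix
#'
#' Vectorised version of [qst()]: identical statistics, one shared set
#' of label permutations across genes (the permutation null is on the
#' sample labels, which all genes share).
#'
#' @param X genes x samples numeric matrix.
#' @param groups group labels, length `ncol(X)`.
#' @inheritParams qst
#' @return data.frame with `qst`, `p`, `vb`, `vw`, one row per row of X.
#' @export
qst_matrix <- function(X, groups, n_perm = 1000L, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("Q_ST needs at least two groups")
  vc <- vc_oneway(X, groups)
  q_obs <- qst_from_vc(vc$vb, vc$vw)
  p <- rep(NA_real_, nrow(X))
  if (n_perm > 0) {
    set.seed(seed)
    hits <- integer(nrow(X))
    for (i in seq_len(n_perm)) {
      vp <- vc_oneway(X, sample(groups))
      hits <- hits + (vp$stat >= vc$stat)
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  data.frame(qst = q_obs, p = p, vb = vc$vb, vw = vc$vw)
}

#' Differential expression between conditions for one genotype
#'
#' Threshold logic: `|log2 FC| > 1` (strict, on pseudocount-stabilised
#' values, pseudocount 1) AND test p < alpha. With within-genotype
#' replicates the test is a Welch t-test on log2(FPKM + 1); with single
#' pooled samples per condition it is the exact conditional binomial
#' form of the two-sample Poisson rate test on rounded pseudocounted
#' values.
#'
#' @param ck,dt FPKM values under control and drought for one genotype
#'   (vectors of replicates, possibly length 1).
#' @param alpha significance level (default 0.05).
#' @return list with `deg` (logical), `log2fc`, `p`.
#' @export
call_deg <- function(ck, dt, alpha = 0.05) {
  l2fc <- log2((mean(dt) + 1) / (mean(ck) + 1))
  if (length(ck) >= 2 && length(dt) >= 2) {
    p <- tryCatch(
      stats::t.test(log2(dt + 1), log2(ck + 1))$p.value,
      error = function(e) 1)
  } else {
    p <- poisson_pair_p(round(sum(dt)), round(sum(ck)))
  }
  list(deg = abs(l2fc) > 1 & p < alpha, log2fc = l2fc, p = p)
}

## internal: exact two-sided p for H0 rate1 == rate2 given two Poisson
## counts, conditioning on the total (X1 | n ~ Binomial(n, 1/2)); the
## null is symmetric so the two-sided p is the symmetric tail sum.
## Vectorised.
poisson_pair_p <- function(x1, x2) {
  n <- x1 + x2
  m <- pmin(x1, x2)
  p <- stats::pbinom(m, n, 0.5) + (1 - stats::pbinom(n - m - 1, n, 0.5))
  p[n == 0] <- 1
  pmin(p, 1)
}

#' Per-genotype DEG calls for all genes (single-sample design)
#'
#' @param ck_mat,dt_mat FPKM matrices (genes x genotypes), matched
#'   columns.
#' @param alpha significance level.
#' @return list of genes x genotypes matrices `deg`, `log2fc`, `p`.
#' @export
call_deg_matrix <- function(ck_mat, dt_mat, alpha = 0.05) {
  stopifnot(all(dim(ck_mat) == dim(dt_mat)))
  l2fc <- log2((dt_mat + 1) / (ck_mat + 1))
  p <- poisson_pair_p(round(dt_mat), round(ck_mat))
  dim(p) <- dim(ck_mat)
  list(deg = abs(l2fc) > 1 & p < alpha, log2fc = l2fc, p = p)
}

#' Drought-responsive gene (DRG) calls
#'
#' A gene is a DRG iff it is a DEG in at least one genotype AND a
#' paired t-test across genotypes (CK vs DT sample pairs, on
#' log2(FPKM + 1)) gives p < alpha.
#'
#' @param deg genes x genotypes logical DEG matrix
#'   (from [call_deg_matrix()]).
#' @param ck_mat,dt_mat FPKM matrices (genes x genotypes).
#' @param alpha significance level.
#' @return list with logical `drg`, `deg_count` per gene, paired-t `p`.
#' @export
call_drg <- function(deg, ck_mat, dt_mat, alpha = 0.05) {
  stopifnot(all(dim(ck_mat) == dim(dt_mat)), all(dim(deg) == dim(ck_mat)))
  d <- log2(dt_mat + 1) - log2(ck_mat + 1)
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1))
  tt <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  p[sdd == 0 & md == 0] <- 1
  deg_count <- rowSums(deg)
  list(drg = deg_count >= 1 & !is.na(p) & p < alpha,
       deg_count = deg_count, p = p)
}

#' Correlation between expression Q_ST and sequence F_ST across genes
#'
#' @param qst,fst per-gene values (same order); genes with either value
#'   missing are dropped.
#' @return list with `r`, `p`, `n`.
#' @export
qst_fst_correlation <- function(qst, fst) {
  ok <- !is.na(qst) & !is.na(fst)
  if (sum(ok) < 3) stop("need >= 3 genes with both Q_ST and F_ST defined")
  ct <- stats::cor.test(qst[ok], fst[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Paired Wilcoxon comparison of dispersion statistics
#'
#' Reporting utility for comparing per-gene C.V. or E_d between two
#' conditions (paired over genes) by Wilcoxon signed-rank test.
#'
#' @param x,y per-gene dispersion values under the two conditions.
#' @return `htest` object.
#' @export
compare_dispersion <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::wilcox.test(x[ok], y[ok], paired = TRUE)
}

#' Per-gene expression summary table
#'
#' E_d (total and per ecotype), C.V., expression Q_ST between ecotypes
#' with permutation p. E_d and C.V. are computed on FPKM (the scale the
#' statistics are defined on); Q_ST variance components on
#' log2(FPKM + 1) for variance stabilisation.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param meta sample metadata (`sample`, `ecotype`).
#' @param n_perm,seed permutation settings for Q_ST.
#' @return data.frame, one row per gene.
#' @export
expression_summary <- function(expr, meta, n_perm = 1000L, seed = 1L) {
  stopifnot(all(colnames(expr) == meta$sample))
  up <- meta$ecotype == "upland"
  ed_of <- function(m) {
    n <- ncol(m)
    ep <- rowMeans(m)
    ifelse(ep > 0, rowSums(abs(m - ep)) / ((n - 1) * ep), NA_real_)
  }
  cv <- ifelse(rowMeans(expr) > 0,
               apply(expr, 1, stats::sd) / rowMeans(expr), NA_real_)
  q <- qst_matrix(log2(expr + 1), meta$ecotype, n_perm = n_perm, seed = seed)
  data.frame(
    gene_id = rownames(expr),
    ed_total = ed_of(expr),
    ed_upland = ed_of(expr[, up, drop = FALSE]),
    ed_lowland = ed_of(expr[, !up, drop = FALSE]),
    cv = cv,
    qst_expr = q$qst, qst_p = q$p, vb = q$vb, vw = q$vw,
    stringsAsFactors = FALSE
  )
}
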