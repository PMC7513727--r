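#' Between-ecotype Welch t-test per gene
#'
#' Two-sample unequal-variance t-test of log2(FPKM + 1) between typical
#' upland and typical lowland samples, vectorised over genes. Ecotype
#' variances are allowed to differ (upland panels are systematically
#' more variable), hence Welch.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param meta sample metadata (`sample`, `ecotype`, `typical`).
#' @param typical_only restrict to typical samples (default TRUE).
#' @return data.frame with per-gene `t`, `p`, `mean_upland`,
#'   `mean_lowland` (log2 scale).
#' @export
ecotype_ttest <- function(expr, meta, typical_only = TRUE) {
  stopifnot(all(colnames(expr) == meta$sample))
  keep <- if (typical_only) meta$typical else rep(TRUE, nrow(meta))
  up <- keep & meta$ecotype == "upland"
  low <- keep & meta$ecotype == "lowland"
  n1 <- sum(up); n2 <- sum(low)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per ecotype")
  y <- log2(expr + 1)
  m1 <- rowMeans(y[, up, drop = FALSE])
  m2 <- rowMeans(y[, low, drop = FALSE])
  v1 <- rowSums((y[, up, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, low, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- ifelse(abs(m1 - m2)[se2 == 0] > 0, 0, 1)
  data.frame(gene_id = rownames(expr), t = tt, p = p,
             mean_upland = m1, mean_lowland = m2, stringsAsFactors = FALSE)
}

#' Between-individual variance from the nested mixed model
#'
#' The between-individual variance of each gene is the residual
#' variance after removing random origin and ecotype effects. With
#' origins nested within ecotypes the method-of-moments (Henderson III)
#' estimator of the residual component is the pooled within-origin mean
#' square of log2(FPKM + 1); centring on origin means removes both
#' random factors. Non-negative by construction; REML on the same model
#' gives the cross-check in the test-suite.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param meta sample metadata (`sample`, `ecotype`, `origin`).
#' @return numeric vector of per-gene between-individual variances.
#' @export
between_individual_variance <- function(expr, meta) {
  stopifnot(all(colnames(expr) == meta$sample))
  y <- log2(expr + 1)
  f <- as.factor(paste(meta$ecotype, meta$origin, sep = "/"))
  ind <- stats::model.matrix(~ f - 1)
  n_i <- colSums(ind)
  if (any(n_i < 2)) warning("origin level(s) with a single sample")
  gm <- (y %*% ind) %*% diag(1 / n_i, length(n_i))
  resid2 <- rowSums(y^2) - rowSums(sweep(gm^2, 2, n_i, "*"))
  biv <- pmax(resid2 / (ncol(y) - nlevels(f)), 0)
  names(biv) <- rownames(expr)
  biv
}

#' Low-variance cutoff from the ranked variance curve
#'
#' Between-individual variances are sorted in decreasing order against
#' rank. A least-squares line is fitted through the top 1% of genes
#' (the steep high-variance tail) and another through the bottom 80%
#' (the shallow bulk); the cutoff is the variance value of the sorted
#' curve at the intersection rank of the two lines. If the lines are
#' parallel or intersect outside the rank range, the fallback is the
#' boundary rank between the two fitted segments, with a warning.
#'
#' @param biv numeric vector of between-individual variances (>= 200
#'   genes).
#' @param top_frac,bottom_frac segment definitions (defaults 0.01 and
#'   0.80).
#' @return list with `cutoff`, `rank` (intersection rank) and the two
#'   fitted lines.
#' @export
variance_cutoff <- function(biv, top_frac = 0.01, bottom_frac = 0.80) {
  biv <- biv[!is.na(biv)]
  n <- length(biv)
  if (n < 200) stop("variance cutoff needs >= 200 genes")
  v <- sort(biv, decreasing = TRUE)
  r <- seq_len(n)
  k_top <- max(2L, ceiling(top_frac * n))
  k_bot <- floor(bottom_frac * n)
  i_top <- seq_len(k_top)
  i_bot <- seq.int(n - k_bot + 1L, n)
  f1 <- stats::lm.fit(cbind(1, r[i_top]), v[i_top])$coefficients
  f2 <- stats::lm.fit(cbind(1, r[i_bot]), v[i_bot])$coefficients
  denom <- f1[2] - f2[2]
  fallback <- FALSE
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    fallback <- TRUE
  } else {
    r_star <- (f2[1] - f1[1]) / denom
    if (!is.finite(r_star) || r_star < 1 || r_star > n) fallback <- TRUE
  }
  if (fallback) {
    warning("rank-variance segments parallel or non-intersecting; ",
            "falling back to the segment boundary")
    r_star <- n - k_bot + 1L
  }
  rank_star <- min(max(round(r_star), 1L), n)
  list(cutoff = unname(v[rank_star]), rank = rank_star,
       line_top = unname(f1), line_bottom = unname(f2),
       fallback = fallback)
}

#' Call transcriptionally selected genes (TDSGs)
#'
#' Flag iff the between-ecotype test p-value is below `alpha` (high
#' interspecies divergence) AND the between-individual variance is at
#' most the rank-curve cutoff (low within-ecotype, between-individual
#' variance). Run separately per condition.
#'
#' @param t_p per-gene between-ecotype p-values.
#' @param biv per-gene between-individual variances.
#' @param cutoff variance cutoff (from [variance_cutoff()]).
#' @param alpha significance level (default 0.05).
#' @return logical flag vector.
#' @export
call_tdsg <- function(t_p, biv, cutoff, alpha = 0.05) {
  stopifnot(length(t_p) == length(biv))
  !is.na(t_p) & t_p < alpha & !is.na(biv) & biv <= cutoff
}

#' Expression selection index (SI)
#'
#' McDonald-Kreitman-style contrast of expression variance ratios
#' against neutral sequence variation:
#' `SI = 1 - (V_w * D_xy) / (V_b * pi)`, with `V_w`/`V_b` the within-
#' and between-ecotype expression variance components and `pi`/`D_xy`
#' the within-ecotype polymorphism and between-ecotype divergence of
#' the gene's own region. SI = 0 when the expression ratio matches the
#' neutral sequence expectation; positive SI (bounded above by 1)
#' indicates directional selection on expression. Genes with `pi = 0`
#' or `V_b = 0` get a missing SI.
#'
#' @param vw,vb expression variance components (within/between ecotype).
#' @param pi within-ecotype nucleotide diversity (mean of the two
#'   ecotypes) of the gene region.
#' @param dxy between-ecotype divergence of the gene region.
#' @return numeric vector of SI values (NA where undefined).
#' @export
selection_index <- function(vw, vb, pi, dxy) {
  ifelse(!is.na(vb) & vb > 0 & !is.na(pi) & pi > 0 & !is.na(dxy),
         1 - (vw * dxy) / (vb * pi), NA_real_)
}

#' Full TDSG scan for one condition
#'
#' Runs the between-ecotype t-test, the mixed-model between-individual
#' variance, the rank-curve cutoff and the conjunction call, and
#' attaches the selection index computed against the per-gene sequence
#' statistics.
#'
#' @param expr FPKM matrix for one condition (genes x samples).
#' @param meta sample metadata.
#' @param popgen per-gene [popgen_scan()] table (matched by gene id),
#'   or NULL to skip SI.
#' @param alpha significance level for the divergence test.
#' @return data.frame, one row per gene: `t_p`, `biv`, `cutoff`,
#'   `tdsg`, `si`, variance components.
#' @export
tdsg_scan <- function(expr, meta, popgen = NULL, alpha = 0.05) {
  tt <- ecotype_ttest(expr, meta, typical_only = TRUE)
  biv <- between_individual_variance(expr, meta)
  vcut <- variance_cutoff(biv)
  flag <- call_tdsg(tt$p, biv, vcut$cutoff, alpha = alpha)
  vc <- vc_oneway(log2(expr + 1), meta$ecotype)
  out <- data.frame(
    gene_id = tt$gene_id, t_p = tt$p, biv = unname(biv),
    cutoff = vcut$cutoff, tdsg = flag,
    vb_expr = vc$vb, vw_expr = vc$vw,
    si = NA_real_, stringsAsFactors = FALSE
  )
  if (!is.null(popgen)) {
    m <- match(out$gene_id, popgen$gene_id)
    pi_within <- (popgen$pi_upland[m] + popgen$pi_lowland[m]) / 2
    out$si <- selection_index(vc$vw, vc$vb, pi_within, popgen$dxy[m])
  }
  out
}
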