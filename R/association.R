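#' Trait-level divergence profile: Q_ST versus neutral F_ST
#'
#' Q_ST of each trait between ecotypes (variance-component form with
#' permutation p-values) compared against the neutral genomic F_ST
#' band from intergenic SNPs (mean +/- `band_sd` bootstrap SEs). A
#' trait is flagged divergently selected when its Q_ST exceeds the
#' upper edge of the neutral band and its permutation p is below
#' `alpha`.
#'
#' @param traits trait data.frame (`sample` column plus numeric trait
#'   columns).
#' @param meta sample metadata (`sample`, `ecotype`).
#' @param neutral list from [neutral_fst()] (`mean`, `se`).
#' @param n_perm,seed permutation settings.
#' @param band_sd half-width of the neutral band in bootstrap SEs
#'   (default 2).
#' @param alpha permutation significance level (default 0.05).
#' @return data.frame: trait, qst, p, vb, vw, neutral mean/band,
#'   `divergent` flag.
#' @export
trait_qst_profile <- function(traits, meta, neutral,
                              n_perm = 1000L, seed = 1L,
                              band_sd = 2, alpha = 0.05) {
  stopifnot(all(traits$sample == meta$sample))
  num <- vapply(traits, is.numeric, logical(1))
  X <- t(as.matrix(traits[, num, drop = FALSE]))
  q <- qst_matrix(X, meta$ecotype, n_perm = n_perm, seed = seed)
  upper <- neutral$mean + band_sd * neutral$se
  data.frame(
    trait = rownames(X),
    qst = q$qst, p = q$p, vb = q$vb, vw = q$vw,
    neutral_fst = neutral$mean, neutral_upper = upper,
    divergent = q$qst > upper & q$p < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-trait gene sets by expression-trait correlation
#'
#' Pearson correlation of every gene's expression (FPKM) with every
#' trait among typical genotypes; genes with p < alpha form the
#' trait-correlated set. Benjamini-Hochberg q-values are emitted
#' alongside. Constant genes are excluded (reported missing).
#'
#' @param expr FPKM matrix (genes x samples).
#' @param traits trait data.frame (`sample` plus numeric columns).
#' @param meta sample metadata (`sample`, `typical`).
#' @param typical_only restrict to typical samples (default TRUE).
#' @param alpha per-test significance level (default 0.05).
#' @return list of per-trait data.frames (`gene_id`, `r`, `p`, `q`,
#'   `in_set`), plus attribute-free helper columns.
#' @export
trait_correlated_genes <- function(expr, traits, meta,
                                   typical_only = TRUE, alpha = 0.05) {
  stopifnot(all(colnames(expr) == meta$sample),
            all(traits$sample == meta$sample))
  keep <- if (typical_only) meta$typical else rep(TRUE, nrow(meta))
  X <- expr[, keep, drop = FALSE]
  n <- ncol(X)
  sdx <- apply(X, 1, stats::sd)
  num <- names(traits)[vapply(traits, is.numeric, logical(1))]
  out <- list()
  for (tr in num) {
    y <- traits[[tr]][keep]
    if (stats::sd(y) == 0) next
    r <- suppressWarnings(as.numeric(stats::cor(t(X), y)))
    r[sdx == 0] <- NA_real_
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    q <- stats::p.adjust(p, method = "BH")
    out[[tr]] <- data.frame(
      gene_id = rownames(expr), r = r, p = p, q = q,
      in_set = !is.na(p) & p < alpha, stringsAsFactors = FALSE
    )
  }
  out
}

#' Correlation of TDSG enrichment ratios with trait Q_ST
#'
#' For each trait, the ratio of trait-correlated genes inside the TDSG
#' set over the TDSG set size; Pearson correlation of these ratios
#' against the traits' Q_ST values across traits.
#'
#' @param trait_sets list from [trait_correlated_genes()].
#' @param tdsg_genes character vector of TDSG gene ids.
#' @param trait_qst data.frame from [trait_qst_profile()] (`trait`,
#'   `qst`).
#' @return list with per-trait `ratio` table and `r`, `p` of the
#'   correlation (NA with a message when ratios are constant).
#' @export
ratio_vs_qst_correlation <- function(trait_sets, tdsg_genes, trait_qst) {
  if (length(tdsg_genes) == 0) stop("empty TDSG set")
  traits <- intersect(names(trait_sets), trait_qst$trait)
  ratio <- vapply(traits, function(tr) {
    s <- trait_sets[[tr]]
    sum(s$in_set & s$gene_id %in% tdsg_genes) / length(tdsg_genes)
  }, numeric(1))
  qv <- trait_qst$qst[match(traits, trait_qst$trait)]
  tab <- data.frame(trait = traits, ratio = unname(ratio), qst = qv,
                    stringsAsFactors = FALSE)
  if (length(traits) < 3 || stats::sd(ratio) == 0 || stats::sd(qv) == 0)
    return(list(table = tab, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(ratio, qv)
  list(table = tab, r = unname(ct$estimate), p = ct$p.value)
}

#' Drought-tolerance / tillering trade-off genes
#'
#' Genes whose expression is oppositely correlated with leaf relative
#' water content under drought (RWC-DT) and tiller number under
#' control (NT-CK), both at FDR < `fdr`: `q_RWC < fdr`, `q_NT < fdr`
#' and `sign(r_RWC) == -sign(r_NT)`.
#'
#' @param rwc_tab,nt_tab per-gene correlation tables for RWC-DT and
#'   NT-CK (from [trait_correlated_genes()]).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame of trade-off genes with both correlations.
#' @export
tradeoff_genes <- function(rwc_tab, nt_tab, fdr = 0.05) {
  stopifnot(all(rwc_tab$gene_id == nt_tab$gene_id))
  sel <- !is.na(rwc_tab$q) & !is.na(nt_tab$q) &
    rwc_tab$q < fdr & nt_tab$q < fdr &
    sign(rwc_tab$r) == -sign(nt_tab$r) & rwc_tab$r != 0 & nt_tab$r != 0
  data.frame(
    gene_id = rwc_tab$gene_id[sel],
    r_rwc_dt = rwc_tab$r[sel], q_rwc_dt = rwc_tab$q[sel],
    r_nt_ck = nt_tab$r[sel], q_nt_ck = nt_tab$q[sel],
    stringsAsFactors = FALSE
  )
}

#' Fisher exact enrichment of one gene set in another
#'
#' 2x2 table of membership in `set_a` vs `set_b` over `universe`;
#' hypergeometric-exact p (via [stats::fisher.test()]) and the
#' sample odds ratio `(n11*n00)/(n10*n01)`. Two-sided by default, with
#' the one-sided enrichment alternative available.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector of all gene ids under study.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list: the 2x2 `table`, `odds_ratio` (sample OR; NA when a
#'   margin is empty), `p`.
#' @export
fisher_enrichment <- function(set_a, set_b, universe,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  a <- universe %in% set_a
  b <- universe %in% set_b
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  tab <- matrix(c(n11, n01, n10, n00), 2, 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  or <- if (n10 * n01 > 0) (n11 * n00) / (n10 * n01) else NA_real_
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(table = tab, odds_ratio = or, p = p)
}

#' Direction consistency of RWC-correlated selected genes
#'
#' Each RWC-correlated drought-responsive TDSG is classified by the
#' sign of its RWC correlation and the sign of its upland-minus-lowland
#' mean expression; Fisher's exact test of association between the two
#' signs asks whether positively RWC-correlated genes tend to be
#' expressed higher in upland material (and negatively correlated ones
#' lower). Genes with zero mean difference are excluded.
#'
#' @param genes gene ids to classify (e.g. RWC-correlated D-TDSGs).
#' @param rwc_tab per-gene RWC-DT correlation table.
#' @param mean_upland,mean_lowland named per-gene ecotype mean
#'   expression (log2 scale).
#' @param alternative passed to [stats::fisher.test()] (default
#'   "greater": positive association).
#' @return list: 2x2 `table` (RWC sign x expression-difference sign),
#'   `odds_ratio`, `p`, `n_excluded`.
#' @export
rwc_direction_consistency <- function(genes, rwc_tab, mean_upland,
                                      mean_lowland,
                                      alternative = "greater") {
  m <- match(genes, rwc_tab$gene_id)
  r <- rwc_tab$r[m]
  d <- mean_upland[genes] - mean_lowland[genes]
  ok <- !is.na(r) & r != 0 & !is.na(d) & d != 0
  n_excluded <- sum(!ok)
  tab <- table(rwc_sign = r[ok] > 0, up_higher = d[ok] > 0)
  if (!all(dim(tab) == c(2, 2)))
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_,
                n_excluded = n_excluded))
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  list(table = tab, odds_ratio = or, p = ft$p.value,
       n_excluded = n_excluded)
}
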