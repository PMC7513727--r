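#' Run the full divergence pipeline on a dataset bundle
#'
#' Executes the per-gene popgen scan (pi, D_xy, F_ST, HDG and sweep
#' calls), the expression summaries (E_d, C.V., expression Q_ST),
#' DEG/DRG calling, the TDSG scan with selection index for both
#' conditions, the cis-element-altering SNP scan with haplotype-level
#' expression comparisons for highly differentiated hub genes, the
#' co-expression network on drought-responsive TDSGs, and the trait
#' association stage. Writes per-stage TSVs, a joined per-gene master
#' table and a run manifest when `out_dir` is given. Fully
#' deterministic given `seed`.
#'
#' @param data dataset bundle from [simulate_dataset()] or
#'   [read_dataset()].
#' @param out_dir optional output directory.
#' @param seed integer seed for all permutation/bootstrap stages.
#' @param n_perm permutations for Q_ST p-values (default 1000).
#' @param alpha significance level for the p < .05 rules.
#' @param fdr FDR threshold for trade-off gene calls.
#' @param hdg_quantile HDG F_ST quantile (default 0.95).
#' @param dsg_tail pi/D_xy lower tail (default 0.05).
#' @param softpower,min_module_size,merge_distance,edge_threshold,hub_fraction
#'   network parameters.
#' @param max_haplotype_genes cap on genes taken into the
#'   haplotype-vs-ecotype comparison (default 15).
#' @return list with all stage results, the `master` table and the
#'   applied-threshold `log`.
#' @export
run_pipeline <- function(data, out_dir = NULL, seed = 1L,
                         n_perm = 1000L, alpha = 0.05, fdr = 0.05,
                         hdg_quantile = 0.95, dsg_tail = 0.05,
                         softpower = 6, min_module_size = 30L,
                         merge_distance = 0.20, edge_threshold = 0.01,
                         hub_fraction = 0.15,
                         max_haplotype_genes = 15L) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  meta <- data$meta
  up <- meta$sample[meta$ecotype == "upland"]
  low <- meta$sample[meta$ecotype == "lowland"]

  ## --- 1. popgen ----------------------------------------------------
  pg <- popgen_scan(data$geno, data$sites, data$regions, meta)
  ig <- data$sites$zone == "intergenic"
  neutral <- neutral_fst(data$geno[ig, , drop = FALSE], up, low,
                         seed = derive_seed(seed, 11L))
  hdg <- call_hdg(pg$fst, probs = hdg_quantile)
  pg$hdg <- hdg$flag
  note("HDG threshold: F_ST > ", signif(hdg$threshold, 4),
       " (empirical ", hdg_quantile * 100, "th percentile)")
  scan_u <- pi_dxy_scan(pg$ratio_upland, pg$gene_id, tail = dsg_tail)
  scan_l <- pi_dxy_scan(pg$ratio_lowland, pg$gene_id, tail = dsg_tail)
  pg$u_dsg <- scan_u$flag
  pg$l_dsg <- scan_l$flag
  note("pi/D_xy lower tail: ", dsg_tail * 100, "% (",
       scan_u$n_excluded, " genes with D_xy=0 excluded)")
  gene_pos <- (data$regions$start + data$regions$end) / 2
  dens <- list(
    hdg = density_uniformity_test(gene_pos[pg$hdg], data$genome_length),
    u_dsg = density_uniformity_test(gene_pos[pg$u_dsg], data$genome_length),
    l_dsg = density_uniformity_test(gene_pos[pg$l_dsg], data$genome_length)
  )

  ## --- 2. expression summaries --------------------------------------
  es_ck <- expression_summary(data$expr_ck, meta, n_perm = n_perm,
                              seed = derive_seed(seed, 21L))
  es_dt <- expression_summary(data$expr_dt, meta, n_perm = n_perm,
                              seed = derive_seed(seed, 22L))
  note("expression Q_ST permutations: ", n_perm)

  ## --- 3. DEG / DRG -------------------------------------------------
  deg <- call_deg_matrix(data$expr_ck, data$expr_dt, alpha = alpha)
  drg <- call_drg(deg$deg, data$expr_ck, data$expr_dt, alpha = alpha)
  note("DEG rule: |log2FC| > 1 and p < ", alpha,
       "; DRG rule: DEG in >= 1 genotype and paired t p < ", alpha)

  ## --- 4. TDSG scan per condition -----------------------------------
  td_ck <- tdsg_scan(data$expr_ck, meta, popgen = pg, alpha = alpha)
  td_dt <- tdsg_scan(data$expr_dt, meta, popgen = pg, alpha = alpha)
  note("TDSG variance cutoffs: CK ", signif(td_ck$cutoff[1], 4),
       ", DT ", signif(td_dt$cutoff[1], 4))
  tdsg_any <- td_ck$tdsg | td_dt$tdsg

  ## --- 5. cis-element-altering SNPs ---------------------------------
  cis <- classify_cis_snps(data$promoters, data$promoter_snps,
                           data$motifs)
  cis_genes <- unique(cis$gene_id)
  has_cis <- data$regions$gene_id %in% cis_genes
  note(length(unique(cis$snp_id)), " cis-altering SNPs in ",
       length(cis_genes), " genes")

  ## --- 6. network on drought-responsive TDSGs -----------------------
  net_genes <- data$regions$gene_id[tdsg_any & drg$drg]
  net <- NULL
  mt_cor <- NULL
  if (length(net_genes) >= 2L * min_module_size) {
    net <- coexpression_network(
      data$expr_dt[net_genes, , drop = FALSE],
      softpower = softpower, min_module_size = min_module_size,
      merge_distance = merge_distance, edge_threshold = edge_threshold,
      hub_fraction = hub_fraction)
    if (ncol(net$eigengenes) > 0)
      mt_cor <- module_trait_correlation(net$eigengenes, data$traits)
    note("network: ", length(net_genes), " drought-responsive TDSGs, ",
         net$n_modules, " modules (softpower ", softpower,
         ", min size ", min_module_size, ", merge ", merge_distance,
         ", edge ", edge_threshold, ", hub top ",
         hub_fraction * 100, "%)")
  } else {
    note("network skipped: only ", length(net_genes),
         " drought-responsive TDSGs")
  }

  ## --- 7. trait associations ----------------------------------------
  tq <- trait_qst_profile(data$traits, meta, neutral, n_perm = n_perm,
                          seed = derive_seed(seed, 31L), alpha = alpha)
  trait_names <- setdiff(names(data$traits), "sample")
  ck_traits <- grepl("_CK$", trait_names)
  sets_ck <- trait_correlated_genes(
    data$expr_ck, data$traits[, c("sample", trait_names[ck_traits])],
    meta, alpha = alpha)
  sets_dt <- trait_correlated_genes(
    data$expr_dt, data$traits[, c("sample", trait_names[!ck_traits])],
    meta, alpha = alpha)
  trait_sets <- c(sets_ck, sets_dt)
  tdsg_ids <- data$regions$gene_id[tdsg_any]
  ratio_cor <- if (length(tdsg_ids))
    ratio_vs_qst_correlation(trait_sets, tdsg_ids, tq) else NULL
  tradeoff <- tradeoff_genes(trait_sets[["RWC_DT"]],
                             trait_sets[["NT_CK"]], fdr = fdr)
  note(nrow(tradeoff), " RWC-DT/NT-CK trade-off genes at FDR < ", fdr)

  universe <- data$regions$gene_id
  drg_ids <- universe[drg$drg]
  enrich <- list(
    drg_in_tdsg = fisher_enrichment(drg_ids, tdsg_ids, universe,
                                    alternative = "greater"),
    cis_in_tdsg = fisher_enrichment(cis_genes, tdsg_ids, universe,
                                    alternative = "greater"),
    tradeoff_in_tdsg = fisher_enrichment(tradeoff$gene_id, tdsg_ids,
                                         universe,
                                         alternative = "greater")
  )
  d_tdsg_ids <- universe[td_dt$tdsg & drg$drg]
  rwc_dir <- NULL
  if (length(d_tdsg_ids) >= 4) {
    y <- log2(data$expr_dt + 1)
    mu_up <- rowMeans(y[, meta$ecotype == "upland", drop = FALSE])
    mu_low <- rowMeans(y[, meta$ecotype == "lowland", drop = FALSE])
    rwc_cor_genes <- with(trait_sets[["RWC_DT"]], gene_id[in_set])
    rwc_dir <- rwc_direction_consistency(
      intersect(d_tdsg_ids, rwc_cor_genes), trait_sets[["RWC_DT"]],
      mu_up, mu_low)
  }

  ## --- 8. haplotype vs ecotype Q_ST for hub HDGs with cis SNPs ------
  hap <- NULL
  if (!is.null(net)) {
    hub_ids <- names(net$hub)[net$hub]
    cand <- intersect(intersect(hub_ids, universe[pg$hdg]), cis_genes)
    cand <- utils::head(cand, max_haplotype_genes)
    if (length(cand)) {
      y <- log2(data$expr_dt + 1)
      hap <- do.call(rbind, lapply(cand, function(g) {
        snps <- unique(cis$snp_id[cis$gene_id == g])
        h <- assign_haplotypes(data$geno[snps, , drop = FALSE])
        r <- haplotype_vs_ecotype_qst(
          y[g, ], h, meta$ecotype, n_perm = n_perm,
          seed = derive_seed(seed, 41L))
        if (is.null(r)) return(NULL)
        data.frame(gene_id = g, qst_hap = r$qst_hap, qst_eco = r$qst_eco,
                   q95_perm = r$q95_perm, flag = r$flag,
                   n_groups = r$n_groups, n_excluded = r$n_excluded,
                   stringsAsFactors = FALSE)
      }))
    }
  }

  ## --- 9. master table ----------------------------------------------
  master <- pg
  master$ed_ck <- es_ck$ed_total
  master$ed_dt <- es_dt$ed_total
  master$cv_ck <- es_ck$cv
  master$cv_dt <- es_dt$cv
  master$qst_expr_ck <- es_ck$qst_expr
  master$qst_expr_p_ck <- es_ck$qst_p
  master$qst_expr_dt <- es_dt$qst_expr
  master$qst_expr_p_dt <- es_dt$qst_p
  master$deg_count <- drg$deg_count
  master$drg <- drg$drg
  master$t_p_ck <- td_ck$t_p
  master$t_p_dt <- td_dt$t_p
  master$biv_ck <- td_ck$biv
  master$biv_dt <- td_dt$biv
  master$tdsg_ck <- td_ck$tdsg
  master$tdsg_dt <- td_dt$tdsg
  master$si_ck <- td_ck$si
  master$si_dt <- td_dt$si
  master$n_cis_snps <- as.integer(table(
    factor(cis$gene_id[!duplicated(cis$snp_id)], levels = universe)))
  master$has_cis <- has_cis
  master$module <- if (!is.null(net))
    as.integer(net$module[match(universe, names(net$module))]) else
      NA_integer_
  master$hub <- if (!is.null(net))
    net$hub[match(universe, names(net$hub))] else NA

  res <- list(
    popgen = pg, neutral_fst = neutral, hdg_threshold = hdg$threshold,
    density = dens, expr_summary_ck = es_ck, expr_summary_dt = es_dt,
    deg = deg, drg = drg, tdsg_ck = td_ck, tdsg_dt = td_dt,
    cis = cis, network = net, module_trait = mt_cor,
    trait_qst = tq, trait_sets = trait_sets, ratio_cor = ratio_cor,
    tradeoff = tradeoff, enrichment = enrich, rwc_direction = rwc_dir,
    haplotype = hap, master = master, log = log, seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_tsv(pg, p("popgen.tsv"))
    write_tsv(es_ck, p("expression_ck_summary.tsv"))
    write_tsv(es_dt, p("expression_dt_summary.tsv"))
    write_tsv(td_ck, p("tdsg_ck.tsv"))
    write_tsv(td_dt, p("tdsg_dt.tsv"))
    write_tsv(cis, p("cis_snps.tsv"))
    if (!is.null(hap)) write_tsv(hap, p("haplotype_qst.tsv"))
    write_tsv(tq, p("trait_qst.tsv"))
    write_tsv(tradeoff, p("tradeoff_genes.tsv"))
    enr_df <- do.call(rbind, lapply(names(enrich), function(nm) {
      e <- enrich[[nm]]
      data.frame(comparison = nm, n11 = e$table[1, 1],
                 odds_ratio = e$odds_ratio, p = e$p,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(enr_df, p("enrichment.tsv"))
    if (!is.null(net)) {
      write_tsv(data.frame(gene_id = names(net$module),
                           module = as.integer(net$module),
                           hub = net$hub, stringsAsFactors = FALSE),
                p("modules.tsv"))
      if (ncol(net$eigengenes) > 0) {
        eg <- data.frame(sample = meta$sample, net$eigengenes,
                         check.names = FALSE)
        write_tsv(eg, p("eigengenes.tsv"))
      }
      if (!is.null(mt_cor)) {
        mt <- data.frame(module = rownames(mt_cor$r), mt_cor$r,
                         check.names = FALSE)
        write_tsv(mt, p("module_trait_cor.tsv"))
      }
    }
    write_tsv(master, p("master.tsv"))
    manifest <- list(
      package = "ecodiverge",
      version = as.character(utils::packageVersion("ecodiverge")),
      seed = seed,
      parameters = list(
        n_perm = n_perm, alpha = alpha, fdr = fdr,
        hdg_quantile = hdg_quantile, dsg_tail = dsg_tail,
        softpower = softpower, min_module_size = min_module_size,
        merge_distance = merge_distance, edge_threshold = edge_threshold,
        hub_fraction = hub_fraction),
      thresholds_applied = log
    )
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA),
               p("manifest.json"))
  }
  res
}
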