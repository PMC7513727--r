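#!/usr/bin/env Rscript

## Stage 3: score every caller against the planted ground truth.
##
## Sensitivity and false-discovery rates for HDGs, sweep genes, TDSGs,
## DRGs and trade-off genes; adjusted Rand index of the recovered
## co-expression modules; selection-index summary; the direction
## checks (positive SI of planted TDSGs, opposed RWC/NT module
## correlations, elevated F_ST of planted TDSGs). Writes
## results/recovery_summary.tsv.

suppressPackageStartupMessages(library(ecodiverge))

ds <- read_dataset("results/data")
tr <- ds$truth
pg <- read_tsv("results/pipeline/popgen.tsv")
td_ck <- read_tsv("results/pipeline/tdsg_ck.tsv")
master <- read_tsv("results/pipeline/master.tsv")
tradeoff <- read_tsv("results/pipeline/tradeoff_genes.tsv")
modules <- read_tsv("results/pipeline/modules.tsv")

sens <- function(called, planted) mean(called[planted])
fdr <- function(called, planted) mean(!planted[called])

mod_genes <- tr$planted_module > 0
det <- modules$module[match(tr$gene_id[mod_genes], modules$gene_id)]
det[is.na(det)] <- 0L
ari <- adjusted_rand_index(det, tr$planted_module[mod_genes])

si <- td_ck$si[tr$planted_tdsg]
si <- si[!is.na(si)]

summary <- data.frame(
  quantity = c("hdg_sensitivity", "sweep_sensitivity_upland",
               "sweep_sensitivity_lowland", "tdsg_sensitivity_ck",
               "tdsg_fdr_ck", "drg_sensitivity", "tradeoff_sensitivity",
               "module_ari", "mean_si_planted_tdsg_ck",
               "mean_fst_planted_tdsg", "mean_fst_genomic"),
  value = c(
    sens(pg$hdg, tr$planted_hdg),
    sens(pg$u_dsg, tr$planted_sweep_upland),
    sens(pg$l_dsg, tr$planted_sweep_lowland),
    sens(td_ck$tdsg, tr$planted_tdsg),
    fdr(td_ck$tdsg, tr$planted_tdsg),
    sens(master$drg, tr$planted_drg),
    mean(tr$gene_id[tr$planted_tradeoff] %in% tradeoff$gene_id),
    ari,
    mean(si),
    mean(pg$fst[tr$planted_tdsg], na.rm = TRUE),
    mean(pg$fst, na.rm = TRUE)
  )
)
write_tsv(summary, "results/recovery_summary.tsv")
print(summary, digits = 3, row.names = FALSE)

cat("\nSI of planted TDSGs positive:",
    mean(si) > 0 && quantile(replicate(
      1000, mean(sample(si, length(si), TRUE))), 0.025) > 0, "\n")
cat("F_ST of planted TDSGs above the genomic mean:",
    mean(pg$fst[tr$planted_tdsg], na.rm = TRUE) >
      mean(pg$fst, na.rm = TRUE), "\n")
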