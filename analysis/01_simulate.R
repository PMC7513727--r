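#!/usr/bin/env Rscript

## Stage 1: generate the default synthetic two-ecotype panel.
##
## 40 upland + 50 lowland genotypes, 2,000 genes on one synthetic
## chromosome, with planted highly differentiated genes, sweep genes,
## transcriptionally selected genes organised in four co-expression
## modules, drought-responsive genes, cis-element-altering promoter
## SNPs and trait structure with an RWC/NT trade-off. All downstream
## stages read the interchange files written here; the planted truth
## tables are kept alongside for the recovery summaries.

suppressPackageStartupMessages(library(ecodiverge))

seed <- as.integer(Sys.getenv("ECOD_SEED", "1"))
cfg <- sim_config(seed = seed)
print(cfg)

ds <- simulate_dataset(cfg)
print(ds)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/data")
cat("dataset written to results/data (",
    nrow(ds$geno), "SNPs,", nrow(ds$regions), "genes,",
    ncol(ds$geno), "samples )\n")
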