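#' Simulate FPKM expression matrices for both watering conditions
#'
#' Log-normal baseline expression on the log2(FPKM + 1) scale with
#' per-gene noise SDs drawn from a log-normal (heavy-tailed across
#' genes, as in real FPKM panels). Planted TDSGs receive a
#' between-ecotype mean shift of `effect_tdsg` within-ecotype SDs with
#' reduced within-ecotype variance; drought-responsive TDSGs additionally
#' share per-module latent factors (within-module correlation
#' `module_cor`), with the ecotype-shift direction coherent within a
#' module (co-regulated genes move together, and an unsigned network
#' needs sign-coherent blocks). Planted DRGs are shifted by
#' `drought_log2fc` (random direction) in the drought matrix. A random
#' origin effect (nested within ecotype) is injected for the mixed
#' model, and `neutral_expr_drift_sd` optionally adds drift-like
#' between-ecotype offsets to unselected genes.
#'
#' @param cfg a [sim_config()].
#' @param truth gene-level ground-truth table from [simulate_genotypes()]
#'   (element `truth`), generated from the same `cfg`.
#' @return list with FPKM matrices `ck` and `dt` (genes x samples),
#'   `meta` (sample metadata), `log2_ck`/`log2_dt` (the underlying
#'   log2(FPKM+1) values), and per-gene attributes `tdsg_sign`,
#'   `drought_sign`.
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"),
            is.data.frame(truth), nrow(truth) == cfg$n_genes)
  meta <- sim_metadata(cfg)
  n <- cfg$n_genes
  ns <- nrow(meta)
  eco_up <- meta$ecotype == "upland"
  set.seed(derive_seed(cfg$seed, 4L))

  mu <- stats::rnorm(n, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
  sigma <- stats::rlnorm(n, cfg$noise_meanlog, cfg$noise_sdlog)

  is_tdsg <- truth$planted_tdsg
  module <- truth$planted_module
  in_mod <- module > 0L

  ## within-module latent factors, one value per sample, shared across
  ## conditions (they represent genotype-level expression states)
  n_mod <- max(0L, cfg$n_modules)
  factors <- matrix(stats::rnorm(ns * max(1L, n_mod)), nrow = ns)
  lambda <- if (cfg$module_cor >= 1) Inf else
    cfg$tdsg_noise_sd * sqrt(cfg$module_cor / (1 - cfg$module_cor))
  sd_mod_total <- sqrt(lambda^2 + cfg$tdsg_noise_sd^2)
  sd_plain_tdsg <- 1.5 * cfg$tdsg_noise_sd  # non-module TDSGs: no factor

  ## per-gene residual SD and ecotype shift
  gene_sd <- sigma
  gene_sd[is_tdsg] <- sd_plain_tdsg
  gene_sd[in_mod] <- cfg$tdsg_noise_sd
  within_sd <- sigma
  within_sd[is_tdsg] <- sd_plain_tdsg
  within_sd[in_mod] <- sd_mod_total

  ## shift direction: module-coherent for module genes (odd modules up
  ## in upland), random for other TDSGs; drift offsets for the rest
  tdsg_sign <- integer(n)
  tdsg_sign[is_tdsg] <- sample(c(-1L, 1L), sum(is_tdsg), replace = TRUE)
  tdsg_sign[in_mod] <- ifelse(module[in_mod] %% 2L == 1L, 1L, -1L)
  shift <- numeric(n)
  shift[is_tdsg] <- cfg$effect_tdsg * within_sd[is_tdsg] * tdsg_sign[is_tdsg]
  if (cfg$neutral_expr_drift_sd > 0) {
    neut <- !is_tdsg
    shift[neut] <- stats::rnorm(sum(neut), 0,
                                cfg$neutral_expr_drift_sd * sigma[neut])
  }

  ## random origin effect, per gene x origin, shared across conditions
  orig_levels <- sort(unique(meta$origin))
  orig_idx <- match(meta$origin, orig_levels)
  u <- matrix(stats::rnorm(n * length(orig_levels), 0, cfg$origin_effect_sd),
              nrow = n)

  drought_sign <- integer(n)
  drought_sign[truth$planted_drg] <-
    sample(c(-1L, 1L), sum(truth$planted_drg), replace = TRUE)

  eco_half <- ifelse(eco_up, 0.5, -0.5)
  base <- mu + outer(shift, eco_half) + u[, orig_idx]
  if (n_mod > 0 && any(in_mod)) {
    load <- matrix(0, n, n_mod)
    load[cbind(which(in_mod), module[in_mod])] <- lambda
    base <- base + load %*% t(factors)
  }
  ## split residual noise into a genotype-intrinsic component shared
  ## across the two fields (the same plants are measured under CK and
  ## DT, so most expression variation persists across conditions) and
  ## a condition-specific residual
  psi <- cfg$genotype_noise_frac
  g_shared <- matrix(stats::rnorm(n * ns, 0, sqrt(psi) * gene_sd), n, ns)
  resid_sd <- sqrt(1 - psi) * gene_sd
  y_ck <- base + g_shared + matrix(stats::rnorm(n * ns, 0, resid_sd), n, ns)
  y_dt <- base + cfg$drought_log2fc * drought_sign + g_shared +
    matrix(stats::rnorm(n * ns, 0, resid_sd), n, ns)

  to_fpkm <- function(y) {
    m <- pmax(2^y - 1, 0)
    dimnames(m) <- list(truth$gene_id, meta$sample)
    m
  }
  log2m <- function(y) {
    dimnames(y) <- list(truth$gene_id, meta$sample)
    y
  }
  list(ck = to_fpkm(y_ck), dt = to_fpkm(y_dt), meta = meta,
       log2_ck = log2m(y_ck), log2_dt = log2m(y_dt),
       tdsg_sign = tdsg_sign, drought_sign = drought_sign)
}

#' Simulate a planted-block co-expression matrix
#'
#' Clean block-structured expression for validating the network stage:
#' `n_blocks` modules of `genes_per_block` genes, each sharing a latent
#' sample factor so that the expected within-block Pearson correlation
#' is `within_r`; genes in different blocks are independent.
#'
#' @param n_blocks number of planted modules (default 4).
#' @param genes_per_block genes per module (default 150).
#' @param n_samples number of samples (default 90).
#' @param within_r target within-block correlation (default 0.8).
#' @param seed integer seed.
#' @return list with `expr` (FPKM-scale matrix) and integer `block`
#'   labels.
#' @export
simulate_module_expression <- function(n_blocks = 4L,
                                       genes_per_block = 150L,
                                       n_samples = 90L, within_r = 0.8,
                                       seed = 1L) {
  stopifnot(within_r > 0, within_r < 1)
  set.seed(seed)
  n <- n_blocks * genes_per_block
  block <- rep(seq_len(n_blocks), each = genes_per_block)
  lam <- sqrt(within_r / (1 - within_r))
  L <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
  mu <- stats::rnorm(n, 5, 1)
  y <- mu + lam * t(L[, block]) +
    matrix(stats::rnorm(n * n_samples), n, n_samples)
  expr <- pmax(2^y - 1, 0)
  dimnames(expr) <- list(sprintf("bgene%04d", seq_len(n)),
                         sprintf("s%03d", seq_len(n_samples)))
  list(expr = expr, block = block)
}
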