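#' Simulate agronomic and drought-tolerance traits
#'
#' Traits are linear combinations of latent factors *derived from the
#' planted TDSG expression* (standardised module mean profiles, computed
#' separately from the well-watered and drought matrices), plus ecotype
#' mean offsets and Gaussian noise. The designated trade-off gene set
#' (the planted module genes) receives opposite-sign loadings on RWC-DT
#' and NT-CK with magnitude scaled by `tradeoff_strength`, which also
#' scales the (negative) ecotype offset of tiller number; at strength 0
#' neither the factor coupling nor the NT divergence is planted.
#' Ecotype offsets make NT (both conditions), FLW-DT and RWC-DT
#' divergent traits.
#'
#' Measured traits: PH, NT, FLL, FLW, NG, GW100, GY, biomass, HI and
#' fecundity in both conditions (`_CK`/`_DT` columns), RWC under drought
#' only, and RGY = GY_DT/GY_CK.
#'
#' @param cfg a [sim_config()].
#' @param expr_ck,expr_dt FPKM matrices from [simulate_expression()].
#' @param meta sample metadata.
#' @param truth gene-level ground-truth table.
#' @return data.frame, one row per sample; attribute
#'   `planted_divergent` names the traits planted with ecotype
#'   divergence.
#' @export
simulate_traits <- function(cfg, expr_ck, expr_dt, meta, truth) {
  stopifnot(inherits(cfg, "sim_config"), nrow(meta) == ncol(expr_ck))
  ns <- nrow(meta)
  set.seed(derive_seed(cfg$seed, 5L))
  eco <- ifelse(meta$ecotype == "upland", 0.5, -0.5)
  g <- cfg$tradeoff_strength
  tau <- cfg$trait_noise_sd

  ## latent factors: standardised mean z-score profile of each planted
  ## module, per condition, centred *within ecotype* so the factors do
  ## not inherit the modules' ecotype shift (traits pick up ecotype
  ## divergence only through their explicit offsets); plus the signed
  ## trade-off composite
  module_factor <- function(expr, m) {
    genes <- truth$gene_id[truth$planted_module == m]
    if (length(genes) < 2) return(stats::rnorm(ns))
    y <- log2(expr[genes, , drop = FALSE] + 1)
    for (e in unique(meta$ecotype)) {
      idx <- meta$ecotype == e
      y[, idx] <- y[, idx] - rowMeans(y[, idx, drop = FALSE])
    }
    sds <- apply(y, 1, stats::sd)
    z <- y / ifelse(sds > 0, sds, 1)
    as.numeric(scale(colMeans(z)))
  }
  n_mod <- max(1L, cfg$n_modules)
  f_ck <- sapply(seq_len(n_mod), function(m) module_factor(expr_ck, m))
  f_dt <- sapply(seq_len(n_mod), function(m) module_factor(expr_dt, m))
  s_m <- ifelse(seq_len(n_mod) %% 2L == 1L, 1, -1)  # module shift signs
  t_ck <- as.numeric(scale(f_ck %*% s_m))
  t_dt <- as.numeric(scale(f_dt %*% s_m))
  fk <- function(fm, m) if (m <= ncol(fm)) fm[, m] else stats::rnorm(ns)
  noise <- function() stats::rnorm(ns, 0, tau)

  raw <- list(
    PH_CK  = 0.10 * eco + 0.4 * fk(f_ck, 2) + noise(),
    PH_DT  = 0.30 * eco + 0.4 * fk(f_dt, 2) + noise(),
    NT_CK  = g * (-1.2 * eco - 0.8 * t_ck) + noise(),
    NT_DT  = g * (-1.2 * eco - 0.6 * t_dt) + noise(),
    FLL_CK = 0.15 * eco + 0.3 * fk(f_ck, 1) + noise(),
    FLL_DT = 0.15 * eco + 0.3 * fk(f_dt, 1) + noise(),
    FLW_CK = 0.20 * eco + 0.3 * fk(f_ck, 1) + noise(),
    FLW_DT = 1.00 * eco + 0.3 * fk(f_dt, 1) + noise(),
    NG_CK  = -0.2 * g * eco + 0.5 * fk(f_ck, 3) + noise(),
    NG_DT  = -0.2 * g * eco + 0.5 * fk(f_dt, 3) + noise(),
    GW100_CK = 0.4 * fk(f_ck, 4) + noise(),
    GW100_DT = 0.4 * fk(f_dt, 4) + noise(),
    GY_CK  = -0.2 * g * eco + 0.5 * fk(f_ck, 3) + 0.3 * fk(f_ck, 4) + noise(),
    GY_DT  = -0.2 * g * eco + 0.5 * fk(f_dt, 3) + 0.3 * fk(f_dt, 4) + noise(),
    biomass_CK = 0.3 * fk(f_ck, 2) + 0.3 * fk(f_ck, 3) + noise(),
    biomass_DT = 0.3 * fk(f_dt, 2) + 0.3 * fk(f_dt, 3) + noise(),
    HI_CK  = -0.15 * g * eco + 0.4 * fk(f_ck, 3) + noise(),
    HI_DT  = -0.15 * g * eco + 0.4 * fk(f_dt, 3) + noise(),
    fecundity_CK = -0.2 * g * eco + 0.4 * fk(f_ck, 3) + noise(),
    fecundity_DT = -0.2 * g * eco + 0.4 * fk(f_dt, 3) + noise(),
    RWC_DT = 1.20 * eco + 0.8 * g * t_dt + noise()
  )
  ## affine maps onto plausible measurement units
  aff <- function(x, a, b, lo = -Inf, hi = Inf) pmin(pmax(a + b * x, lo), hi)
  out <- data.frame(
    sample = meta$sample,
    PH_CK = aff(raw$PH_CK, 110, 15), PH_DT = aff(raw$PH_DT, 95, 15),
    NT_CK = aff(raw$NT_CK, 22, 4, lo = 1), NT_DT = aff(raw$NT_DT, 14, 3, lo = 1),
    FLL_CK = aff(raw$FLL_CK, 30, 5), FLL_DT = aff(raw$FLL_DT, 26, 5),
    FLW_CK = aff(raw$FLW_CK, 1.6, 0.25, lo = 0.2),
    FLW_DT = aff(raw$FLW_DT, 1.4, 0.25, lo = 0.2),
    NG_CK = aff(raw$NG_CK, 120, 25, lo = 0), NG_DT = aff(raw$NG_DT, 70, 20, lo = 0),
    GW100_CK = aff(raw$GW100_CK, 2.6, 0.3, lo = 0.5),
    GW100_DT = aff(raw$GW100_DT, 2.3, 0.3, lo = 0.5),
    GY_CK = aff(raw$GY_CK, 25, 5, lo = 0.5), GY_DT = aff(raw$GY_DT, 12, 4, lo = 0.5),
    biomass_CK = aff(raw$biomass_CK, 55, 8, lo = 1),
    biomass_DT = aff(raw$biomass_DT, 35, 6, lo = 1),
    HI_CK = aff(raw$HI_CK, 0.45, 0.05, 0, 1), HI_DT = aff(raw$HI_DT, 0.32, 0.05, 0, 1),
    fecundity_CK = aff(raw$fecundity_CK, 0.85, 0.06, 0, 1),
    fecundity_DT = aff(raw$fecundity_DT, 0.60, 0.08, 0, 1),
    RWC_DT = aff(raw$RWC_DT, 0.72, 0.07, 0, 1),
    stringsAsFactors = FALSE
  )
  out$RGY <- out$GY_DT / out$GY_CK
  divergent <- c("FLW_DT", "RWC_DT")
  if (g != 0) divergent <- c("NT_CK", "NT_DT", divergent)
  attr(out, "planted_divergent") <- divergent
  out
}
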