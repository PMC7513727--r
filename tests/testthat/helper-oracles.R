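## Brute-force oracles, independent of the package implementations.

## mean pairwise difference between allele pools (diploid genotypes
## expanded to 2n alleles per site), per site, divided by region length
oracle_pi <- function(geno, samples, len) {
  g <- geno[, samples, drop = FALSE]
  tot <- 0
  for (s in seq_len(nrow(g))) {
    al <- unlist(lapply(g[s, ], function(x) {
      if (is.na(x)) return(integer(0))
      c(rep(1L, x), rep(0L, 2L - x))
    }))
    n <- length(al)
    if (n < 2) next
    d <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) d <- d + (al[i] != al[j])
    tot <- tot + d / choose(n, 2)
  }
  unname(tot) / len
}

oracle_dxy <- function(geno, ga, gb, len) {
  A <- geno[, ga, drop = FALSE]
  B <- geno[, gb, drop = FALSE]
  tot <- 0
  for (s in seq_len(nrow(A))) {
    ala <- unlist(lapply(A[s, ], function(x)
      if (is.na(x)) integer(0) else c(rep(1L, x), rep(0L, 2L - x))))
    alb <- unlist(lapply(B[s, ], function(x)
      if (is.na(x)) integer(0) else c(rep(1L, x), rep(0L, 2L - x))))
    if (!length(ala) || !length(alb)) next
    d <- 0
    for (i in seq_along(ala)) for (j in seq_along(alb))
      d <- d + (ala[i] != alb[j])
    tot <- tot + d / (length(ala) * length(alb))
  }
  unname(tot) / len
}

## Hudson ratio-of-sums from per-site brute-force pairwise differences
oracle_hudson <- function(geno, ga, gb) {
  hw_sum <- 0; hb_sum <- 0; any_site <- FALSE
  for (s in seq_len(nrow(geno))) {
    pools <- lapply(list(ga, gb), function(gr) {
      unlist(lapply(geno[s, gr], function(x)
        if (is.na(x)) integer(0) else c(rep(1L, x), rep(0L, 2L - x))))
    })
    if (any(vapply(pools, length, integer(1)) < 2)) next
    within <- vapply(pools, function(al) {
      n <- length(al); d <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) d <- d + (al[i] != al[j])
      d / choose(n, 2)
    }, numeric(1))
    d <- 0
    for (i in seq_along(pools[[1]])) for (j in seq_along(pools[[2]]))
      d <- d + (pools[[1]][i] != pools[[2]][j])
    hb <- d / (length(pools[[1]]) * length(pools[[2]]))
    hw_sum <- hw_sum + mean(within)
    hb_sum <- hb_sum + hb
    any_site <- TRUE
  }
  if (!any_site || hb_sum <= 0) return(NA_real_)
  unname(min(max(1 - hw_sum / hb_sum, 0), 1))
}

## direct formula evaluation of the topological overlap matrix
oracle_tom <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    ki <- sum(adj[i, -i]); kj <- sum(adj[j, -j])
    out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  out
}

## two-sided / one-sided Fisher p by exhaustive hypergeometric tail sum
oracle_fisher_p <- function(n11, n10, n01, n00,
                            alternative = "two.sided") {
  m <- n11 + n10        # size of set A
  k <- n11 + n01        # size of set B
  N <- n11 + n10 + n01 + n00
  lo <- max(0L, m + k - N); hi <- min(m, k)
  supp <- lo:hi
  dens <- stats::dhyper(supp, k, N - k, m)
  obs <- stats::dhyper(n11, k, N - k, m)
  if (alternative == "greater") return(sum(dens[supp >= n11]))
  if (alternative == "less") return(sum(dens[supp <= n11]))
  sum(dens[dens <= obs * (1 + 1e-7)])
}

## regex-expansion motif scanner (oracle for the Biostrings route)
oracle_scan <- function(sequence, motifs, both_strands = TRUE) {
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    for (s in if (both_strands) c("+", "-") else "+") {
      pat <- if (s == "+") motifs$iupac[i] else revcomp(motifs$iupac[i])
      rx <- iupac_to_regex(pat)
      L <- nchar(motifs$iupac[i])
      starts <- integer(0)
      from <- 1L
      repeat {
        m <- regexpr(rx, substr(sequence, from, nchar(sequence)), perl = TRUE)
        if (m == -1) break
        starts <- c(starts, from + as.integer(m) - 1L)
        from <- from + as.integer(m)  # allow overlapping matches
      }
      if (length(starts))
        out[[length(out) + 1L]] <- data.frame(
          motif = motifs$name[i], start = starts - 1L, end = starts + L - 1L,
          strand = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$motif, res$strand), , drop = FALSE]
}

## oracle SNP classifier: compare full-sequence occurrence scans of the
## two allele sequences, restricted to occurrences overlapping the SNP
oracle_classify <- function(sequence, offset, ref, alt, motifs,
                            both_strands = TRUE) {
  sref <- sequence; substr(sref, offset, offset) <- ref
  salt <- sequence; substr(salt, offset, offset) <- alt
  hit_r <- oracle_scan(sref, motifs, both_strands)
  hit_a <- oracle_scan(salt, motifs, both_strands)
  over <- function(h) unique(h$motif[h$start < offset & h$end >= offset])
  r <- over(hit_r); a <- over(hit_a)
  data.frame(motif = c(setdiff(a, r), setdiff(r, a)),
             effect = rep(c("gain", "loss"),
                          c(length(setdiff(a, r)), length(setdiff(r, a)))),
             stringsAsFactors = FALSE)
}

## cached default-scale dataset + pipeline shared by the heavier tests
.ecod_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.ecod_cache$run)) {
    ds <- simulate_dataset(sim_config(seed = 42L))
    .ecod_cache$ds <- ds
    .ecod_cache$run <- run_pipeline(ds, seed = 42L, n_perm = 500L)
  }
  list(ds = .ecod_cache$ds, res = .ecod_cache$run)
}
small_ds <- function() {
  if (is.null(.ecod_cache$small))
    .ecod_cache$small <- simulate_dataset(
      sim_config(seed = 7L, n_genes = 300L, n_intergenic_snps = 400L))
  .ecod_cache$small
}
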