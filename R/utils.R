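#' @keywords internal
"_PACKAGE"

## IUPAC degenerate nucleotide codes and their expansions.
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Round half away from zero
#'
#' Planted-flag counts in the synthetic-data generator are defined as
#' `round_half_up(fraction * n)` so that counts are exactly testable
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between a detected module assignment and a planted
#' partition, corrected for chance. 1 = identical partitions, 0 =
#' expected value under random labelling.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Reverse complement of plain character sequences
#' @param x character vector of A/C/G/T (IUPAC codes allowed).
#' @return character vector.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert an IUPAC motif to a POSIX regular expression
#'
#' Each degenerate code becomes a character class; used by the
#' independent brute-force matcher in the test-suite oracles as well as
#' by convenience utilities.
#'
#' @param motif single IUPAC string.
#' @return regular expression string.
#' @export
iupac_to_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste(vapply(ch, function(k) {
    exp <- IUPAC_CODES[[k]]
    if (nchar(exp) == 1) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

## internal: stop unless all values are finite fractions in [0, 1]
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name), call. = FALSE)
  x
}

## internal: deterministic seed derivation for sub-stages, kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483629L
}
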