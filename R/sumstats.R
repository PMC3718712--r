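# Summary statistics on haplotype matrices: the classical battery used to
# validate population-genetic simulators against coalescent expectations.

.as_bits <- function(m) {
  if (inherits(m, "hap_matrix")) m$bits
  else {
    b <- as.matrix(m)
    storage.mode(b) <- "logical"
    b
  }
}

#' Number of segregating sites
#'
#' Positions at which both alleles are present among the rows.
#'
#' @param m a [hap_matrix] or logical 0/1 matrix (rows = haplotypes).
#' @return Integer count.
#' @export
segregating_sites <- function(m) {
  b <- .as_bits(m)
  if (ncol(b) == 0) return(0L)
  cs <- colSums(b)
  sum(cs > 0 & cs < nrow(b))
}

#' Nucleotide diversity
#'
#' Average number of pairwise differences between sampled haplotypes,
#' reported per locus by default (so it compares directly to
#' `theta = 4 N_e mu L`); `per_site = TRUE` divides by `L`.
#'
#' @param m a [hap_matrix] or logical matrix.
#' @param per_site divide by the sequence length (requires a `hap_matrix`
#'   or explicit `L`).
#' @param L sequence length, for `per_site` on a plain matrix.
#' @return Numeric value.
#' @export
nucleotide_diversity <- function(m, per_site = FALSE, L = NULL) {
  b <- .as_bits(m)
  n <- nrow(b)
  if (n < 2) stop("nucleotide diversity needs at least 2 haplotypes")
  if (ncol(b) == 0) return(0)
  d <- colSums(b)
  pi <- sum(d * (n - d)) / choose(n, 2)
  if (per_site) {
    if (is.null(L)) L <- if (inherits(m, "hap_matrix")) m$L else
      stop("give L for per-site diversity on a plain matrix")
    pi <- pi / L
  }
  pi
}

#' Number of distinct haplotypes
#'
#' @param m a [hap_matrix] or logical matrix.
#' @return Integer count of distinct rows.
#' @export
haplotype_count <- function(m) {
  b <- .as_bits(m)
  if (ncol(b) == 0) return(min(1L, nrow(b)))
  nrow(unique(b))
}

#' Site frequency spectrum
#'
#' Counts of segregating sites by derived-allele count: `xi[i]` is the
#' number of sites where exactly `i` of the `n` sampled haplotypes carry
#' the derived allele, for `i = 1 .. n-1`.  The simulator knows the
#' ancestral state, so the spectrum is unfolded.  Under neutrality at
#' equilibrium `E[xi_i]` is proportional to `1/i`.
#'
#' @param m a [hap_matrix] or logical matrix.
#' @return Integer vector of length `nrow(m) - 1`.
#' @export
site_frequency_spectrum <- function(m) {
  b <- .as_bits(m)
  n <- nrow(b)
  if (n < 2) stop("the SFS needs at least 2 haplotypes")
  if (ncol(b) == 0) return(integer(n - 1))
  d <- colSums(b)
  tabulate(d[d > 0 & d < n], nbins = n - 1)
}

#' Watterson's expected number of segregating sites
#'
#' `E[S] = theta * a_{n-1}` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`, the
#' neutral-equilibrium closed form used as an independent reference for
#' validation.
#'
#' @param theta scaled mutation rate `4 N_e mu L`.
#' @param n sample size (haplotypes).
#' @return Expected segregating-site count.
#' @export
watterson_expected_s <- function(theta, n) theta * sum(1 / seq_len(n - 1))

#' Harmonic number `a_n = sum_{i=1}^{n} 1/i`
#' @param n upper index.
#' @return Numeric.
#' @export
harmonic_number <- function(n) sum(1 / seq_len(n))

#' One-row summary of a haplotype matrix
#'
#' @param m a [hap_matrix] or logical matrix.
#' @return Tibble with `n`, `S` (segregating sites), `pi` (nucleotide
#'   diversity per locus), `K` (distinct haplotypes).
#' @export
summary_stats <- function(m) {
  b <- .as_bits(m)
  tibble(n = nrow(b),
         S = segregating_sites(b),
         pi = if (nrow(b) >= 2) nucleotide_diversity(b) else NA_real_,
         K = haplotype_count(b))
}
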