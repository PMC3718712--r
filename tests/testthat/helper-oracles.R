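# Shared fixtures and independent oracles for the test suite.

tiny_params <- function(N_e = 20, L = 5000, mu = 2e-5, r = 2e-5,
                        n_generations = 10 * N_e, sample_size = 10,
                        mode = "for", seed = 1, ...) {
  sim_params(N_e = N_e, L = L, mu = mu, r = r,
             n_generations = n_generations, sample_size = sample_size,
             mode = mode, seed = seed, ...)
}

# brute-force recombinant: per-position donor lookup
brute_recombinant <- function(hap_a, hap_b, bps) {
  donor_of <- function(pos) findInterval(pos, bps) %% 2 # 0 -> a, 1 -> b
  sort(c(hap_a[donor_of(hap_a) == 0], hap_b[donor_of(hap_b) == 1]))
}

# exact fragmented surviving segments by naive backward propagation
# (independent of the compiled super-region backtracker); segments are
# closed intervals; returns per generation a list per haplotype of
# two-column matrices, NULL when no material survives
exact_segments <- function(fr, locus = 1) {
  anc <- fr$ancestry
  L <- fr$params$locus_lengths[locus]
  pm <- begsim:::hap_parent_map(anc, locus)
  G <- length(anc$sizes) - 1L
  rec <- anc$rec[anc$rec$locus == locus, , drop = FALSE]
  key <- paste(rec$generation, rec$hap_index)
  nh <- anc$n_haps
  segs <- vector("list", G + 1L)
  segs[[G + 1L]] <- lapply(seq_len(nh[G + 1L]), function(j) cbind(0, L))
  for (g in G:1) {
    prev <- vector("list", nh[g])
    for (j in seq_len(nh[g + 1L])) {
      s <- segs[[g + 1L]][[j]]
      if (is.null(s) || nrow(s) == 0) next
      p <- pm[[g + 1L]][j] # 0-based parent haplotype
      e <- match(paste(g, j - 1L), key)
      bps <- if (is.na(e)) integer(0) else rec$breakpoints[[e]]
      bounds <- c(0, bps, L + 1)
      for (seg in seq_len(length(bounds) - 1L)) {
        lo <- pmax(s[, 1], bounds[seg])
        hi <- pmin(s[, 2], bounds[seg + 1L] - 1)
        sel <- lo <= hi
        if (any(sel)) {
          d <- if (seg %% 2 == 1) p else bitwXor(p, 1L)
          prev[[d + 1L]] <- rbind(prev[[d + 1L]], cbind(lo[sel], hi[sel]))
        }
      }
    }
    segs[[g]] <- prev
  }
  segs
}

# hand-built 4-generation ancestry with one recombination and three
# neutral mutations; expected present-day sequences derived on paper
fig_fixture <- function() {
  sizes <- rep(2L, 5) # 4 haplotypes per generation, G = 4
  L <- 100L
  anc <- ancestry_log(sizes)
  for (g in 1:4)
    for (j in 0:3)
      anc <- ancestry_record(anc, g, j, j) # straight inheritance
  anc <- ancestry_record(anc, 2, 0, 0, breakpoints = 50L)
  stubs <- tibble::tibble(generation = c(1L, 1L, 3L),
                          hap_index = c(0L, 1L, 2L),
                          position = c(10L, 70L, 30L),
                          base = c(1L, 1L, 1L))
  expected <- matrix(c(1, 0, 1,   # hap 0: {10, 70} (recombinant)
                       0, 0, 1,   # hap 1: {70}
                       0, 1, 0,   # hap 2: {30}
                       0, 0, 0),  # hap 3: {}
                     nrow = 4, byrow = TRUE) == 1
  list(anc = anc, stubs = stubs, L = L, expected = expected,
       positions = c(10L, 30L, 70L))
}
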