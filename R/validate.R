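# Validation harness: the five neutral demographic scenarios, the two
# selection scenarios, distributional mode-equivalence tests, and the exact
# replay oracle that pins the ancestry-based path against naive forward
# propagation of the very same committed event stream.

#' Parameters of the neutral validation scenarios
#'
#' Five demographic scenarios over an initial diploid size of 500, a 1 Mbp
#' locus, per-base rates of `1e-8` for mutation (and recombination, where it
#' applies), run for `10 N_e` generations with 50 sampled haplotypes
#' (75 for the exponential-growth scenario):
#'
#' * `"i"` mutation only (no recombination);
#' * `"ii"` mutation and recombination;
#' * `"iii"` plus a doubling in size `0.2 N_p` generations ago;
#' * `"iv"` plus a factor-2 bottleneck `0.25 N_p` generations ago;
#' * `"v"` plus exponential growth from `0.5 N_p` generations ago
#'   (rate chosen to double the population over that window).
#'
#' `N_p` is the present population size implied by the scenario.
#'
#' @param id scenario id, `"i"` to `"v"`.
#' @param mode neutral-mutation handling: `"anc"`, `"for"` or `"mix"`.
#' @param seed run seed.
#' @param N_e,L,mu,r base parameters (defaults are the validation values).
#' @return A [sim_params()] object.
#' @export
scenario_params <- function(id = c("i", "ii", "iii", "iv", "v"),
                            mode = "anc", seed = 1,
                            N_e = 500, L = 1e6, mu = 1e-8, r = 1e-8) {
  id <- match.arg(id)
  use_r <- if (id == "i") 0 else r
  demog <- switch(id,
    i = demog_constant(),
    ii = demog_constant(),
    iii = demography(list(demog_step(round(0.2 * 2 * N_e), 2))),
    iv = demography(list(demog_step(round(0.25 * 0.5 * N_e), 0.5))),
    v = demography(list(demog_exp(round(0.5 * 2 * N_e),
                                  log(2) / round(0.5 * 2 * N_e)))))
  sim_params(N_e = N_e, L = L, mu = mu, r = use_r, neutral_fraction = 1,
             n_generations = 10 * N_e, demography = demog,
             sample_size = if (id == "v") 75 else 50,
             mode = mode, seed = seed)
}

#' Run a neutral validation scenario
#'
#' Simulates `n_replicates` independent runs of a scenario (replicate `k`
#' uses seed `seed + k - 1`) and returns the summary statistics per
#' replicate.
#'
#' @param id scenario id (see [scenario_params()]).
#' @param mode `"anc"`, `"for"` or `"mix"`.
#' @param n_replicates number of replicates.
#' @param seed base seed.
#' @param keep_sfs also return each replicate's site frequency spectrum as
#'   a list column.
#' @param ... passed to [scenario_params()] (e.g. smaller `N_e` for quick
#'   exploratory runs).
#' @return Tibble with one row per replicate: `scenario`, `mode`,
#'   `replicate`, `S`, `pi`, `K` (and `sfs` if requested).
#' @export
run_scenario <- function(id, mode = "anc", n_replicates = 10, seed = 1,
                         keep_sfs = FALSE, ...) {
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    p <- scenario_params(id, mode = mode, seed = seed + k - 1L, ...)
    res <- simulate_population(p)
    m <- res$matrices[[1]]
    st <- summary_stats(m)
    rows[[k]] <- tibble(scenario = id, mode = mode, replicate = k,
                        S = st$S, pi = st$pi, K = st$K,
                        sfs = if (keep_sfs) list(site_frequency_spectrum(m)) else list(NULL))
  }
  out <- do.call(rbind, rows)
  if (!keep_sfs) out$sfs <- NULL
  out
}

#' Parameters and runs of the selection validation scenarios
#'
#' Both scenarios use a diploid size of 250, a 100 kbp locus, per-base
#' rates `mu = r = 1e-6`, `10 N_e` generations, 50 sampled haplotypes, and
#' every mutation under selection.  Scenario 1 uses a fixed coefficient
#' `|s| = 0.01`, beneficial for 20% of mutations and deleterious for 80%;
#' scenario 2 draws the fitness effect from `Normal(-0.01, 0.001)`
#' (deleterious on average).
#'
#' @param id scenario id, 1 or 2.
#' @param seed run seed.
#' @return A [sim_params()] object.
#' @export
selection_scenario_params <- function(id = 1, seed = 1) {
  stopifnot(id %in% 1:2)
  model <- if (id == 1) selection_fixed(0.01, p_positive = 0.2)
           else selection_normal(-0.01, 0.001)
  sim_params(N_e = 250, L = 1e5, mu = 1e-6, r = 1e-6,
             neutral_fraction = 0, selection_model = model,
             n_generations = 2500, sample_size = 50, mode = "for",
             seed = seed)
}

#' @rdname selection_scenario_params
#' @param n_replicates number of replicates (replicate `k` uses seed
#'   `seed + k - 1`).
#' @return For `run_selection_scenario()`: a tibble of per-replicate
#'   summary statistics.
#' @export
run_selection_scenario <- function(id = 1, n_replicates = 10, seed = 1) {
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    p <- selection_scenario_params(id, seed = seed + k - 1L)
    res <- simulate_population(p)
    st <- summary_stats(res$matrices[[1]])
    rows[[k]] <- tibble(scenario = id, replicate = k,
                        S = st$S, pi = st$pi, K = st$K)
  }
  do.call(rbind, rows)
}

#' Distributional equivalence of the neutral-mutation modes
#'
#' Pairwise two-sample Kolmogorov-Smirnov tests on each summary statistic
#' between the modes present in `df`, with Bonferroni correction across
#' the whole family of comparisons.
#'
#' @param df per-replicate statistics, e.g. stacked [run_scenario()]
#'   outputs over several modes (columns `mode` plus the statistics).
#' @param stats statistic columns to compare.
#' @param alpha family-wise significance level.
#' @return Tibble with one row per (pair, statistic): `p_value`, the
#'   Bonferroni-corrected threshold, and `reject`.
#' @export
mode_equivalence_test <- function(df, stats = c("S", "pi", "K"),
                                  alpha = 0.01) {
  modes <- unique(df$mode)
  prs <- utils::combn(modes, 2, simplify = FALSE)
  rows <- list()
  for (pr in prs) {
    for (st in stats) {
      x <- df[[st]][df$mode == pr[1]]
      y <- df[[st]][df$mode == pr[2]]
      p <- suppressWarnings(ks.test(x, y)$p.value)
      rows[[length(rows) + 1L]] <-
        tibble(mode_a = pr[1], mode_b = pr[2], statistic = st, p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  out$threshold <- alpha / nrow(out)
  out$reject <- out$p_value < out$threshold
  out
}

# ---------------------------------------------------------------------------
# Exact replay oracle
# ---------------------------------------------------------------------------

# logical matrices over the union of both matrices' positions
.matrices_equal <- function(a, b) {
  pos <- sort(unique(c(a$positions, b$positions)))
  expand <- function(m) {
    bits <- matrix(FALSE, nrow(m$bits), length(pos))
    if (length(m$positions)) bits[, match(m$positions, pos)] <- m$bits
    bits
  }
  identical(expand(a), expand(b))
}

#' Exact replay oracle for the ancestry-based neutral path
#'
#' Runs one forward simulation in which neutral mutations *are* carried
#' forward (so the final haplotypes are the ground truth of naive forward
#' propagation), then feeds the identical committed neutral event stream —
#' generation, haplotype, position, base — together with the recorded
#' ancestry into the Backward Event Graph pipeline, and verifies that the
#' BEG-extracted present-day neutral sequences are bit-identical to the
#' forward ones for every haplotype of the present generation.
#'
#' This is the decisive per-instance correctness check of the graph
#' algorithm: distributional tests compare laws, the replay oracle compares
#' realizations.
#'
#' @param params a [sim_params()] object (small instances recommended).
#' @param seed optional seed override.
#' @param corrupt drop one observable M-node before building the graph — a
#'   negative control that must make the oracle fail.
#' @return List with `pass` (logical) and `per_locus` tibble
#'   (`locus`, `n_committed`, `n_stubs`, `identical`).
#' @export
replay_oracle <- function(params, seed = NULL, corrupt = FALSE) {
  p <- params
  if (!is.null(seed)) p$seed <- as.integer(seed)
  if (p$mode != "for") p$mode <- "for"
  fr <- run_forward(p)
  nh <- 2L * fr$sizes[length(fr$sizes)]
  all_idx <- seq_len(nh) - 1L
  reg <- fr$registry_raw
  rows <- vector("list", p$n_loci)
  for (l in seq_len(p$n_loci)) {
    ss <- backtrack_survivors(fr, l)
    sel <- which(as.logical(reg$is_neutral) & reg$locus == l - 1L)
    stubs <- tibble(generation = reg$origin_generation[sel],
                    hap_index = reg$hap_index[sel],
                    position = reg$position[sel],
                    base = reg$base[sel])
    # the pipeline only places mutations on survivors inside the
    # super-region; committed events elsewhere cannot reach the present
    keep <- logical(nrow(stubs))
    for (i in seq_len(nrow(stubs))) {
      g <- stubs$generation[i]
      hit <- match(stubs$hap_index[i], ss$survivors[[g + 1L]])
      keep[i] <- !is.na(hit) &&
        stubs$position[i] >= ss$rs[[g + 1L]][hit] &&
        stubs$position[i] <= ss$re[[g + 1L]][hit]
    }
    stubs <- stubs[keep, , drop = FALSE]
    fwd <- .forward_bits(fr, l, all_idx, neutral_only = TRUE,
                         include_fixed = TRUE)
    if (corrupt) {
      victim <- match(fwd$positions[1], stubs$position)
      if (!is.na(victim)) stubs <- stubs[-victim, , drop = FALSE]
    }
    beg <- build_beg(fr, ss, stubs, check_stubs = FALSE)
    mbeg <- extract_sequences(beg,
                              fraction = p$explicit_node_fraction)
    rows[[l]] <- tibble(locus = l, n_committed = length(sel),
                        n_stubs = nrow(stubs),
                        identical = .matrices_equal(mbeg, fwd))
  }
  per_locus <- do.call(rbind, rows)
  list(pass = all(per_locus$identical), per_locus = per_locus)
}

# ---------------------------------------------------------------------------
# Genome-scale run
# ---------------------------------------------------------------------------

# approximate female human chromosome lengths (Mbp), chr1-22 + X
.chrom_mbp <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155)

#' Genome-scale partially neutral simulation
#'
#' 23 unlinked loci in human-chromosome proportions totalling
#' `3.037e9 * scale` bp, per-base mutation and recombination rates of
#' `2.5e-8`, 10% of mutations non-neutral, `10 N_e` generations, neutral
#' mutations via the ancestry path, and segregating sites counted over the
#' entire present population.  The non-neutral coefficient defaults to a
#' small, effectively neutral magnitude (`N_e |s| = 0.1`): at a genome-wide
#' deleterious rate of several mutations per gamete, any appreciable `|s|`
#' would depress diversity through background selection, which this
#' benchmark setting is not meant to model.  `scale` shrinks every locus
#' length proportionally; expected segregating-site counts scale linearly
#' with it.
#'
#' @param n_individuals diploid population size.
#' @param scale locus-length scaling factor in `(0, 1]`.
#' @param seed run seed.
#' The neutral-site count (`total_S_neutral`) is reported alongside the
#' overall count: the packed-bit sequence output of the ancestry-based
#' path holds the neutral polymorphisms, so genome-scale site totals are
#' naturally quoted for them.
#'
#' @param selection_model selection model for the non-neutral 10%.
#' @return List with `params`, `per_locus` tibble, `total_S` and
#'   `total_S_neutral`.
#' @export
run_genome_scale <- function(n_individuals = 100, scale = 1, seed = 1,
                             selection_model =
                               selection_fixed(0.1 / n_individuals,
                                               p_positive = 0.2)) {
  lengths <- pmax(1L, as.integer(round(.chrom_mbp / sum(.chrom_mbp) *
                                         3.037e9 * scale)))
  p <- sim_params(N_e = n_individuals, locus_lengths = lengths,
                  mu = 2.5e-8, r = 2.5e-8, neutral_fraction = 0.9,
                  selection_model = selection_model,
                  n_generations = 10 * n_individuals,
                  sample_size = 2 * n_individuals, mode = "anc",
                  seed = seed)
  res <- simulate_population(p)
  s_neutral <- vapply(res$matrices, function(m) {
    keep <- m$mutations$is_neutral
    segregating_sites(m$bits[, keep, drop = FALSE])
  }, integer(1))
  per_locus <- tibble(locus = seq_along(lengths), L = lengths,
                      S = vapply(res$matrices, segregating_sites, integer(1)),
                      S_neutral = s_neutral)
  list(params = p, per_locus = per_locus, total_S = sum(per_locus$S),
       total_S_neutral = sum(per_locus$S_neutral))
}
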