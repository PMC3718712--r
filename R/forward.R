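# Wright-Fisher forward engine: fast compiled path plus a pure-R reference
# engine that consumes the random-number stream in exactly the same order,
# so both produce bit-identical runs from the same seed.

# uniform integer on [0, n), matching the compiled ui_int()
.ui <- function(n) {
  v <- floor(runif(1) * n)
  as.integer(if (v >= n) n - 1 else v)
}

.draw_base_r <- function(current) {
  if (current == 0L) return(1L + .ui(3L))
  k <- .ui(2L)
  cand <- setdiff(1:3, current)
  as.integer(cand[k + 1L])
}

.draw_s_r <- function(model) {
  if (model$type_code == 0L) {
    if (runif(1) < model$b) -model$a else model$a
  } else {
    repeat {
      s <- -rnorm(1, model$a, model$b)
      if (s < 1) return(s)
    }
  }
}

#' Draw recombination breakpoints for one gamete
#'
#' The number of breakpoints is Poisson with mean `L * r` (the per-gamete
#' recombination rate); positions are uniform integers on `[1, L - 1]`,
#' returned sorted and deduplicated.  Several breakpoints per gamete and per
#' generation are supported.
#'
#' @param L gamete length in bp.
#' @param r per-base per-generation recombination rate.
#' @return Sorted integer vector of breakpoints (possibly empty).
#' @export
draw_recombinations <- function(L, r) {
  stopifnot(r >= 0, L >= 1)
  if (r == 0 || L < 2) return(integer(0))
  n <- rpois(1, r * L)
  if (n == 0) return(integer(0))
  v <- floor(runif(n) * (L - 1))
  v[v >= L - 1] <- L - 2
  sort(unique(1L + as.integer(v)))
}

#' Recombine two haplotypes at given breakpoints
#'
#' Returns the mosaic that copies `hap_a` on `[0, b1)`, `hap_b` on
#' `[b1, b2)`, and so on, alternating.  Haplotypes are represented by their
#' sorted derived-site positions.
#'
#' @param hap_a,hap_b sorted numeric vectors of mutation positions.
#' @param breakpoints sorted ascending breakpoint positions.
#' @return Sorted positions of the recombinant.
#' @examples
#' make_recombinant(c(10, 500), 300, breakpoints = 250) # 10, 300
#' @export
make_recombinant <- function(hap_a, hap_b, breakpoints = integer(0)) {
  if (length(breakpoints) > 1 && is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be sorted strictly ascending")
  if (length(breakpoints) == 0) return(hap_a)
  keep_a <- findInterval(hap_a, breakpoints) %% 2 == 0
  keep_b <- findInterval(hap_b, breakpoints) %% 2 == 1
  sort(c(hap_a[keep_a], hap_b[keep_b]))
}

#' Draw non-neutral mutations for gametes
#'
#' Per gamete the count is Poisson with mean `mu * L * (1 -
#' neutral_fraction)` (the neutral share is thinned away), positions are
#' uniform on `[0, L)` and selection coefficients come from the params'
#' selection model.
#'
#' @param params a [sim_params()] object.
#' @param n_gametes number of gametes to draw for.
#' @param locus locus index (1-based).
#' @return Tibble with columns `gamete`, `position`, `s`.
#' @export
draw_selected_mutations <- function(params, n_gametes = 1, locus = 1) {
  L <- params$locus_lengths[locus]
  lambda <- params$mu * L * (1 - params$neutral_fraction)
  counts <- if (lambda > 0) rpois(n_gametes, lambda) else integer(n_gametes)
  n <- sum(counts)
  tibble(
    gamete = rep(seq_len(n_gametes), counts),
    position = as.integer(floor(runif(n) * L)),
    s = draw_selection_coefficients(params$selection_model, n))
}

# ---------------------------------------------------------------------------
# Pure-R reference engine
# ---------------------------------------------------------------------------

.new_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$locus <- integer(0); env$position <- integer(0)
  env$origin_generation <- integer(0); env$hap_index <- integer(0)
  env$base <- integer(0); env$s <- numeric(0)
  env$is_neutral <- logical(0); env$fixed_generation <- integer(0)
  env$n <- 0L
  env
}

.reg_add <- function(reg, locus, pos, gen, hap, base, s, neutral) {
  id <- reg$n # 0-based id
  reg$locus <- c(reg$locus, locus); reg$position <- c(reg$position, pos)
  reg$origin_generation <- c(reg$origin_generation, gen)
  reg$hap_index <- c(reg$hap_index, hap); reg$base <- c(reg$base, base)
  reg$s <- c(reg$s, s); reg$is_neutral <- c(reg$is_neutral, neutral)
  reg$fixed_generation <- c(reg$fixed_generation, -1L)
  reg$n <- reg$n + 1L
  id
}

# insert id into position-sorted id list with repeat-hit overwrite
.insert_mut_r <- function(ids, id, reg) {
  p <- reg$position[id + 1L]
  ppos <- reg$position[ids + 1L]
  i <- findInterval(p, ppos)
  if (i > 0 && ppos[i] == p) {
    ids[i] <- id
    ids
  } else {
    append(ids, id, after = i)
  }
}

.current_base_r <- function(ids, pos, reg) {
  ppos <- reg$position[ids + 1L]
  i <- findInterval(pos, ppos)
  if (i > 0 && ppos[i] == pos) reg$base[ids[i] + 1L] else 0L
}

.splice_ids_r <- function(a, b, bps, reg) {
  if (length(bps) == 0) return(a)
  pa <- reg$position[a + 1L]
  pb <- reg$position[b + 1L]
  out <- c(a[findInterval(pa, bps) %% 2 == 0], b[findInterval(pb, bps) %% 2 == 1])
  out[order(reg$position[out + 1L])]
}

#' Founder population state
#'
#' Creates the mutation-free generation-0 state of the reference engine.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `population_state`.
#' @export
founder_population <- function(params) {
  N0 <- demography_sizes(params$demography, params$N_e, params$n_generations)[1]
  haps <- lapply(seq_len(params$n_loci),
                 function(l) rep(list(integer(0)), 2 * N0))
  structure(list(
    generation = 0L,
    n_ind = N0,
    haps = haps,
    registry = .new_registry(),
    hap_fitness = rep(1, 2 * N0),
    log = list(parents = list(integer(0)),
               bits = rep(list(list(integer(0))), params$n_loci),
               rec_locus = integer(0), rec_gen = integer(0),
               rec_hap = integer(0), rec_bps = list())),
    class = "population_state")
}

#' Advance the reference engine by one generation
#'
#' Each of the `N'` offspring draws two parents with probability
#' proportional to fitness (uniformly under neutrality); each transmitted
#' gamete starts from one of the parent's two homologs (fair coin),
#' optionally recombines, and receives newly drawn mutations; fitness is
#' recomputed; parent choices, homolog bits, breakpoints and mutation events
#' are appended to the state's ancestry log.
#'
#' @param state a `population_state`.
#' @param params a [sim_params()] object.
#' @param N_next diploid size of the next generation (defaults to the
#'   demography at that generation).
#' @return The updated `population_state`.
#' @export
step_generation <- function(state, params, N_next = NULL) {
  g <- state$generation + 1L
  if (is.null(N_next)) {
    sz <- demography_sizes(params$demography, params$N_e, params$n_generations)
    if (g > length(sz) - 1L) stop("stepping past n_generations; give N_next")
    N_next <- sz[g + 1L]
  }
  reg <- state$registry
  n_loci <- params$n_loci
  Ls <- params$locus_lengths
  Nprev <- state$n_ind
  nf <- params$neutral_fraction
  fwd_frac <- switch(params$mode, "for" = 1, anc = 0, mix = params$mix_forward_fraction)
  any_sel <- nf < 1

  weighted <- FALSE
  if (any_sel) {
    fit <- state$hap_fitness[2 * seq_len(Nprev) - 1] * state$hap_fitness[2 * seq_len(Nprev)]
    if (any(fit < 0) || sum(fit) <= 0)
      stop("degenerate population: total fitness is zero")
    weighted <- max(fit) > min(fit)
    if (weighted) {
      cumfit <- cumsum(fit)
      total <- cumfit[Nprev]
    }
  }

  haps_next <- lapply(seq_len(n_loci), function(l) vector("list", 2 * N_next))
  parent_ind <- integer(2 * N_next)
  bits <- lapply(seq_len(n_loci), function(l) integer(2 * N_next))
  hf_next <- rep(1, 2 * N_next)
  log <- state$log

  for (k in seq_len(N_next)) {
    par <- integer(2)
    for (m in 1:2) {
      par[m] <- if (weighted) {
        min(Nprev - 1L, findInterval(runif(1) * total, cumfit)) # 0-based
      } else {
        .ui(Nprev)
      }
    }
    for (m in 1:2) {
      j <- 2L * (k - 1L) + (m - 1L) # 0-based child haplotype
      parent_ind[j + 1L] <- par[m]
      hf <- 1
      for (l in seq_len(n_loci)) {
        L <- Ls[l]
        bit <- if (runif(1) < 0.5) 0L else 1L
        bits[[l]][j + 1L] <- bit
        seed <- 2L * par[m] + bit
        child <- state$haps[[l]][[seed + 1L]]

        nrec <- if (L >= 2 && params$r > 0) rpois(1, params$r * L) else 0L
        if (nrec > 0) {
          v <- floor(runif(nrec) * (L - 1))
          v[v >= L - 1] <- L - 2
          bps <- sort(unique(1L + as.integer(v)))
          hom <- bitwXor(seed, 1L)
          child <- .splice_ids_r(state$haps[[l]][[seed + 1L]],
                                 state$haps[[l]][[hom + 1L]], bps, reg)
          log$rec_locus <- c(log$rec_locus, l)
          log$rec_gen <- c(log$rec_gen, g)
          log$rec_hap <- c(log$rec_hap, j)
          log$rec_bps <- c(log$rec_bps, list(bps))
        }

        lam_sel <- params$mu * L * (1 - nf)
        nsel <- if (lam_sel > 0) rpois(1, lam_sel) else 0L
        for (t in seq_len(nsel)) {
          pos <- .ui(L)
          base <- .draw_base_r(.current_base_r(child, pos, reg))
          s <- .draw_s_r(params$selection_model)
          id <- .reg_add(reg, l - 1L, pos, g, j, base, s, FALSE)
          child <- .insert_mut_r(child, id, reg)
        }

        lam_neu <- params$mu * L * nf * fwd_frac
        nneu <- if (lam_neu > 0) rpois(1, lam_neu) else 0L
        for (t in seq_len(nneu)) {
          pos <- .ui(L)
          base <- .draw_base_r(.current_base_r(child, pos, reg))
          id <- .reg_add(reg, l - 1L, pos, g, j, base, 0, TRUE)
          child <- .insert_mut_r(child, id, reg)
        }

        haps_next[[l]][[j + 1L]] <- child
        if (any_sel && length(child) > 0) {
          sel <- child[!reg$is_neutral[child + 1L]]
          if (length(sel) > 0) hf <- hf * prod(1 - reg$s[sel + 1L])
        }
      }
      hf_next[j + 1L] <- hf
    }
  }

  log$parents <- c(log$parents, list(parent_ind))
  for (l in seq_len(n_loci)) log$bits[[l]] <- c(log$bits[[l]], list(bits[[l]]))

  state$generation <- g
  state$n_ind <- N_next
  state$haps <- haps_next
  state$hap_fitness <- hf_next
  state$log <- log

  if (params$cleanup_interval > 0 && g %% params$cleanup_interval == 0)
    state <- cleanup_fixed(state)
  state
}

#' Remove and archive fixed mutations
#'
#' Mutations present on every haplotype of the current generation are
#' removed from all haplotypes and archived with their fixation generation
#' in the registry (`fixed_generation`).  Segregating-site accounting
#' excludes archived mutations.  The sweep consumes no randomness, so runs
#' with and without cleanup are stream-identical.
#'
#' @param state a `population_state`.
#' @return The updated state.
#' @export
cleanup_fixed <- function(state) {
  reg <- state$registry
  if (reg$n == 0) return(state)
  nh <- 2 * state$n_ind
  cnt <- integer(reg$n)
  for (l in seq_along(state$haps))
    for (h in state$haps[[l]]) {
      if (length(h)) cnt[h + 1L] <- cnt[h + 1L] + 1L
    }
  fixed <- which(cnt == nh & reg$fixed_generation < 0) # 1-based rows
  if (length(fixed) == 0) return(state)
  reg$fixed_generation[fixed] <- state$generation
  fixed0 <- fixed - 1L
  for (l in seq_along(state$haps))
    state$haps[[l]] <- lapply(state$haps[[l]],
                              function(h) h[!(h %in% fixed0)])
  # cached per-haplotype fitness keeps the (shared) fixed factors out
  if (any(!reg$is_neutral[fixed])) {
    for (j in seq_len(nh)) {
      hf <- 1
      for (l in seq_along(state$haps)) {
        ids <- state$haps[[l]][[j]]
        sel <- ids[!reg$is_neutral[ids + 1L]]
        if (length(sel)) hf <- hf * prod(1 - reg$s[sel + 1L])
      }
      state$hap_fitness[j] <- hf
    }
  }
  state
}

# ---------------------------------------------------------------------------
# Full forward run
# ---------------------------------------------------------------------------

.registry_tibble <- function(raw) {
  tibble(
    locus = as.integer(raw$locus) + 1L,
    position = as.integer(raw$position),
    origin_generation = as.integer(raw$origin_generation),
    hap_index = as.integer(raw$hap_index),
    base = c("A", "C", "G", "T")[as.integer(raw$base) + 1L],
    s = as.numeric(raw$s),
    is_neutral = as.logical(raw$is_neutral),
    fixed_generation = ifelse(raw$fixed_generation < 0, NA_integer_,
                              as.integer(raw$fixed_generation)))
}

#' Run the forward simulation
#'
#' Executes `n_generations` Wright-Fisher generations from a mutation-free
#' founder population, recording the full ancestry (parent maps, homolog
#' bits, recombination and mutation events).  In mode `"for"` neutral
#' mutations are carried forward as well (as `s = 0` records); in mode
#' `"anc"` they are left entirely to the a-posteriori path.  Deterministic
#' given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; both consume the random stream identically and give
#'   bit-identical runs from the same seed).
#' @param set_seed set `params$seed` before running (default `TRUE`; the
#'   pipeline wrappers manage the seed themselves).
#' @return An object of class `forward_run` with elements `params`, `sizes`,
#'   `mutations` (registry tibble), `final_haps`, `ancestry`
#'   (an [ancestry_log]), and `hap_fitness`.
#' @examples
#' p <- sim_params(N_e = 20, L = 1e4, mu = 1e-6, r = 0, n_generations = 40,
#'                 sample_size = 10, mode = "for", seed = 42)
#' fr <- run_forward(p)
#' fr$mutations
#' @export
run_forward <- function(params, engine = c("cpp", "r"), set_seed = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sim_params"))
  if (set_seed) set.seed(params$seed)
  sizes <- demography_sizes(params$demography, params$N_e, params$n_generations)
  fwd_frac <- switch(params$mode, "for" = 1, anc = 0, mix = params$mix_forward_fraction)

  if (engine == "cpp") {
    res <- cpp_run_forward(sizes, params$locus_lengths, params$mu, params$r,
                           params$neutral_fraction, fwd_frac,
                           params$selection_model$type_code,
                           params$selection_model$a, params$selection_model$b,
                           params$cleanup_interval)
    reg <- res$registry
    anc <- new_ancestry_log(parents = res$parents,
                            homolog_bits = res$homolog_bits,
                            rec = tibble(locus = as.integer(res$rec$locus) + 1L,
                                         generation = as.integer(res$rec$generation),
                                         hap_index = as.integer(res$rec$hap_index),
                                         breakpoints = res$rec$breakpoints),
                            sizes = sizes)
    out <- list(params = params, sizes = sizes,
                mutations = .registry_tibble(reg),
                registry_raw = list(position = reg$position, s = reg$s,
                                    is_neutral = reg$is_neutral,
                                    locus = reg$locus,
                                    origin_generation = reg$origin_generation,
                                    hap_index = reg$hap_index,
                                    base = reg$base,
                                    fixed_generation = reg$fixed_generation),
                final_haps = res$final_haps,
                ancestry = anc,
                hap_fitness = res$hap_fitness)
  } else {
    st <- founder_population(params)
    G <- params$n_generations
    for (g in seq_len(G)) st <- step_generation(st, params, N_next = sizes[g + 1L])
    reg <- st$registry
    anc <- new_ancestry_log(parents = st$log$parents,
                            homolog_bits = st$log$bits,
                            rec = tibble(locus = st$log$rec_locus,
                                         generation = st$log$rec_gen,
                                         hap_index = st$log$rec_hap,
                                         breakpoints = st$log$rec_bps),
                            sizes = sizes)
    out <- list(params = params, sizes = sizes,
                mutations = .registry_tibble(as.list(reg)),
                registry_raw = list(position = reg$position, s = reg$s,
                                    is_neutral = reg$is_neutral,
                                    locus = reg$locus,
                                    origin_generation = reg$origin_generation,
                                    hap_index = reg$hap_index,
                                    base = reg$base,
                                    fixed_generation = reg$fixed_generation),
                final_haps = lapply(st$haps, function(hl) hl),
                ancestry = anc,
                hap_fitness = st$hap_fitness)
  }
  class(out) <- "forward_run"
  out
}

#' @export
print.forward_run <- function(x, ...) {
  cat("<forward_run>\n")
  cat(sprintf("  %d generations, final size %d individuals, %d loci\n",
              x$params$n_generations, x$sizes[length(x$sizes)], x$params$n_loci))
  cat(sprintf("  %d mutation events (%d neutral), %d recombination events\n",
              nrow(x$mutations), sum(x$mutations$is_neutral),
              nrow(x$ancestry$rec)))
  invisible(x)
}
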