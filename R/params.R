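#' Selection-coefficient models
#'
#' A mutation's fitness contribution is the multiplicative factor `1 - s`:
#' deleterious mutations have `s > 0`, beneficial mutations `s < 0`, and
#' neutral mutations `s = 0` (factor 1).
#'
#' `selection_fixed()` draws a coefficient of fixed magnitude `s` whose sign
#' is beneficial (`-s`) with probability `p_positive` and deleterious (`+s`)
#' otherwise.
#'
#' `selection_normal()` is parameterized on the fitness *effect*
#' `e = f - 1 ~ Normal(mean, sd)` so that a negative `mean` is deleterious;
#' internally `s = -e`.  Draws with `s >= 1` (non-positive fitness) are
#' redrawn.
#'
#' @param s magnitude of the fixed selection coefficient, in `[0, 1)`.
#' @param p_positive probability that a new mutation is beneficial.
#' @param mean,sd mean and standard deviation of the normal fitness effect.
#' @return An object of class `selection_model`.
#' @examples
#' selection_fixed(0.01, p_positive = 0.2)
#' selection_normal(-0.01, 0.001)
#' @export
selection_fixed <- function(s = 0.01, p_positive = 0.2) {
  stopifnot(is.numeric(s), length(s) == 1, s >= 0, s < 1,
            is.numeric(p_positive), p_positive >= 0, p_positive <= 1)
  structure(list(type = "fixed", s = s, p_positive = p_positive,
                 type_code = 0L, a = s, b = p_positive),
            class = "selection_model")
}

#' @rdname selection_fixed
#' @export
selection_normal <- function(mean = -0.01, sd = 0.001) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.numeric(sd), sd >= 0)
  structure(list(type = "normal", mean = mean, sd = sd,
                 type_code = 1L, a = mean, b = sd),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  if (x$type == "fixed") {
    cat(sprintf("<selection model: fixed |s| = %g, P(beneficial) = %g>\n",
                x$s, x$p_positive))
  } else {
    cat(sprintf("<selection model: normal fitness effect, mean = %g, sd = %g>\n",
                x$mean, x$sd))
  }
  invisible(x)
}

#' Draw selection coefficients from a selection model
#'
#' @param model a [selection_fixed()] or [selection_normal()] object.
#' @param n number of coefficients to draw.
#' @return Numeric vector of coefficients `s` (fitness factor `1 - s`).
#' @export
draw_selection_coefficients <- function(model, n = 1) {
  stopifnot(inherits(model, "selection_model"), n >= 0)
  if (n == 0) return(numeric(0))
  if (model$type == "fixed") {
    ifelse(runif(n) < model$p_positive, -model$s, model$s)
  } else {
    s <- -rnorm(n, model$mean, model$sd)
    while (any(bad <- s >= 1)) s[bad] <- -rnorm(sum(bad), model$mean, model$sd)
    s
  }
}

#' Simulation parameters
#'
#' Collects every tunable of a run: the diploid effective population size
#' `N_e`, sequence length(s), per-base per-generation mutation and
#' recombination rates, the neutral fraction, the selection model for
#' non-neutral mutations, demography, run length, sampling, and the mode in
#' which neutral mutations are handled:
#'
#' * `"for"` (AF-FOR): every mutation, neutral or not, is carried through the
#'   forward simulation;
#' * `"anc"` (AF-ANC): neutral mutations are placed a posteriori on the
#'   surviving lineages via the Backward Event Graph;
#' * `"mix"` (AF-MIX): the neutral rate is split between the two paths
#'   according to `mix_forward_fraction`.
#'
#' The scaled rates `theta = 4 N_e mu L` and `rho = 4 N_e r L` are derived
#' quantities (see [theta_locus()]), not stored.
#'
#' @param N_e diploid effective population size (individuals, >= 1).
#' @param L sequence length in bp of a single locus; for several unlinked
#'   loci give `locus_lengths` instead.
#' @param mu per-base per-generation mutation rate.
#' @param r per-base per-generation recombination rate.
#' @param neutral_fraction probability that a new mutation is neutral.
#' @param selection_model model for non-neutral coefficients.
#' @param n_generations generations to simulate (default `10 * N_e`).
#' @param demography a [demography()] object (default constant size).
#' @param locus_lengths integer vector of per-locus lengths (unlinked loci).
#' @param sample_size haplotypes sampled from the present generation.
#' @param cleanup_interval generations between fixed-mutation sweeps.
#' @param explicit_node_fraction fraction of highest-visit BEG nodes stored
#'   explicitly during sequence extraction, in `(0, 1]`.
#' @param mode `"anc"`, `"for"` or `"mix"` (see Details).
#' @param mix_forward_fraction in mode `"mix"`, share of the neutral rate
#'   handled forward in time.
#' @param seed integer seed; every run is reproducible given the seed.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(N_e = 100, L = 1e5, mu = 1e-7, r = 1e-7,
#'                 sample_size = 20, seed = 1)
#' theta_locus(p)
#' @export
sim_params <- function(N_e, L = NULL, mu, r,
                       neutral_fraction = 1,
                       selection_model = selection_fixed(),
                       n_generations = 10 * N_e,
                       demography = demog_constant(),
                       locus_lengths = NULL,
                       sample_size = 50,
                       cleanup_interval = 100,
                       explicit_node_fraction = 0.05,
                       mode = c("anc", "for", "mix"),
                       mix_forward_fraction = 0.5,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(locus_lengths)) {
    if (is.null(L)) stop("give either `L` or `locus_lengths`")
    locus_lengths <- L
  }
  locus_lengths <- as.integer(locus_lengths)
  if (!(N_e >= 1)) stop("N_e must be >= 1")
  if (any(locus_lengths < 1)) stop("locus lengths must be >= 1")
  if (mu < 0 || r < 0) stop("mu and r must be non-negative")
  if (neutral_fraction < 0 || neutral_fraction > 1)
    stop("neutral_fraction must lie in [0, 1]")
  if (explicit_node_fraction <= 0 || explicit_node_fraction > 1)
    stop("explicit_node_fraction must lie in (0, 1]")
  if (mix_forward_fraction < 0 || mix_forward_fraction > 1)
    stop("mix_forward_fraction must lie in [0, 1]")
  if (!inherits(selection_model, "selection_model"))
    stop("selection_model must be created by selection_fixed()/selection_normal()")
  if (!inherits(demography, "demography"))
    stop("demography must be created by demography()/demog_*()")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (sample_size < 1) stop("sample_size must be >= 1")

  p <- structure(list(
    N_e = as.integer(N_e),
    locus_lengths = locus_lengths,
    n_loci = length(locus_lengths),
    L = sum(as.double(locus_lengths)),
    mu = mu, r = r,
    neutral_fraction = neutral_fraction,
    selection_model = selection_model,
    n_generations = as.integer(n_generations),
    demography = demography,
    sample_size = as.integer(sample_size),
    cleanup_interval = as.integer(cleanup_interval),
    explicit_node_fraction = explicit_node_fraction,
    mode = mode,
    mix_forward_fraction = mix_forward_fraction,
    seed = as.integer(seed)), class = "sim_params")
  # population size must be >= 1 at every generation
  sz <- demography_sizes(p$demography, p$N_e, p$n_generations)
  if (any(sz < 1)) stop("demography yields population size < 1")
  if (p$sample_size > 2 * sz[length(sz)])
    stop("sample_size exceeds the number of present-day haplotypes")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  N_e = %d, generations = %d, mode = %s, seed = %d\n",
              x$N_e, x$n_generations, toupper(paste0("af_", x$mode)), x$seed))
  cat(sprintf("  loci = %d (total %g bp), mu = %g, r = %g, neutral fraction = %g\n",
              x$n_loci, x$L, x$mu, x$r, x$neutral_fraction))
  cat(sprintf("  sample = %d haplotypes, theta per locus = %s\n",
              x$sample_size,
              paste(signif(theta_locus(x), 4), collapse = ", ")))
  invisible(x)
}

#' Scaled population mutation and recombination rates
#'
#' `theta_locus()` returns `4 N_e mu L` and `rho_locus()` returns
#' `4 N_e r L`, one value per locus.
#'
#' @param params a [sim_params()] object.
#' @return Numeric vector, one entry per locus.
#' @export
theta_locus <- function(params) {
  4 * params$N_e * params$mu * as.double(params$locus_lengths)
}

#' @rdname theta_locus
#' @export
rho_locus <- function(params) {
  4 * params$N_e * params$r * as.double(params$locus_lengths)
}

#' Multiplicative fitness of a diploid individual
#'
#' Fitness is the product of `1 - s` over all non-neutral mutations carried
#' on either haplotype; neutral mutations contribute a factor of 1 and a
#' mutation-free individual has fitness exactly 1.
#'
#' @param individual either a numeric vector of selection coefficients
#'   (both haplotypes pooled), or a list of one or more per-haplotype
#'   components, each a numeric vector of `s` values or a data frame with
#'   columns `s` and (optionally) `is_neutral`.
#' @return Strictly positive fitness value.
#' @examples
#' compute_fitness(list(0.01, 0.02))   # 0.99 * 0.98
#' compute_fitness(numeric(0))         # 1
#' @export
compute_fitness <- function(individual) {
  pull_s <- function(h) {
    if (is.data.frame(h)) {
      s <- h$s
      if (!is.null(h$is_neutral)) s <- s[!h$is_neutral]
      s
    } else {
      as.numeric(h)
    }
  }
  s <- if (is.list(individual) && !is.data.frame(individual)) {
    unlist(lapply(individual, pull_s), use.names = FALSE)
  } else {
    pull_s(individual)
  }
  s <- s[s != 0]
  if (any(s >= 1))
    stop("invalid selection coefficient: s >= 1 gives non-positive fitness")
  prod(1 - s)
}
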