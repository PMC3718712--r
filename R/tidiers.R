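# broom-style tidiers for simulation results.

#' Turn an object into a tidy tibble
#'
#' Generic with methods for begsim result classes (a lightweight stand-in
#' for the broom generics).
#'
#' @param x object to tidy.
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an object
#'
#' @param x object to summarize.
#' @param ... passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn tidy per-locus summary statistics of a simulation result.
#' @export
tidy.sim_result <- function(x, ...) {
  st <- do.call(rbind, lapply(x$matrices, summary_stats))
  tibble(locus = seq_along(x$matrices),
         L = x$params$locus_lengths,
         theta = theta_locus(x$params),
         n = st$n, S = st$S, pi = st$pi, K = st$K)
}

#' @describeIn glance whole-run totals of a simulation result.
#' @export
glance.sim_result <- function(x, ...) {
  td <- tidy(x)
  tibble(n_loci = nrow(td), L_total = sum(as.double(td$L)),
         n_sample = x$params$sample_size,
         S_total = sum(td$S), pi_total = sum(td$pi),
         theta_total = sum(td$theta),
         mode = x$params$mode, seed = x$params$seed)
}

#' @describeIn tidy the mutation table of a forward run.
#' @export
tidy.forward_run <- function(x, ...) x$mutations

#' @describeIn glance event totals of a forward run.
#' @export
glance.forward_run <- function(x, ...) {
  tibble(n_generations = x$params$n_generations,
         final_size = x$sizes[length(x$sizes)],
         n_mutations = nrow(x$mutations),
         n_neutral = sum(x$mutations$is_neutral),
         n_fixed = sum(!is.na(x$mutations$fixed_generation)),
         n_recombinations = nrow(x$ancestry$rec))
}

#' @describeIn tidy survivor counts per generation of a survivor set.
#' @export
tidy.survivor_set <- function(x, ...) survivor_counts(x)
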