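#' Demographic histories
#'
#' A demography is a list of events applied to the initial size `N_e` along
#' the forward timeline.  Supported events: a constant epoch (implicit), an
#' instantaneous size change by a factor (`demog_step()`, e.g. a doubling or
#' a factor-2 bottleneck), and exponential growth at a fixed rate from some
#' generation onward (`demog_exp()`).  Event times are given in generations
#' *before the present* (the last simulated generation), which is how
#' demographic scenarios are usually quoted.
#'
#' `demography()` also accepts a compact textual form, comma-chained:
#' `"const"`, `"step:<gens_ago>:<factor>"`, `"exp:<gens_ago>:<rate>"`, e.g.
#' `"step:200:2"` for a doubling 200 generations ago.
#'
#' @param spec a character scalar in the mini-language above, or a list of
#'   events built by `demog_step()` / `demog_exp()`.
#' @param gens_ago event time in generations before the present.
#' @param factor instantaneous multiplicative size change.
#' @param rate exponential growth rate per generation.
#' @return An object of class `demography`.
#' @examples
#' demog_constant()
#' demography("step:200:2")
#' demography(list(demog_step(200, 2), demog_exp(100, 0.005)))
#' @export
demography <- function(spec = "const") {
  if (inherits(spec, "demography")) return(spec)
  if (is.character(spec)) {
    parts <- unlist(strsplit(spec, ",", fixed = TRUE))
    events <- list()
    for (p in parts) {
      f <- unlist(strsplit(trimws(p), ":", fixed = TRUE))
      events <- switch(f[1],
        const = events,
        step = c(events, list(demog_step(as.numeric(f[2]), as.numeric(f[3])))),
        exp = c(events, list(demog_exp(as.numeric(f[2]), as.numeric(f[3])))),
        stop("unknown demography component: ", p))
    }
    spec <- events
  }
  stopifnot(is.list(spec))
  for (e in spec) {
    if (!is.list(e) || is.null(e$kind))
      stop("demography events must be built with demog_step()/demog_exp()")
  }
  ago <- vapply(spec, function(e) e$gens_ago, numeric(1))
  spec <- spec[order(-ago)] # oldest first along the forward timeline
  structure(list(events = spec), class = "demography")
}

#' @rdname demography
#' @export
demog_constant <- function() demography(list())

#' @rdname demography
#' @export
demog_step <- function(gens_ago, factor) {
  stopifnot(gens_ago >= 0, factor > 0)
  list(kind = "step", gens_ago = gens_ago, factor = factor)
}

#' @rdname demography
#' @export
demog_exp <- function(gens_ago, rate) {
  stopifnot(gens_ago >= 0)
  list(kind = "exp", gens_ago = gens_ago, rate = rate)
}

#' @export
print.demography <- function(x, ...) {
  if (length(x$events) == 0) {
    cat("<demography: constant size>\n")
  } else {
    cat("<demography>\n")
    for (e in x$events)
      cat(sprintf("  %s at %g generations ago: %s\n", e$kind, e$gens_ago,
                  if (e$kind == "step") paste0("x", e$factor)
                  else paste0("rate ", e$rate)))
  }
  invisible(x)
}

#' Population size at every generation
#'
#' Expands a demography into the diploid population size for generations
#' `0..n_generations` (generation 0 being the founders).  Sizes are rounded
#' to the nearest integer and floored at 1.
#'
#' @param demog a [demography()] object.
#' @param N_e initial diploid size at generation 0.
#' @param n_generations number of forward generations.
#' @return Integer vector of length `n_generations + 1`.
#' @examples
#' demography_sizes(demography("step:2:2"), N_e = 10, n_generations = 5)
#' @export
demography_sizes <- function(demog, N_e, n_generations) {
  demog <- demography(demog)
  G <- as.integer(n_generations)
  n <- rep(as.numeric(N_e), G + 1)
  for (e in demog$events) {
    t0 <- G - e$gens_ago # first generation at/after the event
    t0 <- max(0, ceiling(t0))
    if (t0 > G) next
    idx <- seq.int(t0, G) + 1L
    if (e$kind == "step") {
      n[idx] <- n[idx] * e$factor
    } else {
      n[idx] <- n[idx] * exp(e$rate * (seq.int(t0, G) - t0))
    }
  }
  pmax(1L, as.integer(round(n)))
}
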