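# Diagnostic plots (ggplot2, suggested dependency).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 for plotting")
}

#' Plot survivor counts per generation
#'
#' The number of haplotypes per past generation that may still contribute
#' material to the present; its decay (and plateau under recombination)
#' drives the saving of the a-posteriori neutral path.
#'
#' @param ss a `survivor_set` (or the tibble from [survivor_counts()]).
#' @return A ggplot object.
#' @export
plot_survivors <- function(ss) {
  .need_ggplot()
  df <- if (inherits(ss, "survivor_set")) survivor_counts(ss) else ss
  ggplot2::ggplot(df, ggplot2::aes(x = generation,
                                   y = n_survivors)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "surviving haplotypes") +
    ggplot2::theme_minimal()
}

#' Plot a site frequency spectrum
#'
#' Bars of the observed spectrum with the neutral `1/i` expectation scaled
#' to the same total overlaid.
#'
#' @param sfs integer vector from [site_frequency_spectrum()], or a
#'   [hap_matrix].
#' @return A ggplot object.
#' @export
plot_sfs <- function(sfs) {
  .need_ggplot()
  if (inherits(sfs, "hap_matrix")) sfs <- site_frequency_spectrum(sfs)
  i <- seq_along(sfs)
  expected <- (1 / i) / sum(1 / i) * sum(sfs)
  df <- data.frame(i = i, observed = as.numeric(sfs), expected = expected)
  ggplot2::ggplot(df, ggplot2::aes(x = i)) +
    ggplot2::geom_col(ggplot2::aes(y = observed), fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = expected), colour = "red") +
    ggplot2::labs(x = "derived-allele count", y = "sites") +
    ggplot2::theme_minimal()
}

#' Histogram of a summary statistic across modes
#'
#' Freedman-Diaconis binning, as customary for comparing the distributions
#' of segregating sites or diversity across simulator settings.
#'
#' @param df stacked [run_scenario()] output.
#' @param stat column to plot (`"S"`, `"pi"` or `"K"`).
#' @return A ggplot object.
#' @export
plot_mode_distributions <- function(df, stat = "S") {
  .need_ggplot()
  x <- df[[stat]]
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3) # Freedman-Diaconis
  if (!is.finite(bw) || bw <= 0) bw <- 1
  df$value <- x
  ggplot2::ggplot(df, ggplot2::aes(x = value, colour = mode)) +
    ggplot2::geom_freqpoly(binwidth = bw) +
    ggplot2::labs(x = stat, y = "replicates") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("generation", "n_survivors", "i", "observed",
                         "expected", "value", "mode"))
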