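# ms-format text input/output: the lingua franca of coalescent simulators
# (segsites line, positions normalized to [0, 1), one 0/1 row per sampled
# haplotype).  Enables cross-tool comparison of summary statistics.

#' Write haplotype matrices in ms format
#'
#' Positions are normalized to `position / L`; exact bp coordinates live in
#' the TSV sidecar written by [write_haplotype_matrix()].
#'
#' @param x a [hap_matrix] or list of them (one block per replicate).
#' @param path output file.
#' @param command optional first header line (defaults to a synthetic one).
#' @return `path`, invisibly.
#' @export
write_ms <- function(x, path, command = NULL) {
  if (inherits(x, "hap_matrix")) x <- list(x)
  n <- nrow(x[[1]]$bits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(command %||% sprintf("ms %d %d", n, length(x)),
               "begsim", ""), con)
  for (m in x) {
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", ncol(m$bits)), con)
    if (ncol(m$bits) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", m$positions / m$L), collapse = " ")),
                 con)
      apply(m$bits, 1, function(row)
        writeLines(paste(as.integer(row), collapse = ""), con))
    } else {
      writeLines("", con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-format output
#'
#' Parses the common dialect: replicate blocks introduced by `//`, a
#' `segsites:` line, a `positions:` line with positions in `[0, 1)`, then
#' one 0/1 row per haplotype.
#'
#' Matrix columns are indexed 0, 1, ... in site order (summary statistics
#' do not depend on coordinates); the normalized positions are kept in the
#' metadata tibble, rescaled to bp when `L > 1`.
#'
#' @param path an ms-format text file.
#' @param L sequence length used to rescale positions to bp (default 1:
#'   keep normalized positions).
#' @return List of [hap_matrix] objects, one per replicate.
#' @export
read_ms <- function(path, L = 1) {
  lines <- readLines(path)
  starts <- which(trimws(lines) == "//")
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[b] + 1L
    while (i <= length(lines) && !startsWith(trimws(lines[i]), "segsites:"))
      i <- i + 1L
    seg <- as.integer(sub("segsites:\\s*", "", trimws(lines[i])))
    if (seg == 0) {
      out[[b]] <- hap_matrix(matrix(FALSE, 0, 0), integer(0), L = L)
      next
    }
    while (!startsWith(trimws(lines[i]), "positions:")) i <- i + 1L
    pos <- as.numeric(strsplit(sub("positions:\\s*", "", trimws(lines[i])),
                               "\\s+")[[1]])
    i <- i + 1L
    rows <- list()
    while (i <= length(lines) && grepl("^[01]+$", trimws(lines[i]))) {
      rows[[length(rows) + 1L]] <- as.integer(strsplit(trimws(lines[i]), "")[[1]])
      i <- i + 1L
    }
    bits <- do.call(rbind, rows) == 1L
    meta <- tibble(position = seq_along(pos) - 1L,
                   ms_position = pos,
                   bp = if (L > 1) pmin(floor(pos * L), L - 1) else pos)
    out[[b]] <- hap_matrix(bits, seq_along(pos) - 1L, mutations = meta,
                           L = max(L, length(pos)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
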