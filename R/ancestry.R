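# Ancestry log: per-generation surjective parent maps plus recombination and
# mutation event logs.  Haplotype indices are 0-based; indices (2k, 2k+1)
# are the two homologs of individual k, so the homolog of parent index p is
# always p XOR 1.  Internally the log stores the parent *individual* per
# child haplotype plus one homolog-choice bit per locus (the multi-locus
# representation); the per-locus haplotype-level map a_i is derived as
# 2 * parent_individual + bit.

new_ancestry_log <- function(parents, homolog_bits, rec, sizes) {
  structure(list(parents = parents, homolog_bits = homolog_bits,
                 rec = rec, sizes = as.integer(sizes),
                 n_haps = 2L * as.integer(sizes)),
            class = "ancestry_log")
}

#' Create an empty ancestry log
#'
#' Mostly useful for hand-built fixtures; simulation runs produce their log
#' automatically (see [run_forward()]).
#'
#' @param sizes diploid population size per generation (length
#'   `n_generations + 1`, generation 0 first).
#' @param n_loci number of unlinked loci.
#' @return An `ancestry_log` with unset parent maps (-1).
#' @export
ancestry_log <- function(sizes, n_loci = 1) {
  sizes <- as.integer(sizes)
  G <- length(sizes) - 1L
  parents <- c(list(integer(0)),
               lapply(seq_len(G), function(g) rep(-1L, 2L * sizes[g + 1L])))
  bits <- lapply(seq_len(n_loci), function(l)
    c(list(integer(0)),
      lapply(seq_len(G), function(g) integer(2L * sizes[g + 1L]))))
  new_ancestry_log(parents, bits,
                   tibble(locus = integer(0), generation = integer(0),
                          hap_index = integer(0), breakpoints = list()),
                   sizes)
}

#' Record one inheritance event
#'
#' Writes the parent haplotype of `child_hap` in `generation` into the log;
#' a non-empty breakpoint list additionally records a recombination event
#' (an empty list is stored as plain inheritance, no event).
#'
#' @param anc an `ancestry_log`.
#' @param generation generation of the child (>= 1).
#' @param child_hap 0-based child haplotype index.
#' @param parent_hap 0-based parent haplotype index in `generation - 1`.
#' @param breakpoints optional sorted breakpoint positions.
#' @param locus locus index (1-based).
#' @return The updated log.
#' @export
ancestry_record <- function(anc, generation, child_hap, parent_hap,
                            breakpoints = NULL, locus = 1) {
  stopifnot(inherits(anc, "ancestry_log"))
  G <- length(anc$sizes) - 1L
  if (generation < 1 || generation > G) stop("generation out of range")
  if (child_hap < 0 || child_hap >= anc$n_haps[generation + 1L])
    stop("child haplotype index out of range")
  if (parent_hap < 0 || parent_hap >= anc$n_haps[generation])
    stop("parent haplotype index out of range")
  anc$parents[[generation + 1L]][child_hap + 1L] <- parent_hap %/% 2L
  anc$homolog_bits[[locus]][[generation + 1L]][child_hap + 1L] <- parent_hap %% 2L
  if (length(breakpoints) > 0) {
    anc$rec <- rbind(anc$rec,
                     tibble(locus = as.integer(locus),
                            generation = as.integer(generation),
                            hap_index = as.integer(child_hap),
                            breakpoints = list(as.integer(breakpoints))))
  }
  anc
}

#' Parent and homolog of a haplotype
#'
#' @param anc an `ancestry_log`.
#' @param generation generation of the child (must be >= 1; founders have no
#'   parents).
#' @param hap_index 0-based haplotype index in that generation.
#' @param locus locus index (1-based).
#' @return List with `parent` (the mapped parent haplotype index) and
#'   `homolog` (its homolog, `parent XOR 1` — the recombination partner).
#' @export
parent_of <- function(anc, generation, hap_index, locus = 1) {
  stopifnot(inherits(anc, "ancestry_log"))
  if (generation < 1) stop("generation 0 founders have no parent")
  if (hap_index < 0 || hap_index >= anc$n_haps[generation + 1L])
    stop("haplotype index out of range")
  p <- 2L * anc$parents[[generation + 1L]][hap_index + 1L] +
    anc$homolog_bits[[locus]][[generation + 1L]][hap_index + 1L]
  list(parent = p, homolog = bitwXor(p, 1L))
}

# per-locus haplotype-level parent maps a_i (list over generations,
# 0-based indices)
hap_parent_map <- function(anc, locus = 1) {
  G <- length(anc$sizes) - 1L
  out <- vector("list", G + 1L)
  out[[1L]] <- integer(0)
  bits <- anc$homolog_bits[[locus]]
  for (g in seq_len(G))
    out[[g + 1L]] <- 2L * anc$parents[[g + 1L]] + bits[[g + 1L]]
  out
}

#' Ancestry storage-size report
#'
#' Reports, per generation, the minimal number of bytes needed to store the
#' parent map: addressing the previous generation's individuals requires 1,
#' 2 or 4 bytes per entry depending on its size, plus one homolog-choice bit
#' per locus per transmitted gamete.
#'
#' @param anc an `ancestry_log`.
#' @param n_loci number of loci (defaults to the number of bit tracks).
#' @return Tibble with columns `generation`, `entries`, `bytes_parents`,
#'   `bytes_bits`, `bytes_total`.
#' @export
ancestry_storage_report <- function(anc, n_loci = length(anc$homolog_bits)) {
  G <- length(anc$sizes) - 1L
  gens <- seq_len(G)
  entries <- 2L * anc$sizes[gens + 1L]
  prev_ind <- anc$sizes[gens]
  width <- ifelse(prev_ind <= 256, 1L, ifelse(prev_ind <= 65536, 2L, 4L))
  bytes_parents <- as.numeric(entries) * width
  bytes_bits <- ceiling(as.numeric(entries) * n_loci / 8)
  tibble(generation = gens, entries = entries,
         bytes_parents = bytes_parents, bytes_bits = bytes_bits,
         bytes_total = bytes_parents + bytes_bits)
}

#' Export the ancestry event log as TSV
#'
#' One row per event: `INHERIT` rows give the parent haplotype of every
#' child haplotype, `REC` rows the breakpoints, `MUT` rows the mutation
#' events (when a mutation table is supplied).  Intended for small runs and
#' the replay oracle; the format round-trips through
#' [read_ancestry_events()].
#'
#' @param anc an `ancestry_log`.
#' @param path output file.
#' @param mutations optional mutation tibble (as in `forward_run$mutations`).
#' @param locus locus to export.
#' @return `path`, invisibly.
#' @export
write_ancestry_events <- function(anc, path, mutations = NULL, locus = 1) {
  pm <- hap_parent_map(anc, locus)
  G <- length(anc$sizes) - 1L
  rows <- list()
  for (g in seq_len(G)) {
    n <- length(pm[[g + 1L]])
    rows[[g]] <- data.frame(type = "INHERIT", generation = g,
                            hap_index = seq_len(n) - 1L,
                            parent_index = pm[[g + 1L]],
                            positions = "")
  }
  inh <- do.call(rbind, rows)
  rec <- anc$rec[anc$rec$locus == locus, , drop = FALSE]
  rec_df <- if (nrow(rec)) {
    data.frame(type = "REC", generation = rec$generation,
               hap_index = rec$hap_index, parent_index = NA_integer_,
               positions = vapply(rec$breakpoints,
                                  function(b) paste(b, collapse = ","), ""))
  }
  mut_df <- if (!is.null(mutations) && nrow(mutations)) {
    mm <- mutations[mutations$locus == locus, , drop = FALSE]
    data.frame(type = "MUT", generation = mm$origin_generation,
               hap_index = mm$hap_index, parent_index = NA_integer_,
               positions = as.character(mm$position))
  }
  out <- rbind(inh, rec_df, mut_df)
  out <- out[order(out$generation, out$hap_index, out$type), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ancestry_events
#' @export
read_ancestry_events <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE,
                       colClasses = c(positions = "character")))
}

#' @export
print.ancestry_log <- function(x, ...) {
  cat(sprintf("<ancestry_log: %d generations, %d recombination events, %d loci>\n",
              length(x$sizes) - 1L, nrow(x$rec), length(x$homolog_bits)))
  invisible(x)
}
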