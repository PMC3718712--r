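# Backward Event Graph construction: backtracking survivors and their
# surviving super-regions, a-posteriori neutral mutation placement, and the
# forward graph-building pass.
#
# Regions are closed integer bp intervals (r_S, r_E); the empty region is
# (Inf, 0).  A haplotype's true surviving material may be fragmented; the
# super-region (first segment start, last segment end) over-approximates it
# and the exact fragmentation is recovered later, during sequence
# extraction.

#' An empty surviving region
#' @return Numeric vector `c(Inf, 0)`.
#' @export
empty_region <- function() c(Inf, 0)

#' Is a surviving region empty?
#' @param region numeric `c(r_S, r_E)`.
#' @return Logical.
#' @export
region_is_empty <- function(region) region[1] > region[2]

.region_to_int <- function(region) {
  if (region_is_empty(region)) c(.Machine$integer.max, 0L)
  else as.integer(region)
}
.region_from_int <- function(rs, re) {
  if (rs > re) empty_region() else c(rs, re)
}

#' Propagate a surviving region through one inheritance event
#'
#' The child's region is intersected with its donor segments (`[0, b1)` from
#' the parent, then alternating with the homolog) and each donor's
#' super-region is extended to cover its share (min of starts, max of ends).
#' The recombination is *kept* only if some breakpoint actually splits the
#' child's region, i.e. both donors receive material; a single-breakpoint
#' event with `b <= r_S` or `b > r_E` is transparent — the child inherits
#' from only one haplotype and maps directly to it.
#'
#' @param child_region numeric `c(r_S, r_E)` of the child.
#' @param breakpoints sorted breakpoints (possibly empty: plain inheritance).
#' @param parent_region,homolog_region current super-regions of the parent
#'   haplotype and its homolog.
#' @return List with updated `parent_region`, `homolog_region`, and
#'   `keep_recombination`.
#' @examples
#' propagate_region(c(0, 100), 40, empty_region(), empty_region())
#' propagate_region(c(50, 100), 40, empty_region(), empty_region())  # transparent
#' @export
propagate_region <- function(child_region, breakpoints = integer(0),
                             parent_region = empty_region(),
                             homolog_region = empty_region()) {
  c_int <- .region_to_int(child_region)
  p_int <- .region_to_int(parent_region)
  h_int <- .region_to_int(homolog_region)
  res <- cpp_propagate_region(c_int[1], c_int[2], as.integer(breakpoints),
                              p_int[1], p_int[2], h_int[1], h_int[2])
  list(parent_region = .region_from_int(res$parent_rs, res$parent_re),
       homolog_region = .region_from_int(res$hom_rs, res$hom_re),
       keep_recombination = res$keep,
       donor = res$donor) # 0 parent / 1 homolog for transparent events
}

#' Backtrack survivors and surviving regions
#'
#' Starting from the present generation, where every (selected) haplotype
#' gets the maximal region `[0, L]`, regions are propagated parent-ward
#' through the ancestry.  A haplotype of an earlier generation is a
#' *survivor* if its region ends up non-empty, i.e. it may have contributed
#' sequence to the present.  Recombination events that split a surviving
#' region are marked as kept (they become R-nodes).
#'
#' @param x a `forward_run` or an `ancestry_log`.
#' @param locus locus index (1-based).
#' @param present 0-based indices of present haplotypes to seed (default:
#'   all of the present generation).
#' @param L sequence length (required when `x` is an `ancestry_log`).
#' @return An object of class `survivor_set`: per-generation survivor
#'   indices and regions, kept-recombination flags, and the locus's
#'   recombination events.
#' @export
backtrack_survivors <- function(x, locus = 1, present = NULL, L = NULL) {
  anc <- if (inherits(x, "forward_run")) x$ancestry else x
  stopifnot(inherits(anc, "ancestry_log"))
  if (is.null(L)) {
    if (!inherits(x, "forward_run")) stop("give L when passing an ancestry_log")
    L <- x$params$locus_lengths[locus]
  }
  n_haps <- anc$n_haps
  if (is.null(present)) present <- seq_len(n_haps[length(n_haps)]) - 1L
  rec <- anc$rec[anc$rec$locus == locus, , drop = FALSE]
  pm <- hap_parent_map(anc, locus)
  res <- cpp_backtrack(pm, n_haps, rec$generation, rec$hap_index,
                       rec$breakpoints, as.integer(L), as.integer(present))
  structure(list(survivors = res$survivors, rs = res$rs, re = res$re,
                 keep = res$keep, donor = res$donor, rec = rec, L = as.integer(L),
                 locus = locus, n_haps = n_haps, present = present),
            class = "survivor_set")
}

#' @export
print.survivor_set <- function(x, ...) {
  n <- vapply(x$survivors, length, integer(1))
  cat(sprintf("<survivor_set: locus %d, %d generations, %d..%d survivors, %d/%d recombinations kept>\n",
              x$locus, length(n) - 1L, min(n), max(n), sum(x$keep),
              length(x$keep)))
  invisible(x)
}

#' Survivor counts per generation
#'
#' Includes the reduction factor `F = |S_i| / n_haplotypes(i)` by which the
#' expected number of neutral mutations to simulate is reduced in
#' generation `i`.
#'
#' @param ss a `survivor_set`.
#' @return Tibble with `generation`, `n_survivors`, `n_haps`, `F`.
#' @export
survivor_counts <- function(ss) {
  stopifnot(inherits(ss, "survivor_set"))
  gens <- seq_along(ss$survivors) - 1L
  n <- vapply(ss$survivors, length, integer(1))
  tibble(generation = gens, n_survivors = n, n_haps = ss$n_haps,
         F = n / ss$n_haps)
}

#' Place neutral mutations on surviving lineages
#'
#' For each generation and each survivor haplotype the mutation count is
#' Poisson with the full per-gamete neutral rate `mu * L *
#' neutral_fraction` (times the ancestry share of the mode); positions are
#' uniform on `[0, L)` and draws falling outside the survivor's
#' super-region are discarded.  Relative to simulating every haplotype the
#' expected effort is reduced by the factor `F = |S_i| / (2 N_i)` per
#' generation.
#'
#' @param ss a `survivor_set`.
#' @param params a [sim_params()] object.
#' @return Tibble of M-node stubs: `generation`, `hap_index`, `position`,
#'   `base` (derived, never the reference), sorted by generation.
#' @export
place_neutral_mutations <- function(ss, params) {
  stopifnot(inherits(ss, "survivor_set"), inherits(params, "sim_params"))
  anc_share <- switch(params$mode, "for" = 0, anc = 1,
                      mix = 1 - params$mix_forward_fraction)
  rate <- params$mu * ss$L * params$neutral_fraction * anc_share
  res <- cpp_place_neutral(ss$survivors, ss$rs, ss$re, ss$L, rate)
  tibble(generation = res$generation, hap_index = res$hap_index,
         position = res$position, base = res$base)
}

#' Build the Backward Event Graph
#'
#' Constructs the BEG forward in time: node references are propagated along
#' the parent maps; a kept recombination replaces the propagated reference
#' by an R-node with one edge to the donor of `[0, b1)` and one to the
#' homolog's reference, and each mutation stub stacks an M-node (out-degree
#' 1) on its haplotype's current reference.  Node 0 is the founder
#' sentinel; every present haplotype resolves to it by traversal.
#'
#' @param x a `forward_run` or `ancestry_log`.
#' @param ss the matching `survivor_set` (same locus).
#' @param neutral_mutations M-node stub tibble (`generation`, `hap_index`,
#'   `position`, `base`), e.g. from [place_neutral_mutations()].
#' @param check validate the graph's structural invariants after building
#'   (default `TRUE`).
#' @param check_stubs validate that every stub references a survivor
#'   haplotype (default `TRUE`; the pipeline disables this for stubs coming
#'   straight from [place_neutral_mutations()], which are survivors by
#'   construction).
#' @return An object of class `beg`.
#' @export
build_beg <- function(x, ss, neutral_mutations = NULL, check = TRUE,
                      check_stubs = TRUE) {
  anc <- if (inherits(x, "forward_run")) x$ancestry else x
  stopifnot(inherits(anc, "ancestry_log"), inherits(ss, "survivor_set"))
  if (is.null(neutral_mutations))
    neutral_mutations <- tibble(generation = integer(0), hap_index = integer(0),
                                position = integer(0), base = integer(0))
  m <- neutral_mutations[order(neutral_mutations$generation), , drop = FALSE]
  if (check_stubs && nrow(m) > 0) {
    surv_by_gen <- ss$survivors
    ok <- vapply(seq_len(nrow(m)), function(i) {
      g <- m$generation[i]
      g >= 1 && g < length(surv_by_gen) &&
        m$hap_index[i] %in% surv_by_gen[[g + 1L]]
    }, logical(1))
    if (!all(ok))
      stop("mutation stub references a non-survivor haplotype (contract violation)")
  }
  pm <- hap_parent_map(anc, ss$locus)
  res <- cpp_build_graph(pm, anc$n_haps, ss$rec$generation, ss$rec$hap_index,
                         ss$keep, ss$donor, m$generation, m$hap_index)
  beg <- structure(list(kind = res$kind, generation = res$generation,
                        hap_index = res$hap_index, payload = res$payload,
                        e1 = res$e1, e2 = res$e2, entries = res$entries,
                        rec = ss$rec, muts = m, L = ss$L, locus = ss$locus),
                   class = "beg")
  if (check) beg_check(beg)
  beg
}

#' Structural invariants of a BEG
#'
#' Asserts that M-nodes have out-degree 1, R-nodes out-degree 2, that every
#' edge points to an earlier node (so the graph is acyclic and anchored at
#' the founder sentinel), and that edges never point forward in time.
#'
#' @param beg a `beg` object.
#' @return `TRUE` invisibly, or an error.
#' @export
beg_check <- function(beg) {
  stopifnot(inherits(beg, "beg"))
  n <- length(beg$kind)
  id <- seq_len(n) - 1L
  m <- beg$kind == 1L
  r <- beg$kind == 2L
  if (any(beg$e2[m] != -1L) || any(beg$e1[m] < 0L))
    stop("M-node out-degree must be 1")
  if (any(beg$e1[r] < 0L) || any(beg$e2[r] < 0L))
    stop("R-node out-degree must be 2")
  tgt <- c(beg$e1[m | r], beg$e2[r])
  src <- c(id[m | r], id[r])
  if (any(tgt >= src))
    stop("edges must point to earlier nodes (acyclicity)")
  if (any(beg$generation[tgt + 1L] > beg$generation[src + 1L]))
    stop("edges must not point forward in generation")
  invisible(TRUE)
}

#' @export
print.beg <- function(x, ...) {
  cat(sprintf("<beg: locus %d, %d M-nodes, %d R-nodes, %d present entries>\n",
              x$locus, sum(x$kind == 1L), sum(x$kind == 2L),
              length(x$entries)))
  invisible(x)
}

#' Export / import a BEG as a TSV edge list
#'
#' One row per node: id, kind (`F`/`M`/`R`), generation, haplotype index,
#' payload (mutation position or comma-separated breakpoints), and the one
#' or two child-to-parent edges (`e1` toward the donor of the upstream
#' segment, `e2` toward the homolog donor).
#'
#' @param beg a `beg` object.
#' @param path output file.
#' @return `path` invisibly; `read_beg()` returns the node tibble.
#' @export
write_beg <- function(beg, path) {
  payload_str <- character(length(beg$kind))
  m <- which(beg$kind == 1L)
  r <- which(beg$kind == 2L)
  payload_str[m] <- as.character(beg$muts$position[beg$payload[m] + 1L])
  payload_str[r] <- vapply(beg$rec$breakpoints[beg$payload[r] + 1L],
                           function(b) paste(b, collapse = ","), "")
  df <- data.frame(node_id = seq_along(beg$kind) - 1L,
                   kind = c("F", "M", "R")[beg$kind + 1L],
                   generation = beg$generation, hap_index = beg$hap_index,
                   payload = payload_str, e1 = beg$e1, e2 = beg$e2)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beg
#' @export
read_beg <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE,
                       colClasses = c(payload = "character")))
}
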