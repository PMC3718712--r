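# One-shot pipeline: forward simulation, survivor backtracking, neutral
# placement, graph construction and sequence extraction, per unlinked locus.

# bits of the forward-carried mutations for the given haplotypes
.forward_bits <- function(fr, locus, haplotypes, neutral_only = FALSE,
                          include_fixed = FALSE) {
  reg <- fr$registry_raw
  L <- fr$params$locus_lengths[locus]
  lists <- fr$final_haps[[locus]][haplotypes + 1L]
  if (neutral_only)
    lists <- lapply(lists, function(h) h[reg$is_neutral[h + 1L]])
  ids_all <- unique(unlist(lists))
  fixed_rows <- integer(0)
  if (include_fixed) {
    fx <- reg$fixed_generation >= 0 & reg$locus == locus - 1L
    if (neutral_only) fx <- fx & reg$is_neutral
    fixed_rows <- which(fx)
  }
  cand <- c(ids_all + 1L, fixed_rows) # 1-based registry rows
  pos <- sort(unique(reg$position[cand]))
  bits <- matrix(FALSE, length(lists), length(pos))
  for (i in seq_along(lists)) {
    h <- lists[[i]]
    if (length(h)) bits[i, match(reg$position[h + 1L], pos)] <- TRUE
  }
  if (length(fixed_rows))
    bits[, match(unique(reg$position[fixed_rows]), pos)] <- TRUE
  first <- cand[!duplicated(reg$position[cand])]
  first <- first[order(reg$position[first])]
  meta <- tibble(position = reg$position[first],
                 base = c("A", "C", "G", "T")[reg$base[first] + 1L],
                 s = reg$s[first],
                 is_neutral = as.logical(reg$is_neutral[first]))
  hap_matrix(bits, pos, mutations = meta, L = L, haplotypes = haplotypes)
}

# OR-combine hap matrices over the union of their positions
.combine_hap <- function(mats, L) {
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 1) return(mats[[1]])
  pos <- sort(unique(unlist(lapply(mats, function(m) m$positions))))
  bits <- matrix(FALSE, nrow(mats[[1]]$bits), length(pos))
  metas <- list()
  for (m in mats) {
    if (length(m$positions)) {
      idx <- match(m$positions, pos)
      bits[, idx] <- bits[, idx] | m$bits
    }
    if (!is.null(m$mutations)) metas[[length(metas) + 1L]] <- m$mutations
  }
  meta <- do.call(rbind, metas)
  meta <- meta[!duplicated(meta$position), , drop = FALSE]
  meta <- meta[order(meta$position), , drop = FALSE]
  hap_matrix(bits, pos, mutations = meta, L = L,
             haplotypes = mats[[1]]$haplotypes)
}

#' Run the full simulation pipeline
#'
#' Runs the forward engine, samples present-day haplotypes, and — unless
#' every mutation was already handled forward in time — backtracks the
#' survivors, places neutral mutations a posteriori, builds the Backward
#' Event Graph and extracts the sampled sequences from it.  One graph is
#' generated per unlinked locus.
#'
#' @param params a [sim_params()] object.
#' @param store_graph keep the per-locus BEG and survivor sets in the
#'   result (memory-heavy for long runs; default `FALSE`).
#' @param drop_mono drop sites monomorphic within the sample (default
#'   `TRUE`, matching the usual polymorphism-table convention).
#' @return An object of class `sim_result` with elements `params`,
#'   `sample` (0-based haplotype indices), `matrices` (list of
#'   [hap_matrix], one per locus), `mutations` (all mutation records with
#'   their source path), and optionally `graphs` / `survivor_sets`.
#' @examples
#' p <- sim_params(N_e = 30, L = 2e4, mu = 5e-7, r = 5e-7,
#'                 n_generations = 300, sample_size = 12, seed = 9)
#' res <- simulate_population(p)
#' summary_stats(res$matrices[[1]])
#' @export
simulate_population <- function(params, store_graph = FALSE,
                                drop_mono = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  fr <- run_forward(params)
  nh <- 2L * fr$sizes[length(fr$sizes)]
  sample_idx <- sort(sample.int(nh, params$sample_size) - 1L)

  use_beg <- params$mode != "for" && params$neutral_fraction > 0 &&
    params$mu > 0
  matrices <- vector("list", params$n_loci)
  graphs <- if (store_graph) vector("list", params$n_loci)
  ssets <- if (store_graph) vector("list", params$n_loci)
  placed <- list()

  for (l in seq_len(params$n_loci)) {
    L <- params$locus_lengths[l]
    mbeg <- NULL
    if (use_beg || store_graph) {
      ss <- backtrack_survivors(fr, l)
      stubs <- place_neutral_mutations(ss, params)
      beg <- build_beg(fr, ss, stubs, check_stubs = FALSE)
      if (nrow(stubs) > 0)
        mbeg <- extract_sequences(beg, haplotypes = sample_idx,
                                  fraction = params$explicit_node_fraction)
      if (store_graph) {
        graphs[[l]] <- beg
        ssets[[l]] <- ss
      }
      if (nrow(stubs)) placed[[length(placed) + 1L]] <-
        tibble(locus = l, position = stubs$position,
               origin_generation = stubs$generation,
               hap_index = stubs$hap_index,
               base = c("A", "C", "G", "T")[stubs$base + 1L],
               s = 0, is_neutral = TRUE, fixed_generation = NA_integer_)
    }
    fwd <- .forward_bits(fr, l, sample_idx)
    mat <- .combine_hap(list(mbeg, fwd), L)
    if (drop_mono) mat <- drop_monomorphic(mat)
    matrices[[l]] <- mat
  }

  muts <- fr$mutations
  muts$source <- rep("forward", nrow(muts))
  if (length(placed)) {
    pl <- do.call(rbind, placed)
    pl$source <- rep("ancestry", nrow(pl))
    muts <- rbind(muts, pl[, names(muts)])
  }

  structure(list(params = params, sample = sample_idx, matrices = matrices,
                 mutations = muts, sizes = fr$sizes,
                 graphs = graphs, survivor_sets = ssets),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  st <- do.call(rbind, lapply(x$matrices, summary_stats))
  cat(sprintf("<sim_result: %d loci, sample of %d haplotypes, mode %s>\n",
              x$params$n_loci, x$params$sample_size,
              toupper(paste0("af-", x$params$mode))))
  cat(sprintf("  total segregating sites: %d\n", sum(st$S)))
  invisible(x)
}

#' Write every output of a simulation run
#'
#' Per locus: the packed-bit matrix with TSV sidecar
#' ([write_haplotype_matrix()]), a mutation metadata TSV, the BEG edge list
#' (when graphs were stored) and an ms-format mirror of the matrix.
#'
#' @param res a `sim_result`.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(res, prefix) {
  files <- character(0)
  for (l in seq_along(res$matrices)) {
    pl <- if (length(res$matrices) > 1) sprintf("%s.locus%d", prefix, l) else prefix
    write_haplotype_matrix(res$matrices[[l]], pl)
    files <- c(files, paste0(pl, c(".bin", ".positions.tsv")))
    write_ms(res$matrices[[l]], paste0(pl, ".ms"))
    files <- c(files, paste0(pl, ".ms"))
    if (!is.null(res$graphs) && !is.null(res$graphs[[l]])) {
      write_beg(res$graphs[[l]], paste0(pl, ".beg.tsv"))
      files <- c(files, paste0(pl, ".beg.tsv"))
    }
  }
  mt <- paste0(prefix, ".mutations.tsv")
  write.table(res$mutations, mt, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, mt)
  invisible(files)
}
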