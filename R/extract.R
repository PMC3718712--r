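# Sequence extraction: turn a BEG into present-day neutral haplotypes.
# During extraction the *exact* fragmented region of interest is maintained
# (each R-node splits it between its two donors), so mutations that were
# placed inside the super-region but outside the true surviving segments
# are filtered here.  Mutations are mapped to bit-array columns over the
# global sorted position list; carrying material over from cached explicit
# nodes is a masked bitwise OR.

#' Count traversal visits per BEG node
#'
#' One traversal is started per present entry; a traversal stops at nodes
#' already visited (still counting the reach), so `v` is the number of
#' entry-traversals that reached each node.  Nodes with `v >= 2` are
#' coalescent nodes: surviving material of two lineages meets there.
#'
#' @param beg a `beg` object.
#' @param haplotypes 0-based present haplotype indices whose entries seed
#'   the traversals (default: all).
#' @return Integer vector of visit counts, one per node.
#' @export
count_visits <- function(beg, haplotypes = NULL) {
  stopifnot(inherits(beg, "beg"))
  entries <- if (is.null(haplotypes)) beg$entries else beg$entries[haplotypes + 1L]
  cpp_count_visits(beg$kind, beg$e1, beg$e2, entries)
}

#' Select nodes for explicit sequence materialization
#'
#' The `ceiling(fraction * n)` non-founder nodes with the highest visit
#' count are flagged; their packed-bit sequences are cached during
#' extraction so traversals can stop there.  Ties are broken toward higher
#' generation (younger nodes first).  This is purely an optimization: the
#' extracted sequences do not depend on `fraction`.
#'
#' @param beg a `beg` object.
#' @param v visit counts from [count_visits()].
#' @param fraction fraction of nodes to store explicitly, in `(0, 1]`.
#' @return Logical vector, one flag per node.
#' @export
select_explicit_nodes <- function(beg, v, fraction = 0.05) {
  stopifnot(inherits(beg, "beg"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("explicit-node fraction must lie in (0, 1]")
  n <- length(beg$kind)
  flags <- logical(n)
  cand <- which(beg$kind != 0L) # founder sentinel excluded
  if (length(cand) == 0) return(flags)
  k <- ceiling(fraction * length(cand))
  ord <- cand[order(-v[cand], -beg$generation[cand])]
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Extract present-day sequences from a BEG
#'
#' Traverses the graph from each requested entry while maintaining the
#' exact, possibly fragmented region of interest: R-nodes split the region
#' between their two donor edges, and an M-node sets its bit only when its
#' position lies inside the current region.  Traversals stop early at
#' explicit nodes, whose cached rows are OR-merged restricted to the region
#' of interest.
#'
#' @param beg a `beg` object.
#' @param haplotypes 0-based present haplotype indices to extract
#'   (default: all entries).
#' @param fraction explicit-node fraction (default 0.05); see
#'   [select_explicit_nodes()].
#' @param explicit optional logical per-node flags overriding `fraction`.
#' @return A [hap_matrix] whose columns are the sorted neutral mutation
#'   positions of the graph (duplicated positions collapse to one column).
#' @export
extract_sequences <- function(beg, haplotypes = NULL, fraction = 0.05,
                              explicit = NULL) {
  stopifnot(inherits(beg, "beg"))
  if (is.null(haplotypes)) haplotypes <- seq_along(beg$entries) - 1L
  entries <- beg$entries[haplotypes + 1L]
  if (any(is.na(entries) | entries < 0))
    stop("unresolvable entry: broken graph")
  positions <- sort(unique(beg$muts$position))
  if (is.null(explicit)) {
    v <- cpp_count_visits(beg$kind, beg$e1, beg$e2, entries)
    explicit <- select_explicit_nodes(beg, v, fraction)
  }
  m_col <- match(beg$muts$position, positions) - 1L
  bits <- cpp_extract(beg$kind, beg$e1, beg$e2, beg$payload,
                      beg$rec$breakpoints, m_col, beg$muts$position,
                      positions, entries, explicit, beg$L)
  meta <- tibble(position = positions,
                 base = c("A", "C", "G", "T")[
                   beg$muts$base[match(positions, beg$muts$position)] + 1L],
                 s = 0, is_neutral = TRUE)
  hap_matrix(bits, positions, mutations = meta, L = beg$L,
             haplotypes = haplotypes)
}

# ---------------------------------------------------------------------------
# Haplotype matrix
# ---------------------------------------------------------------------------

#' Haplotype polymorphism matrix
#'
#' Present-day haplotypes as one bit row per haplotype over the sorted list
#' of segregating positions; a set bit means the row carries a derived
#' allele at that position.
#'
#' @param bits logical matrix (rows = haplotypes, columns = positions).
#' @param positions sorted integer positions, one per column.
#' @param mutations optional per-position metadata tibble.
#' @param L sequence length in bp.
#' @param haplotypes optional 0-based haplotype indices labelling the rows.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(bits, positions, mutations = NULL, L,
                       haplotypes = NULL) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "logical"
  positions <- as.integer(positions)
  if (ncol(bits) != length(positions))
    stop("row length must equal the number of positions")
  if (length(positions) > 1 && is.unsorted(positions))
    stop("positions must be sorted")
  structure(list(bits = bits, positions = positions, mutations = mutations,
                 L = as.double(L), haplotypes = haplotypes),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix: %d haplotypes x %d sites over %g bp>\n",
              nrow(x$bits), ncol(x$bits), x$L))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$bits)

# drop monomorphic columns (all ancestral and, optionally, all derived)
drop_monomorphic <- function(m, drop_fixed = TRUE) {
  stopifnot(inherits(m, "hap_matrix"))
  cs <- colSums(m$bits)
  keep <- cs > 0
  if (drop_fixed) keep <- keep & cs < nrow(m$bits)
  hap_matrix(m$bits[, keep, drop = FALSE], m$positions[keep],
             mutations = if (!is.null(m$mutations)) m$mutations[keep, , drop = FALSE],
             L = m$L, haplotypes = m$haplotypes)
}

# ---------------------------------------------------------------------------
# Packed-bit binary output + TSV sidecar
# ---------------------------------------------------------------------------

.hm_magic <- charToRaw("BEGSIMBM")

#' Write / read a haplotype matrix as packed bits
#'
#' The binary file holds an 8-byte magic (`BEGSIMBM`), a version and the
#' dimensions as little-endian 32-bit integers, the sequence length as a
#' little-endian double, then one row per haplotype packed 8 sites per
#' byte (bit 0 of byte 0 is the first site; rows padded to whole bytes).
#' Positions and per-site metadata go to the TSV sidecar
#' `<prefix>.positions.tsv`.
#'
#' @param m a [hap_matrix].
#' @param prefix output path prefix; writes `<prefix>.bin` and
#'   `<prefix>.positions.tsv`.
#' @return The prefix, invisibly; `read_haplotype_matrix()` returns the
#'   [hap_matrix].
#' @export
write_haplotype_matrix <- function(m, prefix) {
  stopifnot(inherits(m, "hap_matrix"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(.hm_magic, con)
  writeBin(as.integer(c(1L, nrow(m$bits), ncol(m$bits))), con, size = 4,
           endian = "little")
  writeBin(as.double(m$L), con, size = 8, endian = "little")
  nbytes <- ceiling(ncol(m$bits) / 8)
  for (i in seq_len(nrow(m$bits))) {
    row <- m$bits[i, ]
    length(row) <- nbytes * 8L # pad with NA -> FALSE below
    row[is.na(row)] <- FALSE
    writeBin(packBits(row, "raw"), con)
  }
  meta <- if (!is.null(m$mutations)) m$mutations else tibble(position = m$positions)
  meta$L <- rep(m$L, nrow(meta))
  write.table(meta, paste0(prefix, ".positions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_haplotype_matrix
#' @export
read_haplotype_matrix <- function(prefix) {
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic, .hm_magic)) stop("not a begsim haplotype matrix")
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  L_bin <- readBin(con, "double", 1, size = 8, endian = "little")
  nrow <- hdr[2]; ncol <- hdr[3]
  nbytes <- ceiling(ncol / 8)
  bits <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(nrow)) {
    raw <- readBin(con, "raw", nbytes)
    b <- as.logical(rawToBits(raw))
    bits[i, ] <- b[seq_len(ncol)]
  }
  meta <- as_tibble(read.delim(paste0(prefix, ".positions.tsv"),
                               stringsAsFactors = FALSE))
  meta$L <- NULL
  hap_matrix(bits, meta$position, mutations = meta, L = L_bin)
}
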