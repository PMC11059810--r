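# Windowed extraction from a whole-genome alignment matrix, the
# parsimony-informative-site filter, and a neighbour-joining stand-in for
# per-window tree inference.

#' Read an alignment matrix from FASTA
#'
#' All rows must have equal length; soft-masked (lowercase) bases are
#' uppercased on read, since repeat masking is a sequence-level concern
#' handled before alignment.
#'
#' @param path FASTA path.
#' @return Named character vector of aligned sequences, one per taxon.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(out))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  if (anyDuplicated(names(out)))
    stop("duplicate taxon labels", call. = FALSE)
  out
}

#' Extract fixed-size windows from an alignment
#'
#' Windows start at column 0 and recur with stride
#' `window_size + gap_between` (a gap of `gap_between` alignment columns
#' between consecutive windows); only full-length windows are returned, so
#' a truncated terminal window is dropped.  Each window's
#' parsimony-informative site count is populated on extraction.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param window_size Window width in alignment columns (default 1000).
#' @param gap_between Columns skipped between windows (default 20000).
#' @return List of windows, each a list with `start`, `end` (0-based
#'   half-open columns), `seqs` and `informative_count`.
#' @export
extract_windows <- function(alignment, window_size = 1000,
                            gap_between = 20000) {
  stopifnot(length(alignment) >= 1, window_size >= 1, gap_between >= 0)
  len <- unique(nchar(alignment))
  stopifnot(length(len) == 1L)
  alignment <- toupper(alignment)
  starts <- seq.int(0L, by = window_size + gap_between,
                    length.out = max(0L, (len - window_size) %/%
                                       (window_size + gap_between) + 1L))
  starts <- starts[starts + window_size <= len]
  lapply(starts, function(s) {
    seqs <- substring(alignment, s + 1L, s + window_size)
    names(seqs) <- names(alignment)
    list(start = s, end = s + window_size, seqs = seqs,
         informative_count = count_informative_sites(seqs))
  })
}

#' Count parsimony-informative columns
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' bases each occur in at least two taxa; gaps, `N` and other ambiguity
#' codes are ignored for state counting.
#'
#' @param window A window from [extract_windows()], or a character vector
#'   of equal-length sequences (>= 2).
#' @return Integer count.
#' @export
count_informative_sites <- function(window) {
  seqs <- if (is.list(window)) window$seqs else window
  stopifnot(length(seqs) >= 2)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  tallies <- vapply(bases, function(b) colSums(mat == b),
                    numeric(ncol(mat)))
  if (is.null(dim(tallies))) tallies <- matrix(tallies, nrow = 1)
  sum(rowSums(tallies >= 2) >= 2)
}

#' Filter windows by informative-site count
#'
#' Keeps windows with at least `min_informative` parsimony-informative
#' sites (the published pipeline removes windows with fewer than 10, so a
#' window with exactly 10 is kept).
#'
#' @param windows List of windows from [extract_windows()].
#' @param min_informative Minimum informative-site count (default 10).
#' @return List with `retained` (windows), `tally` (named vector:
#'   retained, removed).
#' @export
filter_windows <- function(windows, min_informative = 10) {
  stopifnot(min_informative >= 0)
  keep <- vapply(windows, function(w) w$informative_count >= min_informative,
                 logical(1))
  list(retained = windows[keep],
       tally = c(retained = sum(keep), removed = sum(!keep)))
}

#' Neighbour-joining tree for one window on K2P distances
#'
#' Pairwise K2P distances (columns with gaps or ambiguity in either
#' sequence excluded per pair) feed `ape::nj`; negative branch lengths are
#' clamped to zero.  Taxa are ordered by label before distance computation
#' so ties break deterministically.  This is a stand-in for likelihood tree
#' inference: real pipelines typically supply externally built trees.
#'
#' @param window A window from [extract_windows()] or a named character
#'   vector of >= 3 aligned sequences.
#' @return An `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(window) {
  seqs <- if (is.list(window)) window$seqs else window
  stopifnot(length(seqs) >= 3, !is.null(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  labels <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      k <- tryCatch(k2p_distance(seqs[[i]], seqs[[j]]), error = function(e)
        stop("cannot compute distance for pair ", labels[i], "/", labels[j],
             ": ", conditionMessage(e), call. = FALSE))
      d[i, j] <- d[j, i] <- as.numeric(k)
    }
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Simulate a star-phylogeny alignment
#'
#' Draws a random ancestral sequence and derives each taxon's row by
#' independent K2P mutation at its own divergence level — a deliberately
#' simple generator for exercising window extraction, the informative-site
#' filter and distance trees (no indels, no rate variation).
#'
#' @param taxa Taxon labels.
#' @param length Alignment length in columns (ignored when `ancestor` is
#'   supplied).
#' @param divergence Per-taxon expected substitutions/site from the
#'   ancestor (recycled).
#' @param ti_tv_ratio Transition:transversion count ratio.
#' @param seed Integer seed or `NULL`.
#' @param ancestor Optional ancestral sequence to evolve from instead of a
#'   random one; chaining calls through this argument builds
#'   tree-structured alignments one internal node at a time.
#' @return Named character vector of aligned sequences.
#' @export
simulate_alignment <- function(taxa, length = 1000, divergence = 0.05,
                               ti_tv_ratio = 2, seed = NULL,
                               ancestor = NULL) {
  stopifnot(length(taxa) >= 1, length >= 1, all(divergence >= 0))
  divergence <- rep_len(divergence, length(taxa))
  with_seed(seed, {
    anc <- if (is.null(ancestor))
      sample(names(TRANSITION), length, replace = TRUE)
    else strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
    out <- vapply(seq_along(taxa), function(i)
      paste(evolve_k2p(anc, divergence[i], 1, ti_tv_ratio), collapse = ""),
      character(1))
    stats::setNames(out, taxa)
  })
}

#' Write an alignment to FASTA
#'
#' @param alignment Named character vector of sequences.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment), path)
  invisible(path)
}
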