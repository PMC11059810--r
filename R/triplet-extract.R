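# Rooted-triplet extraction from per-locus gene trees.

#' Extract one locus's rooted triplet topology and internal branch length
#'
#' Prunes a gene tree to three ingroup taxa plus the outgroup, roots it on
#' the outgroup, and reads off which ingroup pair forms the cherry and the
#' length of the internal branch subtending it (branch lengths along pruned
#' paths are summed by the pruning).  A multifurcating or zero-length cherry
#' is reported as topology `"unresolved"`: such loci enter topology tallies
#' but are excluded from mixture fitting.
#'
#' @param tree An `ape::phylo` object or a Newick string.
#' @param taxa Character vector of three ingroup tip labels.
#' @param outgroup Outgroup tip label.
#' @return List with `topology` (canonical `"X|Y"` pair id, or
#'   `"unresolved"`), `t` (internal branch length; `NA` when unresolved with
#'   no internal edge) and `tips` (the four labels used).  When a required
#'   tip is missing, a list with `skipped = TRUE` and the `reason`.
#' @export
extract_triplet <- function(tree, taxa, outgroup) {
  stopifnot(length(taxa) == 3L, length(outgroup) == 1L)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  need <- c(taxa, outgroup)
  if (!all(need %in% tree$tip.label)) {
    return(list(skipped = TRUE,
                reason = paste("missing taxa:",
                               paste(setdiff(need, tree$tip.label),
                                     collapse = ", "))))
  }
  tr <- ape::keep.tip(tree, need)
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr3 <- ape::drop.tip(tr, outgroup)
  res <- list(topology = "unresolved", t = NA_real_, tips = need)
  if (is.null(tr3) || tr3$Nnode < 2L) return(res)
  # rooted binary 3-tip tree: the non-root internal node subtends the cherry
  root_node <- ape::Ntip(tr3) + 1L
  internal <- which(tr3$edge[, 1] == root_node & tr3$edge[, 2] > ape::Ntip(tr3))
  if (length(internal) != 1L) return(res)   # multifurcation at the root
  cherry_node <- tr3$edge[internal, 2]
  t_len <- tr3$edge.length[internal]
  cherry_tips <- tr3$tip.label[tr3$edge[tr3$edge[, 1] == cherry_node, 2]]
  if (length(cherry_tips) != 2L) return(res)
  res$t <- t_len
  if (t_len > 0) res$topology <- topology_id(cherry_tips[1], cherry_tips[2])
  res
}

#' Extract triplet observations from many gene trees
#'
#' Applies [extract_triplet()] to each locus tree; loci missing any of the
#' four required tips are skipped with a logged reason (attribute
#' `"skipped"` of the result).
#'
#' @param trees List of `phylo` objects, a `multiPhylo`, or a character
#'   vector of Newick strings.
#' @inheritParams extract_triplet
#' @return Data frame with columns `locus`, `topology`, `t`; skipped loci in
#'   `attr(, "skipped")`.
#' @export
extract_triplets <- function(trees, taxa, outgroup) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- length(trees)
  rows <- vector("list", n)
  skipped <- list()
  for (i in seq_len(n)) {
    obs <- extract_triplet(trees[[i]], taxa, outgroup)
    if (isTRUE(obs$skipped)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(locus = i, reason = obs$reason)
      next
    }
    rows[[i]] <- data.frame(locus = i, topology = obs$topology, t = obs$t,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(locus = integer(), topology = character(),
                      t = numeric())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(locus = integer(),
                                          reason = character())
  out
}

#' Tally triplet topologies
#'
#' @param observations Data frame with a `topology` column (as produced by
#'   [extract_triplets()] or [simulate_triplet_loci()]), or a character
#'   vector of topology ids.
#' @return Named integer vector of counts (including `"unresolved"` if
#'   present) with attribute `"total"`.
#' @export
tally_topologies <- function(observations) {
  top <- if (is.data.frame(observations)) observations$topology
         else observations
  counts <- table(factor(top))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "total") <- sum(out)
  out
}

#' Percentage share of each topology
#'
#' @param counts Named counts (e.g. from [tally_topologies()]) or a numeric
#'   vector.
#' @param digits Decimal places; `0` reproduces integer-rounded shares.
#' @return Named numeric vector, `100 * count / total`, rounded.
#' @export
topology_share <- function(counts, digits = 2) {
  out <- round(100 * as.vector(counts) / sum(counts), digits)
  stats::setNames(out, names(counts))
}
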