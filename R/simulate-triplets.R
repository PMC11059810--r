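#' Multispecies-coalescent simulator configuration for a species triplet
#'
#' Describes the generative model for rooted three-taxon gene trees under the
#' multispecies coalescent (MSC) on the species topology
#' `((taxa[1], taxa[2]), taxa[3])`, with an optional locus-level introgression
#' pulse.  Times are in coalescent units (2N generations); branch lengths are
#' additionally emitted in substitutions/site via the linear scaling
#' `subst_scale`.
#'
#' @param taxa Character vector of three distinct ingroup labels; the first
#'   two form the species-tree sister pair.
#' @param outgroup Outgroup label, distinct from `taxa`.
#' @param t2 Species-tree internal branch length, coalescent units (>= 0).
#' @param t_root Branch length above the triplet ancestor before the outgroup
#'   divergence, coalescent units (>= 0).
#' @param gamma Per-locus introgression probability in \[0, 1\].  At an
#'   introgressed locus the `recipient` lineage follows the `donor`'s
#'   population history from the most recent species divergence onward.
#' @param donor,recipient Ingroup labels for the introgression pulse; must be
#'   set (and distinct) whenever `gamma > 0`.
#' @param subst_scale Substitutions/site per coalescent unit (> 0).
#' @param n_loci Number of loci to simulate (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `msc_config`.
#' @seealso [simulate_triplet_loci()]
#' @export
msc_config <- function(taxa = c("A", "B", "C"), outgroup = "O",
                       t2 = 1, t_root = 1, gamma = 0,
                       donor = NULL, recipient = NULL,
                       subst_scale = 0.01, n_loci = 1000, seed = NULL) {
  stopifnot(length(taxa) == 3L, !anyDuplicated(taxa),
            length(outgroup) == 1L, !outgroup %in% taxa,
            t2 >= 0, t_root >= 0, gamma >= 0, gamma <= 1,
            subst_scale > 0, n_loci >= 1)
  if (gamma > 0) {
    if (is.null(donor) || is.null(recipient))
      stop("`donor` and `recipient` must be set when gamma > 0", call. = FALSE)
    if (!all(c(donor, recipient) %in% taxa))
      stop("`donor` and `recipient` must be ingroup taxa", call. = FALSE)
    if (donor == recipient)
      stop("`donor` and `recipient` must differ", call. = FALSE)
  }
  structure(
    list(taxa = taxa, outgroup = outgroup, t2 = t2, t_root = t_root,
         gamma = gamma, donor = donor, recipient = recipient,
         subst_scale = subst_scale, n_loci = as.integer(n_loci), seed = seed),
    class = "msc_config")
}

#' @export
print.msc_config <- function(x, ...) {
  cat("MSC triplet configuration\n")
  cat(sprintf("  species tree : ((%s,%s),%s) + outgroup %s\n",
              x$taxa[1], x$taxa[2], x$taxa[3], x$outgroup))
  cat(sprintf("  T2 = %g, T_root = %g coalescent units; subst_scale = %g\n",
              x$t2, x$t_root, x$subst_scale))
  if (x$gamma > 0)
    cat(sprintf("  introgression: gamma = %g, %s -> %s\n",
                x$gamma, x$donor, x$recipient))
  cat(sprintf("  n_loci = %d\n", x$n_loci))
  invisible(x)
}

#' Simulate rooted triplet gene trees under the multispecies coalescent
#'
#' For each locus, with probability `gamma` the recipient lineage is swapped
#' into the donor's population at the most recent species divergence (an
#' introgression pulse); the effective lineage pair then undergoes the
#' standard three-taxon MSC: the pair coalesces within the internal branch of
#' length `t2` with probability `1 - exp(-t2)`; otherwise all three lineages
#' enter the ancestral population, where the first coalescence happens after
#' an Exponential(rate 3) waiting time between a uniformly chosen pair and
#' the second after a further Exponential(rate 1) time.  The gene-tree
#' internal branch is the time between the two coalescences.  Under pure
#' lineage sorting the discordant-locus internal branch is Exponential(mean
#' 1); concordant loci from within-branch coalescence carry an additional
#' shift — the signal the downstream mixture test exploits.
#'
#' Trees are serialized as rooted Newick with the outgroup attached above the
#' triplet ancestor and branch lengths in substitutions/site
#' (`subst_scale` times the coalescent-unit lengths).  The tip depth to the
#' most recent species divergence is fixed at 1 coalescent unit; it affects
#' only terminal branch lengths, never the topology or the internal branch.
#'
#' @param config An [msc_config()].
#' @return A list with components `trees` (character vector of Newick
#'   strings, one per locus) and `observations`, a data frame with columns
#'   `locus`, `topology` (canonical `"X|Y"` id of the cherry pair), `t_coal`
#'   and `t_subst` (internal branch length in coalescent units and
#'   substitutions/site) and `introgressed`.
#' @export
simulate_triplet_loci <- function(config) {
  stopifnot(inherits(config, "msc_config"))
  with_seed(config$seed, {
    n <- config$n_loci
    taxa <- config$taxa
    tau1 <- 1                       # tip depth to most recent divergence
    tau2 <- tau1 + config$t2        # depth of the triplet ancestor

    intro <- stats::runif(n) < config$gamma
    pair_x <- ifelse(intro, config$donor %||% NA_character_, taxa[1])
    pair_y <- ifelse(intro, config$recipient %||% NA_character_, taxa[2])
    # odd lineage = the ingroup taxon not in the effective pair
    odd <- vapply(seq_len(n), function(i)
      setdiff(taxa, c(pair_x[i], pair_y[i])), character(1))

    p_coal <- 1 - exp(-config$t2)
    u <- stats::runif(n)
    in_branch <- u < p_coal
    # conditional on u < p_coal, -log(1-u) is Exp(1) truncated to [0, t2]
    s <- -log1p(-u)

    h1 <- numeric(n)   # first (cherry) coalescence depth
    h2 <- numeric(n)   # second coalescence depth
    cherry_a <- character(n)
    cherry_b <- character(n)

    # within-internal-branch coalescence: cherry is the effective pair
    idx <- which(in_branch)
    if (length(idx)) {
      h1[idx] <- tau1 + s[idx]
      h2[idx] <- tau2 + stats::rexp(length(idx), rate = 1)
      cherry_a[idx] <- pair_x[idx]
      cherry_b[idx] <- pair_y[idx]
    }
    # deep coalescence: all three lineages exchangeable in the root population
    idx <- which(!in_branch)
    if (length(idx)) {
      h1[idx] <- tau2 + stats::rexp(length(idx), rate = 3)
      h2[idx] <- h1[idx] + stats::rexp(length(idx), rate = 1)
      pick <- sample.int(3L, length(idx), replace = TRUE)
      trio <- cbind(pair_x[idx], pair_y[idx], odd[idx])
      cherry_a[idx] <- trio[cbind(seq_along(idx), c(1L, 1L, 2L)[pick])]
      cherry_b[idx] <- trio[cbind(seq_along(idx), c(2L, 3L, 3L)[pick])]
    }

    other <- vapply(seq_len(n), function(i)
      setdiff(taxa, c(cherry_a[i], cherry_b[i])), character(1))
    h3 <- pmax(h2, tau2 + config$t_root) + stats::rexp(n, rate = 1)

    sc <- config$subst_scale
    trees <- sprintf("(((%s:%.10g,%s:%.10g):%.10g,%s:%.10g):%.10g,%s:%.10g);",
                     cherry_a, h1 * sc, cherry_b, h1 * sc,
                     (h2 - h1) * sc, other, h2 * sc,
                     (h3 - h2) * sc, config$outgroup, h3 * sc)

    topology <- mapply(topology_id, cherry_a, cherry_b, USE.NAMES = FALSE)
    obs <- data.frame(
      locus = seq_len(n),
      topology = topology,
      t_coal = h2 - h1,
      t_subst = (h2 - h1) * sc,
      introgressed = intro,
      stringsAsFactors = FALSE)
    list(trees = trees, observations = obs)
  })
}

#' Sample internal branch lengths from the lineage-sorting mixture
#'
#' Direct sampler for the two-component model the discordance test fits:
#' with probability `pi` a draw is Exponential(mean `lambda`) (pure lineage
#' sorting) and otherwise `C` plus an Exponential(mean `lambda`) (the shifted
#' component produced by introgression or by species-tree concordance).
#'
#' @param n Number of draws.
#' @param pi Mixing weight of the unshifted component, in \[0, 1\].
#' @param lambda Exponential mean (> 0).
#' @param C Non-negative shift of the second component.
#' @param seed Integer seed or `NULL`.
#' @return Numeric vector of `n` branch lengths.
#' @export
sample_mixture_lengths <- function(n, pi, lambda, C = 0, seed = NULL) {
  stopifnot(n >= 1, pi >= 0, pi <= 1, C >= 0)
  if (lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  with_seed(seed, {
    shifted <- stats::runif(n) >= pi
    stats::rexp(n, rate = 1 / lambda) + C * shifted
  })
}
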