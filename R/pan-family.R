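# Pan-genome gene-family classification: core / softcore / dispensable /
# private, saturation curves, and group-specific families.

#' Read an orthogroup membership table
#'
#' Accepts the OrthoFinder `Orthogroups.tsv` dialect (first column
#' `Orthogroup`, one column per genome, cells holding comma-separated gene
#' ids; empty cell means absent) or a plain integer-matrix TSV with the same
#' layout.  Cell values become per-genome gene counts.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, families x genomes, with family ids as row names
#'   and genome ids as column names.
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthogroup file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  genomes <- header[-1]
  if (!length(genomes)) stop("no genome columns in header", call. = FALSE)
  body <- cells[-1]
  ncol_exp <- length(header)
  counts <- matrix(0L, nrow = length(body), ncol = length(genomes),
                   dimnames = list(NULL, genomes))
  fam <- character(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    # trailing empty cells may be dropped by strsplit; pad them back
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    if (length(row) > ncol_exp)
      stop("ragged row at line ", i + 1L, " of ", path, call. = FALSE)
    fam[i] <- row[1]
    vals <- trimws(row[-1])
    num <- suppressWarnings(as.integer(vals))
    is_int <- !is.na(num) | vals == ""
    counts[i, ] <- ifelse(vals == "", 0L,
                          ifelse(is_int, ifelse(is.na(num), 0L, num),
                                 lengths(strsplit(vals, ","))))
  }
  if (anyDuplicated(fam))
    stop("duplicate family id at line ",
         which(duplicated(fam))[1] + 1L, " of ", path, call. = FALSE)
  rownames(counts) <- fam
  counts
}

#' Write an orthogroup count matrix as TSV
#'
#' @param matrix Families x genomes count matrix.
#' @param path Output path.
#' @export
write_orthogroups <- function(matrix, path) {
  df <- data.frame(Orthogroup = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify gene families as core, softcore, dispensable or private
#'
#' With `G` genomes and presence defined as count >= 1: a family is *core*
#' when present in all `G`, *softcore* when present in at least
#' `ceiling(softcore_fraction * G)` but fewer than `G` (more than 90% of
#' genomes at the default), *private* when present in exactly one, and
#' *dispensable* otherwise.  With 13 genomes the default softcore band is
#' presence in exactly 12, so core + softcore together is presence in more
#' than 11 genomes.
#'
#' @param matrix Families x genomes count matrix (>= 2 genomes).
#' @param softcore_fraction Lower presence fraction of the softcore band.
#' @return An object of class `family_classification`: list with `category`
#'   (named factor per family), `presence` (genomes per family), `tally`,
#'   `pct` (two-decimal percentages) and `thresholds`.
#' @export
classify_families <- function(matrix, softcore_fraction = 0.90) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, all(matrix >= 0))
  G <- ncol(matrix)
  presence <- rowSums(matrix >= 1)
  if (any(presence == 0))
    stop("all-zero family rows are not allowed", call. = FALSE)
  soft_lo <- ceiling(softcore_fraction * G)
  category <- ifelse(presence == G, "core",
              ifelse(presence >= soft_lo, "softcore",
              ifelse(presence == 1, "private", "dispensable")))
  lev <- c("core", "softcore", "dispensable", "private")
  category <- factor(category, levels = lev)
  names(category) <- rownames(matrix)
  tally <- table(category)
  structure(
    list(category = category,
         presence = stats::setNames(presence, rownames(matrix)),
         tally = stats::setNames(as.integer(tally), lev),
         pct = round(100 * as.integer(tally) / nrow(matrix), 2) |>
           stats::setNames(lev),
         thresholds = list(softcore_fraction = softcore_fraction,
                           softcore_min_presence = soft_lo, n_genomes = G)),
    class = "family_classification")
}

#' @export
print.family_classification <- function(x, ...) {
  cat(sprintf("Gene-family classification over %d genomes (softcore >= %d)\n",
              x$thresholds$n_genomes, x$thresholds$softcore_min_presence))
  for (lv in names(x$tally))
    cat(sprintf("  %-11s %6d (%.2f%%)\n", lv, x$tally[[lv]], x$pct[[lv]]))
  invisible(x)
}

#' Pan- and core-family saturation curves
#'
#' For each of `n_permutations` random genome orderings and each prefix of
#' `k` genomes, counts the pan families (present in at least one of the
#' first `k`) and core families (present in all of the first `k`).  Pan
#' counts are non-decreasing and core counts non-increasing in `k` within
#' every single permutation.
#'
#' @param matrix Families x genomes count matrix.
#' @param n_permutations Number of random genome orderings (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `saturation_curve`: list with `summary` (data
#'   frame of per-`k` mean/min/max for both curves) and `pan`, `core`
#'   (n_permutations x G matrices of raw counts).
#' @export
saturation_curves <- function(matrix, n_permutations = 100, seed = NULL) {
  stopifnot(is.matrix(matrix), n_permutations >= 1)
  G <- ncol(matrix)
  pres <- matrix >= 1
  pan <- matrix(0L, n_permutations, G)
  core <- matrix(0L, n_permutations, G)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(G)
      acc_any <- rep(FALSE, nrow(matrix))
      acc_all <- rep(TRUE, nrow(matrix))
      for (k in seq_len(G)) {
        col <- pres[, ord[k]]
        acc_any <- acc_any | col
        acc_all <- acc_all & col
        pan[p, k] <- sum(acc_any)
        core[p, k] <- sum(acc_all)
      }
    }
  })
  summary <- data.frame(
    k = seq_len(G),
    pan_mean = colMeans(pan), pan_min = apply(pan, 2, min),
    pan_max = apply(pan, 2, max),
    core_mean = colMeans(core), core_min = apply(core, 2, min),
    core_max = apply(core, 2, max))
  structure(list(summary = summary, pan = pan, core = core,
                 n_permutations = n_permutations, seed = seed),
            class = "saturation_curve")
}

#' Families exclusive to a genome group
#'
#' Returns the families present (count >= 1) in at least one target genome
#' and absent from every non-target genome, together with the number of
#' member genes those families contribute in the target genomes.
#'
#' @param matrix Families x genomes count matrix.
#' @param target_genomes Non-empty subset of the genome ids.
#' @return List with `families` (ids), `n_families` and `gene_count`.
#' @export
group_specific_families <- function(matrix, target_genomes) {
  stopifnot(is.matrix(matrix), length(target_genomes) >= 1)
  unknown <- setdiff(target_genomes, colnames(matrix))
  if (length(unknown))
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  others <- setdiff(colnames(matrix), target_genomes)
  pres <- matrix >= 1
  in_target <- rowSums(pres[, target_genomes, drop = FALSE]) >= 1
  in_others <- if (length(others))
    rowSums(pres[, others, drop = FALSE]) >= 1 else rep(FALSE, nrow(matrix))
  sel <- in_target & !in_others
  fams <- rownames(matrix)[sel]
  list(families = fams, n_families = sum(sel),
       gene_count = sum(matrix[sel, target_genomes, drop = FALSE]))
}

#' Generate an orthogroup matrix with planted category proportions
#'
#' Draws each family's presence count to satisfy its planted category
#' (see [classify_families()]): core families are present in all genomes,
#' softcore in a uniform number within the softcore band, dispensable in
#' 2 up to one below the softcore band, private in exactly one.  Counts
#' where present are 1 plus a Poisson(0.2) paralogue excess.  Category
#' weights are converted to exact integer family counts by largest
#' remainder, so planted fractions are recovered exactly by
#' classification.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_families Number of families.
#' @param category_weights Numeric weights for
#'   `c(core, softcore, dispensable, private)`, summing to 1.
#' @param softcore_fraction Softcore band used for planting (matches the
#'   classifier default).
#' @param seed Integer seed or `NULL`.
#' @return List with `matrix` (families x genomes integer counts) and
#'   `truth` (named factor of planted categories).
#' @export
generate_orthogroup_matrix <- function(n_genomes, n_families,
                                       category_weights =
                                         c(core = 0.441, softcore = 0,
                                           dispensable = 0.532,
                                           private = 0.027),
                                       softcore_fraction = 0.90,
                                       seed = NULL) {
  if (n_genomes < 2) stop("at least 2 genomes are required", call. = FALSE)
  stopifnot(length(category_weights) == 4, all(category_weights >= 0),
            abs(sum(category_weights) - 1) < 1e-8, n_families >= 1)
  lev <- c("core", "softcore", "dispensable", "private")
  names(category_weights) <- lev
  G <- as.integer(n_genomes)
  soft_lo <- ceiling(softcore_fraction * G)
  if (category_weights[["softcore"]] > 0 && soft_lo > G - 1)
    stop("softcore band is empty for ", G, " genomes", call. = FALSE)
  if (category_weights[["dispensable"]] > 0 && soft_lo - 1 < 2)
    stop("dispensable band is empty for ", G, " genomes", call. = FALSE)

  # largest-remainder apportionment to exact integer counts
  raw <- category_weights * n_families
  base <- floor(raw)
  rem <- n_families - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  truth <- factor(rep(lev, times = base), levels = lev)

  with_seed(seed, {
    truth <- sample(truth)   # shuffle family order
    presence_n <- vapply(as.character(truth), function(cat) switch(cat,
      core = G,
      softcore = if (soft_lo == G - 1) soft_lo
                 else sample(seq.int(soft_lo, G - 1), 1),
      dispensable = if (soft_lo - 1 == 2) 2L
                    else sample(seq.int(2, soft_lo - 1), 1),
      private = 1L), numeric(1))
    m <- matrix(0L, n_families, G,
                dimnames = list(sprintf("OG%07d", seq_len(n_families)),
                                sprintf("genome%02d", seq_len(G))))
    for (i in seq_len(n_families)) {
      cols <- sample.int(G, presence_n[i])
      m[i, cols] <- 1L + stats::rpois(length(cols), 0.2)
    }
    names(truth) <- rownames(m)
    list(matrix = m, truth = truth)
  })
}
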