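# Synthetic multi-genome structural-variant tables with planted
# group-specific deletions, plus a small gene-annotation generator.

#' Design for a planted structural-variant simulation
#'
#' Describes a multi-genome SV call set on a shared reference: background
#' SV counts per type per genome, and a set of planted deletions present
#' (up to coordinate jitter) in every genome of a designated group and in
#' no other genome.  Background SVs are placed uniformly at least 1 kb away
#' from every planted deletion, so the planted set is recoverable exactly.
#'
#' @param genomes Character vector of genome labels (>= 2).
#' @param present_group Subset of `genomes` that carries the planted
#'   deletions.
#' @param reference_length Named integer vector of chromosome lengths.
#' @param background_counts Named integer vector of per-genome background
#'   SV counts per type (names among the seven canonical types), or a
#'   genomes x types matrix for per-genome control.
#' @param n_planted Number of planted candidate deletions.
#' @param planted_size Planted deletion size in bp.
#' @param jitter Maximum absolute per-genome coordinate jitter in bp
#'   applied to planted deletions (0 = identical coordinates everywhere).
#' @return An object of class `planted_sv_design`.
#' @export
planted_sv_design <- function(genomes, present_group,
                              reference_length = c(chr1 = 2e6),
                              background_counts = c(deletion = 40,
                                                    insertion = 10),
                              n_planted = 5, planted_size = 500,
                              jitter = 0) {
  stopifnot(length(genomes) >= 2, !anyDuplicated(genomes),
            all(present_group %in% genomes),
            length(present_group) >= 1,
            length(present_group) < length(genomes),
            n_planted >= 0, planted_size >= 1, jitter >= 0,
            !is.null(names(reference_length)), all(reference_length > 0))
  if (is.matrix(background_counts)) {
    stopifnot(nrow(background_counts) == length(genomes),
              all(colnames(background_counts) %in% SV_TYPES))
  } else {
    stopifnot(all(names(background_counts) %in% SV_TYPES))
  }
  structure(list(genomes = genomes, present_group = present_group,
                 reference_length = reference_length,
                 background_counts = background_counts,
                 n_planted = as.integer(n_planted),
                 planted_size = as.integer(planted_size),
                 jitter = as.integer(jitter)),
            class = "planted_sv_design")
}

#' Generate per-genome SV tables from a planted design
#'
#' Plants `n_planted` candidate deletions at uniform positions (kept >= 1 kb
#' apart and within reference bounds) and copies them, with per-genome
#' jitter at most `jitter` bp, into every present-group genome.  Background
#' SVs of the requested types are placed uniformly subject to staying at
#' least 1 kb away from every planted deletion.
#'
#' @param design A [planted_sv_design()].
#' @param seed Integer seed or `NULL`.
#' @return List with `records` (combined SV data frame over all genomes)
#'   and `planted` (data frame of true candidate coordinates).
#' @export
generate_sv_tables <- function(design, seed = NULL) {
  stopifnot(inherits(design, "planted_sv_design"))
  with_seed(seed, {
    chroms <- names(design$reference_length)
    margin <- 1000L
    size_p <- design$planted_size

    # plant candidates, >= 1 kb apart from each other
    planted <- NULL
    if (design$n_planted > 0) {
      slots <- list()
      tries <- 0L
      while (length(slots) < design$n_planted) {
        tries <- tries + 1L
        if (tries > 200L * design$n_planted)
          stop("reference too short for requested planted deletions",
               call. = FALSE)
        chr <- sample(chroms, 1)
        len <- design$reference_length[[chr]]
        if (len < size_p + 2L * margin) next
        st <- sample.int(len - size_p - 2L * margin, 1) + margin
        clash <- any(vapply(slots, function(s)
          s$chr == chr && st < s$end + margin && st + size_p > s$start - margin,
          logical(1)))
        if (!clash)
          slots[[length(slots) + 1L]] <-
            list(chr = chr, start = st, end = st + size_p)
      }
      planted <- data.frame(
        reference = vapply(slots, `[[`, character(1), "chr"),
        start = vapply(slots, function(s) as.integer(s$start), integer(1)),
        end = vapply(slots, function(s) as.integer(s$end), integer(1)),
        stringsAsFactors = FALSE)
      planted <- planted[order(planted$reference, planted$start), ,
                         drop = FALSE]
      rownames(planted) <- NULL
    } else {
      planted <- data.frame(reference = character(), start = integer(),
                            end = integer())
    }

    near_planted <- function(chr, st, en) {
      if (!nrow(planted)) return(FALSE)
      sel <- planted$reference == chr
      any(st < planted$end[sel] + margin & en > planted$start[sel] - margin)
    }

    recs <- list()
    for (g in design$genomes) {
      bg <- if (is.matrix(design$background_counts))
        design$background_counts[match(g, design$genomes), ]
      else design$background_counts
      bg <- bg[bg > 0]
      k <- 0L
      for (ty in names(bg)) {
        for (i in seq_len(bg[[ty]])) {
          placed <- FALSE
          for (tries in seq_len(500L)) {
            chr <- sample(chroms, 1)
            len <- design$reference_length[[chr]]
            # insertions run markedly smaller than deletions, as SV callers
            # report on assembly-to-reference alignments
            sz <- if (ty == "insertion") sample.int(1201L, 1) + 49L
                  else sample.int(4951L, 1) + 49L
            span <- if (ty == "insertion") 1L else sz
            if (len <= span + 2L) next
            st <- sample.int(len - span - 1L, 1)
            if (near_planted(chr, st, st + span)) next
            k <- k + 1L
            recs[[length(recs) + 1L]] <- data.frame(
              reference = chr, start = st, end = st + span,
              id = sprintf("%s_bg_%d", g, k), size = sz, strand = "+",
              type = ty, genome = g, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed)
            stop("reference too short for requested background counts",
                 call. = FALSE)
        }
      }
      if (g %in% design$present_group && nrow(planted)) {
        for (i in seq_len(nrow(planted))) {
          j <- if (design$jitter > 0)
            sample.int(2L * design$jitter + 1L, 1) - design$jitter - 1L
          else 0L
          recs[[length(recs) + 1L]] <- data.frame(
            reference = planted$reference[i],
            start = planted$start[i] + j, end = planted$end[i] + j,
            id = sprintf("%s_cand_%d", g, i), size = size_p,
            strand = "+", type = "deletion", genome = g,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(records = do.call(rbind, recs), planted = planted)
  })
}

#' Generate a toy gene annotation near planted deletions
#'
#' Places one gene within `gene_distance` bp of each planted deletion and
#' `n_background` genes uniformly elsewhere, for exercising
#' [annotate_proximal_genes()].
#'
#' @param planted Data frame of planted deletions (`reference`, `start`,
#'   `end`, 0-based half-open).
#' @param reference_length Named chromosome lengths.
#' @param gene_distance Gap between each planted deletion and its gene, bp.
#' @param gene_size Gene span in bp.
#' @param n_background Number of additional genes placed uniformly.
#' @param seed Integer seed or `NULL`.
#' @return Data frame of genes: `reference`, `start`, `end` (0-based
#'   half-open), `gene_id`.
#' @export
simulate_gene_annotation <- function(planted, reference_length,
                                     gene_distance = 1000, gene_size = 2000,
                                     n_background = 20, seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(planted))) {
      st <- planted$end[i] + gene_distance
      rows[[length(rows) + 1L]] <- data.frame(
        reference = planted$reference[i], start = st, end = st + gene_size,
        gene_id = sprintf("gene_cand_%d", i), stringsAsFactors = FALSE)
    }
    chroms <- names(reference_length)
    for (i in seq_len(n_background)) {
      chr <- sample(chroms, 1)
      st <- sample.int(max(reference_length[[chr]] - gene_size - 1L, 1L), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        reference = chr, start = st, end = st + gene_size,
        gene_id = sprintf("gene_bg_%d", i), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Write genes as a minimal GFF3 file
#'
#' Converts 0-based half-open gene coordinates to the 1-based closed GFF3
#' convention.
#'
#' @param genes Data frame with `reference`, `start`, `end`, `gene_id`.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$reference, genes$start + 1L, genes$end,
                     genes$gene_id), con)
  invisible(path)
}
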