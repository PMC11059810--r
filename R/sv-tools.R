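# Structural-variant tables: parsing the seven-type Assemblytics-style BED
# dialect, summaries, cross-genome matching, the presence/absence candidate
# filter, and proximal-gene annotation.

SV_TYPES <- c("insertion", "deletion", "tandem_expansion",
              "tandem_contraction", "repeat_expansion",
              "repeat_contraction", "inversion")

# Types whose interval consumes reference sequence (start < end required).
REF_CONSUMING <- setdiff(SV_TYPES, "insertion")

normalize_sv_type <- function(type) {
  tolower(gsub("[ ]+", "_", trimws(type)))
}

#' Read an Assemblytics-style structural-variant BED table
#'
#' Columns: reference, start, stop, ID, size, strand, type, and optionally
#' ref_gap_size, query_gap_size, query_coordinates, method.  Coordinates are
#' 0-based half-open.  Type strings are normalised (case and spaces) to the
#' seven canonical names: insertion, deletion, tandem_expansion,
#' tandem_contraction, repeat_expansion, repeat_contraction, inversion.
#'
#' @param path Path to the BED-dialect file; a header line starting with
#'   `#` or `reference` is tolerated.
#' @param genome_label Label attached to every record.
#' @return Data frame with columns `reference`, `start`, `end`, `id`,
#'   `size`, `strand`, `type`, `genome`.
#' @export
read_assemblytics <- function(path, genome_label) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) &&
      (startsWith(lines[1], "#") || grepl("^reference\\b", lines[1])))
    lines <- lines[-1]
  if (!length(lines))
    return(data.frame(reference = character(), start = integer(),
                      end = integer(), id = character(), size = integer(),
                      strand = character(), type = character(),
                      genome = character()))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 7)
  if (length(bad))
    stop("line ", bad[1], ": expected at least 7 tab-separated columns",
         call. = FALSE)
  get <- function(i) vapply(cells, `[[`, character(1), i)
  type <- normalize_sv_type(get(7))
  unknown <- which(!type %in% SV_TYPES)
  if (length(unknown))
    stop("line ", unknown[1], ": unknown SV type \"", get(7)[unknown[1]],
         "\"", call. = FALSE)
  start <- as.integer(get(2))
  end <- as.integer(get(3))
  bad <- which(is.na(start) | is.na(end) |
                 (type %in% REF_CONSUMING & end <= start) |
                 (type == "insertion" & end < start))
  if (length(bad))
    stop("line ", bad[1], ": malformed coordinates (end <= start)",
         call. = FALSE)
  data.frame(reference = get(1), start = start, end = end, id = get(4),
             size = as.integer(get(5)), strand = get(6), type = type,
             genome = genome_label, stringsAsFactors = FALSE)
}

#' Write structural-variant records in the Assemblytics BED dialect
#'
#' @param records Data frame as returned by [read_assemblytics()].
#' @param path Output path.
#' @export
write_assemblytics <- function(records, path) {
  df <- data.frame(reference = records$reference, ref_start = records$start,
                   ref_stop = records$end, ID = records$id,
                   size = records$size, strand = records$strand,
                   type = records$type, ref_gap_size = records$size,
                   query_gap_size = 0L, query_coordinates = ".",
                   method = "synthetic", stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise structural variants by genome and type
#'
#' Tallies counts and base totals per genome and type, and the
#' deletion:insertion fold ratios (by count and by bases) per genome,
#' averaged across genomes.  A genome without insertions has undefined
#' ratios, reported as `NA` and excluded from the averages.
#'
#' @param records Data frame of SV records (with a `genome` column), or a
#'   list of such data frames which are row-bound first.
#' @return List with `by_genome` (genome x type count and base table in
#'   long format), `ratios` (per-genome deletion/insertion ratios),
#'   `mean_count_ratio` and `mean_base_ratio`.
#' @export
summarize_svs <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!nrow(records)) {
    return(list(by_genome = data.frame(genome = character(),
                                       type = character(), count = integer(),
                                       bases = integer()),
                ratios = data.frame(genome = character(),
                                    count_ratio = numeric(),
                                    base_ratio = numeric()),
                mean_count_ratio = NA_real_, mean_base_ratio = NA_real_))
  }
  agg <- stats::aggregate(cbind(count = rep(1L, nrow(records)),
                                bases = records$size),
                          by = list(genome = records$genome,
                                    type = records$type), FUN = sum)
  agg <- agg[order(agg$genome, agg$type), , drop = FALSE]
  rownames(agg) <- NULL
  ratio_one <- function(g) {
    del <- agg[agg$genome == g & agg$type == "deletion", ]
    ins <- agg[agg$genome == g & agg$type == "insertion", ]
    dc <- if (nrow(del)) del$count else 0L
    db <- if (nrow(del)) del$bases else 0L
    if (!nrow(ins) || ins$count == 0)
      return(c(count_ratio = NA_real_, base_ratio = NA_real_))
    c(count_ratio = dc / ins$count, base_ratio = db / ins$bases)
  }
  genomes <- unique(agg$genome)
  rat <- t(vapply(genomes, ratio_one, numeric(2)))
  ratios <- data.frame(genome = genomes, count_ratio = rat[, "count_ratio"],
                       base_ratio = rat[, "base_ratio"],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(by_genome = agg, ratios = ratios,
       mean_count_ratio = mean(ratios$count_ratio, na.rm = TRUE),
       mean_base_ratio = mean(ratios$base_ratio, na.rm = TRUE))
}

#' Do two structural variants of the same type match across genomes?
#'
#' Reference-interval types match by reciprocal overlap: the shared span
#' must cover at least `min_reciprocal_overlap` of each interval.
#' Insertions occupy a point on the reference, so they match when their
#' breakpoints lie within `(1 - min_reciprocal_overlap) * min(size)` of
#' each other (exact breakpoints at `min_reciprocal_overlap = 1`).
#'
#' @param a,b Single SV records (one-row data frames or lists with
#'   `reference`, `start`, `end`, `type`, `size`).
#' @param min_reciprocal_overlap Reciprocal-overlap threshold in (0, 1\].
#' @return Logical.
#' @export
match_svs <- function(a, b, min_reciprocal_overlap = 0.5) {
  r <- min_reciprocal_overlap
  stopifnot(r > 0, r <= 1)
  if (a$type != b$type || a$reference != b$reference) return(FALSE)
  if (a$type == "insertion") {
    return(abs(a$start - b$start) <= (1 - r) * min(a$size, b$size))
  }
  ov <- min(a$end, b$end) - max(a$start, b$start)
  la <- a$end - a$start
  lb <- b$end - b$start
  ov >= r * la && ov >= r * lb
}

# Union-find over record indices, linking matching same-type records.
cluster_records <- function(records, min_reciprocal_overlap) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    ord <- order(records$reference, records$start)
    for (ii in seq_len(n - 1)) {
      i <- ord[ii]
      for (jj in seq.int(ii + 1, n)) {
        j <- ord[jj]
        if (records$reference[j] != records$reference[i] ||
            records$start[j] > records$end[i]) break
        if (match_svs(records[i, ], records[j, ], min_reciprocal_overlap)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Candidate deletions by the presence/absence group filter
#'
#' Clusters deletion records across genomes (single linkage over
#' [match_svs()] edges) and keeps the clusters in which *every* genome of
#' the present group contributes a matching deletion while *no* genome of
#' the absent group has a deletion matching any cluster member.  The
#' representative interval is the union of the matched intervals.
#'
#' @param records Combined SV data frame over all genomes (a list of
#'   per-genome data frames is row-bound first).
#' @param present_group,absent_group Disjoint, non-empty genome label sets.
#' @param min_reciprocal_overlap Matching threshold, see [match_svs()].
#' @return Data frame of candidates: `reference`, `start`, `end`,
#'   `n_members`, `present_genomes` (comma-separated).
#' @export
candidate_deletions <- function(records, present_group, absent_group,
                                min_reciprocal_overlap = 0.5) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(length(present_group) >= 1, length(absent_group) >= 1,
            !length(intersect(present_group, absent_group)))
  dels <- records[records$type == "deletion", , drop = FALSE]
  pres <- dels[dels$genome %in% present_group, , drop = FALSE]
  abs_ <- dels[dels$genome %in% absent_group, , drop = FALSE]
  if (!nrow(pres))
    return(data.frame(reference = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      present_genomes = character()))
  comp <- cluster_records(pres, min_reciprocal_overlap)
  out <- lapply(split(seq_len(nrow(pres)), comp), function(idx) {
    members <- pres[idx, , drop = FALSE]
    if (!setequal(intersect(unique(members$genome), present_group),
                  present_group) ||
        !all(present_group %in% members$genome)) return(NULL)
    hit_absent <- FALSE
    if (nrow(abs_)) {
      for (i in seq_len(nrow(members))) {
        for (j in seq_len(nrow(abs_))) {
          if (match_svs(members[i, ], abs_[j, ], min_reciprocal_overlap)) {
            hit_absent <- TRUE
            break
          }
        }
        if (hit_absent) break
      }
    }
    if (hit_absent) return(NULL)
    data.frame(reference = members$reference[1],
               start = min(members$start), end = max(members$end),
               n_members = nrow(members),
               present_genomes = paste(sort(unique(members$genome)),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(reference = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      present_genomes = character())
  out <- out[order(out$reference, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidate deletions with proximal genes
#'
#' Finds the genes whose span lies within `max_distance` bp of each
#' candidate interval (distance 0 when overlapping; strand is ignored).
#' GFF3 coordinates (1-based closed) are converted on read; candidate
#' coordinates are 0-based half-open.
#'
#' @param candidates Data frame from [candidate_deletions()].
#' @param gff3 Path to a GFF3 file, or a `GenomicRanges::GRanges` of genes.
#' @param max_distance Maximum gap in bp (inclusive).
#' @return Long-format data frame: `candidate`, `reference`, `start`, `end`,
#'   `gene_id`, `distance`; candidates without proximal genes are absent.
#' @export
annotate_proximal_genes <- function(candidates, gff3, max_distance = 2000) {
  empty <- data.frame(candidate = integer(), reference = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), distance = integer())
  if (!nrow(candidates)) return(empty)
  genes <- if (is.character(gff3)) {
    gr <- rtracklayer::import(gff3)
    gr[gr$type == "gene"]
  } else gff3
  if (!length(genes)) return(empty)
  gene_ids <- if (!is.null(genes$ID)) genes$ID
              else if (!is.null(genes$Name)) genes$Name
              else as.character(seq_along(genes))
  cand_gr <- GenomicRanges::GRanges(
    candidates$reference,
    IRanges::IRanges(start = candidates$start + 1L, end = candidates$end))
  hits <- GenomicRanges::findOverlaps(cand_gr, genes,
                                      maxgap = max_distance)
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(cand_gr[q], genes[s])
  keep <- !is.na(d) & d <= max_distance
  data.frame(candidate = q[keep],
             reference = candidates$reference[q[keep]],
             start = candidates$start[q[keep]],
             end = candidates$end[q[keep]],
             gene_id = as.character(gene_ids[s[keep]]),
             distance = as.integer(d[keep]),
             stringsAsFactors = FALSE)
}
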