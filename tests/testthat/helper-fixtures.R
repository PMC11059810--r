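# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# A small planted SV scenario: three southern genomes carry the planted
# deletions, two northern genomes do not.
make_sv_fixture <- function(n_planted = 5, jitter = 0, seed = 42) {
  design <- planted_sv_design(
    genomes = c("Pz", "Ph", "Pm", "apricotA", "apricotB"),
    present_group = c("Pz", "Ph", "Pm"),
    reference_length = c(chr1 = 2e6, chr2 = 1e6),
    background_counts = c(deletion = 30, insertion = 10,
                          tandem_expansion = 5, inversion = 3),
    n_planted = n_planted, planted_size = 500, jitter = jitter)
  c(generate_sv_tables(design, seed = seed), list(design = design))
}

# Brute-force oracle for candidate_deletions: for every deletion of the
# first present genome, demand a matching deletion in every present genome
# and none in any absent genome, by direct all-pairs scanning.
oracle_candidates <- function(records, present, absent, r) {
  dels <- records[records$type == "deletion", , drop = FALSE]
  anchors <- dels[dels$genome == present[1], , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    ok <- TRUE
    members <- list(a)
    for (g in setdiff(present, present[1])) {
      gg <- dels[dels$genome == g, , drop = FALSE]
      m <- which(vapply(seq_len(nrow(gg)), function(j)
        match_svs(a, gg[j, ], r), logical(1)))
      if (!length(m)) {
        ok <- FALSE
        break
      }
      members[[length(members) + 1L]] <- gg[m[1], ]
    }
    if (!ok) next
    for (g in absent) {
      gg <- dels[dels$genome == g, , drop = FALSE]
      if (any(vapply(seq_len(nrow(gg)), function(j)
        any(vapply(members, function(mm) match_svs(mm, gg[j, ], r),
                   logical(1))), logical(1)))) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits[[length(hits) + 1L]] <- a
  }
  if (!length(hits))
    return(data.frame(reference = character(), start = integer(),
                      end = integer()))
  out <- do.call(rbind, hits)[, c("reference", "start", "end")]
  out <- out[order(out$reference, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force per-family pan classification, written independently of
# classify_families.
oracle_classify <- function(m, softcore_fraction = 0.90) {
  G <- ncol(m)
  vapply(seq_len(nrow(m)), function(i) {
    pres <- sum(m[i, ] > 0)
    if (pres == G) "core"
    else if (pres >= ceiling(softcore_fraction * G)) "softcore"
    else if (pres == 1) "private"
    else "dispensable"
  }, character(1))
}
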