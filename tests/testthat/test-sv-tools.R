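# SV parsing, summaries, cross-genome matching, the candidate filter and
# proximal-gene annotation.

test_that("the Assemblytics dialect parses with type normalisation", {
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "reference\tref_start\tref_stop\tID\tsize\tstrand\ttype\tref_gap_size\tquery_gap_size\tquery_coordinates\tmethod",
    "chr1\t100\t400\tsv1\t300\t+\tDeletion\t300\t0\tq:1-2\tbetween_alignments",
    "chr1\t900\t901\tsv2\t120\t+\tInsertion\t0\t120\tq:3-4\tbetween_alignments",
    "chr2\t50\t250\tsv3\t200\t+\tTandem_expansion\t200\t0\tq:5-6\twithin_alignment"),
    path)
  recs <- read_assemblytics(path, "gA")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$type, c("deletion", "insertion", "tandem_expansion"))
  expect_equal(recs$size, c(300L, 120L, 200L))
  expect_true(all(recs$genome == "gA"))

  bad <- tempfile()
  writeLines("chr1\t100\t400\tsv\t300\t+\tTranslocation", bad)
  expect_error(read_assemblytics(bad, "g"), "unknown SV type")
  rev <- tempfile()
  writeLines("chr1\t400\t100\tsv\t300\t+\tDeletion", rev)
  expect_error(read_assemblytics(rev, "g"), "malformed")
})

test_that("SV records round-trip through the BED writer", {
  fx <- make_sv_fixture(seed = 7)
  one <- fx$records[fx$records$genome == "Pz", ]
  path <- tempfile(fileext = ".bed")
  write_assemblytics(one, path)
  back <- read_assemblytics(path, "Pz")
  expect_equal(back[, c("reference", "start", "end", "size", "type")],
               one[, c("reference", "start", "end", "size", "type")],
               ignore_attr = TRUE)
})

test_that("SV summaries compute deletion:insertion fold ratios", {
  recs <- data.frame(
    reference = "chr1", start = c(0, 500, 1000), end = c(100, 800, 1001),
    id = c("d1", "d2", "i1"), size = c(100L, 300L, 50L), strand = "+",
    type = c("deletion", "deletion", "insertion"), genome = "g1")
  s <- summarize_svs(recs)
  expect_equal(s$mean_count_ratio, 2.0)
  expect_equal(s$mean_base_ratio, 8.0)
  expect_equal(sum(s$by_genome$count), nrow(recs))

  two <- rbind(recs, within(recs, genome <- "g2"))
  two$size[two$genome == "g2" & two$type == "insertion"] <- 25L
  # per-genome ratios 2.0 and 2.0 by count; average of per-genome ratios
  expect_equal(summarize_svs(two)$mean_count_ratio, 2.0)

  no_ins <- recs[recs$type == "deletion", ]
  expect_true(is.na(summarize_svs(no_ins)$ratios$count_ratio))
  empty <- summarize_svs(recs[0, ])
  expect_equal(nrow(empty$by_genome), 0)
})

test_that("reciprocal-overlap matching follows the interval arithmetic", {
  rec <- function(s, e, type = "deletion", size = e - s)
    list(reference = "chr1", start = s, end = e, type = type, size = size)
  expect_true(match_svs(rec(0, 100), rec(0, 100), 1.0))
  expect_true(match_svs(rec(0, 100), rec(50, 150), 0.5))
  expect_false(match_svs(rec(0, 100), rec(51, 151), 0.5))
  expect_false(match_svs(rec(0, 100), rec(200, 300), 0.5))
  expect_false(match_svs(rec(0, 100), rec(0, 100, type = "inversion"), 0.5))
  # insertions match on breakpoint proximity
  ins <- function(s, size) rec(s, s + 1, "insertion", size)
  expect_true(match_svs(ins(1000, 200), ins(1050, 200), 0.5))
  expect_false(match_svs(ins(1000, 200), ins(1101, 200), 0.5))
  expect_false(match_svs(ins(1000, 200), ins(1001, 200), 1.0))
})

test_that("candidate deletions equal the brute-force oracle on planted fixtures", {
  present <- c("Pz", "Ph", "Pm")
  absent <- c("apricotA", "apricotB")
  for (seed in c(42, 99)) {
    fx <- make_sv_fixture(n_planted = 5, jitter = 0, seed = seed)
    got <- candidate_deletions(fx$records, present, absent, 1.0)
    want <- oracle_candidates(fx$records, present, absent, 1.0)
    expect_equal(got[, c("reference", "start", "end")], want,
                 ignore_attr = TRUE)
    expect_equal(got[, c("reference", "start", "end")], fx$planted,
                 ignore_attr = TRUE)
  }
})

test_that("candidates survive jitter below the reciprocal-overlap slack", {
  # r = 0.8 tolerates up to (1-r)*size = 100 bp of jitter on 500-bp dels
  fx <- make_sv_fixture(n_planted = 4, jitter = 40, seed = 13)
  got <- candidate_deletions(fx$records, c("Pz", "Ph", "Pm"),
                             c("apricotA", "apricotB"), 0.8)
  expect_equal(nrow(got), 4)
})

test_that("candidate filtering demands presence in all and absence in all", {
  base <- data.frame(reference = "chr1", start = 1000L, end = 1500L,
                     id = "x", size = 500L, strand = "+", type = "deletion",
                     stringsAsFactors = FALSE)
  mk <- function(genomes) do.call(rbind, lapply(genomes, function(g)
    within(base, genome <- g)))
  # shared by every genome: excluded
  all5 <- mk(c("Pz", "Ph", "Pm", "apricotA", "apricotB"))
  expect_equal(nrow(candidate_deletions(all5, c("Pz", "Ph", "Pm"),
                                        c("apricotA", "apricotB"), 1.0)), 0)
  # present in only 2 of 3: excluded
  two <- mk(c("Pz", "Ph"))
  expect_equal(nrow(candidate_deletions(two, c("Pz", "Ph", "Pm"),
                                        c("apricotA", "apricotB"), 1.0)), 0)
  # full present group, empty absent overlap: kept, order-invariant
  three <- mk(c("Pz", "Ph", "Pm"))
  a <- candidate_deletions(three, c("Pz", "Ph", "Pm"),
                           c("apricotA", "apricotB"), 1.0)
  b <- candidate_deletions(three[3:1, ], c("Pm", "Ph", "Pz"),
                           c("apricotB", "apricotA"), 1.0)
  expect_equal(a, b)
  expect_equal(nrow(a), 1)
})

test_that("proximal genes are collected within the distance cutoff", {
  cand <- data.frame(reference = "chr1", start = 10000L, end = 10500L,
                     n_members = 3L, present_genomes = "Pz,Ph,Pm")
  genes <- data.frame(
    reference = "chr1",
    start = c(8000L, 10200L, 12501L, 13000L),
    end = c(8500L, 10300L, 12900L, 13400L),
    gene_id = c("g_up1500", "g_inside", "g_down2001", "g_far"))
  gff <- tempfile(fileext = ".gff3")
  write_gff3(genes, gff)
  ann <- annotate_proximal_genes(cand, gff, max_distance = 2000)
  expect_setequal(ann$gene_id, c("g_up1500", "g_inside"))
  expect_equal(ann$distance[ann$gene_id == "g_up1500"], 1500L)
  expect_equal(ann$distance[ann$gene_id == "g_inside"], 0L)
  # the 2001-bp gene enters exactly at a 2001 cutoff
  ann2 <- annotate_proximal_genes(cand, gff, max_distance = 2001)
  expect_true("g_down2001" %in% ann2$gene_id)
})
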