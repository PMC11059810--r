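# Triplet extraction, tallies, mixture fitting and the BIC difference rule.

test_that("extract_triplet reads topology and internal branch off a rooted quartet", {
  obs <- extract_triplet("(((A:1.0,B:1.0):0.5,C:1.5):1.0,O:2.5);",
                         c("A", "B", "C"), "O")
  expect_identical(obs$topology, "A|B")
  expect_equal(obs$t, 0.5)
})

test_that("extract_triplet prunes extra taxa and sums collapsed branches", {
  # hand-built 6-taxon tree: pruning D and E must add their stem lengths
  # into the paths they interrupt; the A-C cherry's subtending branch is
  # 0.2 + 0.3 after removal of D's attachment point
  nwk <- "((((A:1.0,C:1.0):0.2,(D:0.6,E:0.6):0.4):0.3,B:1.5):1.0,O:2.5);"
  obs <- extract_triplet(nwk, c("A", "B", "C"), "O")
  expect_identical(obs$topology, "A|C")
  expect_equal(obs$t, 0.5)
})

test_that("star triplets and missing taxa are handled without fitting", {
  star <- extract_triplet("((A:1,B:1,C:1):1,O:2);", c("A", "B", "C"), "O")
  expect_identical(star$topology, "unresolved")
  gone <- extract_triplet("((A:1,B:1):1,O:2);", c("A", "B", "C"), "O")
  expect_true(isTRUE(gone$skipped))
  expect_match(gone$reason, "C")
  many <- extract_triplets(c("(((A:1,B:1):0.5,C:1.5):1,O:2.5);",
                             "((A:1,B:1):1,O:2);"),
                           c("A", "B", "C"), "O")
  expect_equal(nrow(many), 1)
  expect_equal(nrow(attr(many, "skipped")), 1)
})

test_that("topology tallies reproduce the published locus shares", {
  counts <- c("A|B" = 761, "A|C" = 411, "B|C" = 302)
  expect_equal(sum(counts), 1474)
  share <- topology_share(counts, digits = 0)
  expect_equal(unname(share[["A|B"]]), 52)
  one <- tally_topologies(data.frame(topology = "A|B"))
  expect_equal(unname(topology_share(one)), 100)
})

test_that("single-exponential MLE matches the closed form", {
  f <- fit_ils_only(c(1, 2, 3))
  expect_equal(f$lambda, 2.0)
  expect_equal(f$loglik, 3 * log(0.5) - 3, tolerance = 1e-12)
  expect_equal(f$bic, log(3) + 10.1589, tolerance = 1e-4)
  # numeric optimiser cross-check of the analytic MLE
  t <- sample_mixture_lengths(200, pi = 1, lambda = 3, seed = 1)
  opt <- stats::optimize(function(l) -sum(stats::dexp(t, 1 / l, log = TRUE)),
                         c(0.01, 50))
  expect_equal(fit_ils_only(t)$lambda, opt$minimum, tolerance = 1e-4)
  x <- sample_mixture_lengths(10000, pi = 1, lambda = 5, seed = 2)
  expect_lt(abs(fit_ils_only(x)$lambda - 5), 3 * 5 / sqrt(10000))
  expect_error(fit_ils_only(c(0, 0, 0)), "degenerate")
})

test_that("mixture fit collapses to the nested model on pure exponential data", {
  t <- sample_mixture_lengths(300, pi = 1, lambda = 1, seed = 42)
  f1 <- fit_ils_only(t)
  f2 <- fit_mixture_em(t)
  expect_gte(f2$loglik, f1$loglik - 1e-9)
  expect_lt(f2$loglik - f1$loglik, 3)
})

test_that("mixture fit recovers a strongly shifted component", {
  t <- sample_mixture_lengths(2000, pi = 0.3, lambda = 1, C = 2, seed = 7)
  f <- fit_mixture_em(t)
  expect_lt(abs(f$pi - 0.3), 0.1)
  expect_lt(abs(f$C - 2), 0.5)
  expect_lt(abs(f$lambda - 1), 0.3)
  expect_true(all(diff(f$trace) > -1e-9))
})

test_that("an all-shifted sample is still called a mixture, moment-consistently", {
  # pi = 0 has no unshifted component at all -- outside the calibrated
  # two-population regime, where the conservative shift estimate is not
  # pinned to min(t); the fit must still reject the single exponential
  # decisively and stay moment-consistent overall
  t <- sample_mixture_lengths(1000, pi = 0, lambda = 1, C = 3, seed = 8)
  f1 <- fit_ils_only(t)
  f2 <- fit_mixture_em(t)
  expect_identical(classify_topology(f1$bic, f2$bic)$classification,
                   "mixture")
  implied_mean <- f2$pi * f2$lambda + (1 - f2$pi) * (f2$C + f2$lambda)
  expect_lt(abs(implied_mean - 4), 0.5)
  expect_error(fit_mixture_em(t[1:5]), "at least 10")
})

test_that("fitting is scale-equivariant", {
  t <- sample_mixture_lengths(800, pi = 0.4, lambda = 1, C = 2.5, seed = 3)
  f <- fit_topology(t)
  g <- fit_topology(t * 0.01)
  expect_equal(g$pi, f$pi, tolerance = 1e-4)
  expect_equal(g$lambda2, f$lambda2 * 0.01, tolerance = 1e-4)
  expect_equal(g$C, f$C * 0.01, tolerance = 1e-6)
  expect_identical(g$classification, f$classification)
  # lnL shift under scaling by c is exactly -n log(c)
  expect_equal(g$loglik1, f$loglik1 - length(t) * log(0.01), tolerance = 1e-6)
})

test_that("the BIC difference rule follows the published thresholds", {
  expect_identical(classify_topology(-100, -85)$classification, "ils_only")
  expect_equal(classify_topology(-100, -85)$delta_bic, 15)
  expect_identical(classify_topology(-85, -100)$classification, "mixture")
  expect_identical(classify_topology(-100, -95)$classification,
                   "indistinguishable")
  expect_identical(classify_topology(-95, -100)$classification,
                   "indistinguishable")
})

test_that("triplet summary weights discordant loci by the fitted ILS fraction", {
  counts <- c("A|B" = 761, "A|C" = 400, "B|C" = 313)
  mk_fit <- function(cls, w) structure(
    list(classification = cls, ils_weight = w), class = "mixture_fit")
  s_all_ils <- summarize_triplet(counts,
                                 list("A|C" = mk_fit("ils_only", 1),
                                      "B|C" = mk_fit("ils_only", 1)),
                                 species_topology = "A|B")
  expect_equal(s_all_ils$ils_loci_estimate, 713)
  expect_equal(s_all_ils$ils_pct, 100)
  expect_false(s_all_ils$introgression_flag)
  expect_equal(s_all_ils$n_total, 1474)
  expect_equal(s_all_ils$n_total - s_all_ils$n_discordant, 761)

  s_mix <- summarize_triplet(counts,
                             list("A|C" = mk_fit("mixture", 0.9045),
                                  "B|C" = mk_fit("ils_only", 1)),
                             species_topology = "A|B")
  expect_equal(s_mix$ils_loci_estimate, 0.9045 * 400 + 313)
  expect_true(s_mix$introgression_flag)

  # the species-topology fit never flags introgression
  s_sp <- summarize_triplet(counts,
                            list("A|B" = mk_fit("mixture", 0.5),
                                 "A|C" = mk_fit("ils_only", 1),
                                 "B|C" = mk_fit("ils_only", 1)),
                            species_topology = "A|B")
  expect_false(s_sp$introgression_flag)
  expect_error(summarize_triplet(counts, list(), "A|D"), "not among")
})

test_that("study-level summary reproduces the published triplet fraction", {
  flags <- rep(c(TRUE, FALSE), c(17, 43))
  s <- summarize_all(flags)
  expect_equal(s$pct_introgression, 28.33)
  expect_equal(s$n_triplets, 60)
  expect_equal(summarize_all(rep(FALSE, 10))$pct_introgression, 0)
})

test_that("the full pipeline flags no introgression on coalescent-only simulations", {
  flags <- vapply(1:6, function(s) {
    cfg <- msc_config(t2 = 1, gamma = 0, n_loci = 400, seed = 1000 + s)
    sim <- simulate_triplet_loci(cfg)
    quibl_triplet(sim$trees, cfg$taxa, cfg$outgroup,
                  species_topology = "A|B")$introgression_flag
  }, logical(1))
  expect_lte(mean(flags), 1 / 6)
})

test_that("the full pipeline detects a strong introgression pulse", {
  cfg <- msc_config(t2 = 1.5, gamma = 0.35, donor = "C", recipient = "B",
                    n_loci = 1200, seed = 77)
  sim <- simulate_triplet_loci(cfg)
  s <- quibl_triplet(sim$trees, cfg$taxa, cfg$outgroup,
                     species_topology = "A|B")
  expect_true(s$introgression_flag)
  expect_identical(s$fits[["B|C"]]$classification, "mixture")
  tab <- triplet_fit_table(s)
  expect_equal(nrow(tab), length(s$counts))
  expect_equal(sum(tab$n), s$n_total)
})
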