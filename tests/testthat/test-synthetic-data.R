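# The generators: coalescent triplet simulator, mixture sampler,
# orthogroup/SV/LTR fixtures.

test_that("triplet topologies are exchangeable when the internal branch vanishes", {
  cfg <- msc_config(t2 = 0, gamma = 0, n_loci = 30000, seed = 11)
  sim <- simulate_triplet_loci(cfg)
  freq <- tally_topologies(sim$observations) / cfg$n_loci
  expect_setequal(names(freq), c("A|B", "A|C", "B|C"))
  se <- sqrt((1 / 3) * (2 / 3) / cfg$n_loci)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("topology frequencies match the closed-form coalescent probabilities", {
  for (t2 in c(0.5, 1.0)) {
    cfg <- msc_config(t2 = t2, gamma = 0, n_loci = 20000, seed = 7)
    sim <- simulate_triplet_loci(cfg)
    freq <- tally_topologies(sim$observations) / cfg$n_loci
    p_conc <- 1 - (2 / 3) * exp(-t2)
    p_disc <- (1 / 3) * exp(-t2)
    expect_lt(abs(freq[["A|B"]] - p_conc),
              3 * sqrt(p_conc * (1 - p_conc) / cfg$n_loci))
    for (top in c("A|C", "B|C"))
      expect_lt(abs(freq[[top]] - p_disc),
                3 * sqrt(p_disc * (1 - p_disc) / cfg$n_loci))
  }
})

test_that("discordant internal branches are Exponential(mean 1) in coalescent units", {
  cfg <- msc_config(t2 = 1, gamma = 0, n_loci = 20000, seed = 3)
  sim <- simulate_triplet_loci(cfg)
  disc <- sim$observations$t_coal[sim$observations$topology != "A|B"]
  expect_lt(abs(mean(disc) - 1), 3 * 1 / sqrt(length(disc)))
  ks <- suppressWarnings(stats::ks.test(disc, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("complete introgression makes the donor-recipient pair the majority topology", {
  cfg <- msc_config(t2 = 5, gamma = 1, donor = "C", recipient = "B",
                    n_loci = 2000, seed = 5)
  sim <- simulate_triplet_loci(cfg)
  counts <- tally_topologies(sim$observations)
  expect_equal(names(which.max(counts)), "B|C")
  expect_gt(counts[["B|C"]] / sum(counts), 0.9)
})

test_that("simulated Newick trees agree with the recorded ground truth", {
  cfg <- msc_config(t2 = 0.8, gamma = 0, n_loci = 50, subst_scale = 0.02,
                    seed = 9)
  sim <- simulate_triplet_loci(cfg)
  for (i in c(1, 17, 50)) {
    obs <- extract_triplet(sim$trees[i], cfg$taxa, cfg$outgroup)
    truth <- sim$observations[i, ]
    if (obs$topology == "unresolved") next
    expect_identical(obs$topology, truth$topology)
    expect_equal(obs$t, truth$t_subst, tolerance = 1e-6)
  }
})

test_that("simulators are reproducible under a fixed seed and leave the RNG alone", {
  cfg <- msc_config(t2 = 1, n_loci = 100, seed = 123)
  a <- simulate_triplet_loci(cfg)
  set.seed(99)
  probe1 <- runif(1)
  b <- simulate_triplet_loci(cfg)
  set.seed(99)
  probe2 <- runif(1)
  expect_identical(a, b)
  expect_identical(probe1, probe2)
})

test_that("mixture sampler has the stated moments and support", {
  x <- sample_mixture_lengths(10000, pi = 1, lambda = 2, seed = 1)
  expect_lt(abs(mean(x) - 2), 3 * 2 / sqrt(10000))
  y <- sample_mixture_lengths(10000, pi = 0, lambda = 1, C = 3, seed = 2)
  expect_gte(min(y), 3)
  expect_lt(abs(mean(y) - 4), 3 * 1 / sqrt(10000))
  expect_error(sample_mixture_lengths(10, pi = 0.5, lambda = 0), "lambda")
  expect_identical(sample_mixture_lengths(50, 0.5, 1, 2, seed = 4),
                   sample_mixture_lengths(50, 0.5, 1, 2, seed = 4))
})

test_that("orthogroup generator plants the requested category fractions exactly", {
  g <- generate_orthogroup_matrix(13, 2000,
                                  category_weights = c(0.441, 0, 0.532, 0.027),
                                  seed = 7)
  cls <- classify_families(g$matrix)
  expect_identical(unname(cls$category), unname(g$truth[names(cls$category)]))
  expect_identical(unname(cls$tally),
                   unname(as.integer(table(g$truth)[names(cls$tally)])))
  # all-core and all-private degenerate weights
  allc <- generate_orthogroup_matrix(5, 100, c(1, 0, 0, 0), seed = 1)
  expect_true(all(classify_families(allc$matrix)$category == "core"))
  allp <- generate_orthogroup_matrix(5, 100, c(0, 0, 0, 1), seed = 1)
  expect_true(all(rowSums(allp$matrix >= 1) == 1))
  expect_error(generate_orthogroup_matrix(1, 10, c(1, 0, 0, 0)), "2 genomes")
})

test_that("SV generator plants exactly the designed candidate deletions", {
  fx <- make_sv_fixture(n_planted = 5, jitter = 0, seed = 42)
  cand <- candidate_deletions(fx$records,
                              present_group = fx$design$present_group,
                              absent_group = c("apricotA", "apricotB"),
                              min_reciprocal_overlap = 1.0)
  expect_equal(nrow(cand), 5)
  expect_equal(cand[, c("reference", "start", "end")], fx$planted,
               ignore_attr = TRUE)
  fx0 <- make_sv_fixture(n_planted = 0, seed = 43)
  cand0 <- candidate_deletions(fx0$records, fx0$design$present_group,
                               c("apricotA", "apricotB"), 1.0)
  expect_equal(nrow(cand0), 0)
})

test_that("LTR pair mutator produces the designed divergence", {
  p0 <- mutate_ltr_pair(1000, true_time = 0, mu = 1e-8, seed = 1)
  expect_identical(p0$ltr5, p0$ltr3)
  expect_equal(as.numeric(k2p_distance(p0$ltr5, p0$ltr3)), 0)
  # equal per-type rates: transversions at two targets, transitions at one
  p <- mutate_ltr_pair(20000, true_time = 5e5, mu = 2e-7, ti_tv_ratio = 0.5,
                       seed = 2)
  k <- k2p_distance(p$ltr5, p$ltr3)
  expect_lt(abs(attr(k, "Q") / attr(k, "P") - 2), 0.4)
})
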