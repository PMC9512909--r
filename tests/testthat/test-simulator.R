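test_that("equal-length Monte Carlo converges to the closed form", {
  e <- fragmentation_experiment(10000, 500, 4, replicates = 1e5, seed = 42)
  est <- equal_length_fragmentation(e, 6)
  expect_lt(abs(est$estimate - 0.5), 3 * est$se)

  # r == f leaves a single surviving phase
  e2 <- fragmentation_experiment(10000, 500, 10, replicates = 1e5, seed = 7)
  est2 <- equal_length_fragmentation(e2, 10)
  expect_lt(abs(est2$estimate - 0.1), 3 * est2$se)

  # determinism: identical seed, identical estimate
  est3 <- equal_length_fragmentation(e, 6)
  expect_identical(est3$estimate, est$estimate)

  expect_error(fragmentation_experiment(100, 0, 200, seed = 1),
               "does not fit")
  expect_error(fragmentation_experiment(100, 0, 10, replicates = 10),
               "seed")
})

test_that("mixture Monte Carlo converges to the distribution-weighted form", {
  d <- fragment_size_distribution(c(6, 8), c(1, 1))
  e <- fragmentation_experiment(10000, 500, 4, replicates = 1e5, seed = 11)
  est <- mixture_fragmentation(e, d)
  expect_lt(abs(est$estimate - 0.5625), 3 * est$se)

  # degenerate mixture equals the equal-length simulator's target
  d0 <- fragment_size_distribution(200, 1)
  e2 <- fragmentation_experiment(10000, 500, 125, replicates = 1e5, seed = 12)
  est2 <- mixture_fragmentation(e2, d0)
  expect_lt(abs(est2$estimate - intact_proportion(125, 200)), 3 * est2$se)

  # ratio of estimates at 175 and 125 cross-checks the long/short ratio
  dd <- random_dist(4, lmin = 130, lmax = 900)
  p175 <- mixture_fragmentation(
    fragmentation_experiment(10000, 500, 175, replicates = 2e5, seed = 13), dd)
  p125 <- mixture_fragmentation(
    fragmentation_experiment(10000, 500, 125, replicates = 2e5, seed = 14), dd)
  mc_ratio <- p175$estimate / p125$estimate
  se_ratio <- mc_ratio * sqrt((p175$se / p175$estimate)^2 +
                              (p125$se / p125$estimate)^2)
  expect_lt(abs(mc_ratio - long_short_ratio(dd, 175, 125)), 3 * se_ratio)
})

test_that("synthetic distributions have the requested shape and mass", {
  d <- synth_distribution("unimodal", mode = 150, seed = 1)
  expect_lte(abs(d$lengths[which.max(d$concentrations)] - 150), 2)
  expect_lt(abs(total_mass(d) - 1000) / 1000, 1e-9)

  lad <- synth_distribution("nucleosome_ladder", n_peaks = 2,
                            total_mass = 50, seed = 2)
  expect_lt(abs(total_mass(lad) - 50) / 50, 1e-9)
  # two local maxima near 166 and 332 bp
  C <- lad$concentrations
  locmax <- which(diff(sign(diff(C))) == -2) + 1
  peaks <- lad$lengths[locmax]
  expect_true(any(abs(peaks - 166) <= 5))
  expect_true(any(abs(peaks - 332) <= 5))
  expect_error(synth_distribution("unimodal", mode = -5), "degenerate")
})

test_that("planted fragment sets respect protection strength", {
  # strength 1: every fragment centred on the nucleosome +/- 10 bp jitter
  fs <- synth_fragment_set(4000, nucleosome_positions = 2000,
                           protection_strength = 1, n_fragments = 200,
                           seed = 3)
  mid <- (fs$start + fs$end) / 2
  expect_true(all(abs(mid - 2000) <= 11))
  expect_true(all(fs$start < fs$end))
  expect_true(!is.unsorted(fs$start))

  # strength 0: uniform background, peak calling finds nothing above null
  fs0 <- synth_fragment_set(4000, nucleosome_positions = 2000,
                            protection_strength = 0, n_fragments = 300,
                            seed = 4)
  track <- compute_wps(fs0, list(chrom = "chrS", start = 500, end = 3500))
  peaks <- call_peaks(track)
  if (nrow(peaks) > 0) {
    # permutation null: max raw score near any called apex should not
    # dwarf the background 99th percentile
    expect_lt(max(peaks$score), stats::quantile(track$scores, 0.99) + 10)
  }
  succeed()
})

test_that("Monte Carlo grid agrees with closed forms in >= 95% of cells", {
  # smaller version of the acceptance sweep for routine runs
  cells <- 0; ok <- 0
  for (f in c(150, 300)) for (r in c(50, 125)) {
    e <- fragmentation_experiment(10000, 100, r, replicates = 2e4,
                                  seed = f + r)
    est <- equal_length_fragmentation(e, f)
    cells <- cells + 1
    ok <- ok + (abs(est$estimate - intact_proportion(r, f)) <= 3 * est$se)
  }
  for (s in 1:4) {
    dd <- random_dist(s)
    for (r in c(60, 150)) {
      e <- fragmentation_experiment(10000, 100, r, replicates = 2e4,
                                    seed = 100 * s + r)
      est <- mixture_fragmentation(e, dd)
      cells <- cells + 1
      ok <- ok + (abs(est$estimate - intact_proportion_distribution(dd, r))
                  <= 3 * est$se)
    }
  }
  expect_gte(ok / cells, 0.95)
})
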