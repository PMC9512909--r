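test_that("bracketing finds the right anchor pair, ties and range errors", {
  refs <- make_refset()
  x <- refs$anchor_ratios
  mid <- mean(x[2:3])
  br <- bracket(refs, mid)
  expect_equal(br$x1, x[2]); expect_equal(br$x2, x[3])
  expect_false(br$degenerate)

  # ratio equal to an anchor: degenerate bracket returns that anchor's value
  br2 <- bracket(refs, x[2])
  expect_true(br2$degenerate)
  expect_equal(interpolate_bracket(br2, x[2]), refs$average_lengths[2])

  # out of range errors by default; clamp warns and uses terminal bracket
  expect_error(bracket(refs, x[1] / 2), "outside the reference anchor range")
  expect_error(bracket(refs, 1.5), "exceeds 1")
  expect_warning(br3 <- bracket(refs, x[1] / 2, clamp = TRUE), "clamped")
  expect_equal(br3$x1, x[1]); expect_equal(br3$x2, x[2])
})

test_that("estimators are exact when the sample is a reference profile", {
  refs <- make_refset()
  G <- 5000
  for (i in c(1L, 3L)) {
    d <- refs$profiles[[i]]$distribution
    m <- assay_measurement(
      c_short = G * intact_proportion_distribution(d, 125),
      c_long = G * intact_proportion_distribution(d, 175))
    expect_equal(estimate_genome_copies(m, refs), G, tolerance = 1e-9)
    for (r in c(50, 125, 160, 300))
      expect_equal(estimate_region_copies(m, refs, r),
                   G * intact_proportion_distribution(d, r),
                   tolerance = 1e-9)
    expect_equal(estimate_average_length(m, refs),
                 refs$profiles[[i]]$average_length, tolerance = 1e-9)
  }
})

test_that("planted genome copies are recovered between tight anchors", {
  # query distribution lies strictly between two close reference modes
  refs <- make_refset(modes = c(280, 320), seed = 20)
  d <- synth_distribution("unimodal", mode = 300, seed = 99)
  G <- 12000
  m <- assay_measurement(
    c_short = G * intact_proportion_distribution(d, 125),
    c_long = G * intact_proportion_distribution(d, 175))
  Ghat <- estimate_genome_copies(m, refs)
  expect_lt(abs(Ghat - G) / G, 0.05)
  for (r in c(50, 150)) {
    truth <- G * intact_proportion_distribution(d, r)
    expect_lt(abs(estimate_region_copies(m, refs, r) - truth) / truth, 0.05)
  }
})

test_that("region estimate at the short amplicon length returns c_short", {
  refs <- make_refset()
  for (ratio_target in c(0.55, 0.65, 0.8)) {
    m <- assay_measurement(1000, 1000 * ratio_target)
    expect_equal(estimate_region_copies(m, refs, 125), 1000,
                 tolerance = 1e-12)
  }
})

test_that("estimates vary piecewise-linearly and monotonically in the ratio", {
  refs <- make_refset()
  x <- refs$anchor_ratios
  grid <- seq(x[1], x[length(x)], length.out = 41)
  genome <- vapply(grid, function(g)
    estimate_genome_copies(assay_measurement(1000, 1000 * g), refs),
    numeric(1))
  avg <- vapply(grid, function(g)
    estimate_average_length(assay_measurement(1000, 1000 * g), refs),
    numeric(1))
  # lower ratio = more fragmentation = more genome copies at fixed c_short
  expect_true(all(diff(genome) < 0))
  # estimated average length is non-decreasing in the measured ratio
  expect_true(all(diff(avg) > 0))
  # piecewise linearity within one bracket: three collinear points
  inb <- grid[grid > x[2] & grid < x[3]][1:3]
  v <- vapply(inb, function(g)
    estimate_average_length(assay_measurement(1000, 1000 * g), refs),
    numeric(1))
  expect_equal(diff(v)[1] / diff(inb)[1], diff(v)[2] / diff(inb)[2],
               tolerance = 1e-9)
})

test_that("degenerate single-anchor genome estimate matches the closed form", {
  # reference with a single fragment length f0: [125]/[1] = (f0-124)/f0
  f0 <- 400
  d1 <- fragment_size_distribution(f0, 2)
  d2 <- fragment_size_distribution(900, 2)
  refs <- reference_set(list(reference_profile("a", d1, f0),
                             reference_profile("b", d2, 900)))
  m <- assay_measurement(1000, 1000 * long_short_ratio(d1, 175, 125))
  expect_equal(estimate_genome_copies(m, refs),
               1000 * f0 / (f0 - 125 + 1), tolerance = 1e-9)
})

test_that("the frag_fit object carries estimates and predicts regions", {
  refs <- make_refset()
  fit <- fragment_calculator(1000, 700, refs)
  expect_s3_class(fit, "frag_fit")
  cf <- coef(fit)
  expect_equal(unname(cf["measured_ratio"]), 0.7)
  m <- assay_measurement(1000, 700)
  expect_equal(unname(cf["genome_copies"]),
               estimate_genome_copies(m, refs))
  expect_equal(unname(cf["average_length"]),
               estimate_average_length(m, refs))
  p <- predict(fit, c(50, 125, 200))
  expect_equal(unname(p[2]), 1000, tolerance = 1e-12)
  expect_equal(attr(p, "extrapolated"), c(FALSE, FALSE, TRUE))
  expect_output(print(fit), "genome copies")
  expect_output(print(summary(fit)), "Reference anchors")
})

test_that("reference sets validate anchors and read from a manifest", {
  # non-monotone anchors: same distribution, contradictory average lengths
  d <- synth_distribution("unimodal", mode = 200, seed = 5)
  d2 <- synth_distribution("unimodal", mode = 350, seed = 6)
  expect_error(
    reference_set(list(reference_profile("a", d, 500),
                       reference_profile("b", d2, 300))),
    "increase strictly")
  expect_error(reference_set(list(reference_profile("a", d, 200))),
               "at least 2")

  dir <- withr::local_tempdir()
  write_distribution(d, file.path(dir, "a.csv"))
  write_distribution(d2, file.path(dir, "b.csv"))
  manifest <- file.path(dir, "refs.tsv")
  utils::write.table(
    data.frame(name = c("a", "b"),
               avg_length_bp = c(average_fragment_length(d),
                                 average_fragment_length(d2)),
               distribution_path = c("a.csv", "b.csv")),
    manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  refs <- read_reference_set(manifest)
  expect_equal(refs$anchor_ratios,
               c(long_short_ratio(d, 175, 125),
                 long_short_ratio(d2, 175, 125)))
})

test_that("measurement validation catches unusable inputs", {
  expect_error(assay_measurement(0, 10), "positive")
  expect_error(assay_measurement(100, -1), "non-negative")
  expect_error(assay_measurement(100, 50, len_short = 175, len_long = 125),
               "exceed")
  refs <- make_refset()
  m <- assay_measurement(1000, 700, len_short = 100, len_long = 150)
  expect_error(estimate_genome_copies(m, refs), "do not match")
})
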