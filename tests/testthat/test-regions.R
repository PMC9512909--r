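test_that("coverage run-length encodes exact per-base counts", {
  iv <- data.frame(chrom = "c", start = c(0, 5), end = c(10, 15))
  tr <- interval_coverage(iv)
  expect_equal(tr$start, c(0, 5, 10))
  expect_equal(tr$end, c(5, 10, 15))
  expect_equal(tr$count, c(1L, 2L, 1L))

  expect_equal(nrow(interval_coverage(iv[0, ])), 0)

  # random instances against the per-base array oracle, incl. zero gaps
  for (s in 1:3) {
    set.seed(600 + s)
    n <- 1000
    st <- sample(0:9000, n, replace = TRUE)
    iv <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = st, end = st + sample(1:400, n, replace = TRUE))
    tr <- interval_coverage(iv)
    for (ch in c("c1", "c2")) {
      got <- track_to_array(tr, ch)
      want <- oracle_coverage_array(iv, ch, got$start,
                                    got$start + length(got$arr))
      expect_equal(got$arr, want)
    }
    # runs are sorted, non-overlapping, and adjacent runs differ in count
    for (ch in unique(tr$chrom)) {
      x <- tr[tr$chrom == ch, ]
      expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
      same <- x$start[-1] == x$end[-nrow(x)]
      expect_true(all(x$count[-1][same] != x$count[-nrow(x)][same]))
    }
  }

  expect_error(interval_coverage(data.frame(chrom = "c", start = 5, end = 5)),
               "row 1")
})

test_that("record filtering drops cell lines, incomplete rows and duplicates", {
  rec <- data.frame(
    chrom = "c", start = c(0, 0, 10, 20, 30), end = c(5, 5, 15, 25, 35),
    sample = c("s1", "s1", "s2", "s3", "s4"),
    cell_line = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    total_cn = c(2, 2, 2, NA, 2),
    minor_allele = c(1, 1, 1, 1, 1))
  out <- dedupe_and_filter_records(rec)
  expect_equal(nrow(out$intervals), 2)
  expect_equal(out$drops, c(cell_line = 1L, incomplete = 1L, duplicate = 1L))
  # same region from two different samples is kept twice
  rec2 <- rec[c(1, 1), ]
  rec2$sample <- c("a", "b")
  expect_equal(nrow(dedupe_and_filter_records(rec2)$intervals), 2)
})

test_that("low-CNA thresholding keeps, merges and derives percentiles", {
  tr <- structure(
    data.frame(chrom = "c", start = c(0, 10, 20), end = c(10, 20, 30),
               count = c(1L, 40L, 2L)),
    class = c("coverage_track", "data.frame"))
  kept <- threshold_low_cna(tr, hard_max = 34)
  expect_equal(kept$start, c(0, 20))
  expect_equal(kept$end, c(10, 30))

  # all counts under the bound merge into the full chromosome span
  kept2 <- threshold_low_cna(tr, hard_max = 40)
  expect_equal(kept2, data.frame(chrom = "c", start = 0, end = 30))

  # derived percentile equals the brute-force per-base quantile
  for (s in 1:3) {
    set.seed(700 + s)
    n <- 300
    st <- sample(0:5000, n, replace = TRUE)
    iv <- data.frame(chrom = "c", start = st,
                     end = st + sample(1:300, n, replace = TRUE))
    tr2 <- interval_coverage(iv)
    arr <- track_to_array(tr2, "c")$arr
    want <- sort(arr)[ceiling(0.10 * length(arr))]
    derived <- fragmetrics:::track_count_quantile(tr2, 0.10)
    expect_equal(derived, want)
    # thresholding at the derived bound matches per-base selection
    kept3 <- threshold_low_cna(tr2, percentile = 0.10)
    base0 <- min(tr2$start)
    want_bases <- which(arr <= want) - 1L + base0
    expect_equal(intervals_to_bases(kept3, "c"), want_bases)
  }

  expect_equal(nrow(threshold_low_cna(tr[0, ], hard_max = 1)), 0)
})

test_that("probe-gap filtering drops candidates over sparse probe space", {
  cand <- data.frame(chrom = "c",
                     start = c(0, 0), end = c(5000, 30000))
  probes <- data.frame(chrom = "c", pos = c(1000, 4000, 25000))
  kept <- probe_gap_filter(cand, probes)
  expect_equal(kept$end, 5000)  # the 24 kb internal gap drops the second

  # no probes on a chromosome: drop all its candidates with a warning
  cand2 <- data.frame(chrom = c("c", "d"), start = 0, end = 1000)
  expect_warning(kept2 <- probe_gap_filter(cand2, probes), "no probes")
  expect_equal(kept2$chrom, "c")

  # random fixture against the naive oracle
  set.seed(801)
  P <- sort(sample(0:100000, 40))
  st <- sample(0:90000, 30, replace = TRUE)
  cand3 <- data.frame(chrom = "c", start = st,
                      end = st + sample(500:20000, 30, replace = TRUE))
  cand3 <- validate_intervals(cand3)
  kept3 <- probe_gap_filter(cand3, data.frame(chrom = "c", pos = P))
  want <- vapply(seq_len(nrow(cand3)), function(i)
    oracle_probe_gap_keep(cand3$start[i], cand3$end[i], P, 10000),
    logical(1))
  expect_equal(paste(kept3$start, kept3$end),
               paste(cand3$start[want], cand3$end[want]))
})

test_that("apex flanking and intersection match per-base set logic", {
  reg <- data.frame(chrom = "c", start = 0, end = 2000)
  out <- flank_and_intersect(data.frame(chrom = "c", pos = 1000), reg)
  expect_equal(out, data.frame(chrom = "c", start = 935, end = 1066))

  # apex outside every region is excluded
  out2 <- flank_and_intersect(data.frame(chrom = "c", pos = 5000), reg)
  expect_equal(nrow(out2), 0)

  # random fixture: equality with brute-force base intersection
  set.seed(802)
  apexes <- data.frame(chrom = "c", pos = sample(100:9900, 15))
  st <- sample(0:9000, 10)
  regs <- validate_intervals(
    data.frame(chrom = "c", start = st, end = st + sample(100:800, 10)))
  got <- flank_and_intersect(apexes, regs)
  windows <- data.frame(chrom = "c", start = pmax(0, apexes$pos - 65),
                        end = apexes$pos + 66)
  want <- oracle_intersect_bases(windows, regs, "c", 11000)
  expect_equal(intervals_to_bases(got, "c"), want)
})

test_that("cytosine-free scanning matches enumeration and handles strands", {
  expect_equal(cytosine_free_windows("ATTAGGCATTA", 4), c(0, 1, 2, 7))
  expect_equal(cytosine_free_windows("CCCC", 2), integer())
  expect_equal(cytosine_free_windows("ATG", 5), integer())
  # N disqualifies a window
  expect_equal(cytosine_free_windows("ATNAT", 2), c(0, 3))

  set.seed(803)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                      prob = c(0.3, 0.28, 0.2, 0.2, 0.02)), collapse = "")
    w <- sample(3:25, 1)
    expect_equal(cytosine_free_windows(s, w), oracle_cfree(s, w))
  }

  expect_equal(revcomp("ATTAGGCATTA"), "TAATGCCTAAT")
  # a C-free window on one strand is G-free on the other
  expect_equal(cytosine_free_windows(revcomp("GGGG"), 2), integer())
})
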