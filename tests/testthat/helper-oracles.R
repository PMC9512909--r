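# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths: per-base arrays, per-molecule
# enumeration and naive loops, kept small enough to be obviously correct.

# random coarse fragment-size distribution
random_dist <- function(seed, n_bins = 12, lmin = 60, lmax = 900) {
  set.seed(seed)
  L <- sort(sample(lmin:lmax, n_bins))
  fragment_size_distribution(L, stats::runif(n_bins, 0.1, 5))
}

# Eq-by-hand intact proportion: explicit loop, no shared code
oracle_intact_dist <- function(d, r) {
  num <- 0; den <- 0
  for (i in seq_along(d$lengths)) {
    f <- d$lengths[i]; C <- d$concentrations[i]
    den <- den + C
    if (f >= r) num <- num + (f - r + 1) / f * C
  }
  num / den
}

# per-molecule enumeration of the number-average length: molecule counts
# proportional to C_f / f
oracle_number_average <- function(d, molecules_per_unit = 1e9) {
  counts <- round(d$concentrations / d$lengths * molecules_per_unit)
  sum(d$lengths * counts) / sum(counts)
}

# per-position, per-fragment WPS recount
oracle_wps <- function(frags, region, window = 120, min_len = 120,
                       max_len = 180) {
  half <- window / 2
  pos <- region$start:(region$end - 1)
  sapply(pos, function(p) {
    ws <- p - half; we <- p + half
    sc <- 0
    for (i in seq_len(nrow(frags))) {
      if (frags$chrom[i] != region$chrom) next
      s <- frags$start[i]; e <- frags$end[i]
      len <- e - s
      if (len < min_len || len > max_len) next
      if (s <= ws && e >= we) sc <- sc + 1
      else if ((s > ws && s < we) || (e > ws && e < we)) sc <- sc - 1
    }
    sc
  })
}

# per-base coverage counting over a bounded span
oracle_coverage_array <- function(intervals, chrom, span_start, span_end) {
  arr <- integer(span_end - span_start)
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    s <- max(iv$start[i], span_start); e <- min(iv$end[i], span_end)
    if (s < e) {
      idx <- (s - span_start + 1):(e - span_start)
      arr[idx] <- arr[idx] + 1L
    }
  }
  arr
}

# expand a coverage track back to a per-base array over its span
track_to_array <- function(track, chrom) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  span <- c(min(tr$start), max(tr$end))
  arr <- rep(NA_integer_, span[2] - span[1])
  for (i in seq_len(nrow(tr))) {
    idx <- (tr$start[i] - span[1] + 1):(tr$end[i] - span[1])
    arr[idx] <- tr$count[i]
  }
  list(arr = arr, start = span[1])
}

# naive per-base set intersection of two interval sets on one chromosome
oracle_intersect_bases <- function(a, b, chrom, span) {
  ina <- rep(FALSE, span)
  inb <- rep(FALSE, span)
  for (i in seq_len(nrow(a)))
    if (a$chrom[i] == chrom && a$start[i] < span)
      ina[(a$start[i] + 1):min(a$end[i], span)] <- TRUE
  for (i in seq_len(nrow(b)))
    if (b$chrom[i] == chrom && b$start[i] < span)
      inb[(b$start[i] + 1):min(b$end[i], span)] <- TRUE
  which(ina & inb) - 1L  # 0-based covered bases
}

# expand an intervals data.frame to its 0-based covered bases
intervals_to_bases <- function(iv, chrom) {
  out <- integer()
  for (i in seq_len(nrow(iv)))
    if (iv$chrom[i] == chrom)
      out <- c(out, iv$start[i]:(iv$end[i] - 1))
  sort(out)
}

# naive substring scan for cytosine-free windows (0-based starts)
oracle_cfree <- function(seq, w) {
  n <- nchar(seq)
  if (w > n) return(integer())
  hits <- integer()
  for (s in 0:(n - w)) {
    win <- substr(seq, s + 1, s + w)
    if (!grepl("[CN]", toupper(win))) hits <- c(hits, s)
  }
  hits
}

# naive probe-gap decision for one candidate on one chromosome: edges need a
# probe within max_gap; internal probe gaps count only over their stretch
# inside the candidate
oracle_probe_gap_keep <- function(s, e, probes, max_gap) {
  P <- sort(probes)
  if (!length(P)) return(FALSE)
  if (min(abs(P - s)) > max_gap) return(FALSE)
  if (min(abs(P - e)) > max_gap) return(FALSE)
  for (i in seq_along(P)[-1]) {
    lo <- P[i - 1]; hi <- P[i]
    if (hi > s && lo < e) {
      if (min(hi, e) - max(lo, s) > max_gap) return(FALSE)
    }
  }
  TRUE
}

# a small synthetic reference set bracketing moderately fragmented samples
make_refset <- function(modes = c(120, 200, 300, 400), seed = 10) {
  profiles <- lapply(seq_along(modes), function(i) {
    d <- synth_distribution("unimodal", mode = modes[i], seed = seed + i)
    reference_profile(paste0("ref", modes[i]), d,
                      average_fragment_length(d))
  })
  reference_set(profiles)
}
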