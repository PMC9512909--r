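#' Validate a table of genomic intervals
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based half-open) plus optional payload columns. Used by all region
#' operations.
#'
#' @param x a data.frame of intervals.
#' @return `x`, sorted by (chrom, start, end), rownames dropped.
#' @export
validate_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("intervals must be a data.frame with columns chrom, start, end")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("malformed interval at row ", bad[1L],
         " (need 0 <= start < end)")
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read intervals from a BED file
#'
#' @param path path to a headerless BED file (3+ columns).
#' @param extra_names optional names for columns beyond the first three.
#' @return A validated intervals data.frame.
#' @export
read_bed <- function(path, extra_names = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names))
    names(tab)[seq_along(extra_names) + 3L] <- extra_names
  validate_intervals(tab)
}

#' Write intervals as BED
#'
#' @param x an intervals data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-base overlap coverage of a set of intervals
#'
#' Counts, at every base, how many intervals cover it, and run-length
#' encodes the result: maximal runs of constant count. Zero-count runs
#' strictly between covered runs on the same chromosome are included (they
#' are genuine zero-CNA space); bases outside the covered span of a
#' chromosome are not reported.
#'
#' @param intervals an intervals data.frame (one row per record; records
#'   should already be deduplicated per sample, see
#'   [dedupe_and_filter_records()]).
#' @return A data.frame with columns `chrom`, `start`, `end`, `count`,
#'   class `c("coverage_track", "data.frame")`. Empty input gives an empty
#'   track.
#' @examples
#' iv <- data.frame(chrom = "c", start = c(0, 5), end = c(10, 15))
#' interval_coverage(iv)
#' @export
interval_coverage <- function(intervals) {
  empty <- structure(
    data.frame(chrom = character(), start = integer(), end = integer(),
               count = integer(), stringsAsFactors = FALSE),
    class = c("coverage_track", "data.frame"))
  if (is.null(intervals) || nrow(intervals) == 0L) return(empty)
  intervals <- validate_intervals(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(iv) {
    # event sweep: +1 at each start, -1 at each end
    ev <- c(iv$start, iv$end)
    dl <- c(rep(1L, nrow(iv)), rep(-1L, nrow(iv)))
    agg <- vapply(split(dl, ev), sum, integer(1))
    pos <- as.integer(names(agg))
    o <- order(pos)
    pos <- pos[o]
    count <- cumsum(agg[o])
    n <- length(pos)
    seg <- data.frame(chrom = iv$chrom[1L],
                      start = pos[-n], end = pos[-1L],
                      count = as.integer(count[-n]),
                      stringsAsFactors = FALSE)
    # merge adjacent equal-count runs
    changed <- c(TRUE, seg$count[-1L] != seg$count[-nrow(seg)])
    grp <- cumsum(changed)
    data.frame(chrom = seg$chrom[1L],
               start = vapply(split(seg$start, grp), min, numeric(1)),
               end = vapply(split(seg$end, grp), max, numeric(1)),
               count = seg$count[changed],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track a coverage track from [interval_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Deduplicate and filter CNA interval records
#'
#' Applies the record-level filters used before building a CNA coverage
#' track: drop records from cell-line samples, drop records missing total
#' copy number or minor allele counts, and keep one record per
#' (sample, region).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `sample`,
#'   `cell_line` (logical), `total_cn` and `minor_allele` (numeric, `NA`
#'   when missing).
#' @return A list with `intervals` (kept records, validated and sorted) and
#'   `drops`, a named integer vector of per-rule drop counts
#'   (`cell_line`, `incomplete`, `duplicate`).
#' @export
dedupe_and_filter_records <- function(records) {
  need <- c("chrom", "start", "end", "sample", "cell_line", "total_cn",
            "minor_allele")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  n0 <- nrow(records)
  cl <- records$cell_line %in% TRUE
  records <- records[!cl, , drop = FALSE]
  inc <- is.na(records$total_cn) | is.na(records$minor_allele)
  records <- records[!inc, , drop = FALSE]
  key <- paste(records$sample, records$chrom, records$start, records$end,
               sep = "\r")
  dup <- duplicated(key)
  records <- records[!dup, , drop = FALSE]
  list(intervals = validate_intervals(records),
       drops = c(cell_line = sum(cl), incomplete = sum(inc),
                 duplicate = sum(dup)))
}

# length-weighted type-1 quantile of per-base counts in a coverage track
track_count_quantile <- function(track, p) {
  len <- track$end - track$start
  o <- order(track$count)
  counts <- track$count[o]
  cumlen <- cumsum(len[o])
  counts[which(cumlen >= p * sum(len))[1L]]
}

#' Select low-CNA (copy-neutral) regions from a coverage track
#'
#' Keeps the runs whose per-base sample count does not exceed a threshold
#' and merges adjacent kept runs. The threshold is either given directly
#' (`hard_max`, the documented operative rule: exclude regions where more
#' samples than this carry a CNA) or derived as the length-weighted
#' percentile of per-base counts (`percentile`, e.g. 0.10 for the bottom
#' 10th percentile).
#'
#' @param track a coverage track from [interval_coverage()].
#' @param percentile fraction in (0, 1]; ignored when `hard_max` is given.
#' @param hard_max maximum allowed per-base sample count.
#' @return An intervals data.frame of kept, merged regions (possibly empty).
#' @examples
#' tr <- structure(data.frame(chrom = "c", start = c(0, 10, 20),
#'                            end = c(10, 20, 30), count = c(1L, 40L, 2L)),
#'                 class = c("coverage_track", "data.frame"))
#' threshold_low_cna(tr, hard_max = 34)  # two intervals
#' @export
threshold_low_cna <- function(track, percentile = NULL, hard_max = NULL) {
  if (nrow(track) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  if (is.null(hard_max)) {
    if (is.null(percentile))
      stop("supply `hard_max` or `percentile`")
    if (percentile <= 0 || percentile > 1)
      stop("`percentile` must be in (0, 1]")
    hard_max <- track_count_quantile(track, percentile)
  }
  kept <- track[track$count <= hard_max, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  merge_contiguous(kept[, c("chrom", "start", "end")])
}

# merge intervals that touch or overlap, per chromosome (input sorted or not)
merge_contiguous <- function(iv) {
  iv <- validate_intervals(iv)
  out <- lapply(split(iv, iv$chrom), function(x) {
    ns <- x$start; ne <- x$end
    keep_s <- ns[1L]; res_s <- integer(); res_e <- integer()
    cur_e <- ne[1L]
    for (i in seq_len(nrow(x))[-1L]) {
      if (ns[i] <= cur_e) {
        cur_e <- max(cur_e, ne[i])
      } else {
        res_s <- c(res_s, keep_s); res_e <- c(res_e, cur_e)
        keep_s <- ns[i]; cur_e <- ne[i]
      }
    }
    res_s <- c(res_s, keep_s); res_e <- c(res_e, cur_e)
    data.frame(chrom = x$chrom[1L], start = res_s, end = res_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Drop candidate regions with sparse copy-number probe coverage
#'
#' A candidate region is dropped when the local copy-number probe spacing
#' cannot support CNA detection: the unassayable stretch inside the
#' candidate left by any gap between consecutive probes (the gap clipped to
#' the candidate) exceeds `max_gap`, or a candidate edge lies more than
#' `max_gap` from the nearest probe, or the chromosome has no probes at all
#' (with a warning).
#'
#' @param candidates intervals data.frame of candidate regions.
#' @param probes data.frame with columns `chrom`, `pos` (0-based probe
#'   positions), or a numeric vector of positions when all candidates share
#'   one chromosome.
#' @param max_gap largest tolerated probe gap, bp (default 10,000).
#' @return The kept candidates (same columns, original order within
#'   chromosome sort).
#' @export
probe_gap_filter <- function(candidates, probes, max_gap = 10000) {
  candidates <- validate_intervals(candidates)
  if (is.numeric(probes))
    probes <- data.frame(chrom = unique(candidates$chrom)[1L], pos = probes,
                         stringsAsFactors = FALSE)
  keep <- logical(nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == ch)
    P <- sort(probes$pos[probes$chrom == ch])
    if (!length(P)) {
      warning("no probes on chromosome ", ch, "; dropping ", length(ci),
              " candidate(s)")
      next
    }
    for (i in ci) {
      s <- candidates$start[i]; e <- candidates$end[i]
      # adjacent probe pairs whose open gap intersects [s, e), clipped
      if (length(P) > 1L) {
        gl <- P[-length(P)]; gr <- P[-1L]
        ov <- gr > s & gl < e
        if (any((pmin(gr, e) - pmax(gl, s))[ov] > max_gap)) next
      }
      # each candidate edge must have a probe within max_gap
      keep[i] <- min(abs(P - s)) <= max_gap && min(abs(P - e)) <= max_gap
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Flank protection-peak apexes and intersect with regions
#'
#' Expands each apex position to the window `[apex - flank, apex + flank + 1)`
#' (the apex base plus `flank` bp either side) and returns the exact
#' intersection of these windows with a set of regions, e.g. the remaining
#' copy-number-invariant space.
#'
#' @param apexes data.frame with columns `chrom`, `pos` (apex positions),
#'   or a numeric vector when `regions` spans a single chromosome.
#' @param regions intervals data.frame to intersect with.
#' @param flank flank width either side of the apex, bp (default 65).
#' @return An intervals data.frame of intersected pieces (possibly empty).
#' @examples
#' flank_and_intersect(data.frame(chrom = "c", pos = 1000),
#'                     data.frame(chrom = "c", start = 0, end = 2000))
#' @export
flank_and_intersect <- function(apexes, regions, flank = 65) {
  if (is.numeric(apexes))
    apexes <- data.frame(chrom = unique(regions$chrom)[1L], pos = apexes,
                         stringsAsFactors = FALSE)
  windows <- data.frame(chrom = apexes$chrom,
                        start = apexes$pos - flank,
                        end = apexes$pos + flank + 1L,
                        stringsAsFactors = FALSE)
  windows$start <- pmax(0L, as.integer(windows$start))
  intersect_intervals(windows, regions)
}

#' Intersect two interval sets
#'
#' Exact interval intersection (every base present in both sets), with the
#' result merged and sorted.
#'
#' @param a,b intervals data.frames.
#' @return An intervals data.frame.
#' @export
intersect_intervals <- function(a, b) {
  a <- validate_intervals(a); b <- validate_intervals(b)
  pieces <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(ai))) {
      s <- pmax(ai$start[i], bi$start); e <- pmin(ai$end[i], bi$end)
      ok <- s < e
      if (any(ok))
        pieces[[length(pieces) + 1L]] <-
          data.frame(chrom = ch, start = s[ok], end = e[ok],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  merge_contiguous(do.call(rbind, pieces))
}

#' Find cytosine-free windows in a sequence
#'
#' Scans a nucleotide sequence for every window of the given width that
#' contains no 'C' and no 'N'. Primer/probe sites placed in such windows on
#' the template strand are unaffected by bisulfite conversion, so one assay
#' amplifies both genomic and converted DNA. The scan is strand-agnostic:
#' screen the reverse complement (see [revcomp()]) separately for the other
#' strand.
#'
#' @param sequence a single character string over A/C/G/T/N (case
#'   insensitive).
#' @param window window width, bp (>= 1).
#' @return Integer vector of 0-based window start offsets (BED convention);
#'   empty when `window` exceeds the sequence length.
#' @examples
#' cytosine_free_windows("ATTAGGCATTA", 4)  # 0 1 2 7
#' @export
cytosine_free_windows <- function(sequence, window) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  window <- check_count(window, "window")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (window > n) return(integer())
  bad <- as.integer(chars %in% c("C", "N"))
  # window starting at 0-based s is clean iff no disqualifying base in
  # chars[(s+1):(s+window)]
  cs <- c(0L, cumsum(bad))
  s <- 0:(n - window)
  s[cs[s + window + 1L] - cs[s + 1L] == 0L]
}

#' Reverse complement of a nucleotide sequence
#'
#' @param sequence a single character string over A/C/G/T/N.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]),
               collapse = ""))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over Biostrings for FASTA input; returns plain character
#' strings for use with [cytosine_free_windows()].
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
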