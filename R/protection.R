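#' Windowed Protection Score configuration
#'
#' Parameters of the WPS: the window width centred on each position and the
#' fragment-length band considered (nucleosome-sized cfDNA fragments).
#'
#' @param window window width, bp; must be even and positive (default 120).
#' @param min_fragment,max_fragment eligible fragment length band, bp
#'   (defaults 120-180).
#' @return An object of class `wps_config`.
#' @export
wps_config <- function(window = 120, min_fragment = 120, max_fragment = 180) {
  window <- check_count(window, "window")
  if (window %% 2L != 0L) stop("`window` must be even")
  min_fragment <- check_count(min_fragment, "min_fragment")
  max_fragment <- check_count(max_fragment, "max_fragment")
  if (min_fragment > max_fragment) stop("`min_fragment` must be <= `max_fragment`")
  structure(list(window = window, min_fragment = min_fragment,
                 max_fragment = max_fragment), class = "wps_config")
}

#' Read cfDNA fragment intervals from a BED file
#'
#' Reads the first three columns (chrom, start, end; 0-based half-open) of a
#' BED file, validates and sorts them.
#'
#' @param path path to a BED file (3+ columns, no header).
#' @return A `fragment_set` data.frame with columns `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("invalid interval (start >= end) at row ",
         which(out$start >= out$end)[1L])
  if (any(out$start < 0)) stop("negative start coordinate")
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

# add `value` to track positions [from, to] (track coordinates), clipped
add_run <- function(vec, from, to, value) {
  from <- max(1L, from); to <- min(length(vec), to)
  if (from <= to) vec[from:to] <- vec[from:to] + value
  vec
}

#' Compute the Windowed Protection Score over a region
#'
#' For each position p in the region, the WPS is the number of eligible
#' (length-banded) fragments that wholly overlap the window
#' `[p - window/2, p + window/2)` minus the number with at least one endpoint
#' strictly inside that window. A fragment that neither spans the window nor
#' truncates inside it contributes 0, so each fragment contributes exactly
#' one of {-1, 0, +1} per position. Positive runs mark nucleosome-protected
#' DNA; negative runs mark preferential fragmentation.
#'
#' The even window is centred as `[p - window/2, p + window/2)`: the scored
#' position sits in the left half. This is a documented convention; the
#' original peak catalogues do not pin down the parity choice.
#'
#' @param frags a `fragment_set` data.frame (see [read_fragments_bed()] or
#'   [synth_fragment_set()]).
#' @param region a list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open) giving the positions to score.
#' @param config a [wps_config()].
#' @return An object of class `wps_track`: list with `chrom`, `start` and an
#'   integer `scores` vector, one score per position in `[start, end)`.
#' @export
compute_wps <- function(frags, region, config = wps_config()) {
  stopifnot(is.data.frame(frags), inherits(config, "wps_config"))
  rs <- as.integer(region$start); re <- as.integer(region$end)
  if (rs >= re) stop("invalid region")
  n <- re - rs
  scores <- integer(n)
  half <- config$window %/% 2L
  f <- frags[frags$chrom == region$chrom, , drop = FALSE]
  len <- f$end - f$start
  f <- f[len >= config$min_fragment & len <= config$max_fragment, ,
         drop = FALSE]
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]
    # span: window within fragment  <=>  p in [s + half, e - half]
    scores <- add_run(scores, s + half - rs + 1L, e - half - rs + 1L, 1L)
    # truncate: an endpoint strictly inside the window. start endpoint:
    # p - half < s < p + half  <=>  p in [s - half + 1, s + half - 1];
    # end endpoint strictly inside  <=>  p in [e - half + 1, e + half - 1].
    # Union, counted once per fragment.
    a1 <- s - half + 1L; b1 <- s + half - 1L
    a2 <- e - half + 1L; b2 <- e + half - 1L
    if (a2 <= b1 + 1L) {        # ranges touch or overlap: single run
      scores <- add_run(scores, a1 - rs + 1L, b2 - rs + 1L, -1L)
    } else {
      scores <- add_run(scores, a1 - rs + 1L, b1 - rs + 1L, -1L)
      scores <- add_run(scores, a2 - rs + 1L, b2 - rs + 1L, -1L)
    }
  }
  structure(list(chrom = region$chrom, start = rs, scores = scores),
            class = "wps_track")
}

#' @export
print.wps_track <- function(x, ...) {
  cat("WPS track:", x$chrom, ":", x$start, "-",
      x$start + length(x$scores), "\n")
  cat("  score range:", min(x$scores), "..", max(x$scores), "\n")
  invisible(x)
}

#' Write a WPS track as bedGraph
#'
#' Adjacent positions with equal score are merged into runs.
#'
#' @param track a `wps_track` from [compute_wps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wps_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "wps_track"))
  r <- rle(track$scores)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  utils::write.table(
    data.frame(track$chrom, starts, ends, r$values),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Call nucleosome protection peaks from a WPS track
#'
#' Adjusts the raw track by subtracting a running median (removing local
#' baseline shifts), smooths with a centred moving mean, and emits maximal
#' runs of positive adjusted score whose lengths fall in
#' `[min_len, max_len]`. The apex of each peak is the position of the
#' maximum *raw* WPS within the run (leftmost on ties) and the peak score is
#' the raw WPS at the apex.
#'
#' The default parameters are nucleosome-scale heuristics: a 1 kb median
#' window (long relative to a nucleosome footprint), 21 bp smoothing, and
#' peak lengths of 40-150 bp. The lower length bound admits the footprint of
#' a tightly positioned nucleosome, whose fully-spanned run is about the
#' eligible fragment length minus the window width (~46 bp for 166 bp
#' fragments and a 120 bp window). `min_score` discards runs whose raw apex
#' score is not positive (baseline-subtraction can lift zero-coverage
#' stretches above the local median without any spanning fragment). The
#' median window is forced odd and capped at the track length.
#'
#' @param track a `wps_track`.
#' @param median_window running-median window, bp.
#' @param smooth_window moving-mean window, bp.
#' @param min_len,max_len accepted peak lengths, bp.
#' @param min_score minimum raw WPS at the apex.
#' @return A data.frame with columns `chrom`, `start`, `end`, `apex`,
#'   `score` (0-based half-open; `apex` is a position). Zero rows when no
#'   peak qualifies.
#' @export
call_peaks <- function(track, median_window = 1000, smooth_window = 21,
                       min_len = 40, max_len = 150, min_score = 1) {
  stopifnot(inherits(track, "wps_track"))
  sc <- as.numeric(track$scores)
  n <- length(sc)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), apex = integer(), score = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  k <- min(median_window, n)
  if (k %% 2L == 0L) k <- k - 1L
  adj <- if (k >= 3L) sc - stats::runmed(sc, k) else sc - stats::median(sc)
  if (smooth_window > 1L) {
    sm <- stats::filter(adj, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    adj <- ifelse(is.na(sm), 0, as.numeric(sm))
  }
  r <- rle(adj > 0)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len & r$lengths <= max_len)
  if (!length(keep)) return(empty)
  peaks <- lapply(keep, function(i) {
    a <- run_start[i]; b <- run_end[i]
    apex_rel <- a + which.max(track$scores[a:b]) - 1L
    data.frame(chrom = track$chrom,
               start = track$start + a - 1L,
               end = track$start + b,
               apex = track$start + apex_rel - 1L,
               score = track$scores[apex_rel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, peaks)
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum distance from an amplicon to a protection-peak apex
#'
#' The farthest base of the amplicon from the apex:
#' `max(|start - apex|, |end - 1 - apex|)`. Assay placement aims to keep
#' this small so the whole amplicon rides the protected (intact) DNA.
#'
#' @param amplicon list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param peak a peak row from [call_peaks()] (uses `chrom`, `apex`), or a
#'   list with those fields.
#' @return Distance in bp.
#' @examples
#' amplicon_peak_distance(list(chrom = "chr2", start = 100, end = 200),
#'                        list(chrom = "chr2", apex = 130))  # 69
#' @export
amplicon_peak_distance <- function(amplicon, peak) {
  if (!identical(as.character(amplicon$chrom), as.character(peak$chrom)))
    stop("amplicon and peak are on different chromosomes")
  max(abs(amplicon$start - peak$apex), abs(amplicon$end - 1L - peak$apex))
}
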