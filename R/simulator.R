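#' Define a Monte Carlo fragmentation experiment
#'
#' Fixes the genome, target region and replication settings for the
#' fragmentation simulator. The simulator is the independent oracle for the
#' closed-form intact-proportion results: it literally cuts a genome at a
#' random phase and checks whether the region survives.
#'
#' On a circular genome the sliding-window law (f - r + 1)/f holds exactly
#' for every region; on a linear genome it differs only within a fragment
#' length of the ends, a relative effect of order f / genome_length.
#'
#' @param genome_length genome length, bp.
#' @param region_start 0-based start of the target region.
#' @param region_length region length r, bp.
#' @param replicates number of Monte Carlo replicates (>= 1).
#' @param seed RNG seed (mandatory; all simulator output is reproducible).
#' @param circular circular genome? Default `TRUE`.
#' @return An object of class `fragmentation_experiment`.
#' @export
fragmentation_experiment <- function(genome_length, region_start,
                                     region_length, replicates = 10000,
                                     seed, circular = TRUE) {
  genome_length <- check_count(genome_length, "genome_length")
  region_length <- check_count(region_length, "region_length")
  replicates <- check_count(replicates, "replicates")
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  if (region_start < 0 || region_start + region_length > genome_length)
    stop("region does not fit in the genome")
  structure(list(genome_length = genome_length,
                 region_start = round(region_start),
                 region_length = region_length,
                 replicates = replicates, seed = seed,
                 circular = circular,
                 rng_kind = "Mersenne-Twister"),
            class = "fragmentation_experiment")
}

new_frag_estimate <- function(estimate, se, replicates, seed) {
  structure(list(estimate = estimate, se = se, replicates = replicates,
                 seed = seed, rng_kind = "Mersenne-Twister"),
            class = "fragmentation_estimate")
}

#' @export
print.fragmentation_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo intact proportion: %.5f (SE %.5f, %d replicates)\n",
              x$estimate, x$se, x$replicates))
  invisible(x)
}

# Vectorised survival check for one replicate set. Cuts fall at positions
# congruent to `phase` modulo f; the region [s, s + r) is broken iff a cut
# lies strictly inside it. d0 = offset from s to the first cut at or after s:
# intact iff the region starts exactly on a cut (d0 == 0, next cut f away)
# or the first interior cut is at or beyond the region end (d0 >= r).
intact_given_phase <- function(phase, f, s, r) {
  d0 <- (phase - s) %% f
  (d0 == 0 & f >= r) | d0 >= r
}

#' Monte Carlo intact proportion at a single fragment length
#'
#' Per replicate, draws a uniform phase in `{0, ..., f - 1}`, cuts the
#' (circular) genome every f bp from that phase, and records whether the
#' target region is uncut. The mean over replicates estimates
#' [intact_proportion()] with a binomial standard error.
#'
#' @param exp a [fragmentation_experiment()].
#' @param f fragment length, bp.
#' @return A `fragmentation_estimate` with fields `estimate`, `se`,
#'   `replicates`, `seed`.
#' @examples
#' e <- fragmentation_experiment(10000, 500, 4, replicates = 1e4, seed = 42)
#' equal_length_fragmentation(e, 6)  # close to 0.5
#' @export
equal_length_fragmentation <- function(exp, f) {
  stopifnot(inherits(exp, "fragmentation_experiment"))
  f <- check_count(f, "f")
  if (exp$region_length > exp$genome_length) stop("region exceeds genome")
  set.seed(exp$seed)
  phase <- sample.int(f, exp$replicates, replace = TRUE) - 1L
  hits <- intact_given_phase(phase, f, exp$region_start, exp$region_length)
  p <- mean(hits)
  new_frag_estimate(p, sqrt(p * (1 - p) / exp$replicates),
                    exp$replicates, exp$seed)
}

#' Monte Carlo intact proportion under a fragment-length mixture
#'
#' Per replicate, draws a fragment length with probability proportional to
#' its mass concentration C_f (genome-equivalent weighting, matching the
#' distribution-weighted closed form), then proceeds as
#' [equal_length_fragmentation()]. Converges to
#' [intact_proportion_distribution()].
#'
#' @param exp a [fragmentation_experiment()].
#' @param d a [fragment_size_distribution()].
#' @return A `fragmentation_estimate`.
#' @export
mixture_fragmentation <- function(exp, d) {
  stopifnot(inherits(exp, "fragmentation_experiment"),
            inherits(d, "fragment_size_distribution"))
  if (total_mass(d) <= 0) stop("zero total mass")
  set.seed(exp$seed)
  idx <- sample.int(length(d$lengths), exp$replicates, replace = TRUE,
                    prob = d$concentrations)
  f <- d$lengths[idx]
  phase <- floor(stats::runif(exp$replicates) * f)
  hits <- intact_given_phase(phase, f, exp$region_start, exp$region_length)
  p <- mean(hits)
  new_frag_estimate(p, sqrt(p * (1 - p) / exp$replicates),
                    exp$replicates, exp$seed)
}

#' Generate a synthetic fragment-size distribution
#'
#' Produces distributions shaped like the two families seen in practice:
#' `"unimodal"` emulates a sonicated genomic DNA profile (log-normal mass
#' density around a modal length, truncated to 35-10,000 bp);
#' `"nucleosome_ladder"` emulates a cfDNA profile (mixture of Gaussian peaks
#' at multiples of 166 bp, the mono-, di-, tri-nucleosome ladder).
#'
#' @param kind `"unimodal"` or `"nucleosome_ladder"`.
#' @param mode modal fragment length for the unimodal kind, bp.
#' @param sdlog log-scale standard deviation of the unimodal density.
#' @param period nucleosome ladder period, bp (default 166).
#' @param n_peaks number of ladder peaks.
#' @param peak_sd within-peak standard deviation, bp.
#' @param peak_weights relative mass per ladder peak (defaults to a
#'   geometric decay 0.6^k, mirroring the dominance of the mononucleosome
#'   peak).
#' @param total_mass total mass of the distribution, pg/ul.
#' @param seed RNG seed (unused by the deterministic densities but accepted
#'   and recorded for interface uniformity).
#' @return A [fragment_size_distribution()] with unit (1 bp) bins.
#' @examples
#' d <- synth_distribution("unimodal", mode = 150, seed = 1)
#' d$lengths[which.max(d$concentrations)]  # ~150
#' @export
synth_distribution <- function(kind = c("unimodal", "nucleosome_ladder"),
                               mode = 150, sdlog = 0.45,
                               period = 166, n_peaks = 3, peak_sd = 20,
                               peak_weights = 0.6^(seq_len(n_peaks) - 1),
                               total_mass = 1000, seed = 1) {
  kind <- match.arg(kind)
  if (total_mass <= 0 || mode <= 0 || sdlog <= 0 || period <= 0 ||
      peak_sd <= 0 || n_peaks < 1)
    stop("degenerate parameters for synthetic distribution")
  grid <- 35:10000
  dens <- switch(kind,
    unimodal = {
      # log-normal with mode at `mode`: mode = exp(meanlog - sdlog^2)
      meanlog <- log(mode) + sdlog^2
      stats::dlnorm(grid, meanlog = meanlog, sdlog = sdlog)
    },
    nucleosome_ladder = {
      if (length(peak_weights) != n_peaks)
        stop("`peak_weights` must have `n_peaks` entries")
      w <- peak_weights / sum(peak_weights)
      rowSums(vapply(seq_len(n_peaks), function(k)
        w[k] * stats::dnorm(grid, mean = period * k, sd = peak_sd),
        numeric(length(grid))))
    })
  keep <- dens > max(dens) * 1e-12
  dens <- dens[keep]; grid <- grid[keep]
  fragment_size_distribution(grid, dens * (total_mass / sum(dens)))
}

#' Generate a synthetic cfDNA fragment set with planted nucleosomes
#'
#' Planted-truth generator for protection-score testing. Fragment lengths
#' are drawn from N(166, 10) (rounded, floored at 30 bp). With probability
#' equal to the per-position protection strength, a fragment is centred on a
#' planted nucleosome position with +/- 10 bp uniform jitter; otherwise it is
#' placed uniformly along the genome. Strength 0 therefore yields a uniform
#' background with no protection signal.
#'
#' @param genome_length genome length, bp.
#' @param nucleosome_positions planted nucleosome centre positions (0-based).
#' @param protection_strength per-position probability in `[0, 1]` that a
#'   fragment is nucleosome-bound (recycled to the number of positions).
#' @param n_fragments number of fragments to generate.
#' @param seed RNG seed (mandatory).
#' @param chrom chromosome name for the output intervals.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted by start; class `c("fragment_set", "data.frame")`.
#' @export
synth_fragment_set <- function(genome_length, nucleosome_positions = integer(),
                               protection_strength = 1,
                               n_fragments = 1000, seed, chrom = "chrS") {
  genome_length <- check_count(genome_length, "genome_length")
  n_fragments <- check_count(n_fragments, "n_fragments")
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  np <- length(nucleosome_positions)
  strength <- rep_len(protection_strength, max(np, 1L))
  if (any(strength < 0 | strength > 1))
    stop("`protection_strength` must be in [0, 1]")
  if (np && (any(nucleosome_positions < 0) ||
             any(nucleosome_positions >= genome_length)))
    stop("nucleosome positions must lie within the genome")
  set.seed(seed)
  len <- pmax(30L, as.integer(round(stats::rnorm(n_fragments, 166, 10))))
  if (np) {
    which_nuc <- sample.int(np, n_fragments, replace = TRUE)
    bound <- stats::runif(n_fragments) < strength[which_nuc]
    centre <- nucleosome_positions[which_nuc] +
      sample(-10:10, n_fragments, replace = TRUE)
    start <- ifelse(bound,
                    as.integer(round(centre - len / 2)),
                    as.integer(floor(stats::runif(n_fragments) *
                                       (genome_length - len))))
  } else {
    start <- as.integer(floor(stats::runif(n_fragments) *
                                (genome_length - len)))
  }
  start <- pmax(0L, pmin(start, genome_length - len))
  out <- data.frame(chrom = chrom, start = start, end = start + len,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}
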