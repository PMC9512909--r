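#' Genome mass model
#'
#' Constants relating DNA mass to haploid genome copies. The mass of one
#' genome in pg is genome_length * bp_molar_mass * pg_per_g / avogadro,
#' which with the defaults evaluates to about 3.4917 pg (commonly quoted as
#' 3.5 pg per haploid human genome).
#'
#' @param genome_length haploid genome length in bp.
#' @param bp_molar_mass average molar mass of a base pair, g/mol/bp.
#' @param avogadro Avogadro's number, molecules/mol.
#' @param pg_per_g picograms per gram.
#' @return An object of class `genome_mass_model` with the four constants and
#'   the derived `genome_mass_pg`.
#' @examples
#' gm <- genome_mass_model()
#' signif(gm$genome_mass_pg, 2)  # 3.5
#' @export
genome_mass_model <- function(genome_length = 3234830000,
                              bp_molar_mass = 650,
                              avogadro = 6.022e23,
                              pg_per_g = 1e12) {
  vals <- c(genome_length, bp_molar_mass, avogadro, pg_per_g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all genome mass model constants must be strictly positive")
  structure(list(genome_length = genome_length,
                 bp_molar_mass = bp_molar_mass,
                 avogadro = avogadro,
                 pg_per_g = pg_per_g,
                 genome_mass_pg =
                   genome_length * bp_molar_mass * pg_per_g / avogadro),
            class = "genome_mass_model")
}

#' @export
print.genome_mass_model <- function(x, ...) {
  cat("Genome mass model:", format(x$genome_length, big.mark = ","),
      "bp x", x$bp_molar_mass, "g/mol/bp\n")
  cat("  1 genome =", format(round(x$genome_mass_pg, 4)), "pg\n")
  invisible(x)
}

check_count <- function(x, name, tol = 1e-8) {
  if (anyNA(x) || !is.numeric(x)) stop("`", name, "` must be numeric")
  if (any(x < 1) || any(abs(x - round(x)) > tol))
    stop("`", name, "` must be a positive integer number of bp")
  round(x)
}

#' Proportion of intact copies at a single fragment length
#'
#' For DNA broken into fragments of a single length f, the probability that a
#' region of length r is not interrupted by a break is (f - r + 1) / f when
#' f >= r, and 0 otherwise (a region cannot survive intact on a fragment
#' shorter than itself). This is the sliding-window argument: of the f
#' possible phases of the fragment grid relative to the region, f - r + 1
#' leave the region wholly within one fragment.
#'
#' @param r region (amplicon) length, bp; positive integer(s).
#' @param f fragment length, bp; positive integer(s). `r` and `f` recycle.
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' intact_proportion(4, 6)     # 0.5
#' intact_proportion(125, 200) # 0.38
#' @export
intact_proportion <- function(r, f) {
  r <- check_count(r, "r")
  f <- check_count(f, "f")
  p <- (f - r + 1) / f
  p[f < r] <- 0
  p
}

#' Proportion of intact copies under a fragment-size distribution
#'
#' Real samples fragment as a distribution of lengths, not a single length.
#' Weighting each length's intact proportion by its mass concentration gives
#' the sample-level proportion of region copies that remain intact:
#' sum over f >= r of ((f - r + 1)/f) C_f, divided by the total mass
#' sum over all f of C_f.
#'
#' @param d a [fragment_size_distribution()] with positive total mass.
#' @param r region length, bp; positive integer(s) (vectorised).
#' @return Proportion(s) in `[0, 1]`; 0 when `r` exceeds the longest fragment.
#' @examples
#' d <- fragment_size_distribution(c(6, 8), c(1, 1))
#' intact_proportion_distribution(d, 4)  # 0.5625
#' @export
intact_proportion_distribution <- function(d, r) {
  stopifnot(inherits(d, "fragment_size_distribution"))
  r <- check_count(r, "r")
  tot <- total_mass(d)
  if (tot <= 0) stop("zero total mass: intact proportion undefined")
  f <- as.numeric(d$lengths); C <- d$concentrations
  vapply(r, function(ri) {
    keep <- f >= ri
    if (!any(keep)) return(0)
    sum(((f[keep] - ri + 1) / f[keep]) * C[keep]) / tot
  }, numeric(1))
}

#' Differential amplicon-length ratio [long]/[short]
#'
#' The ratio of amplifiable copies measured by a longer versus a shorter
#' amplicon over the same sample, predicted from its fragment-size
#' distribution. This is a ratiometric index of fragmentation: 1 for intact
#' DNA, approaching 0 for heavily fragmented DNA.
#'
#' @param d a [fragment_size_distribution()].
#' @param long length of the longer region, bp.
#' @param short length of the shorter region, bp; `long >= short` required.
#' @return Ratio in `[0, 1]`.
#' @examples
#' d <- fragment_size_distribution(200, 5)
#' long_short_ratio(d, 175, 125)  # 26/76
#' @export
long_short_ratio <- function(d, long = 175, short = 125) {
  long <- check_count(long, "long")
  short <- check_count(short, "short")
  if (long < short) stop("`long` must be >= `short`")
  intact_ratio(d, long, short)
}

# Ratio of intact proportions at two region lengths, without the ordering
# contract of long_short_ratio (the calculator needs [short]/[r] for r on
# either side of short).
intact_ratio <- function(d, num_len, den_len) {
  den <- intact_proportion_distribution(d, den_len)
  if (den <= 0)
    stop("no amplifiable copies at the ", den_len,
         " bp denominator region: all fragments are shorter")
  intact_proportion_distribution(d, num_len) / den
}

#' Convert mass concentration to genome copies
#'
#' Divides a DNA mass concentration by the mass of one haploid genome. The
#' result counts genome equivalents -- intact or broken -- per microlitre.
#'
#' @param c_pg_ul mass concentration, pg/ul (vectorised, >= 0).
#' @param model a [genome_mass_model()].
#' @return Genome copies per microlitre (exact reals; round for display).
#' @examples
#' signif(mass_to_copies(35270), 3)  # 10100
#' signif(mass_to_copies(68400), 3)  # 19600
#' @export
mass_to_copies <- function(c_pg_ul, model = genome_mass_model()) {
  stopifnot(inherits(model, "genome_mass_model"))
  if (any(c_pg_ul < 0)) stop("mass concentration must be >= 0")
  c_pg_ul / model$genome_mass_pg
}

#' Convert genome copies to mass concentration
#'
#' Inverse of [mass_to_copies()].
#'
#' @param copies_ul genome copies per microlitre (>= 0).
#' @param model a [genome_mass_model()].
#' @return Mass concentration in pg/ul.
#' @export
copies_to_mass <- function(copies_ul, model = genome_mass_model()) {
  stopifnot(inherits(model, "genome_mass_model"))
  if (any(copies_ul < 0)) stop("copies must be >= 0")
  copies_ul * model$genome_mass_pg
}
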