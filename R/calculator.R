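#' Assay measurement for a short/long amplicon pair
#'
#' Measured concentrations (copies/ul) from two PCR assays of different
#' amplicon lengths over the same sample, typically 125 bp and 175 bp.
#' The measured [long]/[short] ratio is the fragmentation index the
#' Fragment Calculator interpolates on.
#'
#' @param c_short copies/ul at the short amplicon (> 0).
#' @param c_long copies/ul at the long amplicon (>= 0).
#' @param len_short short amplicon length, bp (default 125).
#' @param len_long long amplicon length, bp (default 175); must exceed
#'   `len_short`.
#' @return An object of class `assay_measurement` with a `measured_ratio`
#'   field equal to `c_long / c_short`.
#' @export
assay_measurement <- function(c_short, c_long, len_short = 125,
                              len_long = 175) {
  if (!is.numeric(c_short) || length(c_short) != 1L || c_short <= 0)
    stop("`c_short` must be a single positive concentration")
  if (!is.numeric(c_long) || length(c_long) != 1L || c_long < 0)
    stop("`c_long` must be a single non-negative concentration")
  len_short <- check_count(len_short, "len_short")
  len_long <- check_count(len_long, "len_long")
  if (len_long <= len_short) stop("`len_long` must exceed `len_short`")
  structure(list(c_short = c_short, c_long = c_long,
                 len_short = len_short, len_long = len_long,
                 measured_ratio = c_long / c_short),
            class = "assay_measurement")
}

#' @export
print.assay_measurement <- function(x, ...) {
  cat(sprintf("Assay measurement: [%d bp] = %g, [%d bp] = %g copies/ul\n",
              x$len_short, x$c_short, x$len_long, x$c_long))
  cat(sprintf("  [%d bp]/[%d bp] ratio = %.4g\n",
              x$len_long, x$len_short, x$measured_ratio))
  invisible(x)
}

#' Reference profile
#'
#' One reference sample: its fragment-size distribution and its stated
#' average fragment length. Average lengths are accepted as given (typically
#' reported by the sizing instrument).
#'
#' @param name identifier for the sample.
#' @param distribution a [fragment_size_distribution()].
#' @param average_length average fragment length in bp (> 0).
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(name, distribution, average_length) {
  stopifnot(inherits(distribution, "fragment_size_distribution"))
  if (!is.numeric(average_length) || length(average_length) != 1L ||
      average_length <= 0)
    stop("`average_length` must be a single positive number of bp")
  structure(list(name = as.character(name), distribution = distribution,
                 average_length = average_length),
            class = "reference_profile")
}

#' Reference set for the Fragment Calculator
#'
#' An ordered collection of reference profiles spanning the fragmentation
#' range of interest. Each profile's [long]/[short] anchor ratio is computed
#' from its distribution; anchors must increase strictly with average
#' fragment length (more intact samples have higher ratios), which is
#' validated at construction.
#'
#' @param profiles a list of [reference_profile()] objects (>= 2).
#' @param len_short,len_long amplicon lengths the anchors are computed at
#'   (defaults 125 and 175 bp).
#' @return An object of class `reference_set` with profiles sorted by anchor
#'   ratio and a parallel `anchor_ratios` vector.
#' @export
reference_set <- function(profiles, len_short = 125, len_long = 175) {
  if (!is.list(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "reference_profile")))
    stop("`profiles` must be a list of reference_profile objects")
  if (length(profiles) < 2L)
    stop("a reference set needs at least 2 profiles to interpolate")
  ratios <- vapply(profiles, function(p)
    long_short_ratio(p$distribution, len_long, len_short), numeric(1))
  avg <- vapply(profiles, `[[`, numeric(1), "average_length")
  o <- order(avg)
  ratios <- ratios[o]; profiles <- profiles[o]; avg <- avg[o]
  if (any(diff(ratios) <= 0))
    stop("anchor [long]/[short] ratios must increase strictly with ",
         "average fragment length; offending profile: ",
         profiles[[which(diff(ratios) <= 0)[1L] + 1L]]$name)
  structure(list(profiles = profiles, anchor_ratios = ratios,
                 average_lengths = avg,
                 len_short = check_count(len_short, "len_short"),
                 len_long = check_count(len_long, "len_long")),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set:", length(x$profiles), "profiles,",
      sprintf("[%d bp]/[%d bp] anchors\n", x$len_long, x$len_short))
  tab <- data.frame(name = vapply(x$profiles, `[[`, character(1), "name"),
                    avg_length_bp = x$average_lengths,
                    anchor_ratio = round(x$anchor_ratios, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read a reference set from a manifest
#'
#' The manifest is a TSV with columns `name`, `avg_length_bp` and
#' `distribution_path` (paths relative to the manifest's directory unless
#' absolute), each distribution in the dialect of [read_distribution()].
#'
#' @param manifest path to the manifest TSV.
#' @param ... passed to [reference_set()] (e.g. `len_short`, `len_long`).
#' @return A [reference_set()].
#' @export
read_reference_set <- function(manifest, ...) {
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "avg_length_bp", "distribution_path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  profiles <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$distribution_path[i]
    if (!file.exists(p)) p <- file.path(base, tab$distribution_path[i])
    reference_profile(tab$name[i], read_distribution(p), tab$avg_length_bp[i])
  })
  reference_set(profiles, ...)
}

#' Interpolation bracket
#'
#' A pair of anchor points (x1, y1), (x2, y2) and the line through them:
#' slope m = (y2 - y1)/(x2 - x1), intercept y0 = y1 - m * x1. Degenerate
#' brackets (x1 == x2) carry a single anchor value returned directly.
#'
#' @param x1,x2 anchor ratios, `x1 <= x2`.
#' @param y1,y2 anchor response values.
#' @return An object of class `interpolation_bracket`.
#' @export
interpolation_bracket <- function(x1, x2, y1, y2) {
  if (x1 > x2) stop("`x1` must be <= `x2`")
  degenerate <- x1 == x2
  slope <- if (degenerate) NA_real_ else (y2 - y1) / (x2 - x1)
  intercept <- if (degenerate) NA_real_ else y1 - slope * x1
  structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2,
                 slope = slope, intercept = intercept,
                 degenerate = degenerate),
            class = "interpolation_bracket")
}

#' Evaluate an interpolation bracket
#'
#' Evaluates the bracket's line at `x`. With `printed_rounding = TRUE`, the
#' slope and intercept are rounded to 3 decimal places before evaluation
#' (the convention used when quoting the interpolation chain at 3 decimals);
#' the evaluated ratio itself is never rounded.
#'
#' @param bracket an [interpolation_bracket()].
#' @param x value (measured ratio) to evaluate at.
#' @param printed_rounding round slope and intercept to 3 decimals first?
#' @return Interpolated response value.
#' @export
interpolate_bracket <- function(bracket, x, printed_rounding = FALSE) {
  stopifnot(inherits(bracket, "interpolation_bracket"))
  if (bracket$degenerate) return(bracket$y1)
  m <- bracket$slope; y0 <- bracket$intercept
  if (printed_rounding) {
    m <- round(m, 3)
    y0 <- round(bracket$y1 - m * bracket$x1, 3)
  }
  m * x + y0
}

# Locate the anchor pair a measured ratio falls between. Returns indices
# i1 <= i2 into the reference set (i1 == i2 for an exact anchor hit) plus a
# clamped flag.
locate_bracket <- function(refset, ratio, clamp = FALSE) {
  stopifnot(inherits(refset, "reference_set"))
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio))
    stop("`ratio` must be a single finite number")
  if (ratio > 1)
    stop("measured [long]/[short] ratio ", format(ratio), " exceeds 1, ",
         "which the fragmentation model cannot produce; check for copy ",
         "number aberration or measurement error")
  x <- refset$anchor_ratios
  hit <- which(abs(x - ratio) < 1e-12)
  if (length(hit))
    return(list(i1 = hit[1L], i2 = hit[1L], clamped = FALSE))
  if (ratio < x[1L] || ratio > x[length(x)]) {
    if (!clamp)
      stop("measured ratio ", format(ratio), " is outside the reference ",
           "anchor range [", format(x[1L]), ", ", format(x[length(x)]),
           "]; supply references spanning the sample or use clamp = TRUE")
    i <- if (ratio < x[1L]) c(1L, 2L) else c(length(x) - 1L, length(x))
    warning("measured ratio outside anchor range; clamped to the terminal ",
            "bracket")
    return(list(i1 = i[1L], i2 = i[2L], clamped = TRUE))
  }
  i2 <- findInterval(ratio, x, rightmost.closed = TRUE) + 1L
  list(i1 = i2 - 1L, i2 = i2, clamped = FALSE)
}

#' Find the anchor bracket for a measured ratio
#'
#' Returns the adjacent pair of reference anchors whose [long]/[short]
#' ratios bracket the measured ratio, with the supplied response values
#' attached. A ratio equal to an anchor yields a degenerate bracket.
#'
#' @param refset a [reference_set()].
#' @param ratio measured [long]/[short] ratio.
#' @param response per-profile response values (`y`), aligned with
#'   `refset$profiles`; defaults to the profiles' average lengths.
#' @param clamp if `TRUE`, ratios outside the anchor range use the terminal
#'   bracket with a warning instead of an error.
#' @return An [interpolation_bracket()].
#' @export
bracket <- function(refset, ratio, response = refset$average_lengths,
                    clamp = FALSE) {
  loc <- locate_bracket(refset, ratio, clamp)
  x <- refset$anchor_ratios
  interpolation_bracket(x[loc$i1], x[loc$i2],
                        response[loc$i1], response[loc$i2])
}

# Shared interpolation driver: response_fun(profile) gives the y value for
# one reference profile; only the bracketing pair is evaluated.
interpolate_response <- function(m, refset, response_fun, clamp = FALSE,
                                 printed_rounding = FALSE) {
  stopifnot(inherits(m, "assay_measurement"),
            inherits(refset, "reference_set"))
  if (m$len_short != refset$len_short || m$len_long != refset$len_long)
    stop("measurement amplicon lengths (", m$len_short, "/", m$len_long,
         ") do not match the reference set anchors (", refset$len_short,
         "/", refset$len_long, ")")
  loc <- locate_bracket(refset, m$measured_ratio, clamp)
  x <- refset$anchor_ratios
  y1 <- response_fun(refset$profiles[[loc$i1]])
  y2 <- if (loc$i2 == loc$i1) y1 else response_fun(refset$profiles[[loc$i2]])
  br <- interpolation_bracket(x[loc$i1], x[loc$i2], y1, y2)
  interpolate_bracket(br, m$measured_ratio, printed_rounding)
}

#' Estimate intact copies of a region of any length
#'
#' The Fragment Calculator estimate: for each reference profile bracketing
#' the measured [long]/[short] ratio, compute the [short]/[r] ratio from its
#' distribution, interpolate that ratio linearly at the measured ratio, and
#' divide the measured short-amplicon concentration by it.
#'
#' @param m an [assay_measurement()].
#' @param refset a [reference_set()] with matching amplicon lengths.
#' @param region target region length r, bp (vectorised).
#' @param clamp allow ratios outside the anchor range (terminal bracket,
#'   with a warning)?
#' @param printed_rounding round slope and intercept to 3 decimals
#'   (see [interpolate_bracket()])?
#' @return Estimated intact copies/ul of the region (exact reals).
#' @examples
#' d1 <- synth_distribution("unimodal", mode = 200, seed = 1)
#' d2 <- synth_distribution("unimodal", mode = 300, seed = 2)
#' refs <- reference_set(list(
#'   reference_profile("a", d1, average_fragment_length(d1)),
#'   reference_profile("b", d2, average_fragment_length(d2))))
#' m <- assay_measurement(c_short = 1000, c_long = 700)
#' estimate_region_copies(m, refs, region = 50)
#' @export
estimate_region_copies <- function(m, refset, region, clamp = FALSE,
                                   printed_rounding = FALSE) {
  region <- check_count(region, "region")
  vapply(region, function(r) {
    ratio <- interpolate_response(
      m, refset, function(p) intact_ratio(p$distribution, m$len_short, r),
      clamp = clamp, printed_rounding = printed_rounding)
    if (!is.finite(ratio) || ratio <= 0)
      stop("interpolated [", m$len_short, " bp]/[", r,
           " bp] ratio is not positive; cannot estimate copies")
    m$c_short / ratio
  }, numeric(1))
}

#' Estimate total genome copies
#'
#' Genome copies (intact plus broken genome equivalents) are the intact
#' copies of a 1 bp region: every base survives fragmentation, so dividing
#' the short-amplicon concentration by the interpolated [short]/[1 bp]
#' ratio recovers the pre-fragmentation copy number.
#'
#' @inheritParams estimate_region_copies
#' @return Estimated genome copies/ul.
#' @export
estimate_genome_copies <- function(m, refset, clamp = FALSE,
                                   printed_rounding = FALSE) {
  estimate_region_copies(m, refset, region = 1L, clamp = clamp,
                         printed_rounding = printed_rounding)
}

#' Estimate average fragment length
#'
#' Interpolates the reference profiles' average fragment lengths against
#' their anchor ratios at the measured [long]/[short] ratio.
#'
#' @inheritParams estimate_region_copies
#' @return Estimated average fragment length, bp.
#' @export
estimate_average_length <- function(m, refset, clamp = FALSE,
                                    printed_rounding = FALSE) {
  interpolate_response(m, refset, function(p) p$average_length,
                       clamp = clamp, printed_rounding = printed_rounding)
}

#' Fit the Fragment Calculator to an assay measurement
#'
#' The main entry point: given measured short- and long-amplicon
#' concentrations and a set of reference fragment-size profiles, estimates
#' the sample's average fragment length and total genome copies, and returns
#' a fitted object from which intact copies at any region length can be
#' predicted.
#'
#' @param c_short copies/ul at the short amplicon.
#' @param c_long copies/ul at the long amplicon.
#' @param references a [reference_set()].
#' @param len_short,len_long amplicon lengths, bp (defaults 125/175); must
#'   match the reference set.
#' @param clamp allow measured ratios outside the anchor range (clamped to
#'   the terminal bracket, with a warning)?
#' @return An object of class `frag_fit` with components `measurement`,
#'   `references`, `genome_copies`, `average_length` and `bracket_index`.
#'   Methods: [print.frag_fit()], [summary.frag_fit()], [coef.frag_fit()],
#'   [predict.frag_fit()], [plot.frag_fit()].
#' @examples
#' d1 <- synth_distribution("unimodal", mode = 200, seed = 1)
#' d2 <- synth_distribution("unimodal", mode = 300, seed = 2)
#' refs <- reference_set(list(
#'   reference_profile("a", d1, average_fragment_length(d1)),
#'   reference_profile("b", d2, average_fragment_length(d2))))
#' fit <- fragment_calculator(1000, 700, refs)
#' fit
#' predict(fit, region = c(50, 125, 200))
#' @export
fragment_calculator <- function(c_short, c_long, references,
                                len_short = 125, len_long = 175,
                                clamp = FALSE) {
  m <- assay_measurement(c_short, c_long, len_short, len_long)
  loc <- locate_bracket(references, m$measured_ratio, clamp)
  structure(list(
    measurement = m,
    references = references,
    clamp = clamp,
    bracket_index = c(loc$i1, loc$i2),
    clamped = loc$clamped,
    genome_copies = estimate_genome_copies(m, references, clamp = clamp),
    average_length = estimate_average_length(m, references, clamp = clamp)),
    class = "frag_fit")
}

#' @describeIn fragment_calculator Print a concise fit report.
#' @param x,object a `frag_fit` object.
#' @param ... unused.
#' @export
print.frag_fit <- function(x, ...) {
  m <- x$measurement
  cat("Fragment Calculator fit\n")
  cat(sprintf("  measured: [%d bp] = %g, [%d bp] = %g copies/ul (ratio %.4g)\n",
              m$len_short, m$c_short, m$len_long, m$c_long, m$measured_ratio))
  nm <- vapply(x$references$profiles, `[[`, character(1), "name")
  cat("  bracket: ", nm[x$bracket_index[1L]], " .. ",
      nm[x$bracket_index[2L]],
      if (x$clamped) "  (clamped)" else "", "\n", sep = "")
  cat(sprintf("  genome copies:   %s copies/ul\n",
              format(signif(x$genome_copies, 3), big.mark = ",")))
  cat(sprintf("  average length:  %.1f bp\n", x$average_length))
  invisible(x)
}

#' @describeIn fragment_calculator Fit summary with per-anchor detail.
#' @export
summary.frag_fit <- function(object, ...) {
  refs <- object$references
  tab <- data.frame(
    name = vapply(refs$profiles, `[[`, character(1), "name"),
    avg_length_bp = refs$average_lengths,
    anchor_ratio = refs$anchor_ratios)
  structure(list(fit = object, anchors = tab), class = "summary.frag_fit")
}

#' @export
print.summary.frag_fit <- function(x, ...) {
  print(x$fit)
  cat("\nReference anchors:\n")
  tab <- x$anchors
  tab$anchor_ratio <- round(tab$anchor_ratio, 4)
  in_br <- seq_len(nrow(tab)) %in% x$fit$bracket_index
  tab$bracket <- ifelse(in_br, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn fragment_calculator Estimates as a named vector:
#'   `genome_copies`, `average_length`, `measured_ratio`.
#' @export
coef.frag_fit <- function(object, ...) {
  c(genome_copies = object$genome_copies,
    average_length = object$average_length,
    measured_ratio = object$measurement$measured_ratio)
}

#' @describeIn fragment_calculator Predict intact copies/ul at region
#'   lengths `region` (bp). Regions longer than the long amplicon are
#'   model-space extrapolations and are flagged with an `"extrapolated"`
#'   attribute.
#' @param region region length(s) in bp.
#' @export
predict.frag_fit <- function(object, region, ...) {
  out <- estimate_region_copies(object$measurement, object$references,
                                region, clamp = object$clamp)
  if (any(region > object$measurement$len_long))
    attr(out, "extrapolated") <- region > object$measurement$len_long
  out
}

#' @describeIn fragment_calculator Plot intact copies against region length
#'   with the measured amplicon pair marked.
#' @param to largest region length to plot, bp.
#' @export
plot.frag_fit <- function(x, to = 2 * x$measurement$len_long, ...) {
  r <- seq.int(1L, to)
  cp <- predict(x, r)
  m <- x$measurement
  graphics::plot(r, cp, type = "l", xlab = "region length (bp)",
                 ylab = "intact copies/ul",
                 main = "Fragment Calculator: intact copies vs region length",
                 ...)
  graphics::points(c(m$len_short, m$len_long), c(m$c_short, m$c_long),
                   pch = 19)
  invisible(x)
}
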