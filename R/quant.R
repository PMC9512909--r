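#' Multiplex [long]/[short] fragmentation ratio
#'
#' Computes the differential amplicon-length ratio from a table of per-assay
#' measurements by dividing the mean copies of the long-amplicon assays by
#' the mean copies of the short-amplicon assays (e.g. the two 175 bp assays
#' over the two 125 bp assays of a quantification 4-plex).
#'
#' @param measurements data.frame with columns `amplicon_bp` and `copies`
#'   (one row per assay; additional columns ignored).
#' @param long_len,short_len amplicon lengths defining the two classes
#'   (defaults 175 and 125 bp).
#' @return The dimensionless ratio mean(long) / mean(short).
#' @examples
#' tab <- data.frame(amplicon_bp = c(175, 175, 125, 125),
#'                   copies = c(700, 710, 1000, 990))
#' plex_ratio(tab)
#' @export
plex_ratio <- function(measurements, long_len = 175, short_len = 125) {
  if (!all(c("amplicon_bp", "copies") %in% names(measurements)))
    stop("`measurements` needs columns amplicon_bp and copies")
  if (any(measurements$copies < 0)) stop("copies must be >= 0")
  lo <- measurements$copies[measurements$amplicon_bp == long_len]
  sh <- measurements$copies[measurements$amplicon_bp == short_len]
  if (!length(lo) || !length(sh))
    stop("need at least one assay at each of ", long_len, " and ",
         short_len, " bp")
  ms <- mean(sh)
  if (ms <= 0) stop("mean short-amplicon copies is zero; ratio undefined")
  mean(lo) / ms
}

#' Correct qPCR concentrations of bisulfite-converted DNA
#'
#' After bisulfite conversion only the sense strand of a cytosine-free
#' assay's template amplifies, so qPCR against a genomic standard curve
#' under-reports copies by a factor of 2. This applies the factor-2
#' correction. Do not apply it to ddPCR measurements: droplet counting is
#' absolute and needs no strand correction.
#'
#' @param c_qpcr measured copies/ul (vectorised, >= 0).
#' @return Corrected copies/ul (`2 * c_qpcr`).
#' @seealso [bisulfite_uncorrect()]
#' @export
bisulfite_correct <- function(c_qpcr) {
  if (any(c_qpcr < 0)) stop("concentration must be >= 0")
  2 * c_qpcr
}

#' Undo the bisulfite factor-2 correction
#'
#' @param c_corrected corrected copies/ul.
#' @return `c_corrected / 2`.
#' @export
bisulfite_uncorrect <- function(c_corrected) {
  if (any(c_corrected < 0)) stop("concentration must be >= 0")
  c_corrected / 2
}

#' Proportion of DNA recovered after conversion
#'
#' Divides a converted sample's concentration by the input concentration at
#' the matching dilution factor. Scale-invariant: multiplying both
#' concentrations by a constant leaves the recovery unchanged.
#'
#' @param c_converted converted-sample concentration, copies/ul.
#' @param c_input input (unconverted) concentration, copies/ul (> 0).
#' @param dilution dilution factor applied to the input before comparison
#'   (> 0; default 1).
#' @param percent return a percentage instead of a proportion?
#' @return Recovery as a proportion (or percentage).
#' @examples
#' recovery(90, 180)  # 0.5
#' @export
recovery <- function(c_converted, c_input, dilution = 1, percent = FALSE) {
  if (any(c_input <= 0)) stop("input concentration must be > 0")
  if (any(dilution <= 0)) stop("dilution factor must be > 0")
  out <- c_converted / (c_input / dilution)
  if (percent) 100 * out else out
}

#' Ratio to mean copies across assays at a locus
#'
#' Normalises each assay's measured concentration by the mean concentration
#' of all assays at the same locus, giving an assay/sample-mean ratio whose
#' average is exactly 1. Used to compare positional (nucleosome-protection)
#' effects across samples of differing total concentration.
#'
#' @param copies numeric vector of per-assay copies (>= 2 values), or a
#'   data.frame with columns `copies` and `locus`.
#' @param locus when `copies` is a data.frame, the locus to normalise
#'   within; `NULL` normalises every locus.
#' @return For a vector: the vector of ratios. For a data.frame: the input
#'   with a `ratio_to_mean` column appended.
#' @examples
#' ratio_to_mean(c(10, 20, 30))  # 0.5 1.0 1.5
#' @export
ratio_to_mean <- function(copies, locus = NULL) {
  if (is.data.frame(copies)) {
    if (!all(c("copies", "locus") %in% names(copies)))
      stop("data.frame input needs columns copies and locus")
    tab <- copies
    if (!is.null(locus)) tab <- tab[tab$locus == locus, , drop = FALSE]
    per_locus <- table(tab$locus)
    if (nrow(tab) == 0L || any(per_locus < 2L))
      stop("each locus needs >= 2 assays to normalise")
    tab$ratio_to_mean <- stats::ave(tab$copies, tab$locus,
                                    FUN = function(x) x / mean(x))
    if (any(!is.finite(tab$ratio_to_mean)))
      stop("zero mean copies at a locus; ratio undefined")
    return(tab)
  }
  if (length(copies) < 2L) stop("need >= 2 assays to normalise")
  m <- mean(copies)
  if (m <= 0) stop("zero mean copies; ratio undefined")
  copies / m
}
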