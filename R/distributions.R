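#' Construct a fragment-size distribution
#'
#' A fragment-size distribution records, for each fragment length in base
#' pairs, the mass concentration (pg/ul) of DNA present at that length. This
#' is the binned form of a microfluidic electrophoresis region table (e.g. an
#' Agilent Bioanalyzer export) and is the input to all fragmentation-model
#' computations.
#'
#' Lengths are rounded to the nearest integer bp; rows that round to the same
#' length are mass-summed (coarse instrument exports can repeat a rounded
#' length). Bins are stored sorted ascending.
#'
#' @param lengths numeric vector of fragment lengths in bp (>= 1).
#' @param concentrations numeric vector of mass concentrations in pg/ul
#'   (>= 0), aligned with `lengths`.
#' @return An object of class `fragment_size_distribution` with fields
#'   `lengths` (integer, strictly increasing) and `concentrations` (double).
#' @seealso [read_distribution()], [average_fragment_length()],
#'   [intact_proportion_distribution()]
#' @examples
#' d <- fragment_size_distribution(c(150, 150, 300), c(2, 1, 3))
#' d$lengths         # 150 300
#' d$concentrations  # 3 3
#' @export
fragment_size_distribution <- function(lengths, concentrations) {
  if (length(lengths) != length(concentrations))
    stop("`lengths` and `concentrations` must have the same length")
  if (length(lengths) == 0L)
    stop("empty distribution: no bins")
  if (anyNA(lengths) || anyNA(concentrations))
    stop("NA values in distribution (row ",
         which(is.na(lengths) | is.na(concentrations))[1L], ")")
  if (any(concentrations < 0))
    stop("negative concentration at row ", which(concentrations < 0)[1L])
  L <- as.integer(round(lengths))
  if (any(L < 1L))
    stop("fragment length < 1 bp at row ", which(L < 1L)[1L])
  # merge duplicate (rounded) lengths by mass summation
  conc <- vapply(split(concentrations, L), sum, numeric(1))
  L <- as.integer(names(conc))
  o <- order(L)
  structure(list(lengths = L[o], concentrations = unname(conc)[o]),
            class = "fragment_size_distribution")
}

#' @export
print.fragment_size_distribution <- function(x, ...) {
  pos <- x$concentrations > 0
  cat("Fragment-size distribution:", length(x$lengths), "bins\n")
  if (any(pos)) {
    cat("  range (positive mass):", min(x$lengths[pos]), "-",
        max(x$lengths[pos]), "bp\n")
    cat("  total mass:", format(total_mass(x)), "pg/ul\n")
    cat("  number-average length:",
        format(round(average_fragment_length(x), 1)), "bp\n")
  } else {
    cat("  (all-zero mass)\n")
  }
  invisible(x)
}

#' Total mass of a distribution
#'
#' @param d a [fragment_size_distribution()].
#' @return Total mass concentration (pg/ul), the sum over all bins.
#' @export
total_mass <- function(d) {
  stopifnot(inherits(d, "fragment_size_distribution"))
  sum(d$concentrations)
}

#' Read a fragment-size distribution from a region-table export
#'
#' Reads a delimited text file with a header, as exported from an
#' electrophoresis region table, and returns a validated distribution.
#' Rows may be unsorted; duplicate lengths are mass-summed and non-integer
#' lengths rounded to the nearest bp.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param length_col name of the fragment-length column (bp). Default
#'   `"length_bp"`.
#' @param conc_col name of the concentration column (pg/ul). Default
#'   `"conc_pg_ul"`.
#' @param sep field separator; `NULL` (default) guesses `","` vs tab from the
#'   header line.
#' @return A [fragment_size_distribution()].
#' @export
read_distribution <- function(path, length_col = "length_bp",
                              conc_col = "conc_pg_ul", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty file: ", path)
  for (col in c(length_col, conc_col))
    if (!col %in% names(tab))
      stop("missing column '", col, "' in ", path,
           " (found: ", paste(names(tab), collapse = ", "), ")")
  fragment_size_distribution(tab[[length_col]], tab[[conc_col]])
}

#' Write a fragment-size distribution
#'
#' Writes the same dialect [read_distribution()] reads. With
#' `unit_bins = TRUE` the distribution is resampled to one bin per bp first.
#'
#' @param d a [fragment_size_distribution()].
#' @param path output file path.
#' @param unit_bins resample to unit (1 bp) bins before writing?
#' @param length_col,conc_col output column names.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_distribution <- function(d, path, unit_bins = FALSE,
                               length_col = "length_bp",
                               conc_col = "conc_pg_ul", sep = ",") {
  stopifnot(inherits(d, "fragment_size_distribution"))
  if (unit_bins) d <- resample_to_unit_bins(d)
  tab <- data.frame(d$lengths, d$concentrations)
  names(tab) <- c(length_col, conc_col)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a coarse distribution to 1 bp bins
#'
#' Region-table exports often carry one row per instrument time-window, i.e.
#' coarse, unevenly spaced bins. This redistributes the mass onto one bin per
#' integer bp across the occupied range by linear interpolation of the mass
#' density, then renormalises so that total mass is exactly conserved.
#'
#' Already-unit-binned input is returned unchanged, as is a single-bin input.
#'
#' @param d a [fragment_size_distribution()].
#' @return A [fragment_size_distribution()] with one bin per bp over
#'   the range of `d`; total mass conserved to < 1e-9 relative.
#' @export
resample_to_unit_bins <- function(d) {
  stopifnot(inherits(d, "fragment_size_distribution"))
  L <- d$lengths; C <- d$concentrations
  if (length(L) < 2L) return(d)
  if (all(diff(L) == 1L)) return(d)
  grid <- seq.int(L[1L], L[length(L)])
  dens <- stats::approx(L, C, xout = grid, method = "linear")$y
  tot <- sum(C)
  s <- sum(dens)
  if (s <= 0) stop("degenerate distribution: interpolated mass is zero")
  fragment_size_distribution(grid, dens * (tot / s))
}

#' Average fragment length of a distribution
#'
#' Computes the average fragment length. With number weighting (default) each
#' molecule counts once: the number of molecules at length f is proportional
#' to C_f / f, so the average is sum(C_f) / sum(C_f / f). With mass weighting
#' each picogram counts once: sum(f * C_f) / sum(C_f). The number average is
#' always <= the mass average, with equality only for a single-length sample.
#'
#' @param d a [fragment_size_distribution()] with positive total mass.
#' @param weighting `"number"` (default) or `"mass"`.
#' @return Average fragment length in bp.
#' @examples
#' d <- fragment_size_distribution(c(100, 300), c(1, 1))
#' average_fragment_length(d)           # 150
#' average_fragment_length(d, "mass")   # 200
#' @export
average_fragment_length <- function(d, weighting = c("number", "mass")) {
  stopifnot(inherits(d, "fragment_size_distribution"))
  weighting <- match.arg(weighting)
  tot <- total_mass(d)
  if (tot <= 0) stop("zero total mass: average length undefined")
  f <- as.numeric(d$lengths); C <- d$concentrations
  switch(weighting,
         number = tot / sum(C / f),
         mass = sum(f * C) / tot)
}
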