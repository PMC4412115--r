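#' Absorption spectra of cyanobacterial cultures
#'
#' A spectrum is a data frame with strictly increasing `wavelength_nm` and
#' nonnegative `absorbance`, typically recorded between 400 and 750 nm. The
#' two diagnostic wavelengths are 620 nm (phycocyanin, PC) and 680 nm
#' (the chlorophyll a peak, Chl): a drop in the PC/Chl ratio is the
#' bulk-culture signature of the ethanol-producer pigmentation phenotype.
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param absorbance nonnegative absorbances, same length.
#' @return `spectrum_table()` returns a validated `spectrum` data frame.
#' @export
spectrum_table <- function(wavelengths, absorbance) {
  if (length(wavelengths) != length(absorbance))
    stop("wavelengths and absorbance lengths differ")
  if (length(wavelengths) < 2L) stop("a spectrum needs at least two points")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(absorbance < 0)) stop("absorbance must be nonnegative")
  structure(data.frame(wavelength_nm = wavelengths, absorbance = absorbance),
            class = c("spectrum", "data.frame"))
}

#' @rdname spectrum_table
#' @param path two-column CSV (wavelength_nm, absorbance), with or without a
#'   header.
#' @export
read_spectrum <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  d <- utils::read.csv(path, header = header)
  spectrum_table(as.numeric(d[[1]]), as.numeric(d[[2]]))
}

#' Absorbance at a given wavelength
#'
#' Linear interpolation between the recorded points; reading at the fixed
#' wavelength (rather than peak-finding nearby) keeps values reproducible
#' across instruments.
#'
#' @param s a `spectrum` (see [spectrum_table()]).
#' @param nm wavelength in nm; must lie within the recorded range.
#' @export
absorbance_at <- function(s, nm) {
  stopifnot(inherits(s, "spectrum"))
  if (nm < min(s$wavelength_nm) || nm > max(s$wavelength_nm))
    stop(nm, " nm lies outside the recorded range (",
         min(s$wavelength_nm), "-", max(s$wavelength_nm), " nm)")
  approx(s$wavelength_nm, s$absorbance, xout = nm)$y
}

#' Normalize a spectrum at the chlorophyll peak
#'
#' Scales the whole spectrum so that the absorbance at 680 nm (the
#' chlorophyll a peak) equals 0.45, the convention that makes the
#' phycocyanin-to-chlorophyll balance of different cultures directly
#' comparable by eye. Idempotent, and commutes with [pc_chl_ratio()].
#'
#' @param s a `spectrum` covering 680 nm with A(680) > 0.
#' @return The rescaled `spectrum`.
#' @export
normalize_spectrum <- function(s) {
  a680 <- absorbance_at(s, 680)
  if (a680 <= 0) stop("absorbance at 680 nm is ", a680, "; cannot normalize")
  # dividing first makes the reading at 680 nm exactly 0.45 when 680 nm is a
  # recorded point (a/a == 1 in floating point)
  spectrum_table(s$wavelength_nm, s$absorbance / a680 * 0.45)
}

#' Phycocyanin / chlorophyll ratio
#'
#' `A(620) / A(680)`, by linear interpolation at the exact wavelengths.
#' Scale-invariant: identical before and after [normalize_spectrum()].
#'
#' @param s a `spectrum` covering 620 and 680 nm.
#' @export
pc_chl_ratio <- function(s) {
  a680 <- absorbance_at(s, 680)
  if (a680 <= 0) stop("absorbance at 680 nm is ", a680, "; ratio undefined")
  absorbance_at(s, 620) / a680
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Absorption spectrum:", nrow(x), "points, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), "nm\n")
  ok <- min(x$wavelength_nm) <= 620 && max(x$wavelength_nm) >= 680
  if (ok) cat(sprintf("  PC/Chl ratio (620/680 nm): %.3f\n", pc_chl_ratio(x)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot(x$wavelength_nm, x$absorbance, type = "l", xlab = "wavelength [nm]",
       ylab = "absorbance [rel.]", ...)
  abline(v = c(620, 680), lty = 3, col = c("steelblue", "darkgreen"))
  invisible(x)
}
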