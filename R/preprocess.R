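#' Flat-field illumination correction
#'
#' Divides each channel of a micrograph by a blank (no-sample) image of the
#' same session and rescales by the blank channel's mean intensity, the
#' ImageJ Calculator Plus "Divide" convention: uneven illumination cancels
#' while overall brightness stays comparable across sessions. The blank is
#' median-smoothed (5 x 5 by default) before division so its shot noise is not
#' amplified into the corrected image. Arithmetic is floating point; the
#' result is clipped to \[0, 255\] and, by default, rounded half-up to 8-bit.
#'
#' @param image `H x W x 3` numeric array in \[0, 255\].
#' @param blank blank-field image of identical dimensions.
#' @param smooth_radius radius of the median filter applied to the blank
#'   (2 gives a 5 x 5 kernel); `0` disables smoothing.
#' @param round8 quantize the output to integer 8-bit levels (default `TRUE`).
#' @return Corrected image, same dimensions, values in \[0, 255\].
#' @export
correct_illumination <- function(image, blank, smooth_radius = 2L, round8 = TRUE) {
  image <- as_rgb_image(image); blank <- as_rgb_image(blank)
  if (!identical(dim(image), dim(blank)))
    stop("image (", paste(dim(image)[1:2], collapse = "x"),
         ") and blank (", paste(dim(blank)[1:2], collapse = "x"),
         ") dimensions differ")
  out <- image
  chn <- c("red", "green", "blue")
  for (ch in 1:3) {
    b <- blank[, , ch]
    if (smooth_radius > 0)
      b <- smooth_channel(b, smooth_radius)
    if (min(b) <= 0) {
      p <- which(b <= 0, arr.ind = TRUE)[1, ]
      stop("blank ", chn[ch], " channel is ", signif(min(b), 3), " at pixel (row ",
           p[1], ", col ", p[2], ") after smoothing; cannot divide")
    }
    out[, , ch] <- image[, , ch] * (mean(b) / b)
  }
  out <- clip255(out)
  if (round8) out <- floor(out + 0.5)
  out
}

smooth_channel <- function(channel, radius) {
  medianFilter(channel / 255, radius) * 255
}

#' Median-smooth a blank image once for a whole batch
#'
#' [correct_illumination()] median-smooths the blank on every call; when many
#' micrographs share one blank it is cheaper to smooth it once and correct
#' with `smooth_radius = 0`.
#'
#' @inheritParams correct_illumination
#' @return The smoothed blank.
#' @export
smooth_blank <- function(blank, smooth_radius = 2L) {
  blank <- as_rgb_image(blank)
  if (smooth_radius > 0)
    for (ch in 1:3) blank[, , ch] <- smooth_channel(blank[, , ch], smooth_radius)
  clip255(blank)
}
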