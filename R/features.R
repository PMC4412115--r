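#' Per-particle color features: normalized hue histogram + mean brightness
#'
#' For every member pixel of a particle, hue and value are computed with the
#' standard hexcone RGB-to-HSV transform (hue in \[0, 1): red near 0, yellow
#' near 1/6, green near 1/3; value = max channel / 255). Hue is binned into
#' `bins` equal-width bins and the histogram normalized to sum 1; the mean of
#' value over the particle is appended as one extra feature
#' (`brightness`), giving feature vectors of length `bins + 1`. Achromatic
#' pixels (max = min, hue undefined) are assigned hue 0 by convention.
#' Features are extracted from the same illumination-corrected image that was
#' segmented.
#'
#' @param image illumination-corrected `H x W x 3` array in \[0, 255\].
#' @param mask label matrix from [segment_cells()] (`$mask`).
#' @param bins number of hue bins (default 32).
#' @return `particle_features()`: numeric matrix, one row per particle label
#'   (rows named by label), columns `b0..b{bins-1}` and `brightness`, with a
#'   `fingerprint` attribute recording the feature configuration.
#' @export
particle_features <- function(image, mask, bins = 32L) {
  image <- as_rgb_image(image)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("mask and image dimensions differ")
  n <- max(mask)
  fp <- feature_fingerprint(bins)
  out <- matrix(0, n, bins + 1L,
                dimnames = list(seq_len(n),
                                c(paste0("b", seq_len(bins) - 1L), "brightness")))
  if (n == 0L) { attr(out, "fingerprint") <- fp; return(out) }
  idx <- which(mask > 0L)
  labs <- mask[idx]
  plane <- prod(dim(mask))
  hsv <- rgb2hsv(image[idx], image[idx + plane], image[idx + 2L * plane],
                 maxColorValue = 255)
  bin <- pmin(floor(hsv[1L, ] * bins), bins - 1L) + 1L
  g <- factor(labs, levels = seq_len(n))
  counts <- table(g, factor(bin, levels = seq_len(bins)))
  area <- tabulate(labs, n)
  out[, seq_len(bins)] <- as.matrix(counts) / area
  out[, bins + 1L] <- as.numeric(tapply(hsv[3L, ], g, mean))
  attr(out, "fingerprint") <- fp
  out
}

feature_fingerprint <- function(bins) {
  list(hue_bins = as.integer(bins), brightness = TRUE, achromatic_hue = 0)
}

#' @rdname particle_features
#' @param particle_id label of one particle present in `mask`.
#' @return `extract_features()`: the feature vector of one particle.
#' @export
extract_features <- function(image, mask, particle_id, bins = 32L) {
  if (length(particle_id) != 1L || !any(mask == particle_id) || particle_id < 1L)
    stop("particle ", particle_id, " not present in mask")
  sub <- mask == particle_id
  f <- particle_features(image, sub * 1L, bins = bins)
  structure(f[1L, ], fingerprint = attr(f, "fingerprint"))
}

#' Write a feature matrix as CSV
#'
#' Columns: `particle_id`, the hue bins `b0..`, `brightness`, and optionally
#' the true class.
#'
#' @param features matrix from [particle_features()].
#' @param path output CSV path.
#' @param true_class optional character vector of known labels.
#' @export
write_features <- function(features, path, true_class = NULL) {
  df <- data.frame(particle_id = seq_len(nrow(features)), features,
                   check.names = FALSE)
  if (!is.null(true_class)) df$true_class <- true_class
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
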