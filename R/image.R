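#' RGB image containers and file I/O
#'
#' Micrographs are plain numeric arrays of dimension `H x W x 3` (rows,
#' columns, channels red/green/blue) with 8-bit range: values in \[0, 255\].
#' In memory values may be fractional (generator output, corrected images
#' before the final rounding); they are quantized to integers when written to
#' disk.
#'
#' @param pixels numeric array `H x W x 3` with values in \[0, 255\].
#' @return `as_rgb_image()` returns the validated array.
#' @export
as_rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("an RGB image must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image dimensions must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  pixels
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' @rdname as_rgb_image
#' @param path file path; format chosen by extension (`.tif`/`.tiff` or `.png`).
#' @export
read_image <- function(path) {
  ext <- tolower(file_ext(path))
  a <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  as_rgb_image(round(a * 255))
}

#' @rdname as_rgb_image
#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @export
write_image <- function(image, path) {
  image <- as_rgb_image(image)
  a <- round(image) / 255
  ext <- tolower(file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    png = png::writePNG(a, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a label mask as a 16-bit single-channel TIFF
#'
#' @param mask integer matrix of particle labels (0 = background).
#' @param path output path (`.tif`/`.tiff`).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
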