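#' Phenotype rendering specification
#'
#' Channel statistics and size range used by [render_scene()] to draw cells of
#' one phenotype class. The defaults of [default_phenotypes()] encode the three
#' fluorescence phenotypes seen under a chlorophyll/phycocyanin filter set:
#' wild-type cells fluoresce red (strong chlorophyll signal), ethanol producers
#' appear orange and less bright because phycocyanin down-regulation brings the
#' red and green signals to roughly equal intensity, and dead cells show only
#' an unspecific green fluorescence.
#'
#' @param class_label one of `cell_classes()`.
#' @param red_mean,green_mean,blue_mean mean channel intensities (0-255) inside
#'   a cell.
#' @param channel_sd per-pixel Gaussian spread of the channel intensities.
#' @param radius_range interval (pixels) from which cell radii are drawn
#'   uniformly; cells are rendered as axis-aligned ellipses with the two radii
#'   drawn independently.
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(class_label, red_mean, green_mean, blue_mean,
                           channel_sd = 15, radius_range = c(3, 8)) {
  class_label <- match.arg(class_label, cell_classes())
  means <- c(red_mean, green_mean, blue_mean)
  if (anyNA(means) || min(means) < 0 || max(means) > 255)
    stop("channel means must lie in [0, 255]")
  if (class_label == "WT_RED" && red_mean <= green_mean)
    stop("WT_RED requires red_mean above green_mean")
  if (class_label == "DEAD_GREEN" && green_mean <= red_mean)
    stop("DEAD_GREEN requires green_mean above red_mean")
  if (channel_sd < 0) stop("channel_sd must be nonnegative")
  if (length(radius_range) != 2L || radius_range[1] <= 0 ||
      radius_range[2] < radius_range[1])
    stop("radius_range must be a positive increasing interval")
  structure(list(class_label = class_label, red_mean = red_mean,
                 green_mean = green_mean, blue_mean = blue_mean,
                 channel_sd = channel_sd, radius_range = radius_range),
            class = "phenotype_spec")
}

#' @rdname phenotype_spec
#' @export
default_phenotypes <- function() {
  list(
    WT_RED          = phenotype_spec("WT_RED",          200,  40, 10),
    PRODUCER_ORANGE = phenotype_spec("PRODUCER_ORANGE", 150, 130, 10),
    DEAD_GREEN      = phenotype_spec("DEAD_GREEN",       30, 180, 20)
  )
}

#' Synthetic scene configuration
#'
#' Describes one synthetic micrograph: geometry, cell count, class mixture,
#' illumination inhomogeneity and noise. `class_fractions` follows the order of
#' [cell_classes()].
#'
#' @param image_height,image_width image size in pixels.
#' @param n_cells number of cells to place.
#' @param class_fractions nonnegative 3-vector summing to 1: expected fractions
#'   of WT_RED, PRODUCER_ORANGE and DEAD_GREEN cells.
#' @param vignette_strength strength `s` of the radial multiplicative
#'   illumination falloff: the raw field is `1 - s * (d/dmax)^2` (distance `d`
#'   from the image center, `dmax` to the farthest corner), then rescaled to
#'   unit mean so that corrected and uncorrected scenes share a brightness
#'   scale. `0` means flat illumination.
#' @param noise_sd standard deviation of additive Gaussian read-out noise,
#'   applied per pixel and channel after the illumination field.
#' @param background_level mean background intensity (all channels).
#' @param seed integer seed; a fixed seed makes scene and blank byte-identical
#'   across calls.
#' @param allow_border_cells if `TRUE`, cell centers may fall anywhere and
#'   cells may overlap the image edge; if `FALSE` (default) whole cells are
#'   kept at least one pixel away from the border.
#' @param min_center_distance minimum Euclidean distance between cell centers
#'   (pixels); the default (19) keeps default-size cells from touching.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_height = 768, image_width = 1024, n_cells = 50,
                         class_fractions = c(1, 0, 0), vignette_strength = 0.25,
                         noise_sd = 5, background_level = 10, seed = 1L,
                         allow_border_cells = FALSE, min_center_distance = 19) {
  if (image_height < 1 || image_width < 1) stop("image dimensions must be positive")
  if (n_cells < 0) stop("n_cells must be nonnegative")
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be three nonnegative values summing to 1")
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("vignette_strength must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_cells = as.integer(n_cells),
                 class_fractions = as.numeric(class_fractions),
                 vignette_strength = vignette_strength,
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed),
                 allow_border_cells = isTRUE(allow_border_cells),
                 min_center_distance = min_center_distance),
            class = "scene_config")
}

#' Radial vignette illumination field
#'
#' Smooth multiplicative field emulating uneven microscope illumination:
#' quadratic falloff with distance from the image center, rescaled to unit
#' mean. The center-to-corner ratio is `1 / (1 - strength)`.
#'
#' @param height,width field size in pixels.
#' @param strength falloff strength in \[0, 1).
#' @return `height x width` matrix of positive factors with mean 1.
#' @export
illumination_field <- function(height, width, strength) {
  if (strength == 0) return(matrix(1, height, width))
  cr <- (height + 1) / 2; cc <- (width + 1) / 2
  d2 <- outer((seq_len(height) - cr)^2, (seq_len(width) - cc)^2, "+")
  raw <- 1 - strength * d2 / max(d2)
  raw / mean(raw)
}

# class labels drawn iid from the mixture; kept separate so the sampling
# distribution can be tested at large n without rendering
sample_classes <- function(n, fractions) {
  if (n == 0L) return(integer(0))
  sample.int(3L, n, replace = TRUE, prob = fractions)
}

place_centers <- function(config, ry, rx, max_attempts = 200L) {
  n <- config$n_cells
  H <- config$image_height; W <- config$image_width
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    if (config$allow_border_cells) {
      lo_r <- 1; hi_r <- H; lo_c <- 1; hi_c <- W
    } else {
      lo_r <- ceiling(ry[i]) + 2; hi_r <- H - ceiling(ry[i]) - 1
      lo_c <- ceiling(rx[i]) + 2; hi_c <- W - ceiling(rx[i]) - 1
      if (lo_r > hi_r || lo_c > hi_c)
        stop("image too small for an interior cell of radius ", max(ry[i], rx[i]))
    }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- runif(1, lo_r, hi_r); c <- runif(1, lo_c, hi_c)
      if (i == 1L || min((rows[seq_len(i - 1L)] - r)^2 +
                         (cols[seq_len(i - 1L)] - c)^2) >=
            config$min_center_distance^2) {
        rows[i] <- r; cols[i] <- c; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n, " cells at min_center_distance ",
           config$min_center_distance, " after ", max_attempts,
           " attempts per cell; reduce n_cells or the distance")
  }
  cbind(row = rows, col = cols)
}

ellipse_pixels <- function(cr, cc, ry, rx, H, W) {
  r0 <- max(1L, floor(cr - ry)); r1 <- min(H, ceiling(cr + ry))
  c0 <- max(1L, floor(cc - rx)); c1 <- min(W, ceiling(cc + rx))
  rr <- r0:r1; cc2 <- c0:c1
  inside <- outer(((rr - cr) / ry)^2, ((cc2 - cc) / rx)^2, "+") <= 1
  idx <- which(inside)
  rows <- rr[(idx - 1L) %% length(rr) + 1L]
  cols <- cc2[(idx - 1L) %/% length(rr) + 1L]
  if (length(rows) == 0L) { rows <- round(cr); cols <- round(cc) }  # degenerate
  rows + (cols - 1L) * H
}

#' Render a synthetic micrograph with ground truth
#'
#' Places `n_cells` non-overlapping elliptical cells with class labels drawn
#' from `class_fractions`, fills each with its phenotype's channel means plus
#' per-pixel Gaussian spread, applies the multiplicative illumination field,
#' adds read-out noise and clips to \[0, 255\]. Ground truth (class, center,
#' radius, pre-noise pixel membership) is returned alongside the image, and a
#' matching blank-field image is rendered with [render_blank()].
#'
#' @param config a [scene_config()].
#' @param specs named list of [phenotype_spec()]s covering all three classes.
#' @return A `scene_truth` object: list with `image` and `blank` (`H x W x 3`
#'   arrays), `cells` (data frame: `cell_id`, `class`, `center_x`, `center_y`
#'   (0-based, x = column), `radius`, `area_px`), `pixels` (per-cell linear
#'   pixel indices), and the `config`/`specs` used.
#' @export
render_scene <- function(config, specs = default_phenotypes()) {
  stopifnot(inherits(config, "scene_config"))
  if (!all(cell_classes() %in% names(specs)))
    stop("specs must cover all three classes")
  H <- config$image_height; W <- config$image_width; n <- config$n_cells
  set.seed(config$seed)
  labels <- sample_classes(n, config$class_fractions)
  rr <- t(vapply(labels, function(l) {
    rng <- specs[[cell_classes()[l]]]$radius_range
    runif(2, rng[1], rng[2])
  }, numeric(2)))                                   # columns: ry, rx
  centers <- place_centers(config, rr[, 1], rr[, 2])
  img <- array(config$background_level, c(H, W, 3))
  plane <- H * W
  pixels <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[cell_classes()[labels[i]]]]
    idx <- ellipse_pixels(centers[i, 1], centers[i, 2], rr[i, 1], rr[i, 2], H, W)
    pixels[[i]] <- idx
    means <- c(sp$red_mean, sp$green_mean, sp$blue_mean)
    for (ch in 1:3)
      img[idx + (ch - 1L) * plane] <-
        means[ch] + rnorm(length(idx), 0, sp$channel_sd)
  }
  field <- illumination_field(H, W, config$vignette_strength)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * field
  if (config$noise_sd > 0)
    img <- img + rnorm(length(img), 0, config$noise_sd)
  img <- clip255(img)
  cells <- data.frame(
    cell_id = seq_len(n),
    class = if (n) cell_classes()[labels] else character(0),
    center_x = centers[, 2] - 1, center_y = centers[, 1] - 1,
    radius = if (n) rowMeans(rr) else numeric(0),
    area_px = vapply(pixels, length, integer(1)))
  structure(list(image = img, blank = render_blank(config), cells = cells,
                 pixels = pixels, config = config, specs = specs),
            class = "scene_truth")
}

#' Render the blank (no-sample) illumination reference
#'
#' The illumination field of `config` scaled to mid-gray (mean 128) with the
#' configured read-out noise and no cells: the image a microscopist records
#' "without sample" to flat-field later micrographs. The same `config` (seed,
#' field) yields the field used by [render_scene()], so correction is exact in
#' the noiseless limit.
#'
#' @inheritParams render_scene
#' @return `H x W x 3` numeric array.
#' @export
render_blank <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_height; W <- config$image_width
  set.seed((config$seed %% 2000000000L) + 7919L)
  field <- 128 * illumination_field(H, W, config$vignette_strength)
  img <- array(rep(field, 3L), c(H, W, 3))
  if (config$noise_sd > 0)
    img <- img + rnorm(length(img), 0, config$noise_sd)
  clip255(img)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("Synthetic micrograph:", x$config$image_width, "x", x$config$image_height,
      "px,", nrow(x$cells), "cells\n")
  if (nrow(x$cells)) print(table(factor(x$cells$class, cell_classes())))
  invisible(x)
}

#' Read a scene configuration (and optional phenotype overrides) from YAML
#'
#' The file holds a `scene:` mapping with [scene_config()] fields and an
#' optional `phenotypes:` mapping of class label to [phenotype_spec()] fields.
#'
#' @param path YAML file path.
#' @return list with elements `config` and `specs`.
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  config <- do.call(scene_config, y$scene %||% list())
  specs <- default_phenotypes()
  for (cl in names(y$phenotypes %||% list())) {
    args <- modifyList(unclass(specs[[cl]]), y$phenotypes[[cl]])
    args$radius_range <- as.numeric(args$radius_range)
    specs[[cl]] <- do.call(phenotype_spec, args)
  }
  list(config = config, specs = specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a rendered scene to disk
#'
#' Writes the scene image and blank as 8-bit RGB TIFFs and the ground-truth
#' table as CSV (`cell_id`, `class`, `center_x`, `center_y`, `radius`,
#' `area_px`; 0-based pixel coordinates, x = column).
#'
#' @param scene a `scene_truth` from [render_scene()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "scene_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".tif", "_blank.tif", "_truth.csv")))
  write_image(scene$image, paths[1])
  write_image(scene$blank, paths[2])
  write.csv(scene$cells, paths[3], row.names = FALSE)
  invisible(paths)
}
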