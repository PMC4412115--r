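#' Maximum-entropy (Kapur) threshold of an intensity histogram
#'
#' Picks the threshold `t` maximizing the sum of the Shannon entropies of the
#' class-conditional intensity distributions below and above `t`: background
#' comprises levels `<= t`, foreground levels `> t`. Candidate thresholds that
#' leave either class empty carry no valid split and are skipped (the ImageJ
#' MaxEntropy lineage), not scored as zero. Ties are broken by the smallest
#' `t`.
#'
#' @param counts 256 nonnegative bin counts for intensity levels 0-255.
#' @return Integer threshold in 0-254.
#' @export
kapur_threshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0))
    stop("counts must be 256 nonnegative values")
  total <- sum(counts)
  if (sum(counts > 0) < 2L)
    stop("histogram mass concentrated in ", sum(counts > 0),
         " bin(s); no valid split exists")
  p <- counts / total
  plogp <- ifelse(p > 0, p * log(p), 0)
  C <- cumsum(p)          # P(level <= t), index t + 1
  S <- cumsum(plogp)
  i <- 1:255              # candidate thresholds t = i - 1
  w0 <- C[i]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  h0 <- log(w0) - S[i] / w0
  h1 <- log(w1) - (S[256] - S[i]) / w1
  obj <- ifelse(valid, h0 + h1, -Inf)
  which.max(obj) - 1L     # which.max returns the first (smallest t) maximum
}

#' 256-bin intensity histogram of one channel
#'
#' @param channel numeric matrix with values in \[0, 255\]; fractional values
#'   are binned by rounding.
#' @return Integer vector of 256 counts (levels 0-255).
#' @export
channel_histogram <- function(channel) {
  tabulate(as.integer(round(channel)) + 1L, nbins = 256L)
}

label_components <- function(mask, connectivity = 8L) {
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Segment cells from a corrected micrograph
#'
#' Thresholds the red and green channels independently with
#' [kapur_threshold()] (chlorophyll autofluorescence marks live cells in red;
#' dead cells appear only in green), combines the two binary masks by
#' pixelwise union, labels connected components, and applies the two artifact
#' filters: particles smaller than `min_area` pixels and particles touching
#' the image edge are excluded. Surviving particles are relabeled 1..n.
#'
#' @param image illumination-corrected `H x W x 3` array in \[0, 255\].
#' @param min_area minimum particle area in pixels; areas `>= min_area`
#'   survive (default 10, i.e. "smaller than 10 pixels" is excluded).
#' @param exclude_border drop particles with any pixel on the first/last row
#'   or column (default `TRUE`).
#' @param connectivity 8 (particle-analyzer default) or 4.
#' @return A `cell_segmentation` object: list with `mask` (relabeled `H x W`
#'   integer matrix, 0 = background), `particles` (surviving particles: `id`,
#'   `area_px`, `centroid_row`, `centroid_col`, half-open `bbox_*` bounds,
#'   `touches_border`), `all_particles` (as registered, with
#'   `excluded_reason`), `thresholds` (red, green) and `exclusions` tallies
#'   (`size`, `border` counted per rule; `total` distinct particles removed).
#' @export
segment_cells <- function(image, min_area = 10L, exclude_border = TRUE,
                          connectivity = 8L) {
  image <- as_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  thr <- vapply(c(red = 1L, green = 2L), function(ch) {
    tryCatch(kapur_threshold(channel_histogram(image[, , ch])),
             error = function(e) stop("thresholding failed on the ",
                                      c("red", "green")[ch], " channel: ",
                                      conditionMessage(e), call. = FALSE))
  }, integer(1))
  mask <- round(image[, , 1]) > thr[["red"]] | round(image[, , 2]) > thr[["green"]]
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n_particles")
  if (n == 0L) {
    empty <- data.frame(id = integer(0), area_px = integer(0),
                        centroid_row = numeric(0), centroid_col = numeric(0),
                        bbox_row_min = integer(0), bbox_col_min = integer(0),
                        bbox_row_max = integer(0), bbox_col_max = integer(0),
                        touches_border = logical(0))
    return(structure(list(mask = lab, particles = empty,
                          all_particles = cbind(empty, excluded_reason = character(0)),
                          thresholds = thr,
                          exclusions = list(size = 0L, border = 0L, total = 0L),
                          connectivity = connectivity, min_area = min_area),
                     class = "cell_segmentation"))
  }
  idx <- which(mask)
  labs <- lab[idx]
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  g <- factor(labs, levels = seq_len(n))
  area <- tabulate(labs, n)
  stats <- data.frame(
    id = seq_len(n),
    area_px = area,
    centroid_row = as.numeric(tapply(rows, g, mean)),
    centroid_col = as.numeric(tapply(cols, g, mean)),
    bbox_row_min = as.integer(tapply(rows, g, min)),
    bbox_col_min = as.integer(tapply(cols, g, min)),
    bbox_row_max = as.integer(tapply(rows, g, max)) + 1L,  # half-open
    bbox_col_max = as.integer(tapply(cols, g, max)) + 1L,
    touches_border = as.logical(
      tapply(rows == 1L | rows == H | cols == 1L | cols == W, g, any)))
  small <- stats$area_px < min_area
  border <- exclude_border & stats$touches_border
  stats$excluded_reason <- ifelse(small & border, "size+border",
                           ifelse(small, "size",
                           ifelse(border, "border", "")))
  keep <- !small & !border
  newid <- integer(n); newid[keep] <- seq_len(sum(keep))
  relab <- lab
  relab[idx] <- newid[labs]
  attr(relab, "n_particles") <- sum(keep)
  surv <- stats[keep, setdiff(names(stats), "excluded_reason")]
  surv$id <- seq_len(sum(keep))
  rownames(surv) <- NULL
  structure(list(mask = relab, particles = surv, all_particles = stats,
                 thresholds = thr,
                 exclusions = list(size = sum(small), border = sum(border),
                                   total = sum(!keep)),
                 connectivity = connectivity, min_area = min_area),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("Cell segmentation: thresholds red >", x$thresholds[["red"]],
      ", green >", x$thresholds[["green"]], "\n")
  cat(nrow(x$all_particles), "particles registered;",
      x$exclusions$total, "excluded (", x$exclusions$size, "by size,",
      x$exclusions$border, "touching the border );",
      nrow(x$particles), "kept\n")
  invisible(x)
}

#' Write the registered-particle table as CSV
#'
#' One row per registered particle (before filtering), with an
#' `excluded_reason` column ("" for kept particles).
#'
#' @param seg a `cell_segmentation`.
#' @param path output CSV path.
#' @export
write_particles <- function(seg, path) {
  stopifnot(inherits(seg, "cell_segmentation"))
  write.csv(seg$all_particles, path, row.names = FALSE)
  invisible(path)
}
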