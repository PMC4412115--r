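derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2000000000)
}

#' Analyze one sample: a batch of micrographs sharing a blank image
#'
#' Each image is flat-field corrected ([correct_illumination()]), segmented
#' ([segment_cells()]), featurized ([particle_features()]) and classified with
#' the supplied network. Counts are aggregated across images; class fractions
#' are computed over all classified particles, and additionally over viable
#' (non-dead) particles, since culture mixtures are usually quoted as
#' wild-type vs producer among live cells.
#'
#' @param images list of `H x W x 3` arrays (or a single array).
#' @param blank blank-field image for the whole batch.
#' @param model a trained [phenonet()].
#' @param min_area,exclude_border,connectivity passed to [segment_cells()].
#' @param bins hue bins for [particle_features()]; defaults to the model's
#'   fingerprint.
#' @param min_cells_warning warn when fewer classified cells than this were
#'   monitored across the sample (protocols aim for 500-1000 cells).
#' @param smooth_radius median-filter radius applied once to the blank for the
#'   whole batch (see [smooth_blank()]).
#' @return A `sample_report`: counts (`n_images`, `n_particles_total`
#'   registered, `n_excluded_size`, `n_excluded_border`, `n_excluded` distinct,
#'   `class_counts`), `class_fractions` and `viable_fractions`, a `per_image`
#'   data frame, per-particle results (`particles`: image, id, class,
#'   activations) and any per-image `errors`.
#' @export
analyze_sample <- function(images, blank, model, min_area = 10L,
                           exclude_border = TRUE, connectivity = 8L,
                           bins = NULL, min_cells_warning = 500L,
                           smooth_radius = 2L) {
  if (is.array(images)) images <- list(images)
  if (length(images) < 1L) stop("at least one image is required")
  stopifnot(inherits(model, "phenonet"))
  blank <- smooth_blank(blank, smooth_radius)  # once for the whole batch
  if (is.null(bins))
    bins <- if (!is.null(model$fingerprint)) model$fingerprint$hue_bins else 32L
  classes <- cell_classes()
  per_image <- vector("list", length(images))
  particles <- vector("list", length(images))
  errors <- character(0)
  for (j in seq_along(images)) {
    res <- tryCatch({
      corr <- correct_illumination(images[[j]], blank, smooth_radius = 0L)
      seg <- segment_cells(corr, min_area = min_area,
                           exclude_border = exclude_border,
                           connectivity = connectivity)
      feats <- particle_features(corr, seg$mask, bins = bins)
      if (nrow(feats)) {
        act <- predict(model, feats, type = "activations")
        cls <- factor(classes[max.col(act, ties.method = "first")], classes)
      } else {
        act <- matrix(numeric(0), 0, 3, dimnames = list(NULL, classes))
        cls <- factor(character(0), classes)
      }
      list(seg = seg, cls = cls, act = act)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("image ", j, ": ", conditionMessage(res)))
      next
    }
    per_image[[j]] <- data.frame(
      image = j,
      n_registered = nrow(res$seg$all_particles),
      n_excluded_size = res$seg$exclusions$size,
      n_excluded_border = res$seg$exclusions$border,
      n_excluded = res$seg$exclusions$total,
      n_classified = length(res$cls),
      n_wt = sum(res$cls == "WT_RED"),
      n_producer = sum(res$cls == "PRODUCER_ORANGE"),
      n_dead = sum(res$cls == "DEAD_GREEN"))
    if (length(res$cls))
      particles[[j]] <- data.frame(image = j, particle_id = seq_along(res$cls),
                                   class = res$cls, res$act)
  }
  per_image <- do.call(rbind, per_image)
  if (is.null(per_image))
    stop("all images failed:\n", paste(errors, collapse = "\n"))
  particles <- do.call(rbind, particles)
  counts <- c(WT_RED = sum(per_image$n_wt),
              PRODUCER_ORANGE = sum(per_image$n_producer),
              DEAD_GREEN = sum(per_image$n_dead))
  n_classified <- sum(counts)
  fractions <- if (n_classified) counts / n_classified else counts * NA_real_
  n_viable <- counts[["WT_RED"]] + counts[["PRODUCER_ORANGE"]]
  viable <- if (n_viable) counts[1:2] / n_viable else counts[1:2] * NA_real_
  if (n_classified < min_cells_warning)
    warning("only ", n_classified, " cells monitored; protocols aim for ",
            min_cells_warning, "-1000 cells per sample", call. = FALSE)
  structure(list(n_images = length(images), n_images_ok = nrow(per_image),
                 n_particles_total = sum(per_image$n_registered),
                 n_excluded_size = sum(per_image$n_excluded_size),
                 n_excluded_border = sum(per_image$n_excluded_border),
                 n_excluded = sum(per_image$n_excluded),
                 class_counts = counts, class_fractions = fractions,
                 viable_fractions = viable, per_image = per_image,
                 particles = particles, errors = errors),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Sample report:", x$n_images_ok, "of", x$n_images, "image(s) analyzed\n")
  cat("  registered particles :", x$n_particles_total, "\n")
  cat("  excluded             :", x$n_excluded, "(", x$n_excluded_size,
      "by size,", x$n_excluded_border, "touching border )\n")
  n <- sum(x$class_counts)
  for (cl in names(x$class_counts))
    cat(sprintf("  %-16s: %5d (%5.1f%%)\n", cl, x$class_counts[[cl]],
                if (n) 100 * x$class_counts[[cl]] / n else NA_real_))
  if (length(x$errors)) cat("  errors:", length(x$errors), "image(s) failed\n")
  invisible(x)
}

#' Write a sample report to CSV
#'
#' Writes the per-image breakdown and, when present, the per-particle
#' classifications (image id, particle id, class, output activations).
#'
#' @param report a `sample_report`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_report <- function(report, dir, prefix = "sample") {
  stopifnot(inherits(report, "sample_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_image, file.path(dir, paste0(prefix, "_images.csv")),
            row.names = FALSE)
  if (!is.null(report$particles))
    write.csv(report$particles, file.path(dir, paste0(prefix, "_particles.csv")),
              row.names = FALSE)
  summary_df <- data.frame(
    n_images = report$n_images_ok, n_registered = report$n_particles_total,
    n_excluded_size = report$n_excluded_size,
    n_excluded_border = report$n_excluded_border,
    t(report$class_counts), t(100 * report$class_fractions))
  names(summary_df)[8:10] <- paste0("pct_", names(report$class_fractions))
  write.csv(summary_df, file.path(dir, paste0(prefix, "_summary.csv")),
            row.names = FALSE)
  invisible(dir)
}

#' Build a labeled synthetic training set
#'
#' Renders single-class synthetic scenes per phenotype, runs correction,
#' segmentation and feature extraction, and labels every surviving particle
#' with the scene's class — the in-silico analogue of preparing pure
#' wild-type, producer and dead-cell training samples under the microscope.
#'
#' @param n_per_class particles per class.
#' @param seed integer seed.
#' @param specs phenotype specifications (see [default_phenotypes()]).
#' @param bins hue bins for the features.
#' @param image_size height/width of the training scenes.
#' @param cells_per_scene cells rendered per scene.
#' @param ... further [scene_config()] fields (noise, vignette, ...).
#' @return list with `x` (feature matrix, `fingerprint` attribute set) and `y`
#'   (factor of classes).
#' @export
synthetic_training_set <- function(n_per_class = 100L, seed = 1L,
                                   specs = default_phenotypes(), bins = 32L,
                                   image_size = c(384L, 512L),
                                   cells_per_scene = 50L, ...) {
  xs <- list(); ys <- character(0)
  for (ci in seq_along(cell_classes())) {
    cl <- cell_classes()[ci]
    got <- 0L; iter <- 0L
    while (got < n_per_class) {
      iter <- iter + 1L
      if (iter > 50L) stop("failed to collect ", n_per_class, " particles for ", cl)
      cfg <- scene_config(image_height = image_size[1], image_width = image_size[2],
                          n_cells = cells_per_scene,
                          class_fractions = as.numeric(seq_len(3) == ci),
                          seed = derive_seed(seed, ci * 100L + iter), ...)
      sc <- render_scene(cfg, specs)
      corr <- correct_illumination(sc$image, sc$blank)
      seg <- segment_cells(corr)
      f <- particle_features(corr, seg$mask, bins = bins)
      if (nrow(f)) { xs[[length(xs) + 1L]] <- f; got <- got + nrow(f) }
    }
    ys <- c(ys, rep(cl, got))
  }
  x <- do.call(rbind, xs)
  y <- factor(ys, cell_classes())
  keep <- unlist(lapply(split(seq_along(y), y), function(i) i[seq_len(min(length(i), n_per_class))]))
  keep <- sort(keep)
  structure_x <- x[keep, , drop = FALSE]
  attr(structure_x, "fingerprint") <- feature_fingerprint(bins)
  list(x = structure_x, y = y[keep])
}

#' In-silico mixing experiment
#'
#' Reconstructs the validation protocol in which wild-type and
#' ethanol-producing cultures are mixed at known ratios and the recovered
#' wild-type percentage is compared with the truth: for each requested
#' wild-type fraction and replicate, synthetic micrographs are rendered,
#' analyzed with [analyze_sample()], and the estimated class fractions
#' tabulated against the generator's ground truth.
#'
#' @param wt_fractions wild-type fractions in \[0, 1\] (the remainder is
#'   producer, minus `dead_fraction` dead cells).
#' @param n_cells_per_sample total cells per sample (default 1000, the upper
#'   end of the 500-1000 cells the protocol monitors per sample).
#' @param n_images micrographs per sample (default 20, one per stage
#'   position).
#' @param n_replicates replicates per ratio.
#' @param model a trained [phenonet()]; if `NULL` one is trained on a fresh
#'   synthetic training set (100 particles per class).
#' @param seed integer seed.
#' @param specs phenotype specifications.
#' @param dead_fraction fraction of dead cells mixed into every sample.
#' @param ... further [scene_config()] fields.
#' @return A `mixing_experiment` data frame: one row per ratio x replicate
#'   with true and estimated wild-type/producer/dead fractions and cell
#'   counts.
#' @export
mixing_experiment <- function(wt_fractions = c(0, 0.05, 0.10, 0.25, 0.50, 1),
                              n_cells_per_sample = 1000L, n_images = 20L,
                              n_replicates = 3L, model = NULL, seed = 1L,
                              specs = default_phenotypes(), dead_fraction = 0,
                              ...) {
  stopifnot(all(wt_fractions >= 0 & wt_fractions <= 1),
            n_cells_per_sample >= 100L, n_replicates >= 1L,
            dead_fraction >= 0, dead_fraction < 1)
  if (is.null(model)) {
    ts <- synthetic_training_set(100L, seed = derive_seed(seed, 777L),
                                 specs = specs, ...)
    model <- phenonet(ts$x, ts$y, seed = derive_seed(seed, 778L))
  }
  n_cells <- round(n_cells_per_sample / n_images)
  rows <- list()
  for (ri in seq_along(wt_fractions)) {
    r <- wt_fractions[ri]
    fr <- c(r * (1 - dead_fraction), (1 - r) * (1 - dead_fraction), dead_fraction)
    for (rep_i in seq_len(n_replicates)) {
      scenes <- lapply(seq_len(n_images), function(j)
        render_scene(scene_config(n_cells = n_cells, class_fractions = fr,
                                  seed = derive_seed(seed, ri * 10000L +
                                                       rep_i * 100L + j), ...),
                     specs))
      truth <- table(factor(do.call(rbind, lapply(scenes, `[[`, "cells"))$class,
                            cell_classes()))
      rep_report <- analyze_sample(lapply(scenes, `[[`, "image"),
                                   scenes[[1]]$blank, model,
                                   min_cells_warning = 0L)
      fx <- rep_report$class_fractions
      rows[[length(rows) + 1L]] <- data.frame(
        true_wt = r, replicate = rep_i,
        n_cells_true = sum(truth),
        true_wt_realized = as.numeric(truth["WT_RED"] / sum(truth)),
        n_classified = sum(rep_report$class_counts),
        est_wt = fx[["WT_RED"]], est_producer = fx[["PRODUCER_ORANGE"]],
        est_dead = fx[["DEAD_GREEN"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  class(out) <- c("mixing_experiment", "data.frame")
  out
}

#' @export
print.mixing_experiment <- function(x, ...) {
  cat("In-silico mixing experiment (wild type : producer)\n")
  agg <- aggregate(cbind(est_wt, est_producer, est_dead) ~ true_wt,
                   data = as.data.frame(x), FUN = mean)
  agg[-1] <- round(100 * agg[-1], 1)
  agg$true_wt <- 100 * agg$true_wt
  names(agg) <- c("true wt [%]", "est wt [%]", "est producer [%]", "est dead [%]")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mixing_experiment <- function(x, ...) {
  plot(100 * x$true_wt, 100 * x$est_wt, xlab = "true wild-type fraction [%]",
       ylab = "estimated wild-type fraction [%]", xlim = c(0, 100),
       ylim = c(0, 100), main = "Mixing experiment recovery", ...)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' @importFrom stats aggregate
NULL
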