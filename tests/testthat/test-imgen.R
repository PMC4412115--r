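test_that("a fixed seed fixes every byte of the scene, truth and blank", {
  cfg <- scene_config(n_cells = 25, class_fractions = c(0.4, 0.4, 0.2),
                      seed = 11, image_height = 256, image_width = 256)
  a <- render_scene(cfg)
  b <- render_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$blank, b$blank)
  expect_identical(a$cells, b$cells)
  expect_identical(a$pixels, b$pixels)
})

test_that("an empty scene is pure background with an empty cell list", {
  cfg <- scene_config(n_cells = 0, seed = 2, image_height = 64,
                      image_width = 96, noise_sd = 4, background_level = 10)
  sc <- render_scene(cfg)
  expect_identical(dim(sc$image), c(64L, 96L, 3L))
  expect_identical(nrow(sc$cells), 0L)
  expect_length(sc$pixels, 0)
  expect_lt(max(sc$image), 40)  # background + noise only, far below cell level
})

test_that("noiseless single-class scenes render exact phenotype means", {
  cfg <- quiet_config(n_cells = 20, class_fractions = c(1, 0, 0), seed = 3,
                      image_height = 256, image_width = 256)
  sc <- render_scene(cfg, quiet_specs())
  expect_identical(nrow(sc$cells), 20L)
  expect_true(all(sc$cells$class == "WT_RED"))
  for (px in sc$pixels) {
    expect_true(all(sc$image[px] == 200))                  # red mean, exact
    expect_true(all(sc$image[px + 256 * 256] == 40))       # green mean
    expect_true(all(sc$image[px + 2 * 256 * 256] == 10))   # blue mean
  }
  # red channel dominates green inside every cell
  expect_true(all(sc$image[sc$pixels[[1]]] >
                    sc$image[sc$pixels[[1]] + 256 * 256]))
})

test_that("ground-truth pixel sets are in bounds, nonempty, ids consecutive", {
  cfg <- scene_config(n_cells = 40, class_fractions = c(1, 1, 1) / 3, seed = 7,
                      image_height = 300, image_width = 400)
  sc <- render_scene(cfg)
  expect_identical(sc$cells$cell_id, 1:40)
  npix <- 300L * 400L
  for (px in sc$pixels) {
    expect_gt(length(px), 0)
    expect_true(all(px >= 1 & px <= npix))
  }
  expect_identical(sc$cells$area_px, vapply(sc$pixels, length, integer(1)))
})

test_that("realized class counts follow the requested mixture", {
  # binomial bound on one large scene
  cfg <- scene_config(n_cells = 1000, class_fractions = c(0.5, 0.5, 0),
                      seed = 1, image_height = 1536, image_width = 2048)
  sc <- render_scene(cfg)
  n_wt <- sum(sc$cells$class == "WT_RED")
  expect_lt(abs(n_wt - 500), 3 * sqrt(1000 * 0.25))
  # chi-square goodness of fit on the class-sampling distribution at 10,000
  set.seed(123)
  draws <- phenoscope:::sample_classes(10000, c(0.3, 0.5, 0.2))
  obs <- tabulate(draws, 3)
  gof <- suppressWarnings(chisq.test(obs, p = c(0.3, 0.5, 0.2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("cells cannot be placed when the image is too crowded", {
  cfg <- scene_config(n_cells = 50, image_height = 64, image_width = 64,
                      min_center_distance = 30, seed = 1)
  expect_error(render_scene(cfg), "could not place|too small")
})

test_that("the blank is the illumination field at mid-gray", {
  flat <- scene_config(n_cells = 0, vignette_strength = 0, noise_sd = 0,
                       image_height = 64, image_width = 64, seed = 5)
  expect_true(all(render_blank(flat) == 128))
  vig <- scene_config(n_cells = 0, vignette_strength = 0.5, noise_sd = 0,
                      image_height = 65, image_width = 65, seed = 5)
  b <- render_blank(vig)
  expect_gt(b[33, 33, 1], b[1, 1, 1])          # center brighter than corner
  expect_identical(b, render_blank(vig))       # deterministic
  # center-to-corner ratio reflects the strength
  expect_equal(b[1, 1, 1] / b[33, 33, 1], 0.5, tolerance = 0.01)
})

test_that("the illumination field has unit mean and bounded range", {
  f <- illumination_field(101, 151, 0.4)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_equal(min(f) / max(f), 0.6, tolerance = 1e-9)
  expect_true(all(f > 0))
})

test_that("invalid configurations and specs are rejected", {
  expect_error(scene_config(class_fractions = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(scene_config(n_cells = -1), "nonnegative")
  expect_error(phenotype_spec("WT_RED", 50, 100, 10), "red_mean above")
  expect_error(phenotype_spec("DEAD_GREEN", 200, 100, 10), "green_mean above")
  expect_error(phenotype_spec("WT_RED", 300, 100, 10), "\\[0, 255\\]")
  expect_error(phenotype_spec("WT_RED", 200, 100, 10, radius_range = c(0, 3)),
               "radius_range")
})

test_that("scene YAML round-trips configuration and phenotype overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scene:",
    "  image_height: 120",
    "  image_width: 160",
    "  n_cells: 5",
    "  class_fractions: [0.0, 1.0, 0.0]",
    "  seed: 4",
    "phenotypes:",
    "  PRODUCER_ORANGE:",
    "    red_mean: 140",
    "    green_mean: 135"), path)
  y <- read_scene_yaml(path)
  expect_identical(y$config$image_height, 120L)
  expect_identical(y$config$n_cells, 5L)
  expect_equal(y$specs$PRODUCER_ORANGE$red_mean, 140)
  expect_equal(y$specs$WT_RED$red_mean, 200)   # untouched default
})

test_that("written scenes survive the TIFF/CSV round trip", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(n_cells = 8, seed = 6, image_height = 96, image_width = 128)
  sc <- render_scene(cfg)
  paths <- write_scene(sc, dir, "s1")
  img <- read_image(paths[1])
  expect_identical(dim(img), dim(sc$image))
  expect_true(max(abs(img - round(sc$image))) <= 1)
  truth <- read.csv(paths[3])
  expect_identical(nrow(truth), 8L)
  expect_true(all(truth$center_x >= 0 & truth$center_x < 128))
})
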