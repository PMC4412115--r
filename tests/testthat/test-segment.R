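test_that("maximum-entropy threshold matches the exhaustive oracle", {
  set.seed(42)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(kapur_threshold(h), as.integer(kapur_oracle(h)))
  }
})

test_that("two-spike histograms tie-break to the smallest threshold", {
  h <- integer(256); h[51] <- 40; h[201] <- 60   # levels 50 and 200
  expect_identical(kapur_threshold(h), 50L)
  expect_identical(kapur_oracle(h), 50L)
})

test_that("well-separated bimodal histograms split between the modes", {
  set.seed(7)
  h <- tabulate(c(pmax(0, pmin(255, round(rnorm(4000, 60, 10)))),
                  pmax(0, pmin(255, round(rnorm(4000, 180, 10))))) + 1L, 256)
  t <- kapur_threshold(h)
  expect_gt(t, 80)
  expect_lt(t, 160)
  expect_identical(t, as.integer(kapur_oracle(h)))
})

test_that("degenerate histograms are rejected", {
  h <- integer(256); h[100] <- 500
  expect_error(kapur_threshold(h), "no valid split")
  expect_error(kapur_threshold(rep(0L, 100)), "256")
})

test_that("connected-component labeling matches a flood-fill oracle", {
  set.seed(99)
  for (i in 1:25) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    for (conn in c(8L, 4L)) {
      got <- phenoscope:::label_components(mask, conn)
      want <- label_oracle(mask, conn)
      expect_identical(unclass(got)[seq_along(want)], as.vector(want))
    }
  }
})

test_that("noiseless scenes are segmented to the exact ground-truth count", {
  for (fr in list(c(1, 0, 0), c(0, 0, 1), c(0.4, 0.3, 0.3))) {
    cfg <- quiet_config(n_cells = 20, class_fractions = fr, seed = 21,
                        image_height = 350, image_width = 420)
    sc <- render_scene(cfg, quiet_specs())
    seg <- segment_cells(sc$image)
    expect_identical(nrow(seg$particles), 20L)
    expect_identical(seg$exclusions$total, 0L)
  }
})

test_that("particles below 10 px are excluded, larger ones kept", {
  img <- rect_image(40, 40, list(c(5, 5, 3, 3),      # 9 px: too small
                                 c(20, 20, 3, 4)),   # 12 px: kept
                    color = c(200, 50, 0))
  seg <- segment_cells(img)
  expect_identical(nrow(seg$particles), 1L)
  expect_identical(seg$particles$area_px, 12L)
  expect_identical(seg$exclusions$size, 1L)
  expect_identical(seg$exclusions$border, 0L)
})

test_that("particles touching the image edge are excluded", {
  img <- rect_image(40, 40, list(c(1, 10, 4, 4),     # touches row 1
                                 c(20, 20, 4, 4)),   # interior
                    color = c(200, 50, 0))
  seg <- segment_cells(img)
  expect_identical(nrow(seg$particles), 1L)
  expect_identical(seg$exclusions$border, 1L)
  expect_false(seg$particles$touches_border)
})

test_that("size and border tallies are rule-wise; distinct total is coherent", {
  img <- rect_image(40, 40, list(c(5, 5, 3, 3),      # small interior
                                 c(1, 20, 4, 4),     # big, touches border
                                 c(38, 1, 3, 3),     # small AND border
                                 c(20, 20, 4, 4)))   # kept
  seg <- segment_cells(img)
  expect_identical(seg$exclusions$size, 2L)
  expect_identical(seg$exclusions$border, 2L)
  expect_identical(seg$exclusions$total, 3L)
  expect_identical(nrow(seg$particles), 1L)
  expect_identical(sort(unique(seg$all_particles$excluded_reason)),
                   c("", "border", "size", "size+border"))
})

test_that("the filters commute: size-then-border equals border-then-size", {
  set.seed(5)
  img <- rect_image(60, 60, list(c(1, 5, 3, 3), c(10, 1, 5, 5), c(25, 25, 2, 2),
                                 c(40, 40, 6, 6), c(57, 50, 4, 10)))
  seg <- segment_cells(img)
  ap <- seg$all_particles
  keep_ab <- ap[ap$area_px >= 10, ]
  keep_ab <- keep_ab[!keep_ab$touches_border, ]
  keep_ba <- ap[!ap$touches_border, ]
  keep_ba <- keep_ba[keep_ba$area_px >= 10, ]
  expect_identical(keep_ab$id, keep_ba$id)
  expect_identical(sort(keep_ab$id), sort(seg$all_particles$id[
    seg$all_particles$excluded_reason == ""]))
})

test_that("cells visible only in green are still registered (mask union)", {
  # dead cells: red barely above background, strong green; default read-out
  # noise gives the red channel enough spread to threshold at all
  cfg <- scene_config(n_cells = 15, class_fractions = c(0, 0, 1), seed = 13,
                      image_height = 384, image_width = 384)
  sc <- render_scene(cfg)
  seg <- segment_cells(correct_illumination(sc$image, sc$blank))
  expect_identical(nrow(seg$particles), 15L)
})

test_that("a flat channel makes segmentation fail with the channel named", {
  img <- array(0, c(30, 30, 3))
  img[10:15, 10:15, 1] <- 200   # red fine, green completely flat
  expect_error(segment_cells(img), "green channel")
})

test_that("bounding boxes and centroids describe their particles", {
  img <- rect_image(30, 30, list(c(10, 12, 4, 5)))
  seg <- segment_cells(img)
  p <- seg$particles
  expect_identical(c(p$bbox_row_min, p$bbox_col_min, p$bbox_row_max, p$bbox_col_max),
                   c(10L, 12L, 14L, 17L))
  expect_equal(p$centroid_row, 11.5)
  expect_equal(p$centroid_col, 14)
  expect_identical(p$area_px, 20L)
})
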