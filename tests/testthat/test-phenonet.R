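# Small, well-separated feature clusters embedded in the 33-dim feature space:
# linearly separable, so a one-hidden-layer network can fit them perfectly.
toy_features <- function(n_per_class = 30, sd = 0.02, seed = 1) {
  set.seed(seed)
  centers <- list(c(0.9, 0.1), c(0.1, 0.9), c(0.9, 0.9))
  x <- do.call(rbind, lapply(centers, function(ctr)
    cbind(rnorm(n_per_class, ctr[1], sd), rnorm(n_per_class, ctr[2], sd))))
  X <- matrix(0, nrow(x), 33)
  X[, 1:2] <- x
  list(x = X, y = factor(rep(cell_classes(), each = n_per_class),
                         cell_classes()))
}

test_that("training demands every class and uniform feature lengths", {
  toy <- toy_features()
  expect_error(phenonet(toy$x[1:30, ], toy$y[1:30]), "missing")
  expect_error(phenonet(toy$x, rep("NOT_A_CLASS", 90)), "unknown class")
  expect_error(phenonet(toy$x[1:89, ], toy$y), "lengths differ")
})

test_that("linearly separable toy data reaches zero error within 200 epochs", {
  toy <- toy_features()
  m <- phenonet(toy$x, toy$y, seed = 2,
                control = phenonet_control(max_epochs = 200L))
  expect_identical(m$train_error, 0)
  expect_true(m$converged)
  expect_lte(m$epochs, 200L)
  # consistency: after 0%-error training every training vector gets its label
  expect_identical(as.character(predict(m, toy$x)), as.character(toy$y))
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_features()
  m1 <- phenonet(toy$x, toy$y, seed = 7)
  m2 <- phenonet(toy$x, toy$y, seed = 7)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$log, m2$log)
})

test_that("the GA engages on stalls and elitism never loses the best", {
  # overlapping classes cannot reach 0% error: RPROP stalls, GA phases run
  toy <- toy_features(n_per_class = 40, sd = 0.6, seed = 3)
  m <- phenonet(toy$x, toy$y, seed = 3,
                control = phenonet_control(max_epochs = 150L, max_rounds = 2L,
                                           stall_window = 10L))
  ga <- m$log[m$log$phase == "ga", ]
  expect_gt(nrow(ga), 0)
  for (ep in unique(ga$epoch)) {
    trace <- ga$train_error[ga$epoch == ep]
    expect_true(all(diff(trace) <= 0))        # best fitness is monotone
    before <- utils::tail(m$log$train_error[m$log$phase == "rprop" &
                                              m$log$epoch <= ep], 1)
    expect_lte(min(trace), before)            # GA never worse than incumbent
  }
  expect_false(m$converged)
})

test_that("prediction ties fall to the first class in canonical order", {
  m <- structure(list(W1 = matrix(0, 33, 10), b1 = rep(0, 10),
                      W2 = matrix(0, 10, 3), b2 = rep(0, 3),
                      input_size = 33L, hidden_size = 10L, output_size = 3L,
                      classes = cell_classes(), activation = "sigmoid",
                      fingerprint = NULL),
                 class = "phenonet")
  a <- predict(m, runif(33), type = "activations")
  expect_true(all(a == a[1]))
  expect_identical(as.character(predict(m, runif(33))), "WT_RED")
})

test_that("models survive the JSON round trip bit for bit", {
  toy <- toy_features()
  m <- phenonet(toy$x, toy$y, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_phenonet(m, path)
  m2 <- load_phenonet(path)
  expect_identical(predict(m2, toy$x, type = "activations"),
                   predict(m, toy$x, type = "activations"))
  expect_identical(m2$fingerprint, m$fingerprint)
})

test_that("corrupt and mismatched model files are rejected", {
  toy <- toy_features()
  m <- phenonet(toy$x, toy$y, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_phenonet(m, path)
  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), path)   # truncate
  expect_error(load_phenonet(path), "cannot parse")
  writeLines('{"format": "something-else"}', path)
  expect_error(load_phenonet(path), "not a phenoscope network")
  save_phenonet(m, path)
  obj <- jsonlite::fromJSON(path)
  obj$version <- 99L
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  expect_error(load_phenonet(path), "version")
})

test_that("a feature-configuration mismatch is refused at prediction time", {
  toy <- toy_features()
  x <- toy$x
  attr(x, "fingerprint") <- phenoscope:::feature_fingerprint(32L)
  m <- phenonet(x, toy$y, seed = 5)
  bad <- toy$x
  attr(bad, "fingerprint") <- phenoscope:::feature_fingerprint(16L)
  expect_error(predict(m, bad), "mismatch")
  expect_error(predict(m, toy$x[, 1:10]), "expected 33 features")
})

test_that("held-out accuracy on synthetic phenotypes stays above 95%", {
  accs <- vapply(1:10, function(seed) {
    train <- synthetic_training_set(30, seed = seed, image_size = c(256, 340),
                                    cells_per_scene = 45)
    test <- synthetic_training_set(30, seed = seed + 1000,
                                   image_size = c(256, 340), cells_per_scene = 45)
    m <- phenonet(train$x, train$y, seed = seed)
    mean(predict(m, test$x) == test$y)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
  expect_true(all(accs >= 0.95))
})
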