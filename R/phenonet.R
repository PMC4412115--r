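#' Training control parameters for [phenonet()]
#'
#' The trainer alternates full-batch resilient propagation (the iRPROP- update
#' without weight backtracking) with a genetic-algorithm phase that engages
#' whenever the training misclassification rate stalls: when its relative
#' change over `stall_window` epochs drops below `stall_threshold` (1% by
#' default). Training stops when the misclassification rate reaches
#' `target_error` (0 by default, i.e. every training particle classified
#' correctly) or when the epoch/round budget is exhausted.
#'
#' @param eta_plus,eta_minus RPROP step-size increase/decrease factors.
#' @param delta0,delta_max,delta_min initial, maximum and minimum per-weight
#'   step sizes.
#' @param stall_threshold relative change in the training error rate below
#'   which RPROP is considered stalled and the GA engages.
#' @param stall_window number of epochs over which the change is measured.
#' @param target_error training misclassification rate at which training stops.
#' @param max_epochs hard cap on RPROP epochs.
#' @param max_rounds hard cap on GA phases.
#' @param ga_population,ga_sigma,ga_elites,ga_generations GA phase parameters:
#'   population size (seeded from the current weights plus Gaussian
#'   perturbations of scale `ga_sigma`), number of elites carried over
#'   unchanged, and generations per phase. Fitness is the training
#'   misclassification rate (sum-of-squares error breaks ties).
#' @param validation_fraction optional fraction of the training set held out
#'   to monitor generalization; 0 (default) trains on everything, matching a
#'   protocol that stops at 0% training error.
#' @return A `phenonet_control` list.
#' @export
phenonet_control <- function(eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                             delta_max = 50, delta_min = 1e-6,
                             stall_threshold = 0.01, stall_window = 20L,
                             target_error = 0, max_epochs = 2000L,
                             max_rounds = 10L, ga_population = 30L,
                             ga_sigma = 0.2, ga_elites = 2L,
                             ga_generations = 25L, validation_fraction = 0) {
  stopifnot(eta_plus > 1, eta_minus > 0, eta_minus < 1, delta0 > 0,
            stall_threshold >= 0, stall_window >= 1,
            target_error >= 0, target_error < 1, max_epochs >= 1,
            max_rounds >= 1, ga_population >= 2, ga_elites >= 1,
            ga_elites < ga_population, ga_generations >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(as.list(environment()), class = "phenonet_control")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_unpack <- function(theta, d, h, k) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- theta[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

nn_forward <- function(theta, X, d, h, k) {
  w <- nn_unpack(theta, d, h, k)
  A1 <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% w$W2, 2, w$b2, "+"))
  list(A1 = A1, A2 = A2)
}

nn_eval <- function(theta, X, Tm, yi, d, h, k) {
  A2 <- nn_forward(theta, X, d, h, k)$A2
  list(err = mean(max.col(A2, ties.method = "first") != yi),
       sse = sum((A2 - Tm)^2))
}

nn_grad <- function(theta, X, Tm, d, h, k) {
  w <- nn_unpack(theta, d, h, k)
  A1 <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% w$W2, 2, w$b2, "+"))
  d2 <- 2 * (A2 - Tm) * A2 * (1 - A2)
  d1 <- (d2 %*% t(w$W2)) * A1 * (1 - A1)
  c(as.vector(t(X) %*% d1), colSums(d1),
    as.vector(t(A1) %*% d2), colSums(d2))
}

ga_phase <- function(theta, X, Tm, yi, d, h, k, ctrl) {
  npar <- length(theta); np <- ctrl$ga_population
  pop <- matrix(rnorm(npar * np, sd = ctrl$ga_sigma), npar, np) + theta
  pop[, 1L] <- theta                       # the incumbent survives unperturbed
  best_trace <- numeric(ctrl$ga_generations)
  for (gen in seq_len(ctrl$ga_generations)) {
    ev <- apply(pop, 2, function(th) nn_eval(th, X, Tm, yi, d, h, k))
    err <- vapply(ev, `[[`, numeric(1), "err")
    sse <- vapply(ev, `[[`, numeric(1), "sse")
    ord <- order(err, sse)
    best_trace[gen] <- err[ord[1L]]
    if (err[ord[1L]] <= ctrl$target_error) {
      return(list(theta = pop[, ord[1L]], err = err[ord[1L]],
                  trace = best_trace[seq_len(gen)]))
    }
    elites <- pop[, ord[seq_len(ctrl$ga_elites)], drop = FALSE]
    n_off <- np - ctrl$ga_elites
    rank_of <- integer(np); rank_of[ord] <- seq_len(np)
    pick_parent <- function() {
      cand <- sample.int(np, 3L)
      cand[which.min(rank_of[cand])]       # tournament of 3 on fitness rank
    }
    off <- vapply(seq_len(n_off), function(j) {
      p1 <- pop[, pick_parent()]; p2 <- pop[, pick_parent()]
      cross <- runif(npar) < 0.5
      child <- ifelse(cross, p1, p2)
      child + rnorm(npar, sd = ctrl$ga_sigma)
    }, numeric(npar))
    pop <- cbind(elites, off)
  }
  ev <- apply(pop, 2, function(th) nn_eval(th, X, Tm, yi, d, h, k))
  err <- vapply(ev, `[[`, numeric(1), "err")
  sse <- vapply(ev, `[[`, numeric(1), "sse")
  best <- order(err, sse)[1L]
  list(theta = pop[, best], err = err[best], trace = best_trace)
}

#' Fit the three-class phenotype network
#'
#' Trains a feed-forward neural network with one hidden layer (sigmoid
#' activations, one-hot targets, sum-of-squares loss) that maps per-particle
#' color features (normalized hue histogram + mean brightness, see
#' [particle_features()]) to the three phenotype classes. Training combines
#' resilient propagation with a genetic algorithm: RPROP runs until the change
#' in the training error rate falls below 1% over a window, then a GA phase
#' perturbs the weights out of the plateau, and RPROP resumes from the GA's
#' best individual; the schedule repeats until the training misclassification
#' rate reaches the target (0% by default).
#'
#' @param x numeric feature matrix, one row per particle (typically from
#'   [particle_features()]; its `fingerprint` attribute, when present, is
#'   stored in the model and checked at prediction time).
#' @param y class labels: factor or character with values in `cell_classes()`;
#'   every class must be represented.
#' @param hidden number of hidden units.
#' @param control a [phenonet_control()].
#' @param seed integer seed governing weight initialization and the GA.
#' @return An object of class `phenonet`: weight matrices `W1`, `b1`, `W2`,
#'   `b2`, the architecture, the feature `fingerprint`, `train_error` (final
#'   training misclassification rate), `converged`, `rounds` (GA phases used)
#'   and a training `log` (data frame: epoch, phase, train_error). Methods:
#'   [predict.phenonet()], `print`, `summary`, `coef`, `plot`.
#' @export
phenonet <- function(x, y, hidden = 10L, control = phenonet_control(),
                     seed = 1L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("features contain missing values")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  if (!all(y %in% cell_classes()))
    stop("unknown class labels: ", paste(setdiff(y, cell_classes()), collapse = ", "))
  missing_cl <- setdiff(cell_classes(), y)
  if (length(missing_cl))
    stop("every class needs at least one training example; missing: ",
         paste(missing_cl, collapse = ", "))
  fp <- attr(x, "fingerprint")
  ctrl <- control
  d <- ncol(x); h <- as.integer(hidden); k <- 3L
  yi <- match(y, cell_classes())
  Tm <- diag(3)[yi, , drop = FALSE]
  Xv <- NULL; Tv <- NULL; yv <- NULL
  set.seed(as.integer(seed))
  if (ctrl$validation_fraction > 0) {
    nv <- max(1L, floor(nrow(x) * ctrl$validation_fraction))
    vi <- sample.int(nrow(x), nv)
    Xv <- x[vi, , drop = FALSE]; Tv <- Tm[vi, , drop = FALSE]; yv <- yi[vi]
    x <- x[-vi, , drop = FALSE]; Tm <- Tm[-vi, , drop = FALSE]; yi <- yi[-vi]
    if (!all(1:3 %in% yi)) stop("validation split removed a class from training")
  }
  npar <- d * h + h + h * k + k
  theta <- runif(npar, -0.5, 0.5)
  delta <- rep(ctrl$delta0, npar)
  gprev <- numeric(npar)
  log_epoch <- integer(0); log_phase <- character(0); log_err <- numeric(0)
  err_hist <- numeric(0)
  epoch <- 0L; rounds <- 0L; last_reset <- 0L
  converged <- FALSE
  best_val <- Inf; best_val_theta <- NULL
  repeat {
    e <- nn_eval(theta, x, Tm, yi, d, h, k)$err
    epoch <- epoch + 1L
    err_hist[epoch] <- e
    log_epoch <- c(log_epoch, epoch); log_phase <- c(log_phase, "rprop")
    log_err <- c(log_err, e)
    if (!is.null(Xv)) {
      ve <- nn_eval(theta, Xv, Tv, yv, d, h, k)$err
      if (ve < best_val) { best_val <- ve; best_val_theta <- theta }
    }
    if (e <= ctrl$target_error) { converged <- TRUE; break }
    if (epoch >= ctrl$max_epochs) break
    stalled <- epoch - last_reset > ctrl$stall_window &&
      abs(err_hist[epoch - ctrl$stall_window] - e) /
        max(err_hist[epoch - ctrl$stall_window], 1e-12) < ctrl$stall_threshold
    if (stalled) {
      if (rounds >= ctrl$max_rounds) break
      rounds <- rounds + 1L
      ga <- ga_phase(theta, x, Tm, yi, d, h, k, ctrl)
      theta <- ga$theta
      log_epoch <- c(log_epoch, rep(epoch, length(ga$trace)))
      log_phase <- c(log_phase, rep("ga", length(ga$trace)))
      log_err <- c(log_err, ga$trace)
      delta <- rep(ctrl$delta0, npar)      # fresh RPROP state after the jump
      gprev <- numeric(npar)
      last_reset <- epoch
      next
    }
    g <- nn_grad(theta, x, Tm, d, h, k)
    s <- g * gprev
    delta <- ifelse(s > 0, pmin(delta * ctrl$eta_plus, ctrl$delta_max),
             ifelse(s < 0, pmax(delta * ctrl$eta_minus, ctrl$delta_min), delta))
    g[s < 0] <- 0                          # iRPROP-: forget reversed gradients
    theta <- theta - sign(g) * delta
    gprev <- g
  }
  if (!is.null(best_val_theta) && !converged) theta <- best_val_theta
  final <- nn_eval(theta, x, Tm, yi, d, h, k)
  w <- nn_unpack(theta, d, h, k)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 input_size = d, hidden_size = h, output_size = k,
                 classes = cell_classes(), activation = "sigmoid",
                 fingerprint = fp, train_error = final$err, train_sse = final$sse,
                 converged = converged, epochs = epoch, rounds = rounds,
                 log = data.frame(epoch = log_epoch, phase = log_phase,
                                  train_error = log_err),
                 control = ctrl, seed = as.integer(seed), n_train = nrow(x),
                 call = match.call()),
            class = "phenonet")
}

#' Classify particles with a trained phenotype network
#'
#' Runs the forward pass and assigns each particle to the class with the
#' largest output activation; exact ties fall to the earlier class in
#' `cell_classes()` order. If `newdata` carries a feature `fingerprint`
#' attribute it must match the one the model was trained with.
#'
#' @param object a fitted [phenonet()] model.
#' @param newdata feature matrix (rows = particles) or a single feature vector.
#' @param type `"class"` (factor of labels) or `"activations"` (matrix of the
#'   three output activations).
#' @param ... unused.
#' @export
predict.phenonet <- function(object, newdata, type = c("class", "activations"),
                             ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  fp <- attr(newdata, "fingerprint")
  if (!is.null(fp) && !is.null(object$fingerprint) &&
      !identical(fp, object$fingerprint))
    stop("feature configuration mismatch: the model was trained with ",
         "hue_bins = ", object$fingerprint$hue_bins,
         " but the features use hue_bins = ", fp$hue_bins)
  if (ncol(newdata) != object$input_size)
    stop("expected ", object$input_size, " features, got ", ncol(newdata))
  A1 <- sigmoid(sweep(newdata %*% object$W1, 2, object$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% object$W2, 2, object$b2, "+"))
  colnames(A2) <- object$classes
  if (type == "activations") return(A2)
  factor(object$classes[max.col(A2, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.phenonet <- function(x, ...) {
  cat("Phenotype network:", x$input_size, "->", x$hidden_size, "-> 3 (sigmoid)\n")
  cat(sprintf("training error %.2f%% after %d epochs, %d GA phase(s)%s\n",
              100 * x$train_error, x$epochs, x$rounds,
              if (x$converged) "" else " [did not reach target]"))
  invisible(x)
}

#' @export
summary.phenonet <- function(object, ...) {
  cat("One-hidden-layer feed-forward phenotype classifier\n")
  cat("  architecture :", object$input_size, "inputs,", object$hidden_size,
      "hidden,", object$output_size, "outputs (sigmoid)\n")
  cat("  classes      :", paste(object$classes, collapse = ", "), "\n")
  cat("  weights      :", length(object$W1) + length(object$b1) +
        length(object$W2) + length(object$b2), "\n")
  cat("  training set :", object$n_train, "particles\n")
  cat(sprintf("  train error  : %.3f%% (target %.1f%%)\n",
              100 * object$train_error, 100 * object$control$target_error))
  cat("  schedule     :", object$epochs, "RPROP epochs,", object$rounds,
      "GA phase(s);", if (object$converged) "converged" else "not converged", "\n")
  if (!is.null(object$fingerprint))
    cat("  features     :", object$fingerprint$hue_bins,
        "hue bins + mean brightness\n")
  invisible(object)
}

#' @export
coef.phenonet <- function(object, ...) {
  object[c("W1", "b1", "W2", "b2")]
}

#' @export
plot.phenonet <- function(x, ...) {
  rp <- x$log[x$log$phase == "rprop", ]
  plot(rp$epoch, 100 * rp$train_error, type = "l",
       xlab = "epoch", ylab = "training error [%]",
       main = "Phenotype network training", ...)
  ga <- unique(x$log$epoch[x$log$phase == "ga"])
  if (length(ga)) abline(v = ga, lty = 3, col = "grey50")
  invisible(x)
}

#' Save / load a phenotype network as versioned JSON
#'
#' The file records the architecture, weights at full precision and the
#' feature-configuration fingerprint; `load_phenonet(save_phenonet(m, path))`
#' reproduces `m`'s predictions bit for bit.
#'
#' @param model a [phenonet()] fit.
#' @param path JSON file path.
#' @export
save_phenonet <- function(model, path) {
  stopifnot(inherits(model, "phenonet"))
  obj <- list(format = "phenoscope-network", version = 1L,
              input_size = model$input_size, hidden_size = model$hidden_size,
              output_size = model$output_size, classes = model$classes,
              activation = model$activation, fingerprint = model$fingerprint,
              weights = list(W1 = model$W1, b1 = model$b1,
                             W2 = model$W2, b2 = model$b2),
              train_error = model$train_error, converged = model$converged)
  if (is.null(model$fingerprint)) obj$fingerprint <- NULL
  # I(17) significant digits: doubles survive the decimal round trip exactly
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_phenonet
#' @export
load_phenonet <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(obj$format, "phenoscope-network"))
    stop("'", path, "' is not a phenoscope network file")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported model file version: ", obj$version)
  need <- c("input_size", "hidden_size", "output_size", "classes", "weights")
  if (!all(need %in% names(obj))) stop("model file is missing fields: ",
                                       paste(setdiff(need, names(obj)), collapse = ", "))
  fp <- obj$fingerprint
  if (!is.null(fp) && length(fp) == 0L) fp <- NULL
  if (!is.null(fp)) {   # JSON does not keep R's integer/double distinction
    fp$hue_bins <- as.integer(fp$hue_bins)
    fp$brightness <- as.logical(fp$brightness)
    fp$achromatic_hue <- as.numeric(fp$achromatic_hue)
  }
  m <- list(W1 = obj$weights$W1, b1 = as.numeric(obj$weights$b1),
            W2 = obj$weights$W2, b2 = as.numeric(obj$weights$b2),
            input_size = as.integer(obj$input_size),
            hidden_size = as.integer(obj$hidden_size),
            output_size = as.integer(obj$output_size),
            classes = obj$classes, activation = obj$activation,
            fingerprint = fp, train_error = obj$train_error,
            converged = obj$converged, epochs = NA_integer_,
            rounds = NA_integer_, log = NULL, control = NULL,
            n_train = NA_integer_, call = NULL)
  if (!identical(dim(m$W1), c(m$input_size, m$hidden_size)) ||
      !identical(dim(m$W2), c(m$hidden_size, m$output_size)))
    stop("model file weight shapes are inconsistent with the architecture")
  class(m) <- "phenonet"
  m
}
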