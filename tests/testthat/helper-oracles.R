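# Independent oracles and small fixture builders, deliberately written
# differently from the package internals.

# Exhaustive maximum-entropy threshold: score every candidate t directly from
# the class-conditional distributions.
kapur_oracle <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    lo <- p[seq_len(t + 1)]
    hi <- p[seq(t + 2, 256)]
    w0 <- sum(lo); w1 <- sum(hi)
    if (w0 <= 0 || w1 <= 0) next
    q0 <- lo[lo > 0] / w0
    q1 <- hi[hi > 0] / w1
    h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (h > best + 1e-12) { best <- h; best_t <- t }
  }
  best_t
}

# Connected-component labeling by breadth-first search, scanning in row-major
# order so labels are comparable with the package's.
label_oracle <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        qi <- p[1] + nb[k, 1]; qj <- p[2] + nb[k, 2]
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

random_histogram <- function() {
  kind <- sample(3, 1)
  h <- switch(kind,
    rpois(256, lambda = runif(1, 0.5, 50)),                    # dense
    {h <- integer(256); nz <- sample(256, sample(2:12, 1))     # sparse
     h[nz] <- sample(1:500, length(nz), replace = TRUE); h},
    {m <- sort(sample(30:220, 2))                              # bimodal
     h1 <- dnorm(0:255, m[1], runif(1, 5, 20))
     h2 <- dnorm(0:255, m[2], runif(1, 5, 20))
     round(3000 * (runif(1, 0.2, 0.8) * h1 + runif(1, 0.2, 0.8) * h2))})
  if (sum(h > 0) < 2) h[c(10, 200)] <- h[c(10, 200)] + 1L
  h
}

# A black image with rectangular "cells" of given channel color; rects is a
# list of c(row0, col0, height, width).
rect_image <- function(H, W, rects, color = c(200, 50, 0)) {
  img <- array(0, c(H, W, 3))
  for (r in rects) {
    rows <- r[1]:(r[1] + r[3] - 1)
    cols <- r[2]:(r[2] + r[4] - 1)
    for (ch in 1:3) img[rows, cols, ch] <- color[ch]
  }
  img
}

# noiseless rendering settings: no read-out noise, flat field, and phenotypes
# without per-pixel spread
quiet_specs <- function() {
  sp <- default_phenotypes()
  for (i in seq_along(sp)) sp[[i]]$channel_sd <- 0
  sp
}

quiet_config <- function(...) {
  scene_config(noise_sd = 0, vignette_strength = 0, ...)
}
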