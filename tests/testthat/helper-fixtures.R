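# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from stored data.

# seeded random binary mask
rand_mask <- function(h = 16, w = 16, p = 0.5, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(h * w, 1, p), h, w))
}

# seeded random two-channel probability field (channels sum to 1)
rand_prob_field <- function(h = 8, w = 8, seed = 1) {
  withr::with_seed(seed, {
    p1 <- matrix(runif(h * w), h, w)
    f <- array(0, c(h, w, 2))
    f[, , 1] <- 1 - p1
    f[, , 2] <- p1
    f
  })
}

# one-hot encode a binary mask to the shape of a probability field
onehot <- function(mask) {
  f <- array(0, c(nrow(mask), ncol(mask), 2))
  f[, , 1] <- 1 - mask
  f[, , 2] <- mask
  f
}

# independent brute-force per-pixel confusion tally (explicit loop; the
# oracle deliberately avoids the package's vectorized path)
brute_confusion <- function(y_true, y_pred, cls) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y_true)) {
    t_is <- y_true[i] == cls
    p_is <- y_pred[i] == cls
    if (t_is && p_is) tp <- tp + 1L
    else if (!t_is && p_is) fp <- fp + 1L
    else if (t_is && !p_is) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_iou <- function(y_true, y_pred, cls) {
  cc <- brute_confusion(y_true, y_pred, cls)
  if (cc["tp"] + cc["fp"] + cc["fn"] == 0) return(1)
  unname(cc["tp"] / (cc["tp"] + cc["fp"] + cc["fn"]))
}

# independent binary cross-entropy (mean, natural log, 1e-7 clip)
bce_ref <- function(y, p) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

# small on-disk synthetic dataset, built once per test run
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "glandseg-tiny-ds")
      cache <<- generate_dataset(dir, n_train = 16, n_val = 6, n_test = 6,
                                 size = 32, seed = 99)
    }
    cache
  }
})

# a toy slide with mixed benign/malignant cores, built once
fixture_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_toy_slide(slide_layout(
        256, 256,
        cores = list(
          list(center = c(80, 80), axes = c(60, 45), rotation = 0.3,
               labels = c("N", "GP3")),
          list(center = c(180, 180), axes = c(55, 40), rotation = -0.5,
               labels = c("N", "GP4"))),
        seed = 7))
    }
    cache
  }
})
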