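#' Configuration of the composite segmentation objective
#'
#' The training objective is `Dice_loss + focal_multiplier *
#' BinaryFocal_loss`.  The Dice term is a class-weighted F-beta loss
#' computed from soft precision and recall; the focal term is a
#' modulated binary cross-entropy on the malignant probability channel.
#'
#' @param beta precision/recall balance of the F-beta score (> 0);
#'   `beta = 1` is the symmetric Dice/F1 form.
#' @param alpha focal balancing factor in (0, 1].
#' @param gamma focal focusing exponent (>= 0); `gamma = 0, alpha = 1`
#'   reduces the focal term to plain binary cross-entropy.
#' @param smooth small positive constant guarding empty-class
#'   denominators in soft precision/recall.
#' @param class_weights a [class_weights()] object; weights are
#'   normalized to sum 1 inside the Dice term, so only their ratio
#'   matters.
#' @param focal_multiplier scale of the focal term in the total loss.
#' @return A list with class `"loss_config"`.
#' @export
loss_config <- function(beta = 1, alpha = 0.25, gamma = 2, smooth = 1e-5,
                        class_weights = NULL, focal_multiplier = 1) {
  if (is.null(class_weights)) {
    class_weights <- structure(list(w0 = 1, w1 = 1),
                               class = "class_weights")
  }
  stopifnot(beta > 0, alpha > 0, alpha <= 1, gamma >= 0, smooth > 0,
            inherits(class_weights, "class_weights"))
  structure(list(beta = beta, alpha = alpha, gamma = gamma,
                 smooth = smooth, class_weights = class_weights,
                 focal_multiplier = focal_multiplier),
            class = "loss_config")
}

# Coerce y_true to a two-channel one-hot array shaped like y_pred.
# Accepts a binary matrix/array (class labels) or an already one-hot
# array.  y_pred may be H x W x 2 or H x W x 2 x N.
.canon_fields <- function(y_true, y_pred) {
  dp <- dim(y_pred)
  if (is.null(dp) || !(length(dp) %in% c(3L, 4L)) || dp[3] != 2L) {
    stop("y_pred must be an H x W x 2 (x N) probability array")
  }
  dt <- dim(y_true)
  if (!is.null(dt) && length(dt) == length(dp) && all(dt == dp)) {
    return(list(t = y_true, p = y_pred))
  }
  # label field -> one-hot
  lab_dim <- dp[-3]
  if (is.null(dt)) dt <- length(y_true)
  if (prod(dt) != prod(lab_dim)) {
    stop("y_true shape does not match y_pred (expected ",
         paste(lab_dim, collapse = "x"), " labels or one-hot ",
         paste(dp, collapse = "x"), ")")
  }
  lab <- array(as.numeric(y_true), lab_dim)
  oh <- array(0, dp)
  if (length(dp) == 3L) {
    oh[, , 1] <- 1 - lab
    oh[, , 2] <- lab
  } else {
    oh[, , 1, ] <- 1 - lab
    oh[, , 2, ] <- lab
  }
  list(t = oh, p = y_pred)
}

.channel <- function(a, c) {
  if (length(dim(a)) == 3L) a[, , c] else a[, , c, , drop = FALSE]
}

#' Soft precision and recall for one class
#'
#' Soft confusion counts over all pixels: `TP = sum(t * p)`,
#' `FP = sum((1 - t) * p)`, `FN = sum(t * (1 - p))`, where `t` is the
#' one-hot truth and `p` the predicted probability of the class.  The
#' `smooth` constant enters numerator and denominator, so a perfect
#' hard prediction returns exactly (1, 1).
#'
#' @param y_true binary label field or one-hot array.
#' @param y_pred probability array `H x W x 2 (x N)`.
#' @param class class index, 0 (benign) or 1 (malignant).
#' @param smooth small positive guard constant.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
soft_precision_recall <- function(y_true, y_pred, class = 1,
                                  smooth = 1e-5) {
  f <- .canon_fields(y_true, y_pred)
  ch <- class + 1L
  t <- .channel(f$t, ch); p <- .channel(f$p, ch)
  tp <- sum(t * p)
  fp <- sum((1 - t) * p)
  fn <- sum(t * (1 - p))
  c(precision = (tp + smooth) / (tp + fp + smooth),
    recall = (tp + smooth) / (tp + fn + smooth))
}

.fbeta <- function(precision, recall, beta) {
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Class-weighted Dice (F-beta) loss
#'
#' For each class, an F-beta score is formed from soft precision and
#' recall; the loss is the weighted sum of `1 - F_beta` over the two
#' classes, with class weights normalized to sum 1 (so rescaling both
#' weights leaves the loss unchanged).  A perfect hard prediction gives
#' exactly 0.
#'
#' @inheritParams soft_precision_recall
#' @param config a [loss_config()].
#' @return Non-negative scalar.
#' @export
dice_loss <- function(y_true, y_pred, config = loss_config()) {
  f <- .canon_fields(y_true, y_pred)
  w <- c(config$class_weights$w0, config$class_weights$w1)
  w <- w / sum(w)
  loss <- 0
  for (c in 0:1) {
    pr <- soft_precision_recall(f$t, f$p, class = c,
                                smooth = config$smooth)
    loss <- loss + w[c + 1] * (1 - .fbeta(pr[1], pr[2], config$beta))
  }
  unname(loss)
}

#' Binary focal loss on the malignant channel
#'
#' Mean over pixels of
#' `-y * alpha * (1 - p)^gamma * log(p) - (1 - y) * alpha * p^gamma *
#' log(1 - p)`, where `p` is the predicted malignant probability and
#' `y` the binary truth.  Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]`; natural logarithm.  With `gamma = 0, alpha = 1`
#' this is exactly binary cross-entropy.
#'
#' @inheritParams dice_loss
#' @return Non-negative scalar.
#' @export
binary_focal_loss <- function(y_true, y_pred, config = loss_config()) {
  f <- .canon_fields(y_true, y_pred)
  if (any(f$p < 0) || any(f$p > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  y <- as.numeric(.channel(f$t, 2L))
  p <- as.numeric(.channel(f$p, 2L))
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  a <- config$alpha; g <- config$gamma
  mean(-y * a * (1 - p)^g * log(p) - (1 - y) * a * p^g * log(1 - p))
}

#' Composite training objective
#'
#' `dice_loss + focal_multiplier * binary_focal_loss`.
#'
#' @inheritParams dice_loss
#' @return Non-negative scalar.
#' @export
total_loss <- function(y_true, y_pred, config = loss_config()) {
  dice_loss(y_true, y_pred, config) +
    config$focal_multiplier * binary_focal_loss(y_true, y_pred, config)
}

#' Analytic gradient of the composite objective
#'
#' Gradient of [total_loss()] with respect to every entry of the
#' predicted probability array, treating all entries as independent
#' (the two channels are not constrained to sum to one here, so the
#' result can be checked entry-wise against finite differences).
#' Inside the clipping region of the focal term the gradient is zero.
#'
#' @inheritParams dice_loss
#' @return Array with the shape of `y_pred`.
#' @export
total_loss_grad <- function(y_true, y_pred, config = loss_config()) {
  f <- .canon_fields(y_true, y_pred)
  grad <- array(0, dim(f$p))
  w <- c(config$class_weights$w0, config$class_weights$w1)
  w <- w / sum(w)
  s <- config$smooth; beta <- config$beta
  nd <- length(dim(f$p))

  assign_ch <- function(arr, c, val) {
    if (nd == 3L) arr[, , c] <- val else arr[, , c, ] <- val
    arr
  }
  get_ch <- function(arr, c) {
    v <- .channel(arr, c)
    array(as.numeric(v), dim(f$p)[-3][c(1, 2, if (nd == 4L) 3)])
  }

  # Dice term: chain rule through per-class soft precision/recall
  for (c in 1:2) {
    t <- get_ch(f$t, c); p <- get_ch(f$p, c)
    tp <- sum(t * p)
    pp <- sum(p)      # tp + fp
    yy <- sum(t)      # tp + fn
    P <- (tp + s) / (pp + s)
    R <- (tp + s) / (yy + s)
    den <- beta^2 * P + R
    dF_dP <- (1 + beta^2) * R^2 / den^2
    dF_dR <- (1 + beta^2) * beta^2 * P^2 / den^2
    dP_dp <- (t * (pp + s) - (tp + s)) / (pp + s)^2
    dR_dp <- t / (yy + s)
    dch <- -w[c] * (dF_dP * dP_dp + dF_dR * dR_dp)
    prev <- get_ch(grad, c)
    grad <- assign_ch(grad, c, prev + dch)
  }

  # Focal term: malignant channel only
  y <- get_ch(f$t, 2L)
  p_raw <- get_ch(f$p, 2L)
  eps <- 1e-7
  p <- pmin(pmax(p_raw, eps), 1 - eps)
  a <- config$alpha; g <- config$gamma
  n <- length(p)
  if (g > 0) {
    dfoc <- y * a * (g * (1 - p)^(g - 1) * log(p) - (1 - p)^g / p) +
      (1 - y) * a * (-g * p^(g - 1) * log(1 - p) + p^g / (1 - p))
  } else {
    dfoc <- y * a * (-1 / p) + (1 - y) * a * (1 / (1 - p))
  }
  dfoc[p_raw < eps | p_raw > 1 - eps] <- 0 # clipped region
  prev <- get_ch(grad, 2L)
  grad <- assign_ch(grad, 2L,
                    prev + config$focal_multiplier * dfoc / n)
  grad
}
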