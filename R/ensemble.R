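#' Model-ensemble (ME) probability averaging
#'
#' Per-pixel arithmetic mean of the softmax probability vectors of
#' several models, yielding the ensemble field `f(x) = [P0bar, P1bar]`.
#'
#' @param fields list of probability arrays `H x W x 2`, one per model,
#'   all the same shape.
#' @return Probability array `H x W x 2`.
#' @export
ensemble_probs <- function(fields) {
  stopifnot(length(fields) >= 1)
  d <- dim(fields[[1]])
  for (f in fields) .check_same_shape(fields[[1]], f)
  out <- array(0, d)
  for (f in fields) out <- out + f
  out / length(fields)
}

#' Weighted model-ensemble (WME) probability averaging
#'
#' Per-pixel weighted mean `sum(w_i * field_i) / sum(w_i)`.  Weights
#' are normalized by their sum, so rescaling all weights by a positive
#' constant changes neither the output nor (a fortiori) its argmax;
#' uniform weights reduce to [ensemble_probs()] and a one-hot weight
#' vector reproduces that model's field exactly.
#'
#' @param fields list of probability arrays `H x W x 2`.
#' @param weights numeric vector of non-negative model weights, one per
#'   field, with a positive sum (e.g. `c(0.0, 0.2, 0.4)` for U-Net,
#'   AU-Net, ARU-Net).
#' @return Probability array `H x W x 2`.
#' @export
weighted_ensemble_probs <- function(fields, weights) {
  stopifnot(length(fields) >= 1, length(weights) == length(fields))
  if (any(weights < 0)) stop("ensemble weights must be non-negative")
  if (sum(weights) <= 0) stop("ensemble weights must not all be zero")
  for (f in fields) .check_same_shape(fields[[1]], f)
  w <- weights / sum(weights)
  out <- array(0, dim(fields[[1]]))
  for (i in seq_along(fields)) out <- out + w[i] * fields[[i]]
  out
}

#' Grid search for ensemble weights
#'
#' Exhaustively evaluates every weight tuple on the lattice
#' `{0, step, ..., 1}^m` (excluding the all-zero tuple) by the overall
#' mean IoU of the weighted-ensemble argmax prediction against the
#' ground-truth masks, aggregated over all validation patches.  Ties
#' resolve to the lexicographically smallest tuple.
#'
#' @param fields_per_model list of length `m`; element `i` is the list
#'   of probability fields of model `i` over the validation patches.
#' @param masks list of binary ground-truth matrices, parallel to each
#'   model's field list.
#' @param step lattice step; `1/step` must be an integer (default 0.2).
#' @return List: `weights` (best tuple), `score` (its mean IoU), and
#'   `table` (data.frame of every evaluated tuple with `mean_iou`,
#'   `iou_class0`, `iou_class1`).
#' @export
grid_search_weights <- function(fields_per_model, masks, step = 0.2) {
  m <- length(fields_per_model)
  stopifnot(m >= 1, length(masks) >= 1)
  if (abs(1 / step - round(1 / step)) > 1e-9) {
    stop("step must divide 1 evenly")
  }
  for (fl in fields_per_model) {
    stopifnot(length(fl) == length(masks))
  }
  # stack all patches: per model one row each for channels 0 and 1
  p0 <- do.call(rbind, lapply(fields_per_model, function(fl)
    unlist(lapply(fl, function(f) as.numeric(f[, , 1])))))
  p1 <- do.call(rbind, lapply(fields_per_model, function(fl)
    unlist(lapply(fl, function(f) as.numeric(f[, , 2])))))
  tt <- unlist(lapply(masks, as.numeric))

  levs <- seq(0, 1, by = step)
  grid <- as.matrix(expand.grid(rep(list(levs), m)))
  colnames(grid) <- paste0("w", seq_len(m))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  # lexicographic order on (w1, w2, ...)
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]

  n <- nrow(grid)
  res <- data.frame(grid, mean_iou = NA_real_, iou_class0 = NA_real_,
                    iou_class1 = NA_real_)
  best_i <- 1L; best_v <- -Inf
  for (i in seq_len(n)) {
    w <- grid[i, ]
    s0 <- as.numeric(w %*% p0)
    s1 <- as.numeric(w %*% p1)
    pred <- as.numeric(s1 > s0)
    mi <- mean_iou(tt, pred)
    res$mean_iou[i] <- mi$overall
    res$iou_class0[i] <- mi$per_class[1]
    res$iou_class1[i] <- mi$per_class[2]
    if (mi$overall > best_v) { best_v <- mi$overall; best_i <- i }
  }
  list(weights = unname(grid[best_i, ]), score = best_v, table = res)
}

#' Two-tailed paired t-test
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = a - b` (sample standard deviation, `n - 1` denominator) and a
#' two-tailed p-value from the t distribution with `n - 1` degrees of
#' freedom.
#'
#' @param a,b equal-length numeric score vectors (`n >= 2`).
#' @return A list with class `"paired_ttest"`: `t_value`, `p_value`,
#'   `df`, `n`.
#' @export
#' @examples
#' paired_ttest(c(1, 2, 3), c(2, 4, 6))
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least two paired observations")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    stop("paired differences have zero variance; the t statistic is ",
         "undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  structure(list(t_value = t, p_value = 2 * pt(-abs(t), df = n - 1),
                 df = n - 1L, n = n),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4f (two-tailed)\n",
              x$t_value, x$df, x$p_value))
  invisible(x)
}
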