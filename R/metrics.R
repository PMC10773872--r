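#' Jaccard coefficient of two fields
#'
#' `(intersection + smooth) / (union + smooth)` with
#' `intersection = sum(y_true * y_pred)` and
#' `union = sum(y_true) + sum(y_pred) - intersection`.  Accepts hard
#' 0/1 masks or soft probability fields of identical shape; on hard
#' masks this equals the class-1 IoU of the confusion matrix (up to
#' `smooth`).
#'
#' @param y_true,y_pred numeric arrays of identical shape with values
#'   in \[0, 1\].
#' @param smooth small constant avoiding division by zero; also makes
#'   two empty masks score 1.
#' @return Scalar in \[0, 1\].
#' @export
jaccard_coef <- function(y_true, y_pred, smooth = 1e-5) {
  .check_same_shape(y_true, y_pred)
  i <- sum(y_true * y_pred)
  u <- sum(y_true) + sum(y_pred) - i
  (i + smooth) / (u + smooth)
}

#' Dice coefficient of two fields
#'
#' Two forms are provided.  `"conventional"` (default) is the standard
#' Dice score `(2 * intersection + smooth) / (sum(y_true) +
#' sum(y_pred) + smooth)`, bounded by 1.  `"literal"` divides by the
#' *union* (`sum(y_true) + sum(y_pred) - intersection`) instead, a
#' variant that exceeds 1 for overlapping masks (it equals
#' `2 * Jaccard` up to `smooth`); it is retained because some published
#' formulations print it, but conventional Dice is what reported scores
#' of at most 1 imply.
#'
#' @inheritParams jaccard_coef
#' @param mode `"conventional"` or `"literal"`.
#' @return Scalar (in \[0, 1\] for `"conventional"`).
#' @export
dice_coef <- function(y_true, y_pred, smooth = 1e-5,
                      mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  .check_same_shape(y_true, y_pred)
  i <- sum(y_true * y_pred)
  if (mode == "conventional") {
    (2 * i + smooth) / (sum(y_true) + sum(y_pred) + smooth)
  } else {
    u <- sum(y_true) + sum(y_pred) - i
    (2 * i + smooth) / (u + smooth)
  }
}

.check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (length(da) != length(db) || any(da != db)) {
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
  invisible(TRUE)
}

#' One-vs-rest confusion counts per class
#'
#' @param y_true,y_pred integer label fields with values in
#'   `0:(n_classes - 1)`.
#' @param n_classes number of classes (default 2).
#' @return data.frame with one row per class and columns `class`, `tp`,
#'   `fp`, `fn`, `tn`; each row's counts sum to the pixel count.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = 2) {
  .check_same_shape(y_true, y_pred)
  t <- as.integer(y_true); p <- as.integer(y_pred)
  if (any(t < 0 | t >= n_classes) || any(p < 0 | p >= n_classes)) {
    stop("labels must lie in 0..", n_classes - 1)
  }
  do.call(rbind, lapply(seq_len(n_classes) - 1L, function(c) {
    data.frame(class = c,
               tp = sum(t == c & p == c),
               fp = sum(t != c & p == c),
               fn = sum(t == c & p != c),
               tn = sum(t != c & p != c))
  }))
}

#' Mean intersection-over-union
#'
#' Per-class IoU is `tp / (tp + fp + fn)` from one-vs-rest confusion
#' counts; the overall score is the unweighted mean over classes.  A
#' class absent from both fields (empty one-vs-rest table) contributes
#' `absent_score` (default 1, the empty-mask convention).
#'
#' @inheritParams confusion_counts
#' @param absent_score IoU credited to classes absent from both fields.
#' @return List with `overall` (scalar) and `per_class` (numeric vector
#'   of length `n_classes`).
#' @export
mean_iou <- function(y_true, y_pred, n_classes = 2, absent_score = 1) {
  if (length(y_true) == 0) stop("empty input")
  cc <- confusion_counts(y_true, y_pred, n_classes)
  per <- ifelse(cc$tp + cc$fp + cc$fn == 0, absent_score,
                cc$tp / (cc$tp + cc$fp + cc$fn))
  list(overall = mean(per), per_class = per)
}

#' Evaluate one model over a set of patch pairs
#'
#' Aggregates soft Jaccard/Dice and hard mean IoU globally over all
#' pixels of the supplied pairs.
#'
#' @param probs list of probability fields `H x W x 2`.
#' @param masks list of binary truth matrices.
#' @param smooth smoothing constant for the soft metrics.
#' @return Named list: `jaccard`, `dice`, `mean_iou`, `iou_class0`,
#'   `iou_class1`.
#' @export
evaluate_fields <- function(probs, masks, smooth = 1e-5) {
  stopifnot(length(probs) == length(masks), length(probs) >= 1)
  p1 <- unlist(lapply(probs, function(p) as.numeric(p[, , 2])))
  tt <- unlist(lapply(masks, as.numeric))
  hard <- unlist(lapply(probs, function(p) as.numeric(predict_class(p))))
  mi <- mean_iou(tt, hard)
  list(jaccard = jaccard_coef(tt, p1, smooth),
       dice = dice_coef(tt, p1, smooth),
       mean_iou = mi$overall,
       iou_class0 = mi$per_class[1],
       iou_class1 = mi$per_class[2])
}
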