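#' Specify a segmentation model architecture
#'
#' Three families share one encoder-decoder skeleton: `unet` (forward
#' convolutional units, plain skip concatenation), `aunet` (forward
#' units with attention-gated skips), and `arunet` (residual units with
#' attention-gated skips).  Filters double at each encoder level.
#'
#' @param family `"unet"`, `"aunet"` or `"arunet"`.
#' @param depth number of encoder levels including the bottleneck
#'   (>= 2); the input size must be divisible by `2^(depth - 1)`.
#' @param base_filters channel count of the first level.
#' @param input_size input patch side length in pixels.
#' @param seed integer seed for parameter initialization.
#' @param use_bn include batch normalization inside every unit.
#' @return A list with class `"model_spec"`.
#' @export
#' @examples
#' model_spec("arunet", depth = 3, base_filters = 8, input_size = 64)
model_spec <- function(family = c("unet", "aunet", "arunet"), depth = 5,
                       base_filters = 16, input_size = 256, seed = 0,
                       use_bn = TRUE) {
  family <- match.arg(family)
  stopifnot(depth >= 2, base_filters >= 1, input_size >= 4)
  if (input_size %% 2^(depth - 1) != 0) {
    stop("input_size (", input_size, ") must be divisible by 2^(depth-1) = ",
         2^(depth - 1))
  }
  structure(list(family = family, depth = depth,
                 base_filters = base_filters, input_size = input_size,
                 n_classes = 2L, seed = seed, use_bn = use_bn),
            class = "model_spec")
}

#' Build a segmentation model from a specification
#'
#' Initializes all parameters (He-normal convolutions, unit batch-norm
#' scales) deterministically from `spec$seed`: two builds from the same
#' spec are identical.
#'
#' @param spec a [model_spec()].
#' @return A list with class `"seg_model"`: `spec` plus the nested
#'   parameter list.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  f <- spec$base_filters * 2^(seq_len(spec$depth) - 1L)
  unit_init <- if (spec$family == "arunet") res_init else fcu_init
  attn <- spec$family %in% c("aunet", "arunet")
  ub <- spec$use_bn
  params <- list(enc = list(), dec = list())
  cin <- 3L
  for (l in seq_len(spec$depth - 1L)) {
    params$enc[[l]] <- unit_init(cin, f[l], ub)
    cin <- f[l]
  }
  params$bott <- unit_init(cin, f[spec$depth], ub)
  for (l in rev(seq_len(spec$depth - 1L))) {
    lev <- list(up = upc_init(f[l + 1L], f[l], ub),
                unit = unit_init(2L * f[l], f[l], ub))
    if (attn) lev$ag <- ag_init(f[l], f[l + 1L])
    params$dec[[l]] <- lev
  }
  params$head <- .he_conv(1, f[1L], 2L)
  structure(list(spec = spec, params = params), class = "seg_model")
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar (convolution weights and biases,
#' batch-norm scales and shifts); batch-norm running moments are
#' excluded.
#'
#' @param model a `seg_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

# Full forward pass.  Returns probabilities, logits, the cache stack for
# backward, and the (possibly BN-updated) parameter tree.
model_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  pm <- model$params
  ub <- spec$use_bn
  attn <- spec$family %in% c("aunet", "arunet")
  unit_fw <- if (spec$family == "arunet") res_fw else fcu_fw
  caches <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  h <- x
  for (l in seq_len(spec$depth - 1L)) {
    u <- unit_fw(h, pm$enc[[l]], training, ub)
    pm$enc[[l]] <- u$pm
    caches$enc[[l]] <- u$cache
    skips[[l]] <- u$y
    p <- maxpool_fw(u$y)
    caches$pool[[l]] <- p$cache
    h <- p$y
  }
  u <- unit_fw(h, pm$bott, training, ub)
  pm$bott <- u$pm
  caches$bott <- u$cache
  h <- u$y
  for (l in rev(seq_len(spec$depth - 1L))) {
    lev <- pm$dec[[l]]
    cc <- list()
    if (attn) {
      g <- ag_fw(skips[[l]], h, lev$ag)
      cc$ag <- g$cache
      sk <- g$y
    } else {
      sk <- skips[[l]]
    }
    up <- upc_fw(h, lev$up, training, ub)
    lev$up <- up$pm
    cc$up <- up$cache
    cn <- concat_fw(sk, up$y)
    cc$concat <- cn$cache
    u <- unit_fw(cn$y, lev$unit, training, ub)
    lev$unit <- u$pm
    cc$unit <- u$cache
    pm$dec[[l]] <- lev
    caches$dec[[l]] <- cc
    h <- u$y
  }
  hd <- conv_fw(h, pm$head)
  caches$head <- hd$cache
  probs <- softmax2_fw(hd$y)
  list(probs = probs, logits = hd$y, caches = caches, params = pm)
}

# Backward pass from dL/dlogits; returns the gradient tree.
model_backward <- function(model, caches, dlogits) {
  spec <- model$spec
  ub <- spec$use_bn
  attn <- spec$family %in% c("aunet", "arunet")
  unit_bw <- if (spec$family == "arunet") res_bw else fcu_bw
  grads <- list(enc = vector("list", spec$depth - 1L),
                dec = vector("list", spec$depth - 1L))
  hd <- conv_bw(caches$head, dlogits)
  grads$head <- hd$grads
  d <- hd$dx
  dskips <- vector("list", spec$depth - 1L)
  for (l in seq_len(spec$depth - 1L)) {
    cc <- caches$dec[[l]]
    g <- list()
    u <- unit_bw(cc$unit, d, ub)
    g$unit <- u$grads
    sp <- concat_bw(cc$concat, u$dx)
    up <- upc_bw(cc$up, sp$db, ub)
    g$up <- up$grads
    if (attn) {
      ag <- ag_bw(cc$ag, sp$da)
      g$ag <- ag$grads
      dskips[[l]] <- ag$dskip
      d <- up$dx + ag$dgate
    } else {
      dskips[[l]] <- sp$da
      d <- up$dx
    }
    grads$dec[[l]] <- g
  }
  u <- unit_bw(caches$bott, d, ub)
  grads$bott <- u$grads
  d <- u$dx
  for (l in rev(seq_len(spec$depth - 1L))) {
    d <- maxpool_bw(caches$pool[[l]], d) + dskips[[l]]
    u <- unit_bw(caches$enc[[l]], d, ub)
    grads$enc[[l]] <- u$grads
    d <- u$dx
  }
  grads
}

#' Predict class probabilities for one image patch
#'
#' Runs the full forward pass in inference mode (batch-norm running
#' statistics) and returns the per-pixel two-class softmax output.
#'
#' @param model a trained or freshly built `seg_model`.
#' @param image RGB array `H x W x 3` in \[0, 1\] (values in \[0, 255\]
#'   are rescaled), with `H = W = spec$input_size`.
#' @return Probability array `H x W x 2`; each pixel's two entries sum
#'   to 1.
#' @export
predict_patch <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  sz <- model$spec$input_size
  d <- dim(image)
  if (length(d) != 3 || d[1] != sz || d[2] != sz || d[3] != 3) {
    stop("expected a ", sz, "x", sz, "x3 image, got ",
         paste(d, collapse = "x"))
  }
  if (max(image) > 1) image <- image / 255
  x <- array(image, c(sz, sz, 3, 1))
  fw <- model_forward(model, x, training = FALSE)
  array(fw$probs, c(sz, sz, 2))
}

#' Hard class labels from a probability field
#'
#' Per-pixel argmax over the two channels; exact ties resolve to class
#' 0 (benign).  Since softmax is monotone, this equals the argmax of
#' the underlying logits.
#'
#' @param field probability array `H x W x 2`.
#' @return Integer matrix of 0/1 labels.
#' @export
predict_class <- function(field) {
  stopifnot(length(dim(field)) == 3, dim(field)[3] == 2)
  m <- (field[, , 2] > field[, , 1]) * 1L
  matrix(as.integer(m), dim(field)[1], dim(field)[2])
}

#' Save and load model checkpoints
#'
#' The checkpoint is an RDS of the full model plus a JSON sidecar
#' recording the architecture specification.
#'
#' @param model a `seg_model`.
#' @param path checkpoint path (`.rds`); the sidecar is written next to
#'   it with extension `.json`.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(unclass(model$spec), side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "seg_model"))
  m
}
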