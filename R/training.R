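#' Training configuration
#'
#' Mirrors the training regime used throughout the package: Adam with
#' an initial learning rate of 1e-4, up to 100 epochs, and learning-rate
#' reduction on a validation-Jaccard plateau.
#'
#' @param learning_rate initial Adam learning rate.
#' @param epochs maximum number of epochs.
#' @param batch_size patches per gradient step.
#' @param lr_factor multiplicative learning-rate reduction in (0, 1).
#' @param lr_patience epochs without validation-Jaccard improvement
#'   before the rate is reduced.
#' @param min_lr floor for the learning rate.
#' @param seed integer seed controlling shuffling.
#' @param shuffle reshuffle the training order every epoch.
#' @return A list with class `"training_config"`.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 100,
                            batch_size = 16, lr_factor = 0.5,
                            lr_patience = 5, min_lr = 1e-6, seed = 0,
                            shuffle = TRUE) {
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 1,
            lr_factor > 0, lr_factor < 1, lr_patience >= 1, min_lr > 0)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, lr_factor = lr_factor,
                 lr_patience = lr_patience, min_lr = min_lr, seed = seed,
                 shuffle = shuffle, monitor = "val_jaccard"),
            class = "training_config")
}

#' On-the-fly batch generator over a manifest split
#'
#' Streams `(image, mask)` batches from a patch dataset on disk.
#' Images are normalized to \[0, 1\]; masks are delivered as the
#' two-channel complementary one-hot encoding matching the softmax
#' head (channel sums are 1 at every pixel).  Every pair is visited
#' exactly once per epoch; with `shuffle = TRUE` the order is a seeded
#' permutation redrawn (reproducibly) at every [reset][make_generator].
#'
#' @param manifest manifest data.frame (columns `image_path`,
#'   `mask_path`, optionally filtered to one `split`).
#' @param dir directory paths are relative to; defaults to
#'   `attr(manifest, "dir")`.
#' @param batch_size patches per batch; the final batch of an epoch may
#'   be smaller.
#' @param shuffle permute order each epoch.
#' @param seed seed for the shuffle stream.
#' @param cache preload all pairs into memory (default) instead of
#'   re-reading files at every epoch.
#' @return A list with class `"patch_generator"`: `n`, `n_batches`,
#'   `next_batch()` (returns `list(x, y)` or `NULL` at epoch end) and
#'   `reset()`.
#' @export
make_generator <- function(manifest, dir = attr(manifest, "dir"),
                           batch_size = 16, shuffle = TRUE, seed = 0,
                           cache = TRUE) {
  if (nrow(manifest) == 0) stop("empty manifest")
  paths_i <- file.path(dir, manifest$image_path)
  paths_m <- file.path(dir, manifest$mask_path)
  missing <- c(paths_i, paths_m)[!file.exists(c(paths_i, paths_m))]
  if (length(missing)) {
    stop("missing patch file(s): ", paste(head(missing, 3), collapse = ", "))
  }
  n <- nrow(manifest)
  env <- new.env(parent = emptyenv())
  env$pos <- 0L
  env$order <- seq_len(n)
  env$rng <- NULL
  if (cache) {
    env$imgs <- lapply(paths_i, read_image)
    env$masks <- lapply(paths_m, read_mask)
  }
  load_pair <- function(i) {
    if (cache) list(img = env$imgs[[i]], mask = env$masks[[i]])
    else list(img = read_image(paths_i[i]), mask = read_mask(paths_m[i]))
  }
  reset <- function() {
    env$pos <- 0L
    if (shuffle) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      if (is.null(env$rng)) {
        set.seed(seed)
      } else {
        assign(".Random.seed", env$rng, envir = globalenv())
      }
      env$order <- sample.int(n)
      env$rng <- get(".Random.seed", envir = globalenv())
    }
    invisible(NULL)
  }
  next_batch <- function() {
    if (env$pos >= n) return(NULL)
    take <- env$order[(env$pos + 1L):min(env$pos + batch_size, n)]
    env$pos <- env$pos + length(take)
    first <- load_pair(take[1])
    h <- nrow(first$mask); w <- ncol(first$mask)
    x <- array(0, c(h, w, 3, length(take)))
    y <- array(0, c(h, w, 2, length(take)))
    for (bi in seq_along(take)) {
      pr <- if (bi == 1) first else load_pair(take[bi])
      x[, , , bi] <- pr$img
      m <- pr$mask
      y[, , 1, bi] <- 1 - m
      y[, , 2, bi] <- m
    }
    list(x = x, y = y)
  }
  reset()
  structure(list(n = n, n_batches = ceiling(n / batch_size),
                 batch_size = batch_size, next_batch = next_batch,
                 reset = reset),
            class = "patch_generator")
}

#' Learning-rate reduction on a validation plateau
#'
#' If the monitored validation Jaccard has not improved for
#' `lr_patience` epochs (the best value lies `lr_patience` or more
#' epochs back), the rate is multiplied by `lr_factor`, floored at
#' `min_lr`; otherwise it is unchanged.
#'
#' @param val_jaccard numeric vector of per-epoch validation Jaccard
#'   scores observed so far (most recent last); improvement resets the
#'   plateau count.
#' @param current_lr current learning rate.
#' @param config a [training_config()].
#' @return The new learning rate.
#' @export
reduce_lr_on_plateau <- function(val_jaccard, current_lr,
                                 config = training_config()) {
  stopifnot(length(val_jaccard) >= 1)
  since_best <- length(val_jaccard) - which.max(val_jaccard)
  if (since_best >= config$lr_patience) {
    max(current_lr * config$lr_factor, config$min_lr)
  } else {
    current_lr
  }
}

# evaluate a model over a generator; returns loss + soft metrics
# aggregated globally over all pixels
.eval_stream <- function(model, gen, lconfig) {
  gen$reset()
  p1 <- list(); tt <- list(); losses <- numeric(0); ns <- numeric(0)
  repeat {
    b <- gen$next_batch()
    if (is.null(b)) break
    fw <- model_forward(model, b$x, training = FALSE)
    losses <- c(losses, total_loss(b$y, fw$probs, lconfig))
    ns <- c(ns, dim(b$x)[4])
    p1[[length(p1) + 1L]] <- as.numeric(fw$probs[, , 2, ])
    tt[[length(tt) + 1L]] <- as.numeric(b$y[, , 2, ])
  }
  p1 <- unlist(p1); tt <- unlist(tt)
  list(loss = sum(losses * ns) / sum(ns),
       jaccard = jaccard_coef(tt, p1),
       dice = dice_coef(tt, p1),
       mean_iou = mean_iou(tt, as.numeric(p1 > 0.5))$overall)
}

#' Train a segmentation model
#'
#' Minimizes the composite Dice + binary focal objective with Adam,
#' evaluating validation Jaccard and Dice after every epoch, reducing
#' the learning rate on plateaus, and returning the parameters from the
#' epoch with the best validation Jaccard.
#'
#' @param model a freshly built (or partially trained) `seg_model`.
#' @param train_gen,val_gen [make_generator()] streams.
#' @param tconfig a [training_config()].
#' @param lconfig a [loss_config()].
#' @param verbose print one line per epoch.
#' @return List: `model` (best checkpoint), `history` (one row per
#'   epoch: `epoch`, `loss`, `jaccard`, `dice`, `val_loss`,
#'   `val_jaccard`, `val_dice`, `lr`), `final_model`.
#' @export
train_model <- function(model, train_gen, val_gen,
                        tconfig = training_config(),
                        lconfig = loss_config(), verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"),
            inherits(train_gen, "patch_generator"))
  opt <- adam_init(lr = tconfig$learning_rate)
  lr <- tconfig$learning_rate
  hist <- list()
  best <- list(val_jaccard = -Inf, model = model)
  wait <- 0L
  for (ep in seq_len(tconfig$epochs)) {
    train_gen$reset()
    ep_loss <- numeric(0); ep_n <- numeric(0)
    p1 <- list(); tt <- list()
    repeat {
      b <- train_gen$next_batch()
      if (is.null(b)) break
      fw <- model_forward(model, b$x, training = TRUE)
      model$params <- fw$params
      l <- total_loss(b$y, fw$probs, lconfig)
      if (!is.finite(l)) {
        stop("non-finite training loss at epoch ", ep,
             "; check learning rate and inputs")
      }
      ep_loss <- c(ep_loss, l); ep_n <- c(ep_n, dim(b$x)[4])
      p1[[length(p1) + 1L]] <- as.numeric(fw$probs[, , 2, ])
      tt[[length(tt) + 1L]] <- as.numeric(b$y[, , 2, ])
      dP <- total_loss_grad(b$y, fw$probs, lconfig)
      dZ <- softmax2_bw(fw$probs, dP)
      grads <- model_backward(model, fw$caches, dZ)
      opt$lr <- lr
      model$params <- adam_step(model$params, grads, opt)
    }
    vp1 <- unlist(p1); vtt <- unlist(tt)
    val <- .eval_stream(model, val_gen, lconfig)
    hist[[ep]] <- data.frame(
      epoch = ep,
      loss = sum(ep_loss * ep_n) / sum(ep_n),
      jaccard = jaccard_coef(vtt, vp1),
      dice = dice_coef(vtt, vp1),
      val_loss = val$loss,
      val_jaccard = val$jaccard,
      val_dice = val$dice,
      lr = lr)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  val_loss %.4f  val_jacc %.4f  lr %.2g",
        ep, hist[[ep]]$loss, val$loss, val$jaccard, lr))
    }
    if (val$jaccard > best$val_jaccard) {
      best$val_jaccard <- val$jaccard
      best$model <- model
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= tconfig$lr_patience) {
      lr <- max(lr * tconfig$lr_factor, tconfig$min_lr)
      wait <- 0L
    }
  }
  list(model = best$model, history = do.call(rbind, hist),
       final_model = model)
}
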