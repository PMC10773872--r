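test_that("generator partitions each epoch exactly once", {
  man <- tiny_dataset()
  tr <- man[man$split == "train", ][1:10, ]
  gen <- make_generator(tr, batch_size = 4, shuffle = TRUE, seed = 1)
  expect_equal(gen$n, 10)
  expect_equal(gen$n_batches, 3)
  sizes <- c(); sums <- c()
  repeat {
    b <- gen$next_batch()
    if (is.null(b)) break
    sizes <- c(sizes, dim(b$x)[4])
    sums <- c(sums, apply(b$x, 4, sum))
    # one-hot mask channels sum to 1 at every pixel
    expect_true(all(abs(b$y[, , 1, ] + b$y[, , 2, ] - 1) < 1e-12))
  }
  expect_equal(sizes, c(4, 4, 2))
  # every pair visited exactly once: image checksums match the files
  ref <- vapply(file.path(attr(man, "dir"), tr$image_path),
                function(p) sum(read_image(p)), numeric(1))
  expect_equal(sort(sums), sort(unname(ref)), tolerance = 1e-9)
})

test_that("generator order is seed-reproducible and epoch-varying", {
  man <- tiny_dataset()
  tr <- man[man$split == "train", ]
  first_epoch <- function(seed) {
    gen <- make_generator(tr, batch_size = 4, shuffle = TRUE, seed = seed)
    out <- list()
    repeat {
      b <- gen$next_batch()
      if (is.null(b)) break
      out[[length(out) + 1]] <- b$x
    }
    out
  }
  expect_identical(first_epoch(5), first_epoch(5))
  expect_false(identical(first_epoch(5), first_epoch(6)))
  # consecutive epochs reshuffle deterministically
  gen <- make_generator(tr, batch_size = 16, shuffle = TRUE, seed = 5)
  e1 <- gen$next_batch()$x
  gen$reset()
  e2 <- gen$next_batch()$x
  expect_false(identical(e1, e2))
})

test_that("missing files are reported by path", {
  man <- tiny_dataset()
  bad <- man[man$split == "train", ][1:2, ]
  bad$image_path[1] <- "does-not-exist.png"
  expect_error(make_generator(bad, dir = attr(man, "dir")),
               "does-not-exist.png")
})

test_that("plateau schedule reduces the rate as documented", {
  cfg <- training_config(lr_factor = 0.5, lr_patience = 3, min_lr = 1e-6)
  # monotone improvement: unchanged
  expect_equal(reduce_lr_on_plateau(c(0.1, 0.2, 0.3, 0.4), 1e-4, cfg), 1e-4)
  # flat for patience epochs: halved
  expect_equal(reduce_lr_on_plateau(c(0.5, 0.5, 0.5, 0.5), 1e-4, cfg), 5e-5)
  # improvement resets the plateau
  expect_equal(reduce_lr_on_plateau(c(0.5, 0.5, 0.6, 0.6, 0.6), 1e-4, cfg),
               1e-4)
  # never below the floor
  expect_equal(reduce_lr_on_plateau(rep(0.5, 10), 1.5e-6, cfg), 1e-6)
})

test_that("zero learning rate leaves parameters untouched", {
  man <- tiny_dataset()
  tr <- man[man$split == "train", ][1:8, ]
  va <- man[man$split == "val", ]
  gen <- make_generator(tr, batch_size = 4, seed = 1)
  vgen <- make_generator(va, batch_size = 4, shuffle = FALSE, seed = 1)
  m <- build_model(model_spec("unet", depth = 2, base_filters = 4,
                              input_size = 32, seed = 1))
  before <- glandseg:::flatten_params(m$params)
  fit <- train_model(m, gen, vgen,
                     training_config(learning_rate = 0, epochs = 1,
                                     batch_size = 4))
  after <- glandseg:::flatten_params(fit$final_model$params)
  expect_identical(before, after)
})

test_that("training runs its epochs, improves, and tracks the best", {
  man <- tiny_dataset()
  tr <- man[man$split == "train", ]
  va <- man[man$split == "val", ]
  gen <- make_generator(tr, batch_size = 8, seed = 2)
  vgen <- make_generator(va, batch_size = 8, shuffle = FALSE, seed = 2)
  m <- build_model(model_spec("arunet", depth = 3, base_filters = 4,
                              input_size = 32, seed = 2))
  fit <- train_model(m, gen, vgen,
                     training_config(epochs = 3, batch_size = 8),
                     loss_config())
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_equal(h$epoch, 1:3)
  expect_true(all(diff(h$lr) <= 0))
  expect_gt(h$val_jaccard[3], h$val_jaccard[1])
  # best-checkpoint selection: re-evaluating the returned model gives
  # the maximum recorded validation Jaccard
  best <- glandseg:::.eval_stream(fit$model, vgen, loss_config())
  expect_equal(best$jaccard, max(h$val_jaccard), tolerance = 1e-9)
})

test_that("checkpoints round-trip through disk with their sidecar", {
  m <- build_model(model_spec("aunet", depth = 2, base_filters = 4,
                              input_size = 32, seed = 3))
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  side <- jsonlite::read_json(sub("rds$", "json", path))
  expect_equal(side$family, "aunet")
})
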