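test_that("all three families honour the output-shape contract", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (fam in c("unet", "aunet", "arunet")) {
    m <- build_model(model_spec(fam, depth = 3, base_filters = 4,
                                input_size = 64, seed = 1))
    p <- predict_patch(m, img)
    expect_equal(dim(p), c(64, 64, 2))
    expect_true(all(p >= 0 & p <= 1))
    expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-6)
  }
})

test_that("indivisible input sizes and size mismatches are rejected", {
  expect_error(model_spec("unet", depth = 4, input_size = 100),
               "divisible")
  m <- build_model(model_spec("unet", depth = 2, base_filters = 4,
                              input_size = 32, seed = 1))
  expect_error(predict_patch(m, array(0.5, c(64, 64, 3))), "32x32x3")
})

test_that("parameter initialization is seed-deterministic", {
  s <- model_spec("arunet", depth = 3, base_filters = 4, input_size = 32,
                  seed = 9)
  expect_identical(build_model(s)$params, build_model(s)$params)
  s2 <- model_spec("arunet", depth = 3, base_filters = 4, input_size = 32,
                   seed = 10)
  expect_false(identical(build_model(s)$params, build_model(s2)$params))
})

test_that("parameter counts order as arunet > aunet > unet and are stable", {
  counts <- vapply(c("unet", "aunet", "arunet"), function(fam) {
    count_params(build_model(model_spec(fam, depth = 3, base_filters = 8,
                                        input_size = 64, seed = 1)))
  }, numeric(1))
  expect_gt(counts["aunet"], counts["unet"])
  expect_gt(counts["arunet"], counts["aunet"])
  again <- count_params(build_model(model_spec("arunet", depth = 3,
                                               base_filters = 8,
                                               input_size = 64, seed = 5)))
  expect_equal(unname(counts["arunet"]), again)
})

test_that("forward conv unit preserves shape, clamps at zero, zeroes out", {
  ns <- asNamespace("glandseg")
  withr::with_seed(3, {
    pm <- ns$fcu_init(3, 16, use_bn = FALSE)
    x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    out <- ns$fcu_fw(x, pm, training = FALSE, use_bn = FALSE)
    expect_equal(dim(out$y), c(32, 32, 16, 2))
    expect_true(all(out$y >= 0))
    pm0 <- rapply(pm, function(a) a * 0, how = "replace")
    out0 <- ns$fcu_fw(x, pm0, training = FALSE, use_bn = FALSE)
    expect_true(all(out0$y == 0))
  })
})

test_that("residual unit is the identity when its conv path is zeroed", {
  ns <- asNamespace("glandseg")
  withr::with_seed(4, {
    pm <- ns$res_init(8, 8, use_bn = TRUE)
    pm$conv1$W[] <- 0; pm$conv1$b[] <- 0
    pm$conv2$W[] <- 0; pm$conv2$b[] <- 0
    x <- array(abs(rnorm(16 * 16 * 8 * 2)), c(16, 16, 8, 2))
    out <- ns$res_fw(x, pm, training = TRUE, use_bn = TRUE)
    expect_equal(out$y, x, tolerance = 1e-12)
  })
})

test_that("residual unit with changed width uses a projection shortcut", {
  ns <- asNamespace("glandseg")
  withr::with_seed(5, {
    pm <- ns$res_init(16, 32, use_bn = FALSE)
    expect_false(is.null(pm$proj))
    x <- array(rnorm(32 * 32 * 16), c(32, 32, 16, 1))
    out <- ns$res_fw(x, pm, training = FALSE, use_bn = FALSE)
    expect_equal(dim(out$y), c(32, 32, 32, 1))
    # independent recomputation: conv path + projected shortcut, ReLU'd
    c1 <- ns$conv_fw(x, pm$conv1)$y
    c1[c1 < 0] <- 0
    main <- ns$conv_fw(c1, pm$conv2)$y
    short <- ns$conv_fw(x, pm$proj)$y
    ref <- main + short
    ref[ref < 0] <- 0
    expect_equal(out$y, ref, tolerance = 1e-12)
  })
})

test_that("matched-width residual unit adds an identity shortcut", {
  ns <- asNamespace("glandseg")
  withr::with_seed(6, {
    pm <- ns$res_init(8, 8, use_bn = FALSE)
    x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
    out <- ns$res_fw(x, pm, training = FALSE, use_bn = FALSE)
    c1 <- ns$conv_fw(x, pm$conv1)$y
    c1[c1 < 0] <- 0
    ref <- ns$conv_fw(c1, pm$conv2)$y + x
    ref[ref < 0] <- 0
    expect_equal(out$y, ref, tolerance = 1e-12)
  })
})

test_that("attention gate bounds, pass-through and multiplicative zeroing", {
  ns <- asNamespace("glandseg")
  withr::with_seed(7, {
    pm <- ns$ag_init(8, 16)
    # coefficients in [0, 1] over many random inputs
    n_coef <- 0L
    for (trial in 1:16) {
      skip <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
      gate <- array(rnorm(4 * 4 * 16), c(4, 4, 16, 1))
      out <- ns$ag_fw(skip, gate, pm)
      expect_true(all(out$alpha >= 0 & out$alpha <= 1))
      n_coef <- n_coef + length(out$alpha)
    }
    expect_gte(n_coef, 1000)
    # psi bias pushed high -> alpha ~ 1 -> pass-through
    pm1 <- pm
    pm1$psi$W[] <- 0
    pm1$psi$b[] <- 50
    skip <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
    gate <- array(rnorm(4 * 4 * 16), c(4, 4, 16, 1))
    out1 <- ns$ag_fw(skip, gate, pm1)
    expect_equal(out1$y, skip, tolerance = 1e-10)
    # zero skip -> zero output regardless of the gate
    out0 <- ns$ag_fw(skip * 0, gate, pm)
    expect_true(all(out0$y == 0))
    # wrong spatial relation is rejected
    expect_error(ns$ag_fw(skip, array(0, c(8, 8, 16, 1)), pm),
                 "half the skip")
  })
})

test_that("softmax head matches the closed form", {
  ns <- asNamespace("glandseg")
  z <- array(0, c(1, 1, 2, 1))
  expect_equal(as.numeric(ns$softmax2_fw(z)), c(0.5, 0.5))
  z[1, 1, , 1] <- c(1, 2)
  p <- as.numeric(ns$softmax2_fw(z))
  expect_equal(p, c(0.26894, 0.73106), tolerance = 1e-5)
  # argmax(softmax(z)) == argmax(z) on random logits
  withr::with_seed(8, {
    zz <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
    pp <- ns$softmax2_fw(zz)
    expect_identical(pp[, , 2, 1] > pp[, , 1, 1], zz[, , 2, 1] > zz[, , 1, 1])
  })
})

test_that("constant input yields near-constant output away from borders", {
  img <- array(0.6, c(64, 64, 3))
  for (fam in c("unet", "aunet", "arunet")) {
    m <- build_model(model_spec(fam, depth = 3, base_filters = 4,
                                input_size = 64, seed = 2))
    p <- predict_patch(m, img)
    # margin 28 keeps every receptive field (including the attention
    # gate's pooled path) clear of the zero-padded borders
    interior <- p[29:36, 29:36, 2]
    expect_lt(max(interior) - min(interior), 1e-4)
  }
})

test_that("gradients reach every trainable parameter in one step", {
  ns <- asNamespace("glandseg")
  for (fam in c("unet", "aunet", "arunet")) {
    m <- build_model(model_spec(fam, depth = 3, base_filters = 4,
                                input_size = 32, seed = 3))
    withr::with_seed(11, {
      x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
      lab <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
    })
    y <- array(0, c(32, 32, 2, 4))
    for (b in 1:4) { y[, , 1, b] <- 1 - lab; y[, , 2, b] <- lab }
    fw <- ns$model_forward(m, x, training = TRUE)
    dP <- total_loss_grad(y, fw$probs, loss_config())
    dZ <- ns$softmax2_bw(fw$probs, dP)
    gr <- ns$model_backward(m, fw$caches, dZ)
    flat <- ns$flatten_params(gr)
    expect_identical(sort(names(flat)),
                     sort(names(ns$flatten_params(m$params))))
    dead <- names(flat)[vapply(flat, function(g) all(g == 0), logical(1))]
    expect_length(dead, 0)
  }
})
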