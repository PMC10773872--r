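test_that("mean-ensemble closed forms", {
  f1 <- rand_prob_field(4, 4, seed = 1)
  expect_identical(ensemble_probs(list(f1)), f1)
  mk <- function(p1) array(c(1 - p1, p1), c(1, 1, 2))
  me <- ensemble_probs(list(mk(0.4), mk(0.6), mk(0.9)))
  expect_equal(as.numeric(me), c(0.36667, 0.63333), tolerance = 1e-5)
  expect_equal(ensemble_probs(list(f1, f1, f1)), f1)
  expect_error(ensemble_probs(list(f1, rand_prob_field(5, 5, 2))),
               "shape mismatch")
})

test_that("weighted ensemble degeneracies and the reported weight tuple", {
  mk <- function(p1) array(c(1 - p1, p1), c(1, 1, 2))
  fields <- list(mk(0.4), mk(0.6), mk(0.9))
  # the published best ratios 0.0 / 0.2 / 0.4 normalize to (0, 1/3, 2/3)
  w <- weighted_ensemble_probs(fields, c(0.0, 0.2, 0.4))
  expect_equal(as.numeric(w), c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(predict_class(w)[1, 1], 1L)
  # one-hot weights reproduce that model's field exactly
  f <- lapply(1:3, function(s) rand_prob_field(6, 6, seed = s))
  expect_identical(weighted_ensemble_probs(f, c(1, 0, 0)), f[[1]])
  # uniform weights equal the plain mean ensemble
  expect_equal(weighted_ensemble_probs(f, c(2, 2, 2)), ensemble_probs(f),
               tolerance = 1e-15)
  expect_error(weighted_ensemble_probs(f, c(0, 0, 0)), "zero")
  expect_error(weighted_ensemble_probs(f, c(1, -1, 1)), "non-negative")
})

test_that("argmax is invariant to positive weight rescaling", {
  f <- lapply(1:3, function(s) rand_prob_field(10, 10, seed = 10 + s))
  w <- c(0.2, 0.5, 0.3)
  a <- predict_class(weighted_ensemble_probs(f, w))
  b <- predict_class(weighted_ensemble_probs(f, w * 7.3))
  expect_identical(a, b)
})

test_that("ties in predict_class resolve to the benign class", {
  f <- array(0.5, c(2, 2, 2))
  expect_true(all(predict_class(f) == 0L))
  f[1, 1, ] <- c(0.2, 0.8)
  expect_equal(predict_class(f)[1, 1], 1L)
})

test_that("grid search matches an independent exhaustive evaluation", {
  # two synthetic "models": near-perfect vs uninformative
  masks <- lapply(1:4, function(s) rand_mask(12, 12, 0.45, seed = s))
  good <- lapply(masks, function(m) {
    f <- onehot(m)
    0.9 * f + 0.05 # confident and correct
  })
  noisy <- lapply(seq_along(masks), function(i) rand_prob_field(12, 12,
                                                                seed = 50 + i))
  gs <- grid_search_weights(list(good, noisy), masks, step = 0.2)
  # the 0.2 lattice over 2 models has 6^2 - 1 = 35 admissible tuples
  expect_equal(nrow(gs$table), 35)
  expect_equal(gs$score, max(gs$table$mean_iou))

  # independent oracle: enumerate every tuple with plain loops
  levs <- seq(0, 1, by = 0.2)
  best <- NULL; best_v <- -Inf
  for (w1 in levs) for (w2 in levs) {
    if (w1 + w2 == 0) next
    sc <- local({
      preds <- lapply(seq_along(masks), function(i) {
        p <- weighted_ensemble_probs(list(good[[i]], noisy[[i]]), c(w1, w2))
        predict_class(p)
      })
      mean_iou(unlist(masks), unlist(preds))$overall
    })
    if (sc > best_v + 1e-12) { best_v <- sc; best <- c(w1, w2) }
  }
  expect_equal(gs$weights, best, tolerance = 1e-12)
  expect_equal(gs$score, best_v, tolerance = 1e-12)
  # the selected tuple favors the informative model
  expect_gt(gs$weights[1], gs$weights[2])

  # single model: every tuple is equivalent after normalization
  gs1 <- grid_search_weights(list(good), masks, step = 0.2)
  expect_equal(length(gs1$weights), 1)
  expect_equal(nrow(gs1$table), 5)
  expect_error(grid_search_weights(list(good), masks, step = 0.3),
               "divide")
})

test_that("paired t-test matches the hand-computed example", {
  r <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t_value, -3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  # swapping the arguments negates t, keeps p
  r2 <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t_value, -r$t_value)
  expect_equal(r2$p_value, r$p_value)
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_ttest(1, 2), "at least two")
})

test_that("paired t-test agrees with the reference implementation", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(3:12, 1)
      a <- rnorm(n)
      b <- rnorm(n)
    })
    r <- paired_ttest(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(r$t_value, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(r$df, unname(ref$parameter))
  }
})
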