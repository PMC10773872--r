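test_that("binarization maps exactly GP3 and GP4 to the malignant class", {
  expect_true(all(binarize_mask(matrix(label_code("N"), 5, 5)) == 0L))
  half <- matrix(c(rep(label_code("GP3"), 50), rep(label_code("GP4"), 50)),
                 10, 10)
  expect_true(all(binarize_mask(half) == 1L))
  mixed <- matrix(label_code("Bg"), 10, 10)
  mixed[1:30] <- label_code("GP3")
  expect_equal(sum(binarize_mask(mixed)), 30)
  # every non-GP3/GP4 label maps to benign (one N pixel keeps the raster
  # distinguishable from an already-binary mask)
  for (nm in c("Bg", "Fg", "N", "GP5", "L", "NE", "NS", "PIN", "Blood")) {
    r <- matrix(label_code(nm), 3, 3)
    r[1, 1] <- label_code("N")
    expect_true(all(binarize_mask(r) == 0L))
  }
  # idempotence on an already-binary mask
  bin <- rand_mask(6, 6, 0.5, seed = 1)
  expect_identical(binarize_mask(bin), binarize_mask(binarize_mask(bin)))
  expect_error(binarize_mask(matrix(11L, 2, 2)), "invalid label")
})

test_that("tissue ratio counts non-white pixels", {
  white <- array(1, c(8, 8, 3))
  expect_equal(tissue_ratio(white), 0)
  pink <- array(rep(c(200, 150, 170) / 255, each = 64), c(8, 8, 3))
  expect_equal(tissue_ratio(pink), 1)
  patch <- array(1, c(64, 64, 3))
  patch[1:32, 1:32, ] <- 0.5 # one 32x32 tissue quadrant
  expect_equal(tissue_ratio(patch), 0.25)
  expect_error(tissue_ratio(array(0, c(0, 0, 3))), "empty")
})

test_that("patch extraction produces the documented grid", {
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  lab <- matrix(0L, 512, 512)
  p4 <- extract_patches(img, lab, 256, 256)
  expect_length(p4, 4)
  expect_equal(t(vapply(p4, function(p) c(p$grid_row, p$grid_col),
                        numeric(2))),
               rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_identical(p4[[4]]$image, img[257:512, 257:512, , drop = FALSE])

  p1 <- extract_patches(img[1:300, 1:300, , drop = FALSE],
                        lab[1:300, 1:300], 256, 256)
  expect_length(p1, 1) # partial border patches dropped

  p9 <- extract_patches(img, lab, 256, 128)
  expect_length(p9, 9) # floor((512-256)/128)+1 = 3 per axis

  expect_error(extract_patches(img, lab, 256, 0), "stride")
  expect_error(extract_patches(img[1:100, 1:100, , drop = FALSE],
                               lab[1:100, 1:100], 256), "exceeds")
})

test_that("quality filtering applies both predicates", {
  mk <- function(img_val, lab_val) {
    list(image = array(img_val, c(16, 16, 3)),
         labels = matrix(lab_val, 16, 16), grid_row = 0, grid_col = 0,
         x = 0, y = 0, slide_id = "s")
  }
  all_bg <- mk(1, label_code("Bg"))
  tissue_n <- mk(0.6, label_code("N"))
  # white image but annotated tissue: fails the tissue-ratio predicate
  white_n <- mk(1, label_code("N"))
  # colored but only Bg/Fg labels: fails the annotated-class predicate
  fg_only <- mk(0.6, label_code("Fg"))
  kept <- filter_patches(list(all_bg, tissue_n, white_n, fg_only))
  expect_length(kept, 1)
  expect_identical(kept[[1]], tissue_n)
  # mask-based ratio mode keeps the white-but-annotated patch
  kept2 <- filter_patches(list(white_n), ratio_on = "mask")
  expect_length(kept2, 1)
  expect_length(filter_patches(list()), 0)
})

test_that("class weights follow inverse-frequency balancing", {
  balanced <- matrix(c(0, 1), 10, 10)
  cw <- compute_class_weights(balanced)
  expect_equal(cw$w0, 1)
  expect_equal(cw$w1, 1)

  m <- matrix(0L, 20, 50) # 1000 pixels
  m[seq_len(250)] <- 1L   # N1 = 250, N0 = 750
  cw <- compute_class_weights(m)
  expect_equal(cw$w0, 1000 / (2 * 750), tolerance = 1e-12)
  expect_equal(cw$w1, 2.0)

  # ratio identity w1/w0 = N0/N1 on random masks
  for (s in 1:5) {
    mm <- rand_mask(12, 12, p = 0.2 + 0.1 * s, seed = s)
    cw <- compute_class_weights(mm)
    expect_equal(cw$w1 / cw$w0, sum(mm == 0) / sum(mm == 1),
                 tolerance = 1e-12)
  }
  expect_error(compute_class_weights(matrix(0L, 4, 4)), "absent")
})

test_that("preprocessing a toy slide writes a coherent manifest", {
  sl <- fixture_slide()
  dir <- file.path(tempdir(), "pp-slide")
  man <- preprocess_slides(sl, dir, patch_size = 64, split = "val")
  kept <- filter_patches(extract_patches(sl$image, sl$labels, 64, 64))
  expect_equal(nrow(man), length(kept))
  expect_true(all(man$split == "val"))
  i <- which.max(man$x + man$y)
  m <- read_mask(file.path(dir, man$mask_path[i]))
  expect_true(all(m %in% c(0L, 1L)))
})
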