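test_that("benign patches have empty masks, malignant styles do not", {
  for (kind in c("benign", "gp3_like", "gp4_like")) {
    pp <- generate_patch_pair(gland_style(kind), size = 64, seed = 1)
    expect_equal(dim(pp$image), c(64, 64, 3))
    expect_equal(dim(pp$mask), c(64, 64))
    expect_true(all(pp$mask %in% c(0L, 1L)))
    if (kind == "benign") {
      expect_true(all(pp$mask == 0L))
    } else {
      expect_gt(sum(pp$mask), 0)
      expect_lt(mean(pp$mask), 1)
    }
  }
})

test_that("patch generation is byte-identical under a fixed seed", {
  a <- generate_patch_pair(gland_style("gp3_like"), size = 64, seed = 1)
  b <- generate_patch_pair(gland_style("gp3_like"), size = 64, seed = 1)
  expect_identical(a, b)
  c <- generate_patch_pair(gland_style("gp3_like"), size = 64, seed = 2)
  expect_false(identical(a$image, c$image))
})

test_that("gp4 patch at 256 px hits its coverage target (counted pixels)", {
  pp <- generate_patch_pair(gland_style("gp4_like"), size = 256, seed = 7)
  frac <- sum(pp$mask == 1L) / length(pp$mask)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  # default gp4 coverage target is 0.40; placement stops once reached
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.5)
})

test_that("patch size below 32 px is rejected", {
  expect_error(generate_patch_pair(gland_style("benign"), size = 16, seed = 1),
               "size")
})

test_that("requested malignant fraction is honoured to +/- 0.1", {
  for (kind in c("gp3_like", "gp4_like")) {
    fr <- vapply(1:100, function(s) {
      mean(generate_patch_pair(gland_style(kind), size = 64, seed = s,
                               coverage = 0.3)$mask)
    }, numeric(1))
    expect_true(all(abs(fr - 0.3) <= 0.1),
                info = paste(kind, "fraction range",
                             paste(round(range(fr), 3), collapse = "-")))
  }
})

test_that("generated patches always pass the tissue-ratio filter", {
  tr <- vapply(1:30, function(s) {
    kind <- c("benign", "gp3_like", "gp4_like")[1 + s %% 3]
    tissue_ratio(generate_patch_pair(gland_style(kind), 64, seed = s)$image)
  }, numeric(1))
  expect_true(all(tr >= 0.2))
})

test_that("toy slide with no cores is all background", {
  sl <- generate_toy_slide(slide_layout(64, 48, cores = list(), seed = 1))
  expect_true(all(sl$labels == label_code("Bg")))
  expect_equal(dim(sl$image), c(48, 64, 3))
})

test_that("a benign core covering 25% of the canvas leaves 75% background", {
  ab <- sqrt(0.25 * 200 * 200 / pi) # ellipse area = quarter canvas
  sl <- generate_toy_slide(slide_layout(200, 200, cores = list(
    list(center = c(100, 100), axes = c(ab, ab), labels = "N")), seed = 3))
  bg_frac <- sum(sl$labels == label_code("Bg")) / length(sl$labels)
  expect_equal(bg_frac, 0.75, tolerance = 0.01)
})

test_that("slide polygons rasterize back to the label raster exactly", {
  sl <- fixture_slide()
  again <- rasterize_annotations(sl$polygons, dim(sl$labels))
  expect_identical(again, sl$labels)
})

test_that("overlapping cores with conflicting labels are rejected by name", {
  expect_error(
    generate_toy_slide(slide_layout(128, 128, cores = list(
      list(center = c(50, 50), axes = c(30, 30), labels = "N"),
      list(center = c(70, 50), axes = c(30, 30), labels = "L")), seed = 1)),
    "cores 1 \\(N\\) and 2 \\(L\\)")
})

test_that("toy slides are deterministic under a fixed layout seed", {
  lay <- slide_layout(96, 96, cores = list(
    list(center = c(48, 48), axes = c(30, 22), labels = c("N", "GP3"))),
    seed = 5)
  expect_identical(generate_toy_slide(lay), generate_toy_slide(lay))
})

test_that("generate_dataset writes consistent splits and reloadable pairs", {
  d0 <- file.path(tempdir(), "ds-empty")
  m0 <- generate_dataset(d0, 0, 0, 0, size = 32, seed = 1)
  expect_equal(nrow(m0), 0)

  dir <- file.path(tempdir(), "ds-small")
  man <- generate_dataset(dir, 8, 2, 2, size = 32, seed = 3)
  expect_equal(nrow(man), 12)
  expect_equal(unname(table(man$split)[c("train", "val", "test")]),
               c(8L, 2L, 2L), ignore_attr = TRUE)
  expect_false(any(duplicated(man$patch_id)))
  # reload losslessly: masks stay binary, rebinarization is a no-op
  for (i in seq_len(nrow(man))) {
    m <- read_mask(file.path(dir, man$mask_path[i]))
    expect_true(all(m %in% c(0L, 1L)))
    expect_identical(binarize_mask(m), m + 0L)
    img <- read_image(file.path(dir, man$image_path[i]))
    expect_true(all(img >= 0 & img <= 1))
  }
})

test_that("datasets are bit-identical for the same seed (file hashes)", {
  d1 <- file.path(tempdir(), "ds-rep1")
  d2 <- file.path(tempdir(), "ds-rep2")
  m1 <- generate_dataset(d1, 4, 2, 0, size = 32, seed = 17)
  m2 <- generate_dataset(d2, 4, 2, 0, size = 32, seed = 17)
  h1 <- unname(tools::md5sum(file.path(d1, sort(c(m1$image_path, m1$mask_path)))))
  h2 <- unname(tools::md5sum(file.path(d2, sort(c(m2$image_path, m2$mask_path)))))
  expect_identical(h1, h2)
})
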