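#' Gland appearance styles for the synthetic patch generator
#'
#' Describes the toy-histology morphology drawn into a synthetic patch.
#' Three kinds mirror the glandular architecture relevant to early
#' prostate adenocarcinoma: `benign` (few large glands with wide open
#' lumina), `gp3_like` (many small discrete gland rings, the hallmark of
#' Gleason pattern 3), and `gp4_like` (fused gland blobs built as unions
#' of overlapping ellipses, as in Gleason pattern 4).
#'
#' `crowding` controls nuclear density in the epithelium: higher values
#' darken the epithelial tone and add speckle, emulating the
#' hyperchromatic, crowded nuclei of malignant glands.
#'
#' @param kind one of `"benign"`, `"gp3_like"`, `"gp4_like"`.
#' @param lumen_radius_px lumen radius in pixels (> 0).
#' @param ring_thickness_px epithelial ring thickness in pixels (> 0).
#' @param crowding nuclear crowding fraction in \[0, 1\].
#' @return A list with class `"gland_style"`.
#' @export
#' @examples
#' gland_style("gp3_like")
gland_style <- function(kind = c("benign", "gp3_like", "gp4_like"),
                        lumen_radius_px = NULL,
                        ring_thickness_px = NULL,
                        crowding = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    benign   = list(lumen = 9.0, ring = 3.5, crowd = 0.20),
    gp3_like = list(lumen = 2.5, ring = 2.5, crowd = 0.60),
    gp4_like = list(lumen = 1.5, ring = 2.0, crowd = 0.85)
  )[[kind]]
  lumen <- if (is.null(lumen_radius_px)) defaults$lumen else lumen_radius_px
  ring  <- if (is.null(ring_thickness_px)) defaults$ring else ring_thickness_px
  crowd <- if (is.null(crowding)) defaults$crowd else crowding
  if (lumen <= 0 || ring <= 0) stop("gland radii must be positive")
  if (crowd < 0 || crowd > 1) stop("crowding must lie in [0, 1]")
  structure(list(kind = kind, lumen_radius_px = lumen,
                 ring_thickness_px = ring, crowding = crowd),
            class = "gland_style")
}

# Stylized H&E palette (sRGB in [0, 1]).  Realism is a non-goal: the
# generator provides structure (rings, fused blobs, stroma, lumina) and
# an appearance gradient with nuclear crowding, not stain fidelity.
.palette <- list(
  stroma     = c(0.91, 0.75, 0.82),
  epithelium = c(0.62, 0.45, 0.70),
  nucleus    = c(0.38, 0.24, 0.50),
  lumen      = c(0.97, 0.96, 0.97)
)

# epithelial tone darkens with nuclear crowding
.epithelium_color <- function(crowding) .palette$epithelium * (1 - 0.35 * crowding)

# Paint a disk/annulus gland into image (H x W x 3) and return the
# logical gland footprint.  Vectorized over the gland bounding box.
.draw_gland <- function(img, cx, cy, lumen, ring, ax_ratio, rot, crowding) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r_out <- lumen + ring
  half <- ceiling(r_out * max(1, ax_ratio)) + 1L
  rows <- max(1L, floor(cy - half)):min(h, ceiling(cy + half))
  cols <- max(1L, floor(cx - half)):min(w, ceiling(cx + half))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(rot); st <- sin(rot)
  # rotated elliptical radius
  u <- outer(dy, dx, function(a, b) (b * ct + a * st))
  v <- outer(dy, dx, function(a, b) (-b * st + a * ct))
  rr <- sqrt((u / ax_ratio)^2 + v^2)
  inside <- rr <= r_out
  in_lumen <- rr <= lumen
  in_ring <- inside & !in_lumen
  epi <- .epithelium_color(crowding)
  for (ch in 1:3) {
    sl <- img[rows, cols, ch]
    sl[in_ring] <- epi[ch]
    sl[in_lumen] <- .palette$lumen[ch]
    img[rows, cols, ch] <- sl
  }
  # nuclear speckle on the epithelium, density grows with crowding
  ring_idx <- which(in_ring)
  if (length(ring_idx)) {
    k <- round(length(ring_idx) * (0.15 + 0.35 * crowding))
    if (k > 0) {
      pick <- ring_idx[sample.int(length(ring_idx), k)]
      for (ch in 1:3) {
        sl <- img[rows, cols, ch]
        sl[pick] <- .palette$nucleus[ch]
        img[rows, cols, ch] <- sl
      }
    }
  }
  foot <- matrix(FALSE, h, w)
  foot[rows, cols] <- inside
  list(img = img, foot = foot)
}

#' Generate one synthetic patch with its ground-truth mask
#'
#' Draws a stylized H&E-like RGB patch (pink stroma, purple epithelium,
#' whitish lumina, nuclear speckle) containing glands of the requested
#' style, together with a pixel-accurate binary mask in which malignant
#' pixels (value 1) are exactly the gland footprints of `gp3_like` /
#' `gp4_like` styles.  Benign-style patches have an all-zero mask.
#' Output is fully determined by `seed`.
#'
#' @param style a [gland_style()].
#' @param size patch side length in pixels (>= 32).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param noise_sd additive Gaussian channel noise, default 8/255.
#' @param coverage target fraction of the patch covered by glands, in
#'   (0, 1).  For malignant styles this is the requested malignant pixel
#'   fraction; the empirical fraction is approximate since glands are
#'   placed by rejection sampling.  `NULL` uses a per-style default
#'   (benign 0.25, gp3-like 0.25, gp4-like 0.40).
#' @return A list with class `"patch_pair"`: `image` (`size x size x 3`
#'   array in \[0, 1\]), `mask` (integer matrix, values 0/1), `style`.
#' @export
#' @examples
#' pp <- generate_patch_pair(gland_style("gp3_like"), size = 64, seed = 1)
#' mean(pp$mask)
generate_patch_pair <- function(style, size = 256, seed = 1,
                                noise_sd = 8 / 255, coverage = NULL) {
  stopifnot(inherits(style, "gland_style"))
  if (size < 32) stop("size must be >= 32 (got ", size, ")")
  if (is.null(coverage)) {
    coverage <- switch(style$kind, benign = 0.25, gp3_like = 0.25,
                       gp4_like = 0.40)
  }
  stopifnot(coverage > 0, coverage < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  img <- array(rep(.palette$stroma, each = size * size), c(size, size, 3))
  # sparse stromal nuclei
  n_spk <- round(0.02 * size * size)
  spk <- sample.int(size * size, n_spk)
  for (ch in 1:3) {
    sl <- img[, , ch]
    sl[spk] <- .palette$nucleus[ch]
    img[, , ch] <- sl
  }

  covered <- matrix(FALSE, size, size)
  malignant <- style$kind %in% c("gp3_like", "gp4_like")
  r_out <- style$lumen_radius_px + style$ring_thickness_px
  min_sep <- if (style$kind == "gp4_like") 1.2 * r_out else 2 * r_out + 2
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  # placement budget scales with how many glands the target coverage
  # needs (gland size is absolute, so large patches hold more glands)
  max_attempts <- 40L + 10L * ceiling(coverage * size^2 / (pi * r_out^2))
  # first gland near the centre so gland pixels always exist
  while (mean(covered) < coverage && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (nrow(centers) == 0L) {
      cx <- size / 2 + runif(1, -size / 8, size / 8)
      cy <- size / 2 + runif(1, -size / 8, size / 8)
    } else if (style$kind == "gp4_like" && runif(1) < 0.75) {
      # fuse: bud a new ellipse off an existing gland so blobs merge
      anchor <- centers[sample.int(nrow(centers), 1), ]
      ang <- runif(1, 0, 2 * pi)
      d <- runif(1, 0.7, 1.5) * r_out
      cx <- min(max(anchor[1] + d * cos(ang), r_out), size - r_out)
      cy <- min(max(anchor[2] + d * sin(ang), r_out), size - r_out)
    } else {
      cx <- runif(1, r_out, size - r_out)
      cy <- runif(1, r_out, size - r_out)
    }
    if (nrow(centers) > 0L && style$kind != "gp4_like") {
      d2 <- (centers[, 1] - cx)^2 + (centers[, 2] - cy)^2
      if (min(d2) < min_sep^2) next
    }
    ax_ratio <- runif(1, 0.8, 1.3)
    rot <- runif(1, 0, pi)
    lum <- style$lumen_radius_px * runif(1, 0.8, 1.2)
    rng <- style$ring_thickness_px * runif(1, 0.85, 1.15)
    g <- .draw_gland(img, cx, cy, lum, rng, ax_ratio, rot, style$crowding)
    img <- g$img
    covered <- covered | g$foot
    centers <- rbind(centers, c(cx, cy))
  }

  img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  mask <- matrix(0L, size, size)
  if (malignant) mask[covered] <- 1L
  structure(list(image = img, mask = mask, style = style),
            class = "patch_pair")
}

# save/restore global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Describe the layout of a synthetic toy slide
#'
#' A toy slide is a white canvas carrying elliptical tissue cores.  Each
#' core has a base tissue label (first element of `labels`, usually
#' `"N"`) and optional sub-region labels drawn as smaller ellipses
#' inside the core (e.g. `c("N", "GP3", "GP4")`).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param cores list of cores; each a list with `center = c(x, y)`,
#'   `axes = c(a, b)` (semi-axes, pixels), optional `rotation` (radians)
#'   and `labels` (character, annotation label names).
#' @param background_color RGB triple in \[0, 1\] for the empty canvas.
#' @param seed integer seed controlling sub-region placement and
#'   rendering noise.
#' @return A list with class `"slide_layout"`.
#' @export
slide_layout <- function(width_px, height_px, cores = list(),
                         background_color = c(1, 1, 1), seed = 1) {
  stopifnot(width_px >= 8, height_px >= 8)
  for (co in cores) {
    stopifnot(length(co$center) == 2, length(co$axes) == 2,
              all(co$axes > 0))
    lab <- if (is.null(co$labels)) "N" else co$labels
    label_code(lab) # validates
    if (co$center[1] - max(co$axes) < 0 ||
        co$center[1] + max(co$axes) > width_px ||
        co$center[2] - max(co$axes) < 0 ||
        co$center[2] + max(co$axes) > height_px) {
      stop("core at (", co$center[1], ", ", co$center[2],
           ") extends outside the canvas")
    }
  }
  structure(list(width_px = width_px, height_px = height_px, cores = cores,
                 background_color = background_color, seed = seed),
            class = "slide_layout")
}

.ellipse_polygon <- function(center, axes, rotation = 0, label = "N",
                             n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(rotation); st <- sin(rotation)
  ex <- axes[1] * cos(th); ey <- axes[2] * sin(th)
  annotation_polygon(center[1] + ex * ct - ey * st,
                     center[2] + ex * st + ey * ct, label)
}

# rendering palette per label code; all tissue tones keep min(RGB) well
# below the whiteness threshold so they count as tissue
.label_colors <- function() {
  rbind(Bg    = c(1.00, 1.00, 1.00),
        Fg    = c(0.93, 0.90, 0.91),
        N     = c(0.91, 0.75, 0.82),
        GP3   = c(0.58, 0.42, 0.66),
        GP4   = c(0.47, 0.31, 0.56),
        GP5   = c(0.36, 0.22, 0.45),
        L     = c(0.55, 0.50, 0.75),
        NE    = c(0.80, 0.78, 0.70),
        NS    = c(0.78, 0.72, 0.75),
        PIN   = c(0.70, 0.50, 0.72),
        Blood = c(0.80, 0.30, 0.35))
}

#' Generate a toy slide with label raster and annotation polygons
#'
#' Renders the layout into an RGB raster, a label raster of annotation
#' codes, and the generating polygons.  The label raster is produced by
#' rasterizing the polygons, so `rasterize_annotations(polygons)`
#' reproduces it exactly (round-trip identity).  Cores whose ellipses
#' overlap while carrying different base labels are rejected.
#'
#' @param layout a [slide_layout()].
#' @param noise_sd additive Gaussian channel noise on tissue pixels.
#' @return A list with class `"toy_slide"`: `image` (H x W x 3),
#'   `labels` (integer H x W), `polygons`, `layout`.
#' @export
generate_toy_slide <- function(layout, noise_sd = 8 / 255) {
  stopifnot(inherits(layout, "slide_layout"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(layout$seed)
  h <- as.integer(layout$height_px); w <- as.integer(layout$width_px)

  cores <- layout$cores
  base_lab <- vapply(cores, function(co)
    if (is.null(co$labels)) "N" else co$labels[1], character(1))
  foot <- lapply(cores, function(co) {
    p <- .ellipse_polygon(co$center, co$axes,
                          if (is.null(co$rotation)) 0 else co$rotation)
    .poly_fill(h, w, p$x, p$y)
  })
  if (length(cores) > 1) {
    for (i in seq_along(cores)[-1]) for (j in seq_len(i - 1)) {
      if (base_lab[i] != base_lab[j] && any(foot[[i]] & foot[[j]])) {
        stop("cores ", j, " (", base_lab[j], ") and ", i, " (",
             base_lab[i], ") overlap with conflicting labels")
      }
    }
  }

  polygons <- list()
  for (ci in seq_along(cores)) {
    co <- cores[[ci]]
    rot <- if (is.null(co$rotation)) 0 else co$rotation
    labs <- if (is.null(co$labels)) "N" else co$labels
    polygons <- c(polygons,
                  list(.ellipse_polygon(co$center, co$axes, rot, labs[1])))
    if (length(labs) > 1) {
      for (li in seq_along(labs)[-1]) {
        # deterministic sub-region inside the core
        fr <- runif(1, 0.28, 0.42)
        ang <- runif(1, 0, 2 * pi)
        off <- runif(1, 0.15, 0.45)
        ctr <- co$center + off * min(co$axes) *
          c(cos(ang), sin(ang))
        polygons <- c(polygons,
                      list(.ellipse_polygon(ctr, co$axes * fr, rot, labs[li])))
      }
    }
  }

  labels <- rasterize_annotations(polygons, c(h, w))
  cols <- .label_colors()
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    sl <- matrix(cols[labels + 1L, ch], h, w)
    img[, , ch] <- sl
  }
  tissue <- labels != 0L
  if (any(tissue)) {
    nz <- array(rnorm(length(img), 0, noise_sd), dim(img))
    for (ch in 1:3) {
      sl <- img[, , ch]
      sl[tissue] <- sl[tissue] + nz[, , ch][tissue]
      img[, , ch] <- sl
    }
    # nuclear speckle inside tissue
    idx <- which(tissue)
    k <- round(0.03 * length(idx))
    if (k > 0) {
      pick <- idx[sample.int(length(idx), k)]
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[pick] <- .palette$nucleus[ch]
        img[, , ch] <- sl
      }
    }
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, labels = labels, polygons = polygons,
                 layout = layout),
            class = "toy_slide")
}

#' Generate a synthetic patch dataset on disk
#'
#' Writes `n_train + n_val + n_test` patch pairs (RGB image PNG plus
#' single-channel 0/1 mask PNG) and a manifest CSV with columns
#' `patch_id, slide_id, x, y, split, image_path, mask_path`.  Styles are
#' sampled from `style_probs`; each patch gets its own derived seed so
#' the whole dataset is byte-identical for a fixed `seed`.
#'
#' @param dir output directory (created if needed).
#' @param n_train,n_val,n_test split sizes (>= 0).
#' @param size patch side length in pixels.
#' @param seed integer master seed.
#' @param style_probs named probabilities for `benign`, `gp3_like`,
#'   `gp4_like`.
#' @param noise_sd channel noise passed to [generate_patch_pair()].
#' @return The manifest as a data.frame (also written to
#'   `file.path(dir, "manifest.csv")`), invisibly carrying attribute
#'   `dir`.
#' @export
generate_dataset <- function(dir, n_train, n_val, n_test, size = 64,
                             seed = 1,
                             style_probs = c(benign = 0.4, gp3_like = 0.3,
                                             gp4_like = 0.3),
                             noise_sd = 8 / 255) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  n <- n_train + n_val + n_test
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  man <- data.frame(patch_id = character(0), slide_id = character(0),
                    x = integer(0), y = integer(0), split = character(0),
                    image_path = character(0), mask_path = character(0),
                    stringsAsFactors = FALSE)
  if (n > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    kinds <- sample(names(style_probs), n, replace = TRUE,
                    prob = style_probs)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    ids <- sprintf("p%05d", seq_len(n))
    for (i in seq_len(n)) {
      pp <- generate_patch_pair(gland_style(kinds[i]), size = size,
                                seed = seeds[i], noise_sd = noise_sd)
      ip <- file.path(dir, paste0(ids[i], "_img.png"))
      mp <- file.path(dir, paste0(ids[i], "_mask.png"))
      write_image(pp$image, ip)
      write_mask(pp$mask, mp)
      man[i, ] <- list(ids[i], ids[i], 0L, 0L, split[i],
                       basename(ip), basename(mp))
    }
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(man, "dir") <- dir
  man
}

#' Read and write patch images and masks
#'
#' Images are 8-bit RGB PNG with values scaled to \[0, 1\]; masks are
#' 8-bit single-channel PNG storing raw label codes (0/1 for binary
#' masks, 0-10 for annotation rasters).
#'
#' @param img RGB array H x W x 3 in \[0, 1\].
#' @param mask integer matrix of label codes.
#' @param path file path.
#' @return Readers return the array/matrix; writers return `path`
#'   invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask) / 255, nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
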