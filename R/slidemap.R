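#' Reassemble patch predictions into a slide-level score map
#'
#' Writes each predicted patch's malignant-channel probability back
#' into its grid cell of the slide canvas.  Cells with no prediction
#' (quality-filtered patches, or border area off the patch grid) are
#' `NA` ("no prediction"), keeping missingness explicit rather than
#' conflating it with zero probability.  If several predictions cover
#' the same cell (overlapping grids), their mean is used.
#'
#' @param predictions list of entries, each a list with `grid_row`,
#'   `grid_col` (0-based grid indices) and `prob` (either an
#'   `H x W x 2` probability array or an `H x W` malignant-probability
#'   matrix).
#' @param slide_dims integer `c(height, width)` of the slide in pixels.
#' @param patch_size patch side length in pixels.
#' @param slide_id identifier stored on the map.
#' @return A list with class `"score_map"`: `values` (H x W matrix in
#'   \[0, 1\] with `NA` for missing), `patch_size`, `filtered_cells`
#'   (data.frame of on-grid cells without predictions), `slide_id`.
#' @export
assemble_score_map <- function(predictions, slide_dims, patch_size,
                               slide_id = "slide") {
  h <- as.integer(slide_dims[1]); w <- as.integer(slide_dims[2])
  stopifnot(patch_size >= 1, h >= patch_size, w >= patch_size)
  n_r <- h %/% patch_size
  n_c <- w %/% patch_size
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  seen <- matrix(FALSE, n_r, n_c)
  for (p in predictions) {
    i <- p$grid_row; j <- p$grid_col
    if (i < 0 || j < 0 || i >= n_r || j >= n_c) {
      stop("patch at grid cell (", i, ", ", j, ") lies outside the ",
           n_r, "x", n_c, " grid of a ", h, "x", w, " slide")
    }
    pr <- p$prob
    if (length(dim(pr)) == 3) pr <- pr[, , 2]
    stopifnot(nrow(pr) == patch_size, ncol(pr) == patch_size)
    rows <- i * patch_size + seq_len(patch_size)
    cols <- j * patch_size + seq_len(patch_size)
    acc[rows, cols] <- acc[rows, cols] + pr
    cnt[rows, cols] <- cnt[rows, cols] + 1L
    seen[i + 1L, j + 1L] <- TRUE
  }
  vals <- matrix(NA_real_, h, w)
  got <- cnt > 0L
  vals[got] <- acc[got] / cnt[got]
  miss <- which(!seen, arr.ind = TRUE)
  filtered <- data.frame(grid_row = miss[, 1] - 1L,
                         grid_col = miss[, 2] - 1L)
  filtered <- filtered[order(filtered$grid_row, filtered$grid_col), ,
                       drop = FALSE]
  rownames(filtered) <- NULL
  structure(list(values = vals, patch_size = as.integer(patch_size),
                 filtered_cells = filtered, slide_id = slide_id),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "score_map '%s': %dx%d px, patch %d, %d filtered cell(s), %.1f%% covered\n",
    x$slide_id, d[1], d[2], x$patch_size, nrow(x$filtered_cells),
    100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Probability colormap ramp
#'
#' A green-to-red perceptual ramp (dark green, green, yellow, orange,
#' red) mapping low to high malignancy probability with cooler to
#' hotter tones.
#'
#' @param n number of ramp entries.
#' @param colors ramp anchor colors.
#' @return `n x 3` matrix of RGB values in \[0, 1\].
#' @export
score_colormap <- function(n = 256,
                           colors = c("darkgreen", "green", "yellow",
                                      "orange", "red")) {
  ramp <- grDevices::colorRamp(colors)(seq(0, 1, length.out = n)) / 255
  colnames(ramp) <- c("r", "g", "b")
  ramp
}

#' Render a score-map overlay on the slide image
#'
#' Alpha-blends the colormapped malignancy probability over the slide
#' RGB raster.  Missing cells (`NA` in the map) show the original slide
#' by default, or are treated as probability zero with
#' `missing_mode = "zero"`.
#'
#' @param slide_rgb slide RGB array H x W x 3 in \[0, 1\].
#' @param score_map a [assemble_score_map()] result with matching
#'   dimensions.
#' @param alpha blend weight of the heat colors in \[0, 1\]; 0 returns
#'   the slide unchanged.
#' @param colormap ramp matrix from [score_colormap()].
#' @param missing_mode `"transparent"` (default) or `"zero"`.
#' @return RGB array H x W x 3; the ramp used is attached as attribute
#'   `"colorbar"`.
#' @export
render_overlay <- function(slide_rgb, score_map, alpha = 0.5,
                           colormap = score_colormap(),
                           missing_mode = c("transparent", "zero")) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(inherits(score_map, "score_map"), alpha >= 0, alpha <= 1)
  d <- dim(slide_rgb)
  if (length(d) != 3 || any(d[1:2] != dim(score_map$values))) {
    stop("slide dimensions (", paste(d[1:2], collapse = "x"),
         ") do not match the score map (",
         paste(dim(score_map$values), collapse = "x"), ")")
  }
  s <- score_map$values
  if (missing_mode == "zero") s[is.na(s)] <- 0
  out <- slide_rgb
  idx <- which(!is.na(s))
  if (length(idx) && alpha > 0) {
    n <- nrow(colormap)
    ci <- pmin(pmax(1L, as.integer(round(s[idx] * (n - 1))) + 1L), n)
    for (ch in 1:3) {
      sl <- out[, , ch]
      sl[idx] <- (1 - alpha) * sl[idx] + alpha * colormap[ci, ch]
      out[, , ch] <- sl
    }
  }
  attr(out, "colorbar") <- colormap
  out
}

#' Persist and reload a score map
#'
#' The probability mosaic is written as an 8-bit grayscale PNG
#' (probabilities quantized to 0..254, missing pixels encoded as the
#' reserved value 255) together with a JSON sidecar recording the slide
#' id, patch size, and filtered cells.
#'
#' @param score_map a `score_map`.
#' @param path PNG path; the sidecar uses extension `.json`.
#' @return `write_score_map()` returns `path` invisibly;
#'   `read_score_map()` returns the `score_map`.
#' @export
write_score_map <- function(score_map, path) {
  v <- score_map$values
  enc <- round(v * 254) / 255
  enc[is.na(v)] <- 1
  png::writePNG(enc, path)
  side <- sub("\\.png$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(
    list(slide_id = score_map$slide_id,
         patch_size = score_map$patch_size,
         height = nrow(v), width = ncol(v),
         filtered_cells = score_map$filtered_cells),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_map
#' @export
read_score_map <- function(path) {
  side <- sub("\\.png$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  enc <- round(png::readPNG(path) * 255)
  v <- enc / 254
  v[enc == 255] <- NA
  fc <- as.data.frame(meta$filtered_cells)
  if (nrow(fc) == 0) fc <- data.frame(grid_row = integer(0),
                                      grid_col = integer(0))
  structure(list(values = v, patch_size = as.integer(meta$patch_size),
                 filtered_cells = fc, slide_id = meta$slide_id),
            class = "score_map")
}
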