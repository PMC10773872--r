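#' Binarize a label raster to benign/malignant classes
#'
#' Maps the 11-label annotation raster to the binary segmentation
#' target: Gleason pattern 3 and 4 pixels become the malignant class
#' (1); every other label -- background, foreground, normal, GP5,
#' lymphoid, not-evaluated, not-sure, PIN, blood -- becomes benign (0).
#'
#' @param labels integer matrix of annotation codes 0-10 (or an already
#'   binary 0/1 matrix, which passes through unchanged).
#' @return Integer matrix of the same shape with values in `{0, 1}`.
#' @export
#' @examples
#' binarize_mask(matrix(c(0, 2, 3, 4), 2, 2))
binarize_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  bad <- labels < 0 | labels > 10 | labels != floor(labels)
  if (any(bad)) {
    stop("invalid label code(s) in raster: ",
         paste(unique(labels[bad]), collapse = ", "))
  }
  if (all(labels %in% c(0L, 1L))) {
    # already-binary mask: idempotent pass-through.  (A raster holding
    # only Bg/Fg codes is indistinguishable from a binary mask, but
    # such patches never survive the annotated-tissue filter.)
    return(matrix(as.integer(labels), nrow(labels), ncol(labels)))
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels == label_code("GP3") | labels == label_code("GP4")] <- 1L
  out
}

#' Tissue fraction of an RGB patch
#'
#' Fraction of non-background pixels.  A pixel is background ("white
#' space") when its *minimum* channel value exceeds the whiteness
#' threshold; H&E-stained tissue always pulls at least one channel well
#' below white.  Patches whose tissue fraction falls under 20% are
#' discarded during preprocessing.
#'
#' @param image RGB array H x W x 3 with values in \[0, 1\].
#' @param white_threshold whiteness cutoff in \[0, 1\], default 220/255.
#' @return Scalar fraction in \[0, 1\].
#' @export
tissue_ratio <- function(image, white_threshold = 220 / 255) {
  if (length(image) == 0) stop("empty image")
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  mean(mn <= white_threshold)
}

#' Extract a regular grid of patch pairs from a slide
#'
#' Cuts the slide raster and its label raster into `patch_size` squares
#' on a regular grid with the given stride.  Partial patches at the
#' right/bottom border are dropped.  Grid indices are 0-based
#' `(row, col)`; pixel origins use half-open ranges so that patch
#' `(i, j)` covers rows `i*stride .. i*stride + patch_size - 1`
#' (0-based).
#'
#' @param image slide RGB array H x W x 3.
#' @param labels integer label raster H x W (annotation codes or binary).
#' @param patch_size patch side length in pixels.
#' @param stride grid step in pixels (> 0); defaults to `patch_size`
#'   (non-overlapping).
#' @param slide_id identifier stored on each pair.
#' @return List of patch pairs: each a list with `image`, `labels`
#'   (un-binarized raster crop), `grid_row`, `grid_col`, `x`, `y`
#'   (0-based pixel origin), `slide_id`.
#' @export
extract_patches <- function(image, labels, patch_size, stride = patch_size,
                            slide_id = "slide") {
  stopifnot(length(dim(image)) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  stopifnot(nrow(labels) == h, ncol(labels) == w)
  if (stride <= 0) stop("stride must be positive")
  if (patch_size > h || patch_size > w) {
    stop("patch_size exceeds slide dimensions")
  }
  n_r <- floor((h - patch_size) / stride) + 1L
  n_c <- floor((w - patch_size) / stride) + 1L
  out <- vector("list", n_r * n_c)
  k <- 0L
  for (i in seq_len(n_r) - 1L) {
    for (j in seq_len(n_c) - 1L) {
      r0 <- i * stride; c0 <- j * stride
      rows <- (r0 + 1L):(r0 + patch_size)
      cols <- (c0 + 1L):(c0 + patch_size)
      k <- k + 1L
      out[[k]] <- list(image = image[rows, cols, , drop = FALSE],
                       labels = labels[rows, cols, drop = FALSE],
                       grid_row = i, grid_col = j,
                       x = c0, y = r0, slide_id = slide_id)
    }
  }
  out
}

#' Quality-filter extracted patch pairs
#'
#' Retains a pair iff (a) its tissue fraction is at least
#' `min_tissue_ratio` and (b), when `require_tissue_class` is `TRUE`, it
#' contains at least one pixel labeled something other than background
#' or unspecific foreground -- dropping patches made solely of
#' background, solely of foreground, or a background/foreground mixture.
#'
#' @param pairs list of patch pairs from [extract_patches()] (label
#'   crops must be un-binarized annotation codes for predicate (b)).
#' @param min_tissue_ratio minimum tissue fraction, default 0.2.
#' @param require_tissue_class drop pairs whose labels are all Bg/Fg.
#' @param ratio_on `"image"` computes the tissue fraction from RGB
#'   whiteness (default); `"mask"` computes it as the fraction of
#'   non-background (non-Bg) label pixels.
#' @param white_threshold passed to [tissue_ratio()].
#' @return The retained subset of `pairs`.
#' @export
filter_patches <- function(pairs, min_tissue_ratio = 0.2,
                           require_tissue_class = TRUE,
                           ratio_on = c("image", "mask"),
                           white_threshold = 220 / 255) {
  ratio_on <- match.arg(ratio_on)
  if (length(pairs) == 0) return(pairs)
  bg <- label_code("Bg"); fg <- label_code("Fg")
  keep <- vapply(pairs, function(p) {
    tr <- if (ratio_on == "image") {
      tissue_ratio(p$image, white_threshold)
    } else {
      mean(p$labels != bg)
    }
    if (tr < min_tissue_ratio) return(FALSE)
    if (require_tissue_class && !any(p$labels != bg & p$labels != fg)) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  pairs[keep]
}

#' Inverse-frequency class weights from training masks
#'
#' Computes per-class balancing weights `w_c = N_total / (2 * N_c)` over
#' all pixels of the training-set binary masks, the inverse-frequency
#' scheme used to counter benign/malignant imbalance inside the Dice
#' loss.  Balanced classes give `(1, 1)`; the ratio `w1/w0` always
#' equals the pixel ratio `N0/N1`.
#'
#' @param masks a list of binary 0/1 matrices (or a single matrix).
#' @return A list with class `"class_weights"`: `w0`, `w1`.
#' @export
#' @examples
#' compute_class_weights(matrix(c(0, 0, 0, 1), 2, 2))
compute_class_weights <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  n1 <- sum(vapply(masks, function(m) sum(m == 1), numeric(1)))
  n0 <- sum(vapply(masks, function(m) sum(m == 0), numeric(1)))
  if (n0 + n1 == 0) stop("no pixels supplied")
  if (n0 == 0 || n1 == 0) {
    stop("class ", if (n0 == 0) 0 else 1, " is absent from the training ",
         "masks; supply explicit class weights instead")
  }
  n <- n0 + n1
  class_weights(n / (2 * n0), n / (2 * n1))
}

#' @rdname compute_class_weights
#' @param w0,w1 positive per-class weights.
#' @export
class_weights <- function(w0 = 1, w1 = 1) {
  if (w0 <= 0 || w1 <= 0) stop("class weights must be positive")
  structure(list(w0 = w0, w1 = w1), class = "class_weights")
}

#' Preprocess a toy slide into a filtered patch dataset on disk
#'
#' Applies the full preprocessing chain to one or more toy slides:
#' extract a non-overlapping patch grid, quality-filter (tissue ratio
#' and annotated-tissue predicates), binarize the label crops, and write
#' image/mask PNG pairs plus a manifest CSV.
#'
#' @param slides list of `toy_slide` objects (or a single one).
#' @param dir output directory.
#' @param patch_size,stride grid geometry, see [extract_patches()].
#' @param min_tissue_ratio,require_tissue_class,ratio_on filtering
#'   parameters, see [filter_patches()].
#' @param split split tag recorded in the manifest for every retained
#'   pair (single value or one per slide).
#' @return Manifest data.frame as in [generate_dataset()].
#' @export
preprocess_slides <- function(slides, dir, patch_size = 64,
                              stride = patch_size, min_tissue_ratio = 0.2,
                              require_tissue_class = TRUE,
                              ratio_on = "image", split = "train") {
  if (inherits(slides, "toy_slide")) slides <- list(slides)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  split <- rep_len(split, length(slides))
  rows <- list()
  for (si in seq_along(slides)) {
    sl <- slides[[si]]
    sid <- sprintf("slide%03d", si)
    pairs <- extract_patches(sl$image, sl$labels, patch_size, stride,
                             slide_id = sid)
    pairs <- filter_patches(pairs, min_tissue_ratio, require_tissue_class,
                            ratio_on)
    for (p in pairs) {
      pid <- sprintf("%s_r%03d_c%03d", sid, p$grid_row, p$grid_col)
      ip <- file.path(dir, paste0(pid, "_img.png"))
      mp <- file.path(dir, paste0(pid, "_mask.png"))
      write_image(p$image, ip)
      write_mask(binarize_mask(p$labels), mp)
      rows[[length(rows) + 1L]] <-
        data.frame(patch_id = pid, slide_id = sid, x = p$x, y = p$y,
                   split = split[si], image_path = basename(ip),
                   mask_path = basename(mp), stringsAsFactors = FALSE)
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = character(0), slide_id = character(0),
               x = integer(0), y = integer(0), split = character(0),
               image_path = character(0), mask_path = character(0))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(man, "dir") <- dir
  man
}
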