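#' Tissue annotation taxonomy
#'
#' The 11-label annotation vocabulary used on prostate needle-biopsy
#' slides: background, unspecific foreground, benign/normal glands,
#' Gleason patterns 3-5, lymphoid tissue, not-evaluated and not-sure
#' regions, prostatic intraepithelial neoplasia, and blood.  Codes are
#' the integer pixel values stored in label rasters.
#'
#' @return A data.frame with columns `code` (integer 0-10), `name`, and
#'   `description`.
#' @export
#' @examples
#' annotation_labels()
annotation_labels <- function() {
  data.frame(
    code = 0:10,
    name = c("Bg", "Fg", "N", "GP3", "GP4", "GP5", "L", "NE", "NS",
             "PIN", "Blood"),
    description = c(
      "Background", "Foreground", "Normal/Benign", "Gleason pattern 3",
      "Gleason pattern 4", "Gleason pattern 5", "Lymphoid",
      "Not evaluated", "Not sure/confident",
      "Prostatic intraepithelial neoplasia", "Blood cell"),
    stringsAsFactors = FALSE
  )
}

#' Convert between annotation label names and codes
#'
#' @param name character vector of label names.
#' @param code integer vector of label codes.
#' @return `label_code()` returns integer codes; `label_name()` returns
#'   character names.
#' @export
label_code <- function(name) {
  tab <- annotation_labels()
  i <- match(name, tab$name)
  if (anyNA(i)) {
    stop("unknown annotation label(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "),
         "; valid names are: ", paste(tab$name, collapse = ", "))
  }
  tab$code[i]
}

#' @rdname label_code
#' @export
label_name <- function(code) {
  tab <- annotation_labels()
  i <- match(as.integer(code), tab$code)
  if (anyNA(i)) {
    stop("invalid annotation code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "),
         "; valid codes are 0-10")
  }
  tab$name[i]
}

#' Create an annotation polygon
#'
#' @param x,y numeric vertex coordinates in pixel units.  The centre of
#'   the pixel in row `r`, column `c` of the raster is the point
#'   `(c, r)`; the y axis therefore grows downwards, matching image row
#'   order.
#' @param label an annotation label name (see [annotation_labels()]).
#' @return A list with class `"annotation_polygon"`.
#' @export
annotation_polygon <- function(x, y, label) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  label_code(label) # validates
  structure(list(x = as.numeric(x), y = as.numeric(y), label = label),
            class = "annotation_polygon")
}

#' Rasterize annotation polygons to a label raster
#'
#' Pixels whose centre falls inside a polygon receive that polygon's
#' label code; uncovered pixels are background (`Bg`, code 0).  When
#' polygons overlap, later polygons overwrite earlier ones, so nested
#' annotations must be listed outer-first.
#'
#' @param polygons list of [annotation_polygon()] objects (possibly
#'   empty).
#' @param canvas_size integer `c(height, width)` in pixels.
#' @return Integer matrix `height x width` of label codes.
#' @export
rasterize_annotations <- function(polygons, canvas_size) {
  stopifnot(length(canvas_size) == 2, all(canvas_size >= 1))
  h <- as.integer(canvas_size[1]); w <- as.integer(canvas_size[2])
  out <- matrix(0L, h, w)
  for (p in polygons) {
    if (!inherits(p, "annotation_polygon")) {
      p <- annotation_polygon(p$x, p$y, p$label)
    }
    inside <- .poly_fill(h, w, p$x, p$y)
    out[inside] <- label_code(p$label)
  }
  out
}

#' Read and write annotation polygons as GeoJSON
#'
#' Polygons are stored as a GeoJSON `FeatureCollection` of `Polygon`
#' features carrying a `label` property, with coordinates in pixel
#' units (see [annotation_polygon()] for the coordinate convention).
#'
#' @param path file path.
#' @param polygons list of [annotation_polygon()] objects.
#' @return `read_annotations()` returns a list of polygons;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- vapply(ring, function(pt) c(pt[[1]], pt[[2]]), numeric(2))
    # drop the closing vertex GeoJSON requires
    n <- ncol(xy)
    if (n > 1 && all(xy[, 1] == xy[, n])) xy <- xy[, -n, drop = FALSE]
    annotation_polygon(xy[1, ], xy[2, ], f$properties$label)
  })
}

#' @rdname read_annotations
#' @export
write_annotations <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    ring <- c(lapply(seq_along(p$x), function(i) c(p$x[i], p$y[i])),
              list(c(p$x[1], p$y[1])))
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
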