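#' Labelled polygon region of interest
#'
#' Constructs a polygon ROI in pixel coordinates. Coordinates are 0-based
#' with `x` increasing rightwards (columns) and `y` increasing downwards
#' (rows); the polygon is implicitly closed. ROIs delimit the total
#' reproductive tract, the spermatheca, or the chitinous
#' autofluorescence-reference structure used for crosstalk correction.
#'
#' @param label one of `"total_tract"`, `"spermatheca"`,
#'   `"autofluorescence_reference"`.
#' @param vertices numeric matrix (or two-column data frame) of `(x, y)`
#'   vertex coordinates, at least three rows, describing a simple
#'   (non-self-intersecting) polygon of positive area.
#' @return an object of class `polygon_roi`.
#' @export
polygon_roi <- function(label, vertices) {
  label <- match.arg(label,
                     c("total_tract", "spermatheca",
                       "autofluorescence_reference"))
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  # micro-pixel precision: keeps file round-trips exact and is far below
  # any meaningful rasterization resolution
  vertices <- round(vertices, 6L)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("polygon must have >= 3 (x, y) vertices")
  if (anyNA(vertices)) stop("polygon vertices contain NA")
  if (abs(polygon_area(vertices)) <= .Machine$double.eps)
    stop("degenerate polygon: zero area")
  if (polygon_self_intersects(vertices))
    stop("polygon is self-intersecting")
  structure(list(label = label, vertices = unname(vertices)),
            class = "polygon_roi")
}

# Shoelace signed area.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Proper-crossing test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon ROI to a binary pixel mask
#'
#' A pixel belongs to the mask iff its centre `(x + 0.5, y + 0.5)` lies
#' inside the polygon under the even-odd rule. This pins down area counts
#' exactly: an axis-aligned rectangle with corners `(0, 0)` and `(10, 10)`
#' rasterizes to 100 pixels.
#'
#' @param roi a [polygon_roi()].
#' @param image_shape integer `(height, width)` in pixels.
#' @return logical matrix of dimension `image_shape` (rows = y, cols = x).
#' @export
rasterize_roi <- function(roi, image_shape) {
  stopifnot(inherits(roi, "polygon_roi"), length(image_shape) == 2L)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > w) || any(v[, 2] < 0) || any(v[, 2] > h))
    stop("polygon extends outside the image bounds")
  px <- rep(seq_len(w) - 0.5, each = h)   # pixel-centre x per matrix cell
  py <- rep(seq_len(h) - 0.5, times = w)  # pixel-centre y per matrix cell
  inside <- rep(FALSE, h * w)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xi))
    }
    j <- i
  }
  mask <- matrix(inside, nrow = h, ncol = w)
  if (!any(mask)) stop("rasterized ROI is empty (area < 1 px)")
  mask
}

#' Write ROIs to a JSON polygon file
#'
#' Serializes a list of ROIs as a JSON array of
#' `{"label": ..., "vertices": [[x, y], ...]}` objects.
#'
#' @param rois list of [polygon_roi()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(label = r$label, vertices = r$vertices))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read ROIs from a JSON polygon file
#'
#' @param path JSON file written by [write_roi_json()].
#' @return named list of [polygon_roi()] objects (names = labels).
#' @export
read_roi_json <- function(path) {
  payload <- jsonlite::read_json(path)
  rois <- lapply(payload, function(entry) {
    v <- do.call(rbind, lapply(entry$vertices, function(p)
      c(p[[1]], p[[2]])))
    polygon_roi(entry$label, v)
  })
  names(rois) <- vapply(rois, `[[`, "", "label")
  rois
}
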