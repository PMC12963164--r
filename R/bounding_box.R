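#' Pixel-space bounding box
#'
#' Boxes locate the operating-bed region of interest (ROI) in a frame.
#' Coordinates are 0-based with x increasing rightward and y downward;
#' a box is the half-open pixel set `[x, x + w) x [y, y + h)`.
#'
#' @param x,y Top-left corner, 0-based pixels.
#' @param w,h Width and height in pixels; must be positive.
#' @return An object of class `bounding_box`.
#' @examples
#' bounding_box(100, 100, 200, 100)
#' @export
bounding_box <- function(x, y, w, h) {
  if (!all(is.finite(c(x, y, w, h)))) stop_config("box coordinates must be finite")
  if (w <= 0 || h <= 0) stop_config("box width and height must be positive")
  structure(list(x = x, y = y, w = w, h = h), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' @export
format.bounding_box <- function(x, ...) {
  sprintf("%d,%d,%d,%d", round(x$x), round(x$y), round(x$w), round(x$h))
}

box_area <- function(box) box$w * box$h

#' Intersection over union of two boxes
#'
#' Standard overlap measure used to validate a detected bed box against the
#' generator's ground truth.
#'
#' @param a,b `bounding_box` objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(a$x, b$x)
  iy <- max(a$y, b$y)
  ix2 <- min(a$x + a$w, b$x + b$w)
  iy2 <- min(a$y + a$h, b$y + b$h)
  iw <- max(0, ix2 - ix)
  ih <- max(0, iy2 - iy)
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Expand a bounding box about its center
#'
#' The detected bed box is enlarged 1.2-fold to absorb small movements of the
#' bed after detection. The published description refers to the bounding box
#' *area*, so the default interpretation scales each linear dimension by
#' `sqrt(factor)`; set `mode = "linear"` to scale each dimension by `factor`
#' instead. The expanded box always contains the input box (corners are
#' floored/ceiled to whole pixels) and is clipped to the frame.
#'
#' @param box A `bounding_box` lying within the frame.
#' @param factor Expansion factor, `>= 1`. Under `mode = "area"` the
#'   pre-clipping area ratio equals `factor` up to one pixel per edge.
#' @param frame_dims `c(width, height)` of the frame, used for clipping.
#' @param mode `"area"` (default) or `"linear"`.
#' @return The expanded, clipped `bounding_box` with integer coordinates.
#' @examples
#' expand_box(bounding_box(100, 100, 200, 100), 1.2, frame_dims = c(1280, 720))
#' @export
expand_box <- function(box, factor = 1.2, frame_dims, mode = c("area", "linear")) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor < 1) {
    stop_config("expansion factor must be a single number >= 1")
  }
  scale <- if (mode == "area") sqrt(factor) else factor
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  w2 <- box$w * scale
  h2 <- box$h * scale
  x1 <- floor(cx - w2 / 2)
  y1 <- floor(cy - h2 / 2)
  x2 <- ceiling(cx + w2 / 2)
  y2 <- ceiling(cy + h2 / 2)
  # clip to frame
  x1 <- max(x1, 0)
  y1 <- max(y1, 0)
  x2 <- min(x2, frame_dims[1])
  y2 <- min(y2, frame_dims[2])
  bounding_box(x1, y1, x2 - x1, y2 - y1)
}

# Clip a box to frame dims; error if nothing remains.
clip_box <- function(box, width, height) {
  x1 <- max(box$x, 0)
  y1 <- max(box$y, 0)
  x2 <- min(box$x + box$w, width)
  y2 <- min(box$y + box$h, height)
  if (x2 <= x1 || y2 <= y1) stop_input("box has zero area after clipping to frame")
  bounding_box(x1, y1, x2 - x1, y2 - y1)
}

# 1-based row/col index ranges of a (integer-coordinate) box in an array frame.
box_rows <- function(box) seq.int(floor(box$y) + 1L, floor(box$y + box$h))
box_cols <- function(box) seq.int(floor(box$x) + 1L, floor(box$x + box$w))
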