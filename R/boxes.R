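#' Axis-aligned bounding box
#'
#' Constructs a validated axis-aligned pixel rectangle, the geometric unit
#' of every detector output. Coordinates are absolute pixels with the
#' origin at the image top-left and a half-open extent convention
#' `[x_min, x_max) x [y_min, y_max)`, which makes area and intersection
#' arithmetic exact: a box covers the integer pixel centres
#' `x_min .. x_max - 1`.
#'
#' @param x_min,y_min,x_max,y_max finite, non-negative pixel coordinates
#'   with `x_min < x_max` and `y_min < y_max`.
#' @return named numeric vector of class `bounding_box`.
#' @export
#' @examples
#' b <- bounding_box(0, 0, 10, 10)
#' compute_iou(b, bounding_box(5, 0, 15, 10))
bounding_box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  .validate_box_cols(b["x_min"], b["y_min"], b["x_max"], b["y_max"])
  structure(b, class = "bounding_box")
}

# vectorized invariant check shared by the constructor and the readers
.validate_box_cols <- function(x_min, y_min, x_max, y_max, where = "box") {
  v <- c(x_min, y_min, x_max, y_max)
  if (!all(is.finite(v))) {
    stop(where, ": coordinates must be finite", call. = FALSE)
  }
  if (any(v < 0)) {
    stop(where, ": coordinates must be non-negative", call. = FALSE)
  }
  if (any(x_min >= x_max) || any(y_min >= y_max)) {
    stop(where, ": requires x_min < x_max and y_min < y_max (positive area)",
         call. = FALSE)
  }
  invisible(TRUE)
}

.box4 <- function(b) {
  if (inherits(b, "bounding_box")) return(unclass(b))
  if (is.numeric(b) && length(b) == 4L) {
    return(c(x_min = b[[1L]], y_min = b[[2L]], x_max = b[[3L]], y_max = b[[4L]]))
  }
  if (is.list(b) || is.data.frame(b)) {
    return(c(x_min = b$x_min[[1L]], y_min = b$y_min[[1L]],
             x_max = b$x_max[[1L]], y_max = b$y_max[[1L]]))
  }
  stop("cannot interpret object as a bounding box", call. = FALSE)
}

#' Intersection over Union of two boxes
#'
#' The geometric affinity used to link a cow-identity box to a behavior
#' box: area of overlap divided by area of union, under the half-open
#' pixel convention. Returns 0 for disjoint boxes and 1 for identical
#' ones; symmetric in its arguments.
#'
#' @param a,b bounding boxes ([bounding_box()] objects, plain
#'   `c(x_min, y_min, x_max, y_max)` vectors, or one-row data frames with
#'   those columns).
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' compute_iou(bounding_box(0, 0, 10, 10), bounding_box(5, 0, 15, 10))
compute_iou <- function(a, b) {
  a <- .box4(a); b <- .box4(b)
  .validate_box_cols(a[1L], a[2L], a[3L], a[4L])
  .validate_box_cols(b[1L], b[2L], b[3L], b[4L])
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  unname(inter / union)
}

# IoU of one box against n candidate boxes given as column vectors;
# hot path of the per-frame matcher, so no validation here.
.iou_vec <- function(bx1, by1, bx2, by2, cx1, cy1, cx2, cy2) {
  iw <- pmin(bx2, cx2) - pmax(bx1, cx1)
  ih <- pmin(by2, cy2) - pmax(by1, cy1)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (bx2 - bx1) * (by2 - by1) + (cx2 - cx1) * (cy2 - cy1) - inter
  inter / union
}

#' Convert YOLO-normalized detections to corner coordinates
#'
#' YOLO text files store `x_center y_center width height` normalized to
#' `[0, 1]` by the image size; the pipeline works in absolute half-open
#' corner coordinates. The two conversions are exact inverses of each
#' other (up to floating point) for boxes inside the image; corners
#' falling outside the image are clipped at the parsing boundary.
#'
#' @param x_center,y_center,width,height normalized box parameters.
#' @param image_width,image_height image size in pixels.
#' @return data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @seealso [box_to_yolo()]
#' @export
yolo_to_box <- function(x_center, y_center, width, height,
                        image_width, image_height) {
  data.frame(
    x_min = (x_center - width / 2) * image_width,
    y_min = (y_center - height / 2) * image_height,
    x_max = (x_center + width / 2) * image_width,
    y_max = (y_center + height / 2) * image_height
  )
}

#' Convert corner coordinates to YOLO-normalized parameters
#'
#' @param x_min,y_min,x_max,y_max absolute corner coordinates in pixels.
#' @param image_width,image_height image size in pixels.
#' @return data frame with columns `x_center`, `y_center`, `width`,
#'   `height`, each normalized to `[0, 1]` for boxes inside the image.
#' @seealso [yolo_to_box()]
#' @export
box_to_yolo <- function(x_min, y_min, x_max, y_max,
                        image_width, image_height) {
  data.frame(
    x_center = (x_min + x_max) / 2 / image_width,
    y_center = (y_min + y_max) / 2 / image_height,
    width = (x_max - x_min) / image_width,
    height = (y_max - y_min) / image_height
  )
}
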