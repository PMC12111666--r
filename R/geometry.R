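#' Build a tibble of axis-aligned boxes
#'
#' Boxes are the unit of localization throughout the package. Coordinates
#' are 0-based, half-open pixel intervals `[x0, x1) x [y0, y1)` with the
#' origin at the top-left corner, x growing rightward and y growing
#' downward (screen convention). Under this convention the pixel area of a
#' box is exactly `(x1 - x0) * (y1 - y0)` and two boxes sharing an edge are
#' disjoint.
#'
#' @param x0,y0,x1,y1 Numeric vectors of box corners in pixels.
#' @param label Optional class label per box (recycled).
#' @param score Optional score per box (recycled).
#' @param frame_size Optional `c(height, width)` attached as the
#'   `frame_size` attribute; when present, boxes must lie inside the frame.
#' @return A tibble with columns `x0, y0, x1, y1` and optionally `label`,
#'   `score`, validated by [validate_boxes()].
#' @examples
#' boxes(0, 0, 2, 2, label = "grasper")
#' @export
boxes <- function(x0, y0, x1, y1, label = NULL, score = NULL,
                  frame_size = NULL) {
  out <- tibble::tibble(x0 = as.numeric(x0), y0 = as.numeric(y0),
                        x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (!is.null(label)) out$label <- rep_len(label, nrow(out))
  if (!is.null(score)) out$score <- rep_len(as.numeric(score), nrow(out))
  if (!is.null(frame_size)) attr(out, "frame_size") <- as.numeric(frame_size)
  validate_boxes(out)
}

#' Validate a box table
#'
#' Checks the box invariants: strictly positive extent on both axes,
#' finite non-negative coordinates, and containment in the attached frame
#' when a `frame_size` attribute is present.
#'
#' @param x A data frame with columns `x0, y0, x1, y1`.
#' @return `x`, invisibly coerced to a tibble, if valid; otherwise an error.
#' @export
validate_boxes <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("x0", "y0", "x1", "y1")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("box table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  co <- as.matrix(x[need])
  if (!all(is.finite(co))) stop("box coordinates must be finite")
  if (any(co < 0)) stop("box coordinates must be non-negative")
  if (any(x$x1 <= x$x0) || any(x$y1 <= x$y0)) {
    stop("degenerate box: x1 > x0 and y1 > y0 required (half-open pixels)")
  }
  fs <- attr(x, "frame_size")
  if (!is.null(fs)) {
    if (any(x$x1 > fs[2]) || any(x$y1 > fs[1])) {
      stop("box extends beyond the attached frame (", fs[1], "x", fs[2], ")")
    }
  }
  x
}

box_centers <- function(b) {
  cbind(cx = (b$x0 + b$x1) / 2, cy = (b$y0 + b$y1) / 2)
}

box_areas <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Pairwise intersection-over-union of two box tables
#'
#' @param a,b Box tables (see [boxes()]); every box must have positive area.
#' @return A `nrow(a) x nrow(b)` numeric matrix of IoU values in `[0, 1]`.
#' @examples
#' box_iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  iou_core(a, b)
}

# validation-free kernel shared with the evaluation hot path
iou_core <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  ix <- pmax(0, outer(a$x1, b$x1, pmin) - outer(a$x0, b$x0, pmax))
  iy <- pmax(0, outer(a$y1, b$y1, pmin) - outer(a$y0, b$y0, pmax))
  inter <- ix * iy
  union <- outer(box_areas(a), box_areas(b), "+") - inter
  inter / union
}

#' Pairwise simplified complete-IoU of two box tables
#'
#' The simplified CIoU is the IoU minus a center-distance penalty:
#' `IoU(a, b) - rho^2 / c^2`, where `rho` is the Euclidean distance between
#' the box centers and `c` is the diagonal length of the smallest rectangle
#' enclosing both boxes. It equals the IoU when the centers coincide and is
#' never larger than the IoU; disjoint boxes get a negative value in
#' `(-1, 0]`, so the measure still ranks non-overlapping boxes by
#' proximity. The aspect-ratio term of the full CIoU is deliberately
#' omitted.
#'
#' @inheritParams box_iou
#' @return A `nrow(a) x nrow(b)` numeric matrix with values in `(-1, 1]`.
#' @examples
#' box_ciou(boxes(0, 0, 2, 2), boxes(2, 0, 4, 2)) # -0.2
#' @export
box_ciou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  iou <- iou_core(a, b)
  ca <- box_centers(a); cb <- box_centers(b)
  rho2 <- outer(ca[, "cx"], cb[, "cx"], "-")^2 +
    outer(ca[, "cy"], cb[, "cy"], "-")^2
  ew <- outer(a$x1, b$x1, pmax) - outer(a$x0, b$x0, pmin)
  eh <- outer(a$y1, b$y1, pmax) - outer(a$y0, b$y0, pmin)
  c2 <- ew^2 + eh^2
  # c2 > 0 for valid boxes; guard anyway so a malformed pair cannot yield NaN
  c2[c2 == 0] <- .Machine$double.eps
  iou - rho2 / c2
}

#' Greedy non-maximum suppression
#'
#' Scans boxes in descending score order and keeps a box iff its IoU with
#' every previously kept box is strictly below `iou_threshold`. Ties in
#' score are broken deterministically by ascending `(y0, x0, x1, y1)`.
#'
#' @param b A box table with a `score` column.
#' @param iou_threshold Suppression threshold in `[0, 1]`.
#' @return The kept rows, ordered by descending score.
#' @export
box_nms <- function(b, iou_threshold = 0.5) {
  b <- validate_boxes(b)
  stopifnot(is.numeric(iou_threshold), iou_threshold >= 0, iou_threshold <= 1)
  if (nrow(b) == 0) return(b)
  if (is.null(b$score)) stop("box_nms() needs a `score` column")
  ord <- order(-b$score, b$y0, b$x0, b$x1, b$y1)
  b <- b[ord, ]
  iou <- iou_core(b, b)
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    keep[i] <- !any(iou[i, which(keep)] >= iou_threshold)
  }
  b[keep, ]
}
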