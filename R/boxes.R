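#' Axis-aligned bounding boxes
#'
#' Boxes are plain numeric matrices with columns `x_min`, `y_min`, `x_max`,
#' `y_max`, in continuous pixel coordinates with the origin at the top-left
#' corner of the frame. A box is the half-open rectangle
#' \[x_min, x_max) x \[y_min, y_max), so for integer coordinates its area
#' equals the number of unit pixels it covers. Degenerate (zero-width or
#' zero-height) and negative-coordinate boxes are rejected at construction
#' rather than silently clamped.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of equal length.
#' @return A numeric matrix with one row per box and the four named columns.
#' @examples
#' b <- boundingBox(0, 0, 10, 10)
#' boxArea(b)
#' @export
boundingBox <- function(x_min, y_min, x_max, y_max) {
  b <- cbind(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  bad <- validateBoxes(b)
  if (!is.null(bad)) stop(bad, call. = FALSE)
  b
}

## Returns NULL if all rows are valid boxes, else a message.
validateBoxes <- function(b) {
  if (!is.matrix(b) || ncol(b) != 4) return("boxes must be n x 4 matrices")
  if (any(!is.finite(b))) return("box coordinates must be finite")
  if (any(b < 0)) return("box coordinates must be >= 0")
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    return("degenerate box: need x_min < x_max and y_min < y_max")
  NULL
}

asBoxMatrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  bad <- validateBoxes(b)
  if (!is.null(bad)) stop(bad, call. = FALSE)
  b
}

#' Area of bounding boxes
#'
#' @param box A box (length-4 vector) or an `n x 4` matrix of boxes in
#'   `(x_min, y_min, x_max, y_max)` order.
#' @return Numeric vector of areas in px^2.
#' @examples
#' boxArea(boundingBox(2, 3, 4, 9))  # 12
#' @export
boxArea <- function(box) {
  b <- asBoxMatrix(box)
  unname((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]))
}

#' Jaccard (intersection-over-union) coefficient of box pairs
#'
#' The ratio of the intersection area to the union area of two axis-aligned
#' boxes. Equals 1 exactly when the boxes coincide and 0 when their
#' interiors are disjoint; it is symmetric in its arguments. Applied to a
#' tracked bird's boxes in consecutive frames it acts as a motion proxy:
#' high values mean little apparent movement.
#'
#' @param a,b Boxes (length-4 vectors) or `n x 4` matrices, recycled
#'   row-wise to a common length.
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' boxJaccard(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
boxJaccard <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- boxArea(a) + boxArea(b) - inter
  unname(inter / union)
}
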