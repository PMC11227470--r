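#' Closed contour polylines
#'
#' A contour is stored as an n x 2 numeric matrix of (x, y) vertices in pixel
#' coordinates (y down), implicitly closed (last vertex connects back to the
#' first; the first vertex is not repeated). Orientation is canonicalised so
#' the shoelace signed area is positive, which corresponds to traversal with
#' the interior on the right in a y-down frame.
#'
#' @param xy n x 2 numeric matrix of vertices.
#' @param canonicalise reorient/rotate the vertex list to the package
#'   convention (positive signed area; start at lexicographically smallest
#'   (y, x) vertex).
#' @return object of class `contour_polyline`.
#' @export
contour_polyline <- function(xy, canonicalise = TRUE) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) {
    stop("a contour needs an n x 2 matrix with n >= 3")
  }
  if (anyNA(xy)) stop("contour contains missing coordinates")
  storage.mode(xy) <- "double"
  # drop an explicitly repeated closing vertex
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("a contour needs at least 3 distinct vertices")
  if (canonicalise) {
    if (polygon_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    i0 <- order(xy[, 2], xy[, 1])[1]
    if (i0 > 1L) xy <- xy[c(i0:nrow(xy), 1:(i0 - 1L)), , drop = FALSE]
  }
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(xy, class = c("contour_polyline", "matrix", "array"),
            closed = TRUE, orientation = "interior-right")
}

#' Signed polygon area (shoelace)
#'
#' Positive for the package's canonical orientation.
#'
#' @param xy n x 2 vertex matrix (implicitly closed).
#' @return signed area in squared coordinate units.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @param xy n x 2 vertex matrix (implicitly closed).
#' @return total edge length.
#' @export
polygon_perimeter <- function(xy) {
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

#' Polygon area centroid
#' @param xy n x 2 vertex matrix (implicitly closed).
#' @return length-2 vector (x, y).
#' @export
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Test whether a closed polygon is simple (no self-intersections)
#' @param xy n x 2 vertex matrix (implicitly closed).
#' @return logical scalar.
#' @export
is_simple_polygon <- function(xy) {
  cpp_polygon_is_simple(as.matrix(xy))
}
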