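#' Leaf masks
#'
#' A `leaf_mask` couples a binary foreground grid (TRUE = leaf) with the
#' scan resolution used for physical calibration and a short processing log.
#'
#' @param mask logical matrix, TRUE = leaf pixel.
#' @param dpi scan resolution in dots per inch.
#' @param provenance character vector of processing-log lines.
#' @return object of class `leaf_mask`.
#' @export
leaf_mask <- function(mask, dpi, provenance = character()) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mode(mask) <- "logical"
  if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi)) {
    stop("dpi must be a single number")
  }
  structure(list(mask = mask, dpi = as.numeric(dpi), provenance = provenance),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("leaf_mask: %d x %d px at %g dpi, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$dpi, sum(x$mask)))
  invisible(x)
}

#' Convert an RGB image to its luminance channel
#'
#' Y component of the YUV decomposition with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to integer levels.
#'
#' @param image h x w x 3 numeric array, 0--255.
#' @return h x w numeric matrix of integer-valued luminances.
#' @export
to_luminance <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("format error: expected a 3-channel (h x w x 3) image")
  }
  y <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  dim(y) <- d[1:2]
  y
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustively maximises the between-class variance of the 256-level
#' histogram. Returns the cut t: pixels with value <= t form the dark class.
#'
#' @param gray numeric matrix, values 0--255.
#' @return integer threshold in 0..254.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(round(gray))
  if (length(unique(v)) < 2L) {
    stop("degenerate histogram: image has a single intensity value")
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  w0 <- cumsum(p)                       # P(class <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  w0t <- w0[-256]; mut <- mu[-256]      # candidate cuts t = 0..254
  sb2 <- (muT * w0t - mut)^2 / (w0t * (1 - w0t))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2) - 1L
}

#' Binarise a leaf scan by Otsu thresholding
#'
#' The darker class is taken as foreground (the leaf lies on a near-white
#' background). The result is *not* cleaned; see [clean_mask()].
#'
#' @param gray numeric matrix (luminance, 0--255).
#' @param dpi resolution carried into the mask for later calibration.
#' @return uncleaned `leaf_mask`.
#' @export
otsu_binarize <- function(gray, dpi = 1200) {
  t <- otsu_threshold(gray)
  leaf_mask(round(gray) <= t, dpi,
            sprintf("otsu_binarize: threshold=%d, foreground=dark class", t))
}

#' Clean a binary leaf mask
#'
#' Fills interior holes (background regions not connected to the image
#' border), then removes every foreground component except the largest, as
#' well as any component smaller than `min_component_px`. Hole filling runs
#' before speck removal; the order is recorded in the provenance log.
#'
#' @param mask `leaf_mask`.
#' @param min_component_px smallest foreground component kept (px).
#' @return cleaned `leaf_mask` with exactly one hole-free component.
#' @export
clean_mask <- function(mask, min_component_px = 100L) {
  stopifnot(inherits(mask, "leaf_mask"))
  m <- mask$mask
  if (!any(m)) stop("no leaf found: mask has empty foreground")
  filled <- !cpp_border_background(m)   # foreground + interior holes
  lab <- cpp_label_components(filled, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  if (sizes[keep] < min_component_px) {
    stop("no leaf found: largest component below min_component_px")
  }
  out <- lab == keep
  leaf_mask(out, mask$dpi,
            c(mask$provenance,
              sprintf("clean_mask: holes filled, kept largest of %d component(s), min_component_px=%d",
                      length(sizes), as.integer(min_component_px))))
}

#' Extract the outer contour of a clean mask
#'
#' Traces the crack boundary (pixel-edge boundary) of the single foreground
#' component. Vertices lie on the pixel-corner lattice, so the polygon's
#' shoelace area equals the foreground pixel count exactly for a hole-free
#' component. Orientation and starting vertex follow the package convention
#' (positive signed area; lexicographically smallest (y, x) start).
#'
#' @param mask cleaned `leaf_mask`.
#' @return `contour_polyline` in pixel coordinates.
#' @export
extract_contour <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  if (!any(mask$mask)) stop("no leaf found: mask has empty foreground")
  contour_polyline(cpp_trace_boundary(mask$mask))
}

#' Remove the petiole via a caller-supplied exclusion polygon
#'
#' Pixels whose centres fall inside any exclusion polygon are set to
#' background, then the mask is re-cleaned. The exclusion geometry replaces
#' the interactive petiole-removal step of scan-based workflows.
#'
#' @param mask `leaf_mask`.
#' @param exclusion single polygon (n x 2 matrix, pixel coordinates) or a
#'   list of polygons; `NULL` or an empty list is the identity.
#' @param min_component_px passed to [clean_mask()].
#' @return `leaf_mask` with the exclusion applied.
#' @export
remove_petiole <- function(mask, exclusion, min_component_px = 100L) {
  stopifnot(inherits(mask, "leaf_mask"))
  if (is.null(exclusion) || (is.list(exclusion) && length(exclusion) == 0L)) {
    return(mask)
  }
  if (!is.list(exclusion)) exclusion <- list(exclusion)
  m <- mask$mask
  for (poly in exclusion) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L) next
    inside <- cpp_fill_polygon(poly, nrow(m), ncol(m), 0, 0, 1)
    m[inside] <- FALSE
  }
  if (!any(m)) stop("no leaf found: exclusion removed the entire foreground")
  clean_mask(leaf_mask(m, mask$dpi, c(mask$provenance, "remove_petiole: exclusion applied")),
             min_component_px)
}

#' Physical leaf area of a mask
#'
#' Foreground pixel count converted with the scan resolution:
#' area = n_px * (2.54 / dpi)^2 square centimetres.
#'
#' @param mask `leaf_mask` with a valid dpi.
#' @return area in cm^2.
#' @export
area_cm2 <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  if (mask$dpi <= 0) stop("calibration error: dpi must be positive")
  sum(mask$mask) * (2.54 / mask$dpi)^2
}

#' Full preprocessing chain for one leaf scan
#'
#' RGB image -> BT.601 luminance -> Otsu binarisation -> morphological
#' cleaning (hole fill, largest component) -> optional petiole exclusion.
#'
#' @param image h x w x 3 array or a path to a PGM/PPM file.
#' @param dpi scan resolution.
#' @param petiole_exclusion optional exclusion polygon(s) for [remove_petiole()].
#' @param min_component_px passed to [clean_mask()].
#' @return cleaned `leaf_mask`.
#' @export
preprocess_leaf <- function(image, dpi = 1200, petiole_exclusion = NULL,
                            min_component_px = 100L) {
  if (is.character(image)) image <- read_pnm(image)
  m <- clean_mask(otsu_binarize(to_luminance(image), dpi), min_component_px)
  if (!is.null(petiole_exclusion)) {
    m <- remove_petiole(m, petiole_exclusion, min_component_px)
  }
  m
}
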