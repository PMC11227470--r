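#' Relative area difference of a leaf pair
#'
#' \deqn{\delta_a = 2 |A_1 - A_2| / (A_1 + A_2)}
#' Unitless in [0, 2); reports usually print it times 100 as a percentage.
#'
#' @param area1,area2 leaf areas (same units, > 0).
#' @return unitless relative difference.
#' @export
relative_area_difference <- function(area1, area2) {
  if (any(c(area1, area2) <= 0)) stop("areas must be positive")
  2 * abs(area1 - area2) / (area1 + area2)
}

#' Contour distances between two normalized shapes
#'
#' For every sample point of each contour, the Euclidean distance to the
#' nearest point *on the polyline* of the other contour is computed
#' (symmetric, Hausdorff-style set distance -- not index-matched pairing;
#' set `pairing = "index"` to match points by phase index instead).
#' `d_avg` is the mean and `d_max` the maximum of the pooled per-point
#' distances; the histogram bins the same values.
#'
#' @param s1,s2 `leaf_shape` objects with the same sample count n.
#' @param bin_width histogram bin width in image points (default 10).
#' @param pairing "nearest" (default) or "index".
#' @return list with `d_avg`, `d_max`, `histogram` (counts), `breaks`,
#'   `distances` (the pooled per-point distances).
#' @export
contour_distances <- function(s1, s2, bin_width = 10, pairing = c("nearest", "index")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(s1, "leaf_shape"), inherits(s2, "leaf_shape"))
  if (s1$n != s2$n) stop("configuration error: shapes sampled with different n")
  if (pairing == "nearest") {
    d <- c(cpp_dist_to_polyline(s1$contour, s2$contour),
           cpp_dist_to_polyline(s2$contour, s1$contour))
  } else {
    dd <- sqrt(rowSums((s1$contour - s2$contour)^2))
    d <- c(dd, dd)
  }
  brk <- seq(0, max(d, bin_width) + bin_width, by = bin_width)
  h <- tabulate(findInterval(d, brk, rightmost.closed = TRUE), nbins = length(brk) - 1L)
  list(d_avg = mean(d), d_max = max(d), histogram = h, breaks = brk, distances = d)
}

#' Squared distance in elliptic-Fourier space
#'
#' \deqn{D^2 = \frac{1}{K}\sum_{i=1}^{K} (a_{1i}-a_{2i})^2 + (b_{1i}-b_{2i})^2
#'   + (c_{1i}-c_{2i})^2 + (d_{1i}-d_{2i})^2}
#'
#' @param c1,c2 normalized `efd` objects with at least K harmonics.
#' @param K number of harmonics compared (default: all of c1).
#' @return unitless squared distance.
#' @export
efd_distance <- function(c1, c2, K = c1$K) {
  stopifnot(inherits(c1, "efd"), inherits(c2, "efd"))
  K <- as.integer(K)
  if (K < 1L || K > c1$K || K > c2$K) {
    stop("configuration error: K exceeds stored harmonics")
  }
  sum((c1$coef[seq_len(K), ] - c2$coef[seq_len(K), ])^2) / K
}

#' Mirror a normalized shape about its symmetry axis
#'
#' The symmetry axis of a normalized shape is the horizontal line through the
#' origin (the first-harmonic major axis). Mirroring maps y to -y in both the
#' reconstructed contour and the coefficients (c, d rows change sign).
#'
#' @param s `leaf_shape`.
#' @return mirrored `leaf_shape` (same class, same n).
#' @export
mirror_shape <- function(s) {
  stopifnot(inherits(s, "leaf_shape"))
  cf <- s$coeffs
  coef <- cf$coef
  coef[, 3] <- -coef[, 3]
  coef[, 4] <- -coef[, 4]
  xy <- s$contour
  xy[, 2] <- -xy[, 2]
  structure(list(coeffs = new_efd(coef, c(cf$dc[1], -cf$dc[2]), cf$normalized, cf$norm),
                 contour = xy, n = s$n),
            class = "leaf_shape")
}

#' Axial-symmetry error: mean contour-to-mirror distance
#'
#' \deqn{e_d = \frac{1}{n}\sum_{k=1}^{n} \| C'_k - C \|_2}
#' where C' is the mirror image of the normalized outline C and the norm is
#' the distance from mirrored sample point k to the nearest point on the
#' original polyline. Zero for exactly mirror-symmetric shapes; in image
#' points (major diameter = 1000).
#'
#' @param s `leaf_shape`.
#' @return e_d in image points.
#' @export
symmetry_error_distance <- function(s) {
  stopifnot(inherits(s, "leaf_shape"))
  m <- mirror_shape(s)
  mean(cpp_dist_to_polyline(m$contour, s$contour))
}

#' Axial-symmetry error: mismatch-area ratio
#'
#' \deqn{\varepsilon_a = area(C' \triangle C) / area(C)}
#' the area enclosed between the outline and its mirror image (symmetric
#' difference of the two filled regions) relative to the blade area, computed
#' on a raster grid covering the normalized plane. Unitless; reports print it
#' times 100.
#'
#' @param s `leaf_shape`.
#' @param grid_resolution number of grid cells across the bounding box's
#'   larger dimension (default 2048; must be >= 256 at the 1000-point scale).
#' @return unitless mismatch ratio (0 for perfect symmetry, 2 when the blade
#'   lies entirely on one side of the axis).
#' @export
symmetry_error_area <- function(s, grid_resolution = 2048L) {
  stopifnot(inherits(s, "leaf_shape"))
  if (grid_resolution < 256L) {
    stop("resolution error: grid_resolution must be >= 256")
  }
  xy <- s$contour
  ylim <- max(abs(xy[, 2])) + 2
  xr <- range(xy[, 1])
  pad <- 2
  x0 <- xr[1] - pad; x1 <- xr[2] + pad
  step <- max(x1 - x0, 2 * ylim) / grid_resolution
  nc <- ceiling((x1 - x0) / step)
  # grid made exactly mirror-symmetric about y = 0 (the symmetry axis), so a
  # symmetric shape and its reflection rasterise to the same cell set
  nr <- 2L * as.integer(ceiling(ylim / step))
  y0 <- -(nr / 2) * step
  f1 <- cpp_fill_polygon(xy, nr, nc, x0, y0, step)
  m <- xy; m[, 2] <- -m[, 2]
  f2 <- cpp_fill_polygon(m, nr, nc, x0, y0, step)
  n1 <- sum(f1)
  if (n1 == 0L) stop("resolution error: grid too coarse to resolve the shape")
  sum(xor(f1, f2)) / n1
}

#' Both axial-symmetry errors of one shape
#'
#' @param s `leaf_shape`.
#' @param grid_resolution passed to [symmetry_error_area()].
#' @return list with `e_d` and `epsilon_a`.
#' @export
symmetry_errors <- function(s, grid_resolution = 2048L) {
  list(e_d = symmetry_error_distance(s),
       epsilon_a = symmetry_error_area(s, grid_resolution))
}

#' Population-level shape and asymmetry ratios
#'
#' Five ratio statistics contrasting natural variation (control-control
#' pairs, symmetry of control leaves) with treatment-associated variation
#' (control-touched pairs, symmetry of touched leaves):
#' \itemize{
#'   \item delta_avg = mean(d_avg | cc) / mean(d_avg | ct)
#'   \item delta_max = mean(d_max | cc) / mean(d_max | ct)
#'   \item delta_EFD = sqrt(mean(D^2 | cc) / mean(D^2 | ct))
#'   \item delta_d   = mean(e_d | touched) / mean(e_d | control)
#'   \item delta_a   = mean(eps_a | touched) / mean(eps_a | control)
#' }
#'
#' @param pairs_cc,pairs_ct data frames with columns `d_avg`, `d_max`, `D2`
#'   for control-control and control-touched pairs.
#' @param sym_control,sym_touched data frames with columns `e_d`,
#'   `epsilon_a` per leaf.
#' @return named list of the five ratios.
#' @export
population_ratios <- function(pairs_cc, pairs_ct, sym_control, sym_touched) {
  if (!nrow(pairs_cc) || !nrow(pairs_ct) || !nrow(sym_control) || !nrow(sym_touched)) {
    stop("degenerate population: empty input list")
  }
  den <- c(mean(pairs_ct$d_avg), mean(pairs_ct$d_max), mean(pairs_ct$D2),
           mean(sym_control$e_d), mean(sym_control$epsilon_a))
  if (any(den == 0)) stop("degenerate population: zero denominator in ratio")
  list(delta_avg = mean(pairs_cc$d_avg) / den[1],
       delta_max = mean(pairs_cc$d_max) / den[2],
       delta_EFD = sqrt(mean(pairs_cc$D2) / den[3]),
       delta_d   = mean(sym_touched$e_d) / den[4],
       delta_a   = mean(sym_touched$epsilon_a) / den[5])
}

#' All pairwise metrics for one leaf pair
#'
#' @param s1,s2 `leaf_shape` objects.
#' @param area1,area2 blade areas (cm^2).
#' @param K harmonics for the EFD-space distance.
#' @param bin_width histogram bin width (image points).
#' @param pairing distance pairing mode, see [contour_distances()].
#' @return list: `delta_area`, `d_avg`, `d_max`, `D2`, `histogram`, `breaks`.
#' @export
compare_pair <- function(s1, s2, area1, area2, K = min(s1$coeffs$K, s2$coeffs$K),
                         bin_width = 10, pairing = "nearest") {
  cd <- contour_distances(s1, s2, bin_width = bin_width, pairing = pairing)
  list(delta_area = relative_area_difference(area1, area2),
       d_avg = cd$d_avg, d_max = cd$d_max,
       D2 = efd_distance(s1$coeffs, s2$coeffs, K),
       histogram = cd$histogram, breaks = cd$breaks)
}
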