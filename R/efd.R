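#' Elliptic Fourier descriptors of a closed contour
#'
#' Computes the elliptic Fourier coefficients of Kuhl & Giardina from a closed
#' polygonal contour, using exact arc-length parameterisation of the polygon
#' chain (not vertex-index parameterisation), so unevenly spaced vertices --
#' e.g. from a pixel boundary trace -- are handled correctly.
#'
#' Each harmonic i contributes a quadruple (a_i, b_i, c_i, d_i):
#' \deqn{x(t) = A_0 + \sum_i a_i \cos(i \omega t) + b_i \sin(i \omega t)}
#' \deqn{y(t) = C_0 + \sum_i c_i \cos(i \omega t) + d_i \sin(i \omega t)}
#' with \eqn{\omega = 2\pi/T} and T the contour perimeter.
#'
#' The input vertex list is canonicalised to positive shoelace orientation
#' before the transform, so coefficient signs are deterministic for any
#' traversal direction of the same polygon.
#'
#' Note one subtlety of the arc-length convention: a geometric ellipse
#' traversed at constant speed is *not* a pure first harmonic (in the flat
#' limit its x coordinate is a triangle wave), so an eccentric ellipse
#' produces small genuine higher-harmonic content. The pure-harmonic
#' identity a1 = A, d1 = B holds under phase parameterisation
#' (`parameterization = "index"` with vertices sampled uniformly in the
#' elliptic phase), which is provided for exactness checks.
#'
#' @param contour n x 2 vertex matrix or `contour_polyline` (implicitly
#'   closed, >= 3 vertices).
#' @param K number of harmonics (>= 1).
#' @param parameterization "arc" (chord-length increments, default; correct
#'   for unevenly spaced mask contours) or "index" (one parameter unit per
#'   vertex).
#' @return object of class `efd`: list with `coef` (K x 4 matrix, columns
#'   a, b, c, d), `dc` = (A0, C0), `K`, `normalized` flag and `norm` record.
#' @export
efd_forward <- function(contour, K = 50L, parameterization = c("arc", "index")) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  parameterization <- match.arg(parameterization)
  xy <- unclass(contour_polyline(contour))  # canonical orientation + start
  x <- c(xy[, 1], xy[1, 1])
  y <- c(xy[, 2], xy[1, 2])
  dx <- diff(x); dy <- diff(y)
  dt <- if (parameterization == "arc") sqrt(dx^2 + dy^2) else rep(1, length(dx))
  keep <- dt > 0 & (abs(dx) + abs(dy) > 0)
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3L) stop("degenerate contour: fewer than 3 distinct vertices")
  Tp <- sum(dt)
  if (Tp <= 0) stop("degenerate contour: zero perimeter")
  t <- cumsum(dt)
  phi <- 2 * pi * t / Tp            # phase at the END of each edge
  phi0 <- c(0, phi[-length(phi)])   # phase at the start of each edge
  N <- seq_len(K)
  # difference of cos/sin between edge end points, per harmonic (K x E)
  dcos <- cos(outer(N, phi)) - cos(outer(N, phi0))
  dsin <- sin(outer(N, phi)) - sin(outer(N, phi0))
  fac <- Tp / (2 * N^2 * pi^2)
  vx <- dx / dt; vy <- dy / dt
  a <- fac * as.vector(dcos %*% vx)
  b <- fac * as.vector(dsin %*% vx)
  cc <- fac * as.vector(dcos %*% vy)
  d <- fac * as.vector(dsin %*% vy)
  # DC component = arc-length mean of the piecewise-linear curve (trapezoid)
  xm <- x[c(keep, FALSE)] ; ym <- y[c(keep, FALSE)]
  A0 <- sum(dt * (xm + xm + dx) / 2) / Tp
  C0 <- sum(dt * (ym + ym + dy) / 2) / Tp
  new_efd(cbind(a = a, b = b, c = cc, d = d), c(A0, C0))
}

new_efd <- function(coef, dc, normalized = FALSE, norm = NULL) {
  structure(list(coef = coef, dc = dc, K = nrow(coef),
                 normalized = normalized, norm = norm),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("Elliptic Fourier descriptors: %d harmonics (%s)\n", x$K,
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  dc = (%.4g, %.4g); |H1| semi-axes = (%.4g, %.4g)\n",
              x$dc[1], x$dc[2],
              sqrt(x$coef[1, 1]^2 + x$coef[1, 3]^2),
              sqrt(x$coef[1, 2]^2 + x$coef[1, 4]^2)))
  invisible(x)
}

# starting-point phase shift by theta: harmonic i rotated in parameter by i*theta
efd_start_shift <- function(coef, theta) {
  N <- seq_len(nrow(coef))
  ct <- cos(N * theta); st <- sin(N * theta)
  cbind(a = coef[, 1] * ct + coef[, 2] * st,
        b = -coef[, 1] * st + coef[, 2] * ct,
        c = coef[, 3] * ct + coef[, 4] * st,
        d = -coef[, 3] * st + coef[, 4] * ct)
}

# rigid rotation of the plane by psi (clockwise in standard axes)
efd_rotate <- function(coef, psi) {
  cp <- cos(psi); sp <- sin(psi)
  cbind(a = cp * coef[, 1] + sp * coef[, 3],
        b = cp * coef[, 2] + sp * coef[, 4],
        c = -sp * coef[, 1] + cp * coef[, 3],
        d = -sp * coef[, 2] + cp * coef[, 4])
}

#' Normalise elliptic Fourier descriptors
#'
#' Standard frequency-domain normalisation: the starting point is shifted to
#' an end of the first-harmonic major axis, the shape is rotated so that the
#' major axis is horizontal, the translation term is zeroed, and the size is
#' scaled so that the first-harmonic ellipse major *diameter* equals 1000
#' plane units ("image points"). Reflection is deliberately NOT normalised:
#' chirality must survive for axial-asymmetry measurement.
#'
#' The residual 180-degree ambiguity of major-axis alignment is resolved by a
#' shape-dependent rule: the area centroid of the reconstructed outline is
#' placed at non-positive x (the blade's "heavy" side on the left, the tip
#' pointing right). For shapes that are symmetric front-to-back the two
#' candidates coincide, so the rule is vacuous there.
#'
#' @param coeffs raw `efd` object (first harmonic must be non-degenerate).
#' @return normalized `efd`; `norm` records scale, theta (starting-point
#'   shift), psi (rotation) and whether the 180-degree flip was applied.
#' @export
efd_normalize <- function(coeffs) {
  stopifnot(inherits(coeffs, "efd"))
  coef <- coeffs$coef
  h1 <- coef[1, ]
  if (sum(h1^2) <= 0) stop("degenerate first harmonic: cannot normalise")
  theta <- 0.5 * unname(atan2(2 * (h1[1] * h1[2] + h1[3] * h1[4]),
                       h1[1]^2 - h1[2]^2 + h1[3]^2 - h1[4]^2))
  cf <- efd_start_shift(coef, theta)
  # theta aligns the start with one first-harmonic axis; pick the major one
  if (cf[1, 1]^2 + cf[1, 3]^2 < cf[1, 2]^2 + cf[1, 4]^2) {
    theta <- theta + pi / 2
    cf <- efd_start_shift(coef, theta)
  }
  psi <- unname(atan2(cf[1, 3], cf[1, 1]))
  cf <- efd_rotate(cf, psi)
  E <- unname(cf[1, 1])              # semi-major axis length, > 0
  minor <- sqrt(cf[1, 2]^2 + cf[1, 4]^2)
  if (E > 0 && abs(E - minor) / E < 1e-9) {
    warning("circular first harmonic: orientation is ambiguous")
  }
  # resolve the 180-degree ambiguity: area centroid of the outline at x <= 0
  flipped <- FALSE
  probe <- reconstruct_xy(cf, c(0, 0), 256L)
  cx <- polygon_centroid(probe)[1]
  if (cx > 1e-9 * E) {
    theta <- theta + pi
    psi <- psi + pi
    cf <- efd_rotate(efd_start_shift(coef, theta), psi)
    E <- unname(cf[1, 1])
    flipped <- TRUE
  }
  s <- 500 / E
  new_efd(cf * s, c(0, 0), normalized = TRUE,
          norm = list(scale = s, theta = as.numeric(theta),
                      psi = as.numeric(psi), flipped = flipped))
}

# bare reconstruction used internally (no class bookkeeping)
reconstruct_xy <- function(coef, dc, n) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  N <- seq_len(nrow(coef))
  C <- cos(outer(t, N)); S <- sin(outer(t, N))
  cbind(x = dc[1] + as.vector(C %*% coef[, 1] + S %*% coef[, 2]),
        y = dc[2] + as.vector(C %*% coef[, 3] + S %*% coef[, 4]))
}

#' Inverse elliptic Fourier reconstruction
#'
#' Samples the truncated Fourier series at n uniformly spaced parameter values
#' t_k = 2*pi*(k-1)/n. Point k of two different normalized shapes corresponds
#' to the same parameter value, so reconstructions are phase-aligned.
#'
#' @param coeffs `efd` object.
#' @param n number of sample points (>= 8).
#' @return `contour_polyline` of n points (vertex order preserved, not
#'   re-canonicalised, so phase alignment survives).
#' @export
efd_inverse <- function(coeffs, n = 1000L) {
  stopifnot(inherits(coeffs, "efd"))
  n <- as.integer(n)
  if (n < 8L) stop("n must be >= 8")
  contour_polyline(reconstruct_xy(coeffs$coef, coeffs$dc, n), canonicalise = FALSE)
}

#' Normalised shape of a raw contour
#'
#' Convenience wrapper running the full Fig.-style chain on one outline:
#' forward transform with K harmonics, frequency-domain normalisation, and
#' inverse reconstruction with n phase-aligned samples. The reconstruction
#' doubles as denoising: harmonics above K are discarded.
#'
#' @param contour raw closed contour (pixel coordinates).
#' @param K harmonics kept (default 50).
#' @param n reconstruction samples (default 1000, so distances between sample
#'   points are in the same "image point" units as the 1000-point major
#'   diameter).
#' @return object of class `leaf_shape`: list with `coeffs` (normalized
#'   `efd`), `contour` (n x 2 reconstruction) and `n`.
#' @export
normalized_shape <- function(contour, K = 50L, n = 1000L) {
  cf <- efd_normalize(efd_forward(contour, K))
  structure(list(coeffs = cf, contour = unclass(efd_inverse(cf, n)), n = as.integer(n)),
            class = "leaf_shape")
}

#' @export
print.leaf_shape <- function(x, ...) {
  cat(sprintf("Normalized leaf shape: K = %d harmonics, %d contour samples\n",
              x$coeffs$K, x$n))
  invisible(x)
}

#' Write / read elliptic Fourier coefficients as CSV
#'
#' One row per harmonic (`i,a,b,c,d`); the normalisation record travels in
#' `#`-prefixed header comments.
#'
#' @param coeffs `efd` object.
#' @param path file path.
#' @return `path` invisibly (write); `efd` object (read).
#' @export
write_efd_csv <- function(coeffs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# K=%d normalized=%d A0=%.17g C0=%.17g", coeffs$K,
                     as.integer(coeffs$normalized), coeffs$dc[1], coeffs$dc[2]), con)
  if (!is.null(coeffs$norm)) {
    writeLines(sprintf("# scale=%.17g theta=%.17g psi=%.17g flipped=%d",
                       coeffs$norm$scale, coeffs$norm$theta, coeffs$norm$psi,
                       as.integer(coeffs$norm$flipped)), con)
  }
  writeLines("i,a,b,c,d", con)
  writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g", seq_len(coeffs$K),
                     coeffs$coef[, 1], coeffs$coef[, 2], coeffs$coef[, 3],
                     coeffs$coef[, 4]), con)
  invisible(path)
}

#' @rdname write_efd_csv
#' @export
read_efd_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  getf <- function(key, default = NA_real_) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    m <- unlist(m)
    if (!length(m)) return(default)
    as.numeric(sub(paste0(key, "="), "", m[1]))
  }
  norm <- NULL
  normalized <- isTRUE(getf("normalized", 0) == 1)
  if (normalized) {
    norm <- list(scale = getf("scale", 1), theta = getf("theta", 0),
                 psi = getf("psi", 0), flipped = isTRUE(getf("flipped", 0) == 1))
  }
  new_efd(cbind(a = body$a, b = body$b, c = body$c, d = body$d),
          c(getf("A0", 0), getf("C0", 0)), normalized = normalized, norm = norm)
}
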