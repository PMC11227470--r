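# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Dense-quadrature elliptic Fourier oracle: Fourier coefficients of the
# piecewise-linear closed curve through `xy`, parameterised by arc length
# ("arc") or one unit per vertex ("index"), via Riemann sums on a fine grid.
quad_efd_oracle <- function(xy, K, parameterization = "arc", m = 2^17) {
  x <- c(xy[, 1], xy[1, 1]); y <- c(xy[, 2], xy[1, 2])
  dt <- if (parameterization == "arc") {
    sqrt(diff(x)^2 + diff(y)^2)
  } else {
    rep(1, nrow(xy))
  }
  Tt <- sum(dt)
  tc <- c(0, cumsum(dt))
  ss <- seq(0, Tt, length.out = m + 1)[-(m + 1)] + Tt / (2 * m)  # midpoints
  xi <- approx(tc, x, xout = ss)$y
  yi <- approx(tc, y, xout = ss)$y
  ds <- Tt / m
  coef <- t(vapply(seq_len(K), function(n) {
    w <- 2 * pi * n * ss / Tt
    c(a = sum(xi * cos(w)) * 2 / Tt * ds,
      b = sum(xi * sin(w)) * 2 / Tt * ds,
      c = sum(yi * cos(w)) * 2 / Tt * ds,
      d = sum(yi * sin(w)) * 2 / Tt * ds)
  }, numeric(4)))
  list(coef = coef, dc = c(mean(xi), mean(yi)))
}

# Exhaustive Otsu oracle: scan all 256 cut positions, return the argmax of
# between-class variance computed from first principles.
otsu_brute_oracle <- function(gray) {
  v <- as.integer(round(gray))
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb2 <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb2 > best) { best <- sb2; best_t <- t }
  }
  best_t
}

# brute-force elementwise EFD-space distance (independent of efd_distance)
efd_distance_brute <- function(m1, m2, K) {
  s <- 0
  for (i in seq_len(K)) for (j in 1:4) s <- s + (m1[i, j] - m2[i, j])^2
  s / K
}

# two-pass standard deviation
sd_brute <- function(v) {
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / (length(v) - 1))
}

# polygon fixtures
ellipse_poly <- function(A, B, n = 1000, phase = 0, rot = 0, shift = c(0, 0),
                         scale = 1) {
  t <- 2 * pi * (seq_len(n) - 1) / n + phase
  xy <- cbind(A * cos(t), B * sin(t))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  sweep(xy %*% R * scale, 2, shift, "+")
}

disk_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad)
  cx <- r + pad + 0.5
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - cx)^2 + (j - cx)^2) <= r^2)
}

# irregular random blob mask (star-convex, smooth)
blob_mask <- function(seed, size = 120) {
  set.seed(seed)
  t <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- size / 3 * (1 + 0.25 * sin(3 * t + runif(1, 0, 2 * pi)) +
                     0.15 * cos(5 * t + runif(1, 0, 2 * pi)))
  cx <- size / 2
  poly <- cbind(cx + r * cos(t), cx + r * sin(t))
  ang <- function(i, j) atan2(i - cx, j - cx)
  outer(seq_len(size), seq_len(size), function(i, j) {
    rr <- approx(t, r, xout = (ang(i, j) %% (2 * pi)), rule = 2)$y
    sqrt((i - cx)^2 + (j - cx)^2) <= rr
  })
}

# a small fast study design used by several tests (overridable defaults)
tiny_design <- function(...) {
  args <- list(n_plants_per_group = 2L, dpi = 150, noise_sd = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(study_design, args)
}

# manifest lines with the directory stripped from the path column
manifest_lines <- function(dir) {
  gsub("[^,\"]*/", "", readLines(file.path(dir, "manifest.csv")))
}
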