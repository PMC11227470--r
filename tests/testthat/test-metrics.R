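shape_of <- function(xy, K = 20, n = 500) normalized_shape(xy, K = K, n = n)

leafish <- function(seed, asym = 0.03, area = 15, dpi = 200) {
  make_leaf_outline(leaf_shape_params(area, asymmetry_magnitude = asym,
                                      serration_depth = 0.015, seed = seed),
                    dpi = dpi)
}

test_that("relative area difference matches its closed form", {
  expect_equal(relative_area_difference(10, 10), 0)
  expect_equal(relative_area_difference(3, 1), 1)
  for (k in c(1.1, 2, 5)) {
    expect_equal(relative_area_difference(7, 7 * k), 2 * (k - 1) / (k + 1))
    expect_equal(relative_area_difference(7 * k, 7),
                 relative_area_difference(7, 7 * k))
  }
  expect_error(relative_area_difference(0, 3), "positive")
})

test_that("contour distances: identity, concentric circles, symmetry", {
  s <- shape_of(ellipse_poly(3, 1.4))
  self <- contour_distances(s, s)
  expect_equal(self$d_avg, 0)
  expect_equal(self$d_max, 0)
  expect_equal(sum(self$histogram[-1]), 0)
  expect_equal(self$histogram[1], 2L * s$n)
  # circles normalize to radius 500; scaling d1/a1 shrinks the second to 490
  c1 <- suppressWarnings(shape_of(ellipse_poly(1, 1, n = 800)))
  c2 <- c1
  c2$coeffs$coef <- c1$coeffs$coef * 0.98
  c2$contour <- c1$contour * 0.98
  cd <- contour_distances(c1, c2)
  expect_lt(abs(cd$d_avg - 10) / 10, 0.01)
  expect_lt(abs(cd$d_max - 10) / 10, 0.01)
  s2 <- shape_of(leafish(1))
  s3 <- shape_of(leafish(2))
  ab <- contour_distances(s2, s3); ba <- contour_distances(s3, s2)
  expect_equal(ab$d_avg, ba$d_avg)
  expect_equal(ab$d_max, ba$d_max)
  expect_lte(ab$d_avg, ab$d_max)
  bad <- shape_of(leafish(3), n = 400)
  expect_error(contour_distances(s2, bad), "different n")
})

test_that("EFD-space distance matches algebra and the brute-force loop", {
  s1 <- shape_of(leafish(4), K = 50)
  expect_equal(efd_distance(s1$coeffs, s1$coeffs), 0)
  c2 <- s1$coeffs
  c2$coef[1, "a"] <- c2$coef[1, "a"] + 0.25
  expect_equal(efd_distance(s1$coeffs, c2, K = 50), 0.25^2 / 50)
  set.seed(10)
  for (i in 1:100) {
    m1 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
    m2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
    e1 <- leafmorph:::new_efd(m1, c(0, 0), TRUE)
    e2 <- leafmorph:::new_efd(m2, c(0, 0), TRUE)
    got <- efd_distance(e1, e2, K = 50)
    want <- efd_distance_brute(m1, m2, 50)
    expect_lt(abs(got - want) / want, 1e-12)
  }
  expect_error(efd_distance(s1$coeffs, c2, K = 51), "exceeds")
})

test_that("mirroring is an involution that preserves unsigned area", {
  s <- shape_of(leafish(5))
  mm <- mirror_shape(mirror_shape(s))
  expect_equal(mm$contour, s$contour)
  expect_equal(mm$coeffs$coef, s$coeffs$coef)
  a0 <- polygon_area(s$contour)
  a1 <- polygon_area(mirror_shape(s)$contour)
  expect_equal(a1, -a0)
  expect_lt(abs(abs(a1) - abs(a0)) / abs(a0), 1e-12)
  # symmetric shape maps onto itself as a point set
  e <- shape_of(ellipse_poly(2, 1))
  expect_lt(max(leafmorph:::cpp_dist_to_polyline(mirror_shape(e)$contour,
                                                 e$contour)), 1e-6)
})

test_that("symmetry errors vanish for symmetric shapes and grow with the bump", {
  e <- shape_of(ellipse_poly(2.5, 1, n = 800))
  expect_lt(symmetry_error_distance(e), 1e-3)
  expect_lt(symmetry_error_area(e, 1024), 1e-2)
  eds <- sapply(c(0.01, 0.02, 0.04), function(m)
    symmetry_error_distance(shape_of(leafish(7, asym = m))))
  expect_true(all(diff(eds) > 0))
  # invariance under rigid motion of the raw input
  xy <- unclass(leafish(8))
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(xy %*% R * 1.9, 2, c(300, 500), "+")
  expect_equal(symmetry_error_distance(shape_of(moved)),
               symmetry_error_distance(shape_of(xy)), tolerance = 1e-6)
})

test_that("mismatch-area ratio handles the extreme half-disk and converges", {
  # half-disk entirely above the axis: mirror misses completely, eps_a = 2.
  # Build it directly as a normalized-plane contour.
  t <- seq(0, pi, length.out = 400)
  half <- rbind(cbind(500 * cos(t), 500 * sin(t) + 1e-6),
                cbind(seq(-500, 500, length.out = 200), 1e-6))
  s <- structure(list(coeffs = NULL, contour = half, n = nrow(half)),
                 class = "leaf_shape")
  expect_lt(abs(symmetry_error_area(s, 1024) - 2), 0.04)
  lf <- shape_of(leafish(9, asym = 0.03))
  v1 <- symmetry_error_area(lf, 1024)
  v2 <- symmetry_error_area(lf, 2048)
  expect_lt(abs(v1 - v2) / v2, 0.01)
  expect_error(symmetry_error_area(lf, 128), "resolution")
})

test_that("e_d and eps_a rank leaves identically (same construct)", {
  mags <- seq(0, 0.05, length.out = 24)
  res <- sapply(seq_along(mags), function(i) {
    s <- shape_of(leafish(100 + i, asym = mags[i]))
    c(symmetry_error_distance(s), symmetry_error_area(s, 512))
  })
  expect_gt(cor(res[1, ], res[2, ], method = "spearman"), 0.9)
})

test_that("population ratios: exact unit case and degenerate errors", {
  pair <- data.frame(d_avg = 3.3, d_max = 7.1, D2 = 0.02)
  sym <- data.frame(e_d = 5, epsilon_a = 0.1)
  r <- population_ratios(pair, pair, sym, sym)
  expect_equal(r$delta_avg, 1); expect_equal(r$delta_max, 1)
  expect_equal(r$delta_EFD, 1); expect_equal(r$delta_d, 1)
  expect_equal(r$delta_a, 1)
  zero <- data.frame(d_avg = 0, d_max = 0, D2 = 0)
  expect_error(population_ratios(pair, zero, sym, sym), "zero denominator")
  expect_error(population_ratios(pair[0, ], pair, sym, sym), "empty")
})
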