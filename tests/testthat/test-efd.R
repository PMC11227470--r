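test_that("phase-parameterised ellipse is a pure first harmonic", {
  cf <- efd_forward(ellipse_poly(3, 1.5), K = 10, parameterization = "index")
  nf <- efd_normalize(cf)
  expect_equal(unname(nf$coef[1, "a"]), 500, tolerance = 1e-9)
  expect_lt(abs(nf$coef[1, "b"]), 1e-6)
  expect_lt(abs(nf$coef[1, "c"]), 1e-6)
  expect_equal(unname(nf$coef[1, "d"]), 500 * 1.5 / 3, tolerance = 1e-6)
  amp <- sqrt(rowSums(nf$coef^2))
  expect_lt(max(amp[-1]), 1e-3 * amp[1])
})

test_that("forward coefficients match the dense-quadrature oracle", {
  # circle (spec anchor) plus random simple polygons, both parameterisations
  circ <- ellipse_poly(1, 1, n = 400)
  for (par in c("arc", "index")) {
    got <- efd_forward(circ, K = 10, parameterization = par)
    want <- quad_efd_oracle(unclass(contour_polyline(circ)), 10, par)
    expect_equal(got$coef, want$coef, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(got$dc, want$dc, tolerance = 1e-6)
  }
  set.seed(5)
  for (i in 1:10) {
    t <- sort(runif(40, 0, 2 * pi))
    r <- 2 + 0.5 * sin(3 * t + runif(1, 0, pi)) + rnorm(40, 0, 0.05)
    poly <- cbind(r * cos(t), r * sin(t))
    got <- efd_forward(poly, K = 8)
    want <- quad_efd_oracle(unclass(contour_polyline(poly)), 8, "arc")
    scale <- max(abs(want$coef))
    expect_lt(max(abs(got$coef - want$coef)) / scale, 1e-6)
  }
})

test_that("translation moves only the DC term", {
  poly <- ellipse_poly(2, 1, n = 200, phase = 0.3)
  a <- efd_forward(poly, K = 6)
  b <- efd_forward(sweep(poly, 2, c(13.7, -4.2), "+"), K = 6)
  expect_equal(a$coef, b$coef, tolerance = 1e-9)
  expect_equal(b$dc - a$dc, c(13.7, -4.2), tolerance = 1e-9)
})

test_that("normalisation is similarity-invariant and idempotent", {
  ref <- efd_normalize(efd_forward(ellipse_poly(3, 1.2), K = 8))
  for (th in c(0.01, pi / 5, pi / 2, 2.2, pi, 5.9)) {
    nf <- efd_normalize(efd_forward(
      ellipse_poly(3, 1.2, rot = th, shift = c(40, -7), scale = 2.7), K = 8))
    expect_equal(nf$coef, ref$coef, tolerance = 1e-6)
  }
  twice <- efd_normalize(ref)
  expect_equal(twice$coef, ref$coef, tolerance = 1e-12)
  expect_equal(twice$dc, c(0, 0))
  # normalized invariants
  expect_equal(unname(2 * sqrt(ref$coef[1, "a"]^2 + ref$coef[1, "c"]^2)), 1000,
               tolerance = 1e-6)
  expect_lt(abs(ref$coef[1, "b"]), 1e-9 * 500)
  expect_lt(abs(ref$coef[1, "c"]), 1e-9 * 500)
})

test_that("K=1 inverse lies exactly on the first-harmonic ellipse", {
  cf <- efd_normalize(efd_forward(ellipse_poly(2, 1, n = 500), K = 1,
                                  parameterization = "index"))
  xy <- efd_inverse(cf, n = 64)
  A <- cf$coef[1, "a"]; B <- abs(cf$coef[1, "d"])
  resid <- (xy[, 1] / A)^2 + (xy[, 2] / B)^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("round-trip error shrinks with K and is small at K=50", {
  p <- leaf_shape_params(20, asymmetry_magnitude = 0.02,
                         serration_depth = 0.015, seed = 2)
  outline <- make_leaf_outline(p, dpi = 300)
  errs <- sapply(c(5, 15, 30, 50), function(K) {
    sh <- normalized_shape(outline, K = K, n = 500)
    nrm <- sh$coeffs$norm
    R <- matrix(c(cos(nrm$psi), sin(nrm$psi), -sin(nrm$psi), cos(nrm$psi)), 2)
    raw <- efd_forward(outline, K = 1)   # just for the dc term
    ref <- sweep(unclass(outline), 2, raw$dc, "-") %*% R * nrm$scale
    mean(leafmorph:::cpp_dist_to_polyline(sh$contour, ref))
  })
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[length(errs)], 5)       # < 0.5 % of the 1000-point diameter
})

test_that("starting-vertex rotation does not change normalized coefficients", {
  poly <- unclass(make_leaf_outline(
    leaf_shape_params(10, asymmetry_magnitude = 0.03, serration_depth = 0.015,
                      seed = 4), dpi = 200))
  ref <- efd_normalize(efd_forward(poly, K = 20))
  for (shift in c(17, 200, 519)) {
    rolled <- poly[c((shift + 1):nrow(poly), 1:shift), ]
    nf <- efd_normalize(efd_forward(rolled, K = 20))
    expect_equal(nf$coef, ref$coef, tolerance = 1e-6)
  }
})

test_that("harmonic energy decays beyond the serration harmonic", {
  p <- leaf_shape_params(20, serration_depth = 0.02, seed = 9)
  cf <- efd_normalize(efd_forward(make_leaf_outline(p, dpi = 300), K = 50))
  amp <- sqrt(rowSums(cf$coef^2))
  # marginal teeth modulate into a band around the serration harmonic;
  # energy beyond that band keeps decaying
  expect_lt(mean(amp[22:50]), mean(amp[13:21]))
  expect_lt(mean(amp[40:50]), mean(amp[22:32]))
})

test_that("degenerate contours are rejected", {
  expect_error(efd_forward(cbind(c(0, 0, 0), c(0, 0, 0)), K = 3), "degenerate|distinct")
  expect_error(efd_inverse(efd_forward(ellipse_poly(1, 1, 50), 3), n = 4), "n must")
})

test_that("coefficient CSV round-trips", {
  cf <- efd_normalize(efd_forward(ellipse_poly(3, 2, 300), K = 12))
  p <- tempfile(fileext = ".csv")
  write_efd_csv(cf, p)
  back <- read_efd_csv(p)
  expect_equal(back$coef, cf$coef, ignore_attr = TRUE)
  expect_true(back$normalized)
  expect_equal(back$norm$scale, cf$norm$scale)
})
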