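test_that("luminance follows BT.601 weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_luminance(px(255, 255, 255))[1, 1], 255)
  for (g in c(0, 1, 77, 128, 254)) {
    expect_equal(to_luminance(px(g, g, g))[1, 1], g)
  }
  expect_equal(to_luminance(px(100, 200, 50))[1, 1], 153)
  expect_error(to_luminance(matrix(0, 4, 4)), "3-channel")
})

test_that("Otsu threshold separates bimodal images and matches the exhaustive scan", {
  set.seed(42)
  img <- matrix(sample(c(10, 250), 400, TRUE, prob = c(0.4, 0.6)), 20, 20)
  t <- otsu_threshold(img)
  expect_gte(t, 10); expect_lt(t, 250)   # dark class is {v <= t}
  mask <- otsu_binarize(img, dpi = 100)
  expect_true(all(mask$mask == (img == 10)))  # dark class is foreground
  for (s in 1:20) {
    set.seed(s)
    g <- matrix(pmin(255, pmax(0, round(c(rnorm(2048, 90, 30),
                                          rnorm(2048, 190, 25))))), 64, 64)
    expect_identical(otsu_threshold(g), otsu_brute_oracle(g))
  }
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("clean_mask fills holes, drops specks, and is idempotent", {
  m <- matrix(FALSE, 120, 120)
  m[10:109, 10:109] <- TRUE           # 10^4 blob
  m[50, 50:54] <- FALSE               # 5 px hole
  m[115:119, 10:19] <- TRUE           # 50 px speck
  lm <- leaf_mask(m, 1200)
  cl <- clean_mask(lm, min_component_px = 100)
  expect_equal(sum(cl$mask), 100 * 100)          # hole refilled, speck gone
  expect_equal(sum(cl$mask) - sum(m[10:109, 10:109]), 5)
  again <- clean_mask(cl, min_component_px = 100)
  expect_identical(again$mask, cl$mask)
  lab <- leafmorph:::cpp_label_components(cl$mask, 8L)
  expect_equal(max(lab), 1L)
  expect_error(clean_mask(leaf_mask(matrix(FALSE, 5, 5), 1200)), "no leaf")
})

test_that("extract_contour reproduces square and circle geometry exactly", {
  sq <- matrix(FALSE, 120, 120)
  sq[11:110, 11:110] <- TRUE
  ct <- extract_contour(leaf_mask(sq, 1200))
  expect_equal(polygon_perimeter(ct), 400)
  expect_equal(polygon_area(ct), 100 * 100)      # crack polygon area == px count
  dm <- disk_mask(200)
  ctc <- extract_contour(leaf_mask(dm, 1200))
  expect_equal(polygon_area(ctc), sum(dm))       # exact for hole-free region
  expect_lt(abs(polygon_area(ctc) - pi * 200^2) / (pi * 200^2), 0.01)
})

test_that("contour orientation and start vertex are a fixed convention", {
  for (s in 1:20) {
    m <- blob_mask(s)
    ct <- extract_contour(leaf_mask(m, 1200))
    expect_gt(polygon_area(ct), 0)               # canonical orientation
    first <- ct[1, ]
    expect_true(all(ct[, 2] > first[2] | (ct[, 2] == first[2] & ct[, 1] >= first[1])))
  }
})

test_that("remove_petiole subtracts exactly the excluded stub", {
  m <- matrix(FALSE, 160, 160)
  m[30:129, 30:129] <- TRUE                     # blade
  m[70:89, 130:149] <- TRUE                     # 20x20 stub on the right
  lm <- clean_mask(leaf_mask(m, 1200))
  stub_px <- 20 * 20
  excl <- cbind(c(129.5, 160, 160, 129.5), c(60, 60, 100, 100))
  out <- remove_petiole(lm, excl)
  expect_lt(abs((sum(lm$mask) - sum(out$mask)) - stub_px) / stub_px, 0.01)
  far <- cbind(c(1, 5, 5, 1), c(1, 1, 5, 5))
  expect_identical(sum(remove_petiole(lm, far)$mask), sum(lm$mask))
  expect_identical(remove_petiole(lm, list())$mask, lm$mask)
  all_of_it <- cbind(c(0, 160, 160, 0), c(0, 0, 160, 160))
  expect_error(remove_petiole(lm, all_of_it), "no leaf")
})

test_that("physical area calibration follows (2.54/dpi)^2", {
  one <- leaf_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), 1200)
  expect_equal(area_cm2(one), (2.54 / 1200)^2)
  sq <- matrix(FALSE, 480, 480); sq[5:476, 5:476] <- TRUE
  expect_equal(area_cm2(leaf_mask(sq, 1200)), (472 * 2.54 / 1200)^2,
               tolerance = 1e-12)
  expect_error(area_cm2(leaf_mask(sq, 0)), "calibration")
})

test_that("dpi changes cancel for a fixed physical object", {
  p <- leaf_shape_params(6, serration_depth = 0.015, noise_sd = 0)
  a <- sapply(c(150, 300), function(dpi) {
    ras <- rasterize_leaf(make_leaf_outline(p, dpi = dpi), noise_sd = 0)
    area_cm2(preprocess_leaf(ras$image, dpi = dpi))
  })
  expect_lt(abs(a[1] - a[2]) / a[2], 0.01)
  expect_lt(abs(a[2] - 6) / 6, 0.01)             # generator ground truth
})

test_that("measured area is robust to 90-degree rotation of the scan", {
  p <- leaf_shape_params(5, asymmetry_magnitude = 0.02, serration_depth = 0.015,
                         noise_sd = 0, seed = 11)
  img <- rasterize_leaf(make_leaf_outline(p, dpi = 200), noise_sd = 0)$image
  rot <- array(0, dim = c(dim(img)[2], dim(img)[1], 3))
  for (k in 1:3) rot[, , k] <- t(img[, , k])[, dim(img)[1]:1]
  a1 <- area_cm2(preprocess_leaf(img, dpi = 200))
  a2 <- area_cm2(preprocess_leaf(rot, dpi = 200))
  expect_lt(abs(a1 - a2) / a1, 0.005)
})
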