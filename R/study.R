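# End-to-end measurement of leaves and assembly of the pair tables.

#' Measure one leaf from a raw closed contour
#'
#' Runs the shape chain (EFD forward, normalisation, inverse reconstruction)
#' and the two axial-symmetry errors.
#'
#' @param contour closed contour in pixel coordinates.
#' @param area_cm2 blade area in cm^2 (from the mask, or polygon-derived).
#' @param K,n,grid_resolution analysis settings; see [normalized_shape()] and
#'   [symmetry_error_area()].
#' @return list: `area_cm2`, `e_d`, `epsilon_a`, `shape` (`leaf_shape`).
#' @export
measure_contour <- function(contour, area_cm2, K = 50L, n = 1000L,
                            grid_resolution = 2048L) {
  shape <- normalized_shape(contour, K = K, n = n)
  list(area_cm2 = area_cm2,
       e_d = symmetry_error_distance(shape),
       epsilon_a = symmetry_error_area(shape, grid_resolution),
       shape = shape)
}

#' Measure one leaf from a scan image
#'
#' Full chain: luminance, Otsu mask, morphological cleaning, optional petiole
#' exclusion, contour extraction, physical area, EFD shape and symmetry
#' errors.
#'
#' @param image h x w x 3 array or path to a PPM/PGM file.
#' @param dpi scan resolution.
#' @param petiole_exclusion optional exclusion polygon(s).
#' @param K,n,grid_resolution analysis settings.
#' @param min_component_px speck-removal threshold for [clean_mask()].
#' @return as [measure_contour()], plus `mask`.
#' @export
measure_leaf_image <- function(image, dpi = 1200, petiole_exclusion = NULL,
                               K = 50L, n = 1000L, grid_resolution = 2048L,
                               min_component_px = 100L) {
  mask <- preprocess_leaf(image, dpi = dpi, petiole_exclusion = petiole_exclusion,
                          min_component_px = min_component_px)
  out <- measure_contour(extract_contour(mask), area_cm2(mask),
                         K = K, n = n, grid_resolution = grid_resolution)
  out$mask <- mask
  out
}

#' Build the leaf-pair table for a study
#'
#' Two pair categories follow the reference design: `ct` pairs one touched
#' leaf with the control leaf at the corresponding node and position of the
#' matched replicate (14 per node with default design), and `cc` pairs the
#' two untouched leaves attached to the same node of the same control plant
#' (7 per node), capturing natural variation.
#'
#' @param manifest data frame with `plant_id`, `node`, `treatment`,
#'   `leaf_index` (one row per leaf).
#' @return data frame `id1`, `id2`, `node`, `category`.
#' @export
build_pairs <- function(manifest) {
  id <- leaf_ids(manifest)
  key <- function(tr, p, nd, li) {
    id[manifest$treatment == tr & manifest$plant_id == p &
         manifest$node == nd & manifest$leaf_index == li]
  }
  cpl <- unique(manifest$plant_id[manifest$treatment == "control"])
  tpl <- unique(manifest$plant_id[manifest$treatment == "touched"])
  rows <- list()
  for (nd in unique(manifest$node)) {
    for (i in seq_along(cpl)) {
      l1 <- key("control", cpl[i], nd, 1L)
      l2 <- key("control", cpl[i], nd, 2L)
      if (length(l1) == 1L && length(l2) == 1L) {
        rows[[length(rows) + 1L]] <-
          data.frame(id1 = l1, id2 = l2, node = nd, category = "cc")
      }
      if (i <= length(tpl)) {
        for (li in unique(manifest$leaf_index)) {
          t1 <- key("touched", tpl[i], nd, li)
          c1 <- key("control", cpl[i], nd, li)
          if (length(t1) == 1L && length(c1) == 1L) {
            rows[[length(rows) + 1L]] <-
              data.frame(id1 = c1, id2 = t1, node = nd, category = "ct")
          }
        }
      }
    }
  }
  if (!length(rows)) stop("incomplete design: no valid pairs could be formed")
  do.call(rbind, rows)
}

leaf_ids <- function(manifest) {
  sprintf("%s_%s_%d", manifest$plant_id, manifest$node, manifest$leaf_index)
}

#' Simulate a study and measure every leaf
#'
#' The workhorse for calibration and power experiments: generates a synthetic
#' study and runs the measurement chain on each leaf, either directly on the
#' generated outlines (`raster = FALSE`, fast; bypasses the imaging stage) or
#' through rasterised scans and the full mask pipeline (`raster = TRUE`).
#'
#' @param design `study_design`.
#' @param K,n,grid_resolution analysis settings (reduce n and the grid for
#'   large simulation batches).
#' @param raster run the full image pipeline instead of measuring outlines.
#' @return list: `measurements` (one row per leaf incl. `e_d`, `epsilon_a`),
#'   `pairs` (pair metrics table), `shapes` (named list of `leaf_shape`).
#' @export
simulate_study_measurements <- function(design, K = 50L, n = 1000L,
                                        grid_resolution = 2048L, raster = FALSE) {
  study <- generate_study(design)
  manifest <- study$manifest
  ids <- leaf_ids(manifest)
  shapes <- vector("list", nrow(manifest))
  meas <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    lf <- study$leaves[[i]]
    if (raster) {
      ras <- rasterize_leaf(lf$outline, noise_sd = lf$params$noise_sd,
                            seed = lf$noise_seed)
      m <- measure_leaf_image(ras$image, dpi = design$dpi, K = K, n = n,
                              grid_resolution = grid_resolution)
    } else {
      area <- abs(polygon_area(lf$outline)) * (2.54 / design$dpi)^2
      m <- measure_contour(lf$outline, area, K = K, n = n,
                           grid_resolution = grid_resolution)
    }
    shapes[[i]] <- m$shape
    meas[[i]] <- data.frame(leaf_id = ids[i], manifest[i, , drop = FALSE],
                            area_cm2 = m$area_cm2, e_d = m$e_d,
                            epsilon_a = m$epsilon_a, stringsAsFactors = FALSE)
  }
  names(shapes) <- ids
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  pairs <- build_pairs(manifest)
  pairs <- cbind(pairs, pair_metrics(pairs, measurements, shapes, K = K))
  list(measurements = measurements, pairs = pairs, shapes = shapes)
}

#' Pairwise metrics for a pair table
#'
#' @param pairs data frame from [build_pairs()].
#' @param measurements per-leaf table with `leaf_id` and `area_cm2`.
#' @param shapes named list of `leaf_shape` keyed by leaf id.
#' @param K harmonics for the EFD-space distance.
#' @param bin_width,pairing see [contour_distances()].
#' @return data frame `delta_area`, `d_avg`, `d_max`, `D2`.
#' @export
pair_metrics <- function(pairs, measurements, shapes, K = 50L,
                         bin_width = 10, pairing = "nearest") {
  area <- stats::setNames(measurements$area_cm2, measurements$leaf_id)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    s1 <- shapes[[pairs$id1[i]]]
    s2 <- shapes[[pairs$id2[i]]]
    if (is.null(s1) || is.null(s2)) {
      stop("incomplete design: missing shape for pair ",
           pairs$id1[i], " / ", pairs$id2[i])
    }
    pc <- compare_pair(s1, s2, area[[pairs$id1[i]]], area[[pairs$id2[i]]],
                       K = K, bin_width = bin_width, pairing = pairing)
    data.frame(delta_area = pc$delta_area, d_avg = pc$d_avg,
               d_max = pc$d_max, D2 = pc$D2)
  })
  do.call(rbind, out)
}
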