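# Synthetic single-leaf scans with the statistical structure the analysis
# assumes: an ovate, serrated, nettle-like blade defined directly in elliptic
# Fourier space, an antisymmetric normal-displacement field as the asymmetry
# ground truth, and a two-treatment study layout.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generator calls do not
#' perturb the global random stream.
#' @param seed integer seed.
#' @param code expression.
#' @return value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-leaf sub-seed, independent of generation order;
# all factors small enough that the product stays exact in double precision
derive_seed <- function(master_seed, counter, stream = 1L) {
  ((as.numeric(master_seed) %% 2147483629) * 1048573 +
     as.numeric(counter) * 7919 + as.numeric(stream) * 104729) %% 2147483629 + 1
}

#' Default base outline coefficients of the synthetic leaf
#'
#' Low-harmonic elliptic Fourier quadruples (columns a, b, c, d) of a
#' mirror-symmetric ovate blade with an acute tip: harmonic 1 sets the
#' aspect ratio, harmonics 2--3 the ovate taper. Only (a, d) entries are
#' non-zero, which makes the outline exactly symmetric about the x axis.
#'
#' @return 3 x 4 coefficient matrix.
#' @export
default_leaf_coefficients <- function() {
  cbind(a = c(1.00, -0.10, 0.05),
        b = c(0, 0, 0),
        c = c(0, 0, 0),
        d = c(0.55, 0.10, -0.03))
}

#' Parameters of one synthetic leaf outline
#'
#' @param area_cm2 target blade area (cm^2), > 0.
#' @param asymmetry_magnitude amplitude (relative to the semi-major axis) of
#'   the antisymmetric normal-displacement field; 0 = perfectly symmetric.
#' @param serration_depth amplitude of the marginal tooth ripple (relative
#'   units); 0 = smooth margin.
#' @param noise_sd pixel-intensity noise sd on the 0--255 scale (used at
#'   rasterisation).
#' @param seed RNG seed driving the random direction of the asymmetry field.
#' @param base_coefficients low-harmonic (a, b, c, d) matrix of the blade
#'   body; see [default_leaf_coefficients()].
#' @param serration_harmonic angular frequency of the marginal teeth.
#' @param n_vertices outline sampling density.
#' @return object of class `leaf_shape_params`.
#' @export
leaf_shape_params <- function(area_cm2, asymmetry_magnitude = 0,
                              serration_depth = 0, noise_sd = 5, seed = 1L,
                              base_coefficients = default_leaf_coefficients(),
                              serration_harmonic = 18L, n_vertices = 720L) {
  if (!is.numeric(area_cm2) || area_cm2 <= 0) stop("area_cm2 must be > 0")
  if (asymmetry_magnitude < 0) stop("asymmetry_magnitude must be >= 0")
  if (serration_depth < 0) stop("serration_depth must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(area_cm2 = area_cm2,
                 asymmetry_magnitude = asymmetry_magnitude,
                 serration_depth = serration_depth,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 base_coefficients = base_coefficients,
                 serration_harmonic = as.integer(serration_harmonic),
                 n_vertices = as.integer(n_vertices)),
            class = "leaf_shape_params")
}

#' Generate a synthetic leaf outline
#'
#' The blade body is reconstructed from the base coefficients; a marginal
#' ripple (`serration_depth * cos(m t)`, even in t, hence symmetric) and an
#' antisymmetric normal-displacement field
#' `asymmetry_magnitude * sum_j w_j sin(j t)` (odd in t about the tip-to-base
#' axis, random direction weights w from the seed, RMS-normalised) are added
#' along the outward normal. The polygon is then scaled so its enclosed area
#' equals `area_cm2` at the stated dpi exactly.
#'
#' @param params `leaf_shape_params`.
#' @param dpi raster resolution used for the physical-size conversion.
#' @return `contour_polyline` in pixel units, centred at the origin.
#' @export
make_leaf_outline <- function(params, dpi = 1200) {
  stopifnot(inherits(params, "leaf_shape_params"))
  n <- params$n_vertices
  t <- 2 * pi * (seq_len(n) - 1L) / n
  cf <- params$base_coefficients
  K <- nrow(cf)
  N <- seq_len(K)
  Ct <- cos(outer(t, N)); St <- sin(outer(t, N))
  x <- as.vector(Ct %*% cf[, 1] + St %*% cf[, 2])
  y <- as.vector(Ct %*% cf[, 3] + St %*% cf[, 4])
  # analytic tangent of the Fourier curve -> outward unit normal (y', -x')
  dxdt <- as.vector(-St %*% (N * cf[, 1]) + Ct %*% (N * cf[, 2]))
  dydt <- as.vector(-St %*% (N * cf[, 3]) + Ct %*% (N * cf[, 4]))
  sp <- sqrt(dxdt^2 + dydt^2)
  nx <- dydt / sp; ny <- -dxdt / sp
  disp <- params$serration_depth * cos(params$serration_harmonic * t)
  if (params$asymmetry_magnitude > 0) {
    w <- with_seed(params$seed, stats::rnorm(4L))
    w <- w / sqrt(sum(w^2) / 2)        # field sum_j w_j sin(j t) has unit RMS
    field <- as.vector(sin(outer(t, 1:4)) %*% w)
    disp <- disp + params$asymmetry_magnitude * field
  }
  x <- x + disp * nx
  y <- y + disp * ny
  xy <- cbind(x = x, y = y)
  if (!cpp_polygon_is_simple(xy)) {
    stop(sprintf(paste0("invalid shape: outline self-intersects ",
                        "(serration_depth=%g, asymmetry_magnitude=%g)"),
                 params$serration_depth, params$asymmetry_magnitude))
  }
  target_px <- params$area_cm2 * (dpi / 2.54)^2
  s <- sqrt(target_px / abs(polygon_area(xy)))
  contour_polyline(xy * s)
}

#' Rasterise a leaf outline into a colour scan
#'
#' Produces a near-white background with a darker, green-toned filled blade,
#' plus optional additive Gaussian pixel noise -- emulating a flatbed scan of
#' a detached leaf. Deterministic for a fixed seed.
#'
#' @param outline closed contour in pixel coordinates.
#' @param noise_sd intensity noise sd (0--255 scale).
#' @param seed RNG seed for the noise.
#' @param margin_px background margin around the blade.
#' @param canvas_px optional c(width, height); error if the outline does not
#'   fit.
#' @param leaf_rgb,bg_rgb blade / background colours.
#' @return list: `image` (h x w x 3 array), `mask` (ground-truth fill),
#'   `outline` (the shifted contour in canvas coordinates).
#' @export
rasterize_leaf <- function(outline, noise_sd = 5, seed = 1L, margin_px = 10L,
                           canvas_px = NULL, leaf_rgb = c(70, 115, 60),
                           bg_rgb = c(250, 250, 248)) {
  xy <- as.matrix(outline)
  off <- c(margin_px - min(xy[, 1]), margin_px - min(xy[, 2]))
  xy[, 1] <- xy[, 1] + off[1]
  xy[, 2] <- xy[, 2] + off[2]
  w <- ceiling(max(xy[, 1])) + margin_px
  h <- ceiling(max(xy[, 2])) + margin_px
  if (!is.null(canvas_px)) {
    if (w > canvas_px[1] || h > canvas_px[2]) {
      stop(sprintf("canvas overflow: outline needs %d x %d px, canvas is %d x %d",
                   w, h, canvas_px[1], canvas_px[2]))
    }
    w <- canvas_px[1]; h <- canvas_px[2]
  }
  mask <- cpp_fill_polygon(xy, h, w, 0, 0, 1)
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    ch <- matrix(bg_rgb[k], h, w)
    ch[mask] <- leaf_rgb[k]
    img[, , k] <- ch
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  img <- round(img)
  list(image = img, mask = mask, outline = contour_polyline(xy))
}

#' Study design of the synthetic touch experiment
#'
#' Defaults mirror the reference design: 7 replicate plants per treatment,
#' three analysed top nodes (a, b, c) with two leaves each, i.e. 84 leaves;
#' control per-node mean areas follow the reference measurements, touched
#' areas are scaled per node by `area_effect`, and touched asymmetry
#' magnitudes are scaled by `asymmetry_factor` so the expected symmetry-error
#' ratio between treatments equals that factor (both symmetry errors are, to
#' first order, proportional to the injected magnitude).
#'
#' @param n_plants_per_group replicate plants per treatment (default 7).
#' @param nodes node labels, top first (default c("a", "b", "c")).
#' @param leaves_per_node leaves per node (default 2).
#' @param area_means_control per-node mean control areas, cm^2.
#' @param area_effect per-node multiplicative area change in touched plants.
#' @param asymmetry_factor target touched/control symmetry-error ratio.
#' @param within_group_cv log-normal coefficient of variation of area.
#' @param base_asymmetry mean asymmetry magnitude of control leaves.
#' @param asym_cv log-normal CV of per-leaf asymmetry magnitude.
#' @param shape_jitter_sd sd of the per-leaf perturbation of the symmetric
#'   base coefficients (natural shape variation between leaves).
#' @param serration_depth marginal tooth amplitude.
#' @param noise_sd scan noise sd.
#' @param dpi raster resolution.
#' @param master_seed seed from which every per-leaf stream is derived.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_plants_per_group = 7L,
                         nodes = c("a", "b", "c"),
                         leaves_per_node = 2L,
                         area_means_control = c(4.67, 22.61, 23.96),
                         area_effect = c(0.86, 0.29, 0.43),
                         asymmetry_factor = 1.6,
                         within_group_cv = 0.45,
                         base_asymmetry = 0.015,
                         asym_cv = 0.3,
                         shape_jitter_sd = 0.03,
                         serration_depth = 0.015,
                         noise_sd = 5,
                         dpi = 1200,
                         master_seed = 1L) {
  if (length(area_means_control) != length(nodes)) {
    stop("area_means_control must have one entry per node")
  }
  if (length(area_effect) == 1L) area_effect <- rep(area_effect, length(nodes))
  if (length(area_effect) != length(nodes)) {
    stop("area_effect must have one entry per node (or a scalar)")
  }
  structure(list(n_plants_per_group = as.integer(n_plants_per_group),
                 nodes = nodes, leaves_per_node = as.integer(leaves_per_node),
                 area_means_control = area_means_control,
                 area_effect = area_effect,
                 asymmetry_factor = asymmetry_factor,
                 within_group_cv = within_group_cv,
                 base_asymmetry = base_asymmetry, asym_cv = asym_cv,
                 shape_jitter_sd = shape_jitter_sd,
                 serration_depth = serration_depth,
                 noise_sd = noise_sd, dpi = dpi,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

# mean-exact log-normal draw: E[value] = m, CV = cv
rlnorm_mean <- function(n, m, cv) {
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

# draw one leaf's ground-truth parameters and outline; the rare jitter draw
# whose serrated outline would self-intersect is rejected and redrawn from a
# derived sub-seed (bounded, deterministic)
generate_leaf <- function(design, treatment, node_idx, counter) {
  seed_draw <- derive_seed(design$master_seed, counter, 1L)
  touched <- treatment == "touched"
  draws <- with_seed(seed_draw, {
    m_area <- design$area_means_control[node_idx] *
      (if (touched) design$area_effect[node_idx] else 1)
    m_asym <- design$base_asymmetry *
      (if (touched) design$asymmetry_factor else 1)
    list(area = rlnorm_mean(1L, m_area, design$within_group_cv),
         asym = rlnorm_mean(1L, m_asym, design$asym_cv))
  })
  # per-harmonic jitter scales: natural variation is dominated by aspect
  # ratio and ovate taper; tip harmonics vary least
  jsc <- design$shape_jitter_sd * c(1, 0.5, 0.5, 0.25, 0.25)
  for (attempt in 1:12) {
    seed_shape <- derive_seed(design$master_seed, counter, 10L + attempt)
    jitter <- with_seed(seed_shape, stats::rnorm(5L)) * jsc
    cf <- default_leaf_coefficients()
    cf[1, 4] <- cf[1, 4] + jitter[1]              # aspect ratio
    cf[2, 1] <- cf[2, 1] + jitter[2]              # ovate taper
    cf[2, 4] <- cf[2, 4] + jitter[3]
    cf[3, 1] <- cf[3, 1] + jitter[4]              # tip acuteness
    cf[3, 4] <- cf[3, 4] + jitter[5]
    params <- leaf_shape_params(area_cm2 = draws$area,
                                asymmetry_magnitude = draws$asym,
                                serration_depth = design$serration_depth,
                                noise_sd = design$noise_sd, seed = seed_shape,
                                base_coefficients = cf)
    outline <- tryCatch(make_leaf_outline(params, design$dpi),
                        error = function(e) NULL)
    if (!is.null(outline)) {
      return(list(params = params, outline = outline,
                  noise_seed = derive_seed(design$master_seed, counter, 3L)))
    }
  }
  stop("could not draw a simple outline after 12 attempts; ",
       "reduce shape_jitter_sd, serration_depth or asymmetry settings")
}

#' Generate a full synthetic study
#'
#' Produces one outline (and optionally one scan image on disk) per leaf,
#' plus the pairing manifest. With `out_dir` set, images are written as
#' binary PPM files and the manifest as `manifest.csv` with columns
#' `plant_id,node,treatment,leaf_index,path,true_area_cm2,true_asym`;
#' the design is serialised alongside as `design.json`.
#'
#' @param design `study_design`.
#' @param out_dir output directory (created if missing); `NULL` = no files,
#'   outlines returned in memory only.
#' @return invisibly, list with `manifest` (data frame) and `leaves`
#'   (list of per-leaf `params`/`outline`/`noise_seed`).
#' @export
generate_study <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  write_files <- !is.null(out_dir)
  if (write_files && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  leaves <- list()
  counter <- 0L
  for (treatment in c("control", "touched")) {
    for (p in seq_len(design$n_plants_per_group)) {
      for (ni in seq_along(design$nodes)) {
        for (li in seq_len(design$leaves_per_node)) {
          counter <- counter + 1L
          lf <- generate_leaf(design, treatment, ni, counter)
          plant_id <- sprintf("%s%02d", if (treatment == "touched") "T" else "C", p)
          node <- design$nodes[ni]
          fname <- sprintf("%s_%s_%d.ppm", plant_id, node, li)
          path <- if (write_files) file.path(out_dir, fname) else fname
          if (write_files) {
            ras <- rasterize_leaf(lf$outline, noise_sd = lf$params$noise_sd,
                                  seed = lf$noise_seed)
            write_pnm(ras$image, path)
          }
          rows[[counter]] <- data.frame(plant_id = plant_id, node = node,
                                        treatment = treatment, leaf_index = li,
                                        path = path,
                                        true_area_cm2 = lf$params$area_cm2,
                                        true_asym = lf$params$asymmetry_magnitude,
                                        stringsAsFactors = FALSE)
          leaves[[counter]] <- lf
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (write_files) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(unclass(design), auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "design.json"))
  }
  invisible(list(manifest = manifest, leaves = leaves))
}
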