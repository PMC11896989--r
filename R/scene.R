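#' Configuration for a synthetic banana-canopy scene
#'
#' Defines the study conditions emulated by [generate_scene()]: two plots at
#' different growth stages (leaf development vs fruit development), circular
#' plant footprints on a 50-pixel grid separable from soil by NDVI, a spatially
#' autocorrelated brightness field partially correlated with the chlorophyll
#' field, and ground measurement points whose SPAD value aggregates a plant
#' footprint.
#'
#' @param seed integer seed driving all randomness of the scene.
#' @param n_rows,n_cols scene size in pixels. The defaults (300 x 650) fit a
#'   6 x 5 grid of 50-pixel plant cells in plot 1 and 6 x 8 in plot 2, enough
#'   for the default 30 + 44 ground points with non-overlapping 50 x 50 ROIs.
#' @param wavelengths band centers in nm; default 164 bands spanning
#'   350-1000 nm.
#' @param n_points number of ground measurement points (default 74, split
#'   30/44 across the two plots).
#' @param lcc_range chlorophyll range in SPAD units, default 45-70; plot 1
#'   occupies the lower and plot 2 the upper sub-range.
#' @param soil_fraction proportion of soil pixels per plant cell in \[0, 1).
#' @param texture_corr correlation in \[-1, 1\] between the multiplicative
#'   brightness field and the chlorophyll field; this is what makes
#'   brightness-driven textures (PC1 mean in particular) informative for SPAD.
#' @param noise_sd per-band additive reflectance noise (sd).
#' @param spad_noise_sd sd of the SPAD measurement noise added to each ground
#'   point's footprint-mean chlorophyll.
#' @param structure_sd sd of the per-plant leaf-structure factor that scales
#'   pigment absorption; it confounds spectral chlorophyll retrieval at the
#'   plant level (the brightness/texture channel is unaffected).
#' @param rededge_jitter_sd sd (nm) of the per-plant red-edge midpoint
#'   offset, emulating canopy-structure (leaf angle / LAI) shifts of the
#'   apparent red-edge position that are independent of leaf chlorophyll.
#' @param nir_amp_sd sd of the per-plant near-infrared scattering amplitude
#'   (multiplies the NIR ramp relative to the visible baseline).
#' @param nir_slope_sd sd of the per-plant spectral tilt of the NIR ramp
#'   amplitude (fractional change per 100 nm around 802 nm), emulating
#'   canopy scattering whose spectral shape varies between plants. Together
#'   with `structure_sd`, `rededge_jitter_sd` and `nir_amp_sd` this caps the
#'   accuracy of purely spectral chlorophyll retrieval at the plant level,
#'   which is why the (unaffected) brightness/texture channel carries
#'   complementary information.
#' @param spad_cal_a,spad_cal_b parameters of the laboratory calibration
#'   `LCC_lab = a * exp(b * SPAD)` used by [simulate_lab_calibration()] and
#'   inverted to link SPAD to extractable chlorophyll.
#' @return A validated list of class `scene_config`.
#' @seealso [generate_scene()]
#' @export
scene_config <- function(seed = 42L,
                         n_rows = 300L, n_cols = 650L,
                         wavelengths = seq(350, 1000, length.out = 164),
                         n_points = 74L,
                         lcc_range = c(45, 70),
                         soil_fraction = 0.4,
                         texture_corr = 0.6,
                         noise_sd = 0.004,
                         spad_noise_sd = 1.0,
                         structure_sd = 0.06,
                         rededge_jitter_sd = 0.8,
                         nir_amp_sd = 0.08,
                         nir_slope_sd = 0.15,
                         spad_cal_a = 3.5, spad_cal_b = 0.05) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("config error: wavelengths must be strictly increasing", call. = FALSE)
  if (n_points < 2) stop("config error: n_points must be >= 2", call. = FALSE)
  if (lcc_range[1] >= lcc_range[2])
    stop("config error: lcc_range must satisfy min < max", call. = FALSE)
  if (noise_sd < 0 || spad_noise_sd < 0 || structure_sd < 0 ||
      rededge_jitter_sd < 0 || nir_amp_sd < 0 || nir_slope_sd < 0)
    stop("config error: noise sds must be >= 0", call. = FALSE)
  if (soil_fraction < 0 || soil_fraction >= 1)
    stop("config error: soil_fraction must be in [0, 1)", call. = FALSE)
  if (abs(texture_corr) > 1)
    stop("config error: texture_corr must be in [-1, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), wavelengths = wavelengths,
                 n_points = as.integer(n_points), lcc_range = lcc_range,
                 soil_fraction = soil_fraction, texture_corr = texture_corr,
                 noise_sd = noise_sd, spad_noise_sd = spad_noise_sd,
                 structure_sd = structure_sd,
                 rededge_jitter_sd = rededge_jitter_sd,
                 nir_amp_sd = nir_amp_sd, nir_slope_sd = nir_slope_sd,
                 spad_cal_a = spad_cal_a, spad_cal_b = spad_cal_b),
            class = "scene_config")
}

# Leaf reflectance model constants. Chlorophyll enters through (i) saturating
# absorption wells at 446/550/682 nm and (ii) a logistic red-edge ramp whose
# midpoint shifts +0.25 nm per SPAD unit, so the red-edge information center
# sits near 730 nm at the middle of the default 45-70 SPAD range.
.leaf <- list(
  vis_base = 0.14, nir = 0.48,
  ramp_mid0 = 722.4, ramp_shift = 0.25, ramp_width = 7,
  well_center = c(446, 550, 682),
  well_width  = c(22, 28, 16),
  well_amp    = c(0.10, 0.045, 0.11),
  well_sat    = 30  # half-saturation SPAD of the well depth
)

#' Synthetic leaf/canopy reflectance spectrum
#'
#' A compact analytic leaf model: a flat visible baseline plus a logistic
#' near-infrared ramp (the red edge), minus Gaussian absorption wells at 446,
#' 550 and 682 nm whose depth saturates with chlorophyll. Chlorophyll shifts
#' the red-edge midpoint to longer wavelengths (+0.25 nm per SPAD unit), so
#' the wavelength of maximum slope between 690 and 750 nm increases with
#' chlorophyll while red reflectance (682 nm) decreases.
#'
#' @param lcc chlorophyll in SPAD units; must be > 0. Scalar or vector.
#' @param wavelengths band centers in nm within \[350, 1000\].
#' @param structure leaf-structure factor (default 1) multiplying the well
#'   depths; models plant-to-plant variation in pigment packing.
#' @param midpoint_shift additive offset (nm, default 0) on the red-edge
#'   ramp midpoint; models canopy-geometry shifts of the apparent red edge.
#' @param nir_scale multiplicative factor (default 1) on the NIR ramp
#'   amplitude; models plant-to-plant scattering variability.
#' @param nir_slope fractional tilt (per 100 nm around 802 nm, default 0) of
#'   the NIR ramp amplitude; models spectrally varying scattering.
#' @return If `lcc` is scalar, a reflectance vector in \[0, 1\] over
#'   `wavelengths`; otherwise a `length(lcc)` x `length(wavelengths)` matrix.
#' @examples
#' wl <- seq(350, 1000, length.out = 164)
#' r50 <- leaf_reflectance(50, wl)
#' r60 <- leaf_reflectance(60, wl)
#' r60[nearest_band(wl, 682)] < r50[nearest_band(wl, 682)]  # deeper red well
#' @export
leaf_reflectance <- function(lcc, wavelengths, structure = 1,
                             midpoint_shift = 0, nir_scale = 1,
                             nir_slope = 0) {
  if (any(lcc <= 0)) stop("domain error: lcc must be > 0", call. = FALSE)
  if (any(wavelengths < 350 | wavelengths > 1000))
    stop("domain error: wavelengths must lie within [350, 1000] nm", call. = FALSE)
  p <- .leaf
  lcc <- as.numeric(lcc)
  structure <- rep_len(as.numeric(structure), length(lcc))
  midpoint_shift <- rep_len(as.numeric(midpoint_shift), length(lcc))
  nir_scale <- rep_len(as.numeric(nir_scale), length(lcc))
  nir_slope <- rep_len(as.numeric(nir_slope), length(lcc))
  mid <- p$ramp_mid0 + p$ramp_shift * lcc + midpoint_shift
  # ramp: n_lcc x n_wl
  amp <- nir_scale * (1 + outer(nir_slope, (wavelengths - 802) / 100))
  R <- p$vis_base +
    (p$nir - p$vis_base) * amp *
      plogis(outer(-mid, wavelengths, "+") / p$ramp_width)
  depth <- structure * lcc / (lcc + p$well_sat)  # saturating in lcc
  for (k in seq_along(p$well_center)) {
    g <- exp(-((wavelengths - p$well_center[k])^2) / (2 * p$well_width[k]^2))
    R <- R - (p$well_amp[k] * depth) %o% g
  }
  R <- pmin(pmax(R, 0), 1)
  if (length(lcc) == 1L) drop(R) else R
}

#' Red-edge inflection wavelength of a spectrum
#'
#' Wavelength of the maximum first derivative (finite differences on the given
#' grid) restricted to the red-edge region.
#'
#' @param spectrum reflectance vector.
#' @param wavelengths matching wavelength grid (nm).
#' @param range wavelength window searched, default 690-750 nm.
#' @return Midpoint wavelength (nm) of the steepest interval.
#' @export
red_edge_inflection <- function(spectrum, wavelengths, range = c(690, 750)) {
  d <- diff(spectrum) / diff(wavelengths)
  mids <- (wavelengths[-1] + wavelengths[-length(wavelengths)]) / 2
  keep <- mids >= range[1] & mids <= range[2]
  if (!any(keep)) stop("no wavelength intervals inside the red-edge range", call. = FALSE)
  mids[keep][which.max(d[keep])]
}

# Separable Gaussian smoothing of a matrix (reflected edges).
gauss_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_filter <- function(x) {
    # x: matrix; filter along rows (dim 1) with reflection padding
    top <- x[half:1, , drop = FALSE]; bot <- x[nrow(x):(nrow(x) - half + 1), , drop = FALSE]
    xp <- rbind(top, x, bot)
    f <- stats::filter(xp, k, sides = 2)
    f[(half + 1):(half + nrow(x)), , drop = FALSE]
  }
  t(pad_filter(t(pad_filter(m))))
}

# Two-plot plant-cell layout. Cells are 50x50; each cell hosts one circular
# plant footprint; the first n_k cells (row-major) of each plot carry a ground
# point at the cell center.
scene_layout <- function(cfg) {
  cell <- 50L
  cr <- cfg$n_rows %/% cell
  cc <- cfg$n_cols %/% cell
  n1 <- max(1L, round(cfg$n_points * 30 / 74))
  n2 <- cfg$n_points - n1
  cols1 <- ceiling(n1 / cr)
  cols2 <- cc - cols1
  if (cr < 1L || cols2 < 1L || cr * cols1 < n1 || cr * cols2 < n2)
    stop(sprintf(paste0("configuration error: scene %dx%d cannot place %d ",
                        "non-overlapping 50x50 ROIs across two plots"),
                 cfg$n_rows, cfg$n_cols, cfg$n_points), call. = FALSE)
  list(cell = cell, cell_rows = cr, cols1 = cols1, cols2 = cols2,
       n1 = n1, n2 = n2, split_col = cols1 * cell)
}

#' Generate a synthetic hyperspectral canopy scene
#'
#' Builds a two-plot banana scene with known per-pixel chlorophyll: circular
#' plant footprints on a 50-pixel grid (soil in between), chlorophyll drawn
#' from plot-specific sub-ranges with a smooth spatial trend, leaf spectra
#' from [leaf_reflectance()] with a per-plant structure factor, a
#' multiplicative spatially autocorrelated brightness field whose correlation
#' with the chlorophyll field equals `texture_corr`, additive band noise, and
#' `n_points` ground points whose SPAD equals the footprint-mean chlorophyll
#' plus measurement noise. Identical seeds give bit-identical output.
#'
#' @param config a [scene_config()].
#' @return A list of class `banana_scene` with elements `cube`
#'   (a [hyperspec_cube()]) and `truth` (list: `lcc_map` matrix with `NA` on
#'   soil, `vegetation_mask_true`, `brightness`, `points` data.frame with
#'   columns id, row, col, spad, plot).
#' @examples
#' sc <- generate_scene(scene_config(seed = 1, n_rows = 100, n_cols = 150,
#'                                   n_points = 6))
#' nrow(sc$truth$points)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  lay <- scene_layout(cfg)
  with_seed(cfg$seed, {
    nr <- cfg$n_rows; nc <- cfg$n_cols
    cell <- lay$cell
    r_veg <- sqrt((1 - cfg$soil_fraction) * cell^2 / pi)

    # --- plant cells -------------------------------------------------------
    cells <- expand.grid(cr = seq_len(lay$cell_rows),
                         cc = seq_len(lay$cols1 + lay$cols2))
    cells$plot <- ifelse(cells$cc <= lay$cols1, 1L, 2L)
    cells$center_row <- (cells$cr - 1L) * cell + cell %/% 2  # = +25 (1-based)
    cells$center_col <- (cells$cc - 1L) * cell + cell %/% 2

    # plot-specific chlorophyll sub-ranges (early vs late growth stage)
    span <- diff(cfg$lcc_range)
    lo <- c(cfg$lcc_range[1], cfg$lcc_range[1] + 0.52 * span)
    hi <- c(cfg$lcc_range[1] + 0.48 * span, cfg$lcc_range[2])
    # smooth within-plot gradient + plant-level variation
    g <- with(cells, ave(cr / max(cr) + cc / max(cc), plot,
                         FUN = function(z) (z - min(z)) / max(1e-9, diff(range(z)))))
    u <- pmin(pmax(0.5 * g + 0.25 + rnorm(nrow(cells), 0, 0.18), 0), 1)
    cells$lcc <- lo[cells$plot] + (hi[cells$plot] - lo[cells$plot]) * u
    cells$structure <- pmax(0.5, rnorm(nrow(cells), 1, cfg$structure_sd))
    cells$re_shift <- rnorm(nrow(cells), 0, cfg$rededge_jitter_sd)
    cells$nir_scale <- pmax(0.6, rnorm(nrow(cells), 1, cfg$nir_amp_sd))
    cells$nir_slope <- rnorm(nrow(cells), 0, cfg$nir_slope_sd)

    # --- per-pixel maps ----------------------------------------------------
    row_ix <- matrix(seq_len(nr), nr, nc)
    col_ix <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cell_r <- (row_ix - 1L) %/% cell + 1L
    cell_c <- (col_ix - 1L) %/% cell + 1L
    in_grid <- cell_r <= lay$cell_rows & cell_c <= (lay$cols1 + lay$cols2)
    cell_id <- ifelse(in_grid, (cell_c - 1L) * lay$cell_rows + cell_r, NA_integer_)
    cells <- cells[order((cells$cc - 1L) * lay$cell_rows + cells$cr), ]

    dr <- (row_ix - 1L) %% cell + 1L - (cell %/% 2)
    dc <- (col_ix - 1L) %% cell + 1L - (cell %/% 2)
    veg <- in_grid & (dr^2 + dc^2 <= r_veg^2)

    lcc_map <- matrix(NA_real_, nr, nc)
    pix_cell <- cell_id[veg]
    lcc_map[veg] <- cells$lcc[pix_cell] + rnorm(sum(veg), 0, 0.3)
    structure_map <- matrix(1, nr, nc)
    structure_map[veg] <- cells$structure[pix_cell]
    re_shift_map <- matrix(0, nr, nc)
    re_shift_map[veg] <- cells$re_shift[pix_cell]
    nir_scale_map <- matrix(1, nr, nc)
    nir_scale_map[veg] <- cells$nir_scale[pix_cell]
    nir_slope_map <- matrix(0, nr, nc)
    nir_slope_map[veg] <- cells$nir_slope[pix_cell]

    # chlorophyll field extended to soil (cell value) for the brightness link
    lcc_full <- matrix(mean(cells$lcc), nr, nc)
    lcc_full[in_grid] <- cells$lcc[cell_id[in_grid]]
    lcc_full[veg] <- lcc_map[veg]

    # --- brightness field: corr(brightness, lcc) ~= texture_corr -----------
    # Three unit-variance components: the chlorophyll field (weight tc), a
    # smooth independent field, and pixel-scale roughness whose amplitude
    # increases toward low chlorophyll (stressed canopies are more
    # heterogeneous), scaled so the total correlation with lcc stays ~= tc.
    # The roughness modulation is itself proportional to tc, so an
    # uncorrelated brightness field (tc = 0) carries no chlorophyll signal.
    zn <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc), 3)
    zn <- (zn - mean(zn)) / sd(zn)
    wn <- matrix(rnorm(nr * nc), nr, nc)
    zl <- (lcc_full - mean(lcc_full)) / sd(lcc_full)
    tc <- cfg$texture_corr
    u_full <- pmin(pmax((lcc_full - cfg$lcc_range[1]) / span, 0), 1)
    rough2 <- 0.35 * (1 - tc^2) * pmax(1 + 1.6 * tc * (0.5 - u_full), 0.1)
    bz <- tc * zl + sqrt(0.65 * (1 - tc^2)) * zn + sqrt(rough2) * wn
    brightness <- 1 + 0.08 * bz

    # --- spectra -----------------------------------------------------------
    nb <- length(cfg$wavelengths)
    refl <- matrix(0, nr * nc, nb)
    vi <- which(veg)
    refl[vi, ] <- leaf_reflectance(lcc_map[vi], cfg$wavelengths,
                                   structure = structure_map[vi],
                                   midpoint_shift = re_shift_map[vi],
                                   nir_scale = nir_scale_map[vi],
                                   nir_slope = nir_slope_map[vi])
    si <- which(!veg)
    soil_spec <- 0.13 + 0.17 * (cfg$wavelengths - 350) / 650
    refl[si, ] <- rep(soil_spec, each = length(si))
    refl <- refl * as.vector(brightness)
    if (cfg$noise_sd > 0)
      refl <- refl + rnorm(length(refl), 0, cfg$noise_sd)
    refl <- pmin(pmax(refl, 0), 1.2)
    dim(refl) <- c(nr, nc, nb)

    # --- ground points -----------------------------------------------------
    pts <- list()
    for (p in 1:2) {
      pc <- cells[cells$plot == p, ]
      pc <- pc[order(pc$cr, pc$cc), ]
      pc <- pc[seq_len(if (p == 1) lay$n1 else lay$n2), ]
      pts[[p]] <- data.frame(row = pc$center_row, col = pc$center_col,
                             lcc_plant = pc$lcc, plot = p)
    }
    pts <- do.call(rbind, pts)
    foot_mean <- vapply(seq_len(nrow(pts)), function(i) {
      cid <- (pts$col[i] %/% cell) * lay$cell_rows + (pts$row[i] %/% cell) + 1L
      mean(lcc_map[veg & cell_id == cid], na.rm = TRUE)
    }, numeric(1))
    pts$spad <- foot_mean + rnorm(nrow(pts), 0, cfg$spad_noise_sd)
    points <- data.frame(id = sprintf("P%02d", seq_len(nrow(pts))),
                         row = pts$row, col = pts$col,
                         spad = pts$spad, plot = pts$plot,
                         stringsAsFactors = FALSE)

    cube <- hyperspec_cube(refl, cfg$wavelengths)
    truth <- list(lcc_map = lcc_map, vegetation_mask_true = veg,
                  brightness = brightness, points = points)
    structure(list(cube = cube, truth = truth, config = cfg),
              class = "banana_scene")
  })
}

#' @export
print.banana_scene <- function(x, ...) {
  cat(sprintf("<banana_scene> seed %d: %d x %d px, %d bands, %d ground points\n",
              x$config$seed, x$config$n_rows, x$config$n_cols,
              length(x$config$wavelengths), nrow(x$truth$points)))
  tab <- table(x$truth$points$plot)
  cat(sprintf("  plot 1: %d points, plot 2: %d points; vegetation %.1f%%\n",
              tab[["1"]], tab[["2"]],
              100 * mean(x$truth$vegetation_mask_true)))
  invisible(x)
}

#' Simulate a laboratory SPAD calibration data set
#'
#' Emulates the chemical verification of the SPAD meter: `n` leaf samples with
#' extractable chlorophyll following `LCC_lab = a * exp(b * SPAD)` plus
#' multiplicative lognormal noise.
#'
#' @param n number of samples (default 18).
#' @param a,b calibration parameters (defaults from [scene_config()]).
#' @param spad_range SPAD range sampled.
#' @param noise_cv coefficient of variation of the lab measurement.
#' @param seed RNG seed.
#' @return data.frame with columns `spad`, `lcc_lab`.
#' @seealso [fit_exponential()]
#' @export
simulate_lab_calibration <- function(n = 18, a = 3.5, b = 0.05,
                                     spad_range = c(45, 70),
                                     noise_cv = 0.05, seed = 1L) {
  with_seed(seed, {
    spad <- sort(runif(n, spad_range[1], spad_range[2]))
    lcc <- a * exp(b * spad) * exp(rnorm(n, 0, noise_cv))
    data.frame(spad = spad, lcc_lab = lcc)
  })
}
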