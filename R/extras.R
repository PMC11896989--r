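#' Red-edge band sweep of the VI_re registry
#'
#' For every red-edge vegetation index and every cube band center inside
#' `range`, the index is recomputed with that band substituted into its
#' red-edge slot (fixed slots - NIR, red, blue - are untouched), averaged
#' over the ground-point ROIs, and fitted linearly against SPAD. The r2
#' surface localizes the most chlorophyll-informative red-edge wavelength.
#'
#' @param cube a [hyperspec_cube()].
#' @param points ground-point data.frame.
#' @param mask logical vegetation mask.
#' @param range swept wavelength window in nm (default 702-742).
#' @param roi_size ROI edge length (default 50).
#' @param vis VI_re names to sweep (default: all with a red-edge slot).
#' @return A `sweep_result` data.frame (vi, wavelength, r2) with attribute
#'   `best` (per-VI argmax band).
#' @export
rededge_sweep <- function(cube, points, mask = NULL, range = c(702, 742),
                          roi_size = 50L, vis = NULL) {
  reg <- vi_registry()
  if (is.null(vis)) vis <- reg$name[reg$has_red_edge_slot]
  bands <- cube$wavelengths[cube$wavelengths >= range[1] &
                              cube$wavelengths <= range[2]]
  if (!length(bands))
    stop(sprintf("no cube bands inside [%g, %g] nm", range[1], range[2]),
         call. = FALSE)
  rows <- list()
  for (v in vis) {
    for (w in bands) {
      img <- compute_vi(cube, v, red_edge = w, mask = mask)
      ft <- roi_feature_means(list(x = img), points, mask = mask,
                              size = roi_size)
      fit <- fit_linear(ft$x, ft$spad)
      rows[[length(rows) + 1L]] <- data.frame(vi = v, wavelength = w,
                                              r2 = fit$r2,
                                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(res, res$vi), function(d)
    d[which.max(d$r2), ]))
  rownames(best) <- NULL
  structure(res, class = c("sweep_result", "data.frame"), best = best)
}

#' @export
print.sweep_result <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf("<sweep_result> %d indices x %d bands\n",
              length(unique(x$vi)), length(unique(x$wavelength))))
  cat("best band per index:\n")
  print.data.frame(b, digits = 3)
  invisible(x)
}

#' Total chlorophyll from ethanol-extract absorbance
#'
#' Chlorophyll a and b concentrations of a 95% ethanol extract from
#' absorbance at 665 and 649 nm (Wellburn's spectrophotometric equations):
#' `Ca = 13.95 A665 - 6.88 A649`, `Cb = 24.96 A649 - 7.32 A665`, total
#' `Ca + Cb` in ug/mL. Negative component concentrations indicate an
#' inconsistent measurement and are flagged with a warning.
#'
#' @param a649,a665 absorbances (>= 0), vectorized.
#' @param coef named coefficient vector to swap in constants for other
#'   solvents.
#' @return data.frame with columns `ca`, `cb`, `total`.
#' @examples
#' chlorophyll_from_absorbance(0.3, 0.5)  # total 8.739
#' @export
chlorophyll_from_absorbance <- function(a649, a665,
                                        coef = c(ca665 = 13.95, ca649 = 6.88,
                                                 cb649 = 24.96, cb665 = 7.32)) {
  if (any(a649 < 0 | a665 < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  ca <- coef["ca665"] * a665 - coef["ca649"] * a649
  cb <- coef["cb649"] * a649 - coef["cb665"] * a665
  if (any(ca < 0 | cb < 0))
    warning("negative pigment concentration: inconsistent absorbance pair")
  data.frame(ca = unname(ca), cb = unname(cb), total = unname(ca + cb))
}

#' Fit the exponential SPAD calibration
#'
#' Nonlinear least squares of `lcc_lab = a * exp(b * spad)`, initialized
#' from the log-linear OLS fit (which requires strictly positive responses).
#'
#' @param spad SPAD readings.
#' @param lcc_lab laboratory chlorophyll (> 0).
#' @return A `spad_calibration` list: a, b, their standard errors, r2
#'   (on the original scale), n.
#' @export
fit_exponential <- function(spad, lcc_lab) {
  ok <- is.finite(spad) & is.finite(lcc_lab)
  spad <- spad[ok]; lcc_lab <- lcc_lab[ok]
  n <- length(spad)
  if (n < 3) stop("calibration needs n >= 3 points", call. = FALSE)
  if (any(lcc_lab <= 0))
    stop("lcc_lab must be > 0 for the exponential model", call. = FALSE)
  if (sd(spad) == 0) stop("constant spad: calibration unidentifiable",
                          call. = FALSE)
  ols <- lm.fit(cbind(1, spad), log(lcc_lab))
  start <- list(a = unname(exp(ols$coefficients[1])),
                b = unname(ols$coefficients[2]))
  fit <- minpack.lm::nlsLM(lcc_lab ~ a * exp(b * spad), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  pred <- predict(fit)
  r2 <- 1 - sum((lcc_lab - pred)^2) / sum((lcc_lab - mean(lcc_lab))^2)
  structure(list(a = cf["a", "Estimate"], b = cf["b", "Estimate"],
                 se_a = cf["a", "Std. Error"], se_b = cf["b", "Std. Error"],
                 r2 = r2, n = n, fit = fit),
            class = "spad_calibration")
}

#' @export
print.spad_calibration <- function(x, ...) {
  cat(sprintf("<spad_calibration> lcc_lab = %.4g * exp(%.4g * SPAD), r2 = %.3f (n = %d)\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Map chlorophyll per pixel
#'
#' Applies a trained estimator over the vegetation pixels of a scene; soil
#' pixels are `NA` (nodata). Two estimator kinds are supported:
#' a [best_combination()] row (closed-form `slope * combination + intercept`
#' from a VI image and a TF image) and an [mlra_train()] fit (per-pixel
#' feature matrix from named feature images; the GPR family also returns a
#' per-pixel predictive-sd layer). Texture images supplied at map time
#' should be quantized with the training scene's bounds (see
#' [pc_texture_images()]) so feature semantics match.
#'
#' @param object `twopair_best` or `mlra_fit`.
#' @param ... method-specific arguments.
#' @return For `twopair_best`: a matrix. For `mlra_fit`: list with `map`
#'   and (GPR) `sd_map` matrices.
#' @export
predict_map <- function(object, ...) UseMethod("predict_map")

#' @rdname predict_map
#' @param vi_image,tf_image feature images of the fitted pair.
#' @param mask logical vegetation mask.
#' @export
predict_map.twopair_best <- function(object, vi_image, tf_image, mask = NULL,
                                     ...) {
  map <- predict(object, vi_image, tf_image)
  if (!is.null(mask)) map[!mask] <- NA_real_
  map
}

#' @rdname predict_map
#' @param images named list of feature images covering `object$features`.
#' @param chunk pixels per prediction block (memory control).
#' @export
predict_map.mlra_fit <- function(object, images, mask = NULL,
                                 chunk = 50000L, ...) {
  feats <- object$features
  missing <- setdiff(feats, names(images))
  if (length(missing))
    stop(sprintf("feature mismatch: map-time images lack %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  dims <- dim(images[[feats[1]]])
  sel <- if (is.null(mask)) matrix(TRUE, dims[1], dims[2]) else mask
  X <- vapply(feats, function(f) images[[f]][sel], numeric(sum(sel)))
  ok <- rowSums(!is.finite(X)) == 0
  map <- matrix(NA_real_, dims[1], dims[2])
  sd_map <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(sel)[ok]
  Xok <- X[ok, , drop = FALSE]
  for (s in seq(1, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    p <- predict(object, Xok[s:e, , drop = FALSE])
    map[idx[s:e]] <- p$mean
    sd_map[idx[s:e]] <- p$sd
  }
  if (object$model == "GPR") list(map = map, sd_map = sd_map)
  else list(map = map)
}
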