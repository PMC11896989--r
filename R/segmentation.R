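#' NDVI image of a cube
#'
#' `(Rnir - Rred) / (Rnir + Rred)` using the bands nearest 802 and 682 nm.
#' Pixels with a zero denominator are `NaN`.
#'
#' @param cube a [hyperspec_cube()].
#' @param nir,red band-center wavelengths (nm).
#' @return Numeric matrix in \[-1, 1\] (NaN where undefined).
#' @export
compute_ndvi <- function(cube, nir = 802, red = 682) {
  n <- band_image(cube, nir); r <- band_image(cube, red)
  den <- n + r
  out <- (n - r) / den
  out[den == 0] <- NaN
  out
}

#' Derive an NDVI segmentation threshold from labelled samples
#'
#' Reproduces the statistic-based segmentation calibration: pure-vegetation
#' and pure-soil pixel samples are pooled, and every midpoint between adjacent
#' sorted NDVI values (plus the two outer half-open cuts) is scanned for the
#' threshold minimizing the misclassification count under the rule
#' `vegetation <=> NDVI > threshold`. Ties go to the larger threshold.
#'
#' @param ndvi NDVI image (matrix) or vector.
#' @param veg_sample,soil_sample index vectors (or NDVI value vectors when
#'   `ndvi` is missing) of pure-class pixels; must be non-empty and disjoint.
#' @return Threshold (scalar) with attributes `misclassified` and `n`.
#' @export
derive_threshold <- function(ndvi, veg_sample, soil_sample) {
  if (missing(ndvi)) { v <- veg_sample; s <- soil_sample }
  else {
    if (length(intersect(veg_sample, soil_sample)))
      stop("veg_sample and soil_sample must be disjoint", call. = FALSE)
    v <- ndvi[veg_sample]; s <- ndvi[soil_sample]
  }
  if (!length(v) || !length(s))
    stop("both class samples must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(v, s)))
  cuts <- if (length(pooled) > 1)
    (pooled[-1] + pooled[-length(pooled)]) / 2 else numeric(0)
  cuts <- c(min(pooled) - 1e-6, cuts, max(pooled) + 1e-6)
  err <- vapply(cuts, function(t) sum(v <= t) + sum(s > t), numeric(1))
  best <- max(which(err == min(err)))  # ties toward the larger threshold
  if (min(err) >= (length(v) + length(s)) / 2)
    warning("class NDVI distributions indistinguishable; threshold unreliable")
  structure(cuts[best], misclassified = as.integer(min(err)),
            n = length(v) + length(s))
}

#' Apply an NDVI threshold to produce a vegetation mask
#'
#' Vegetation is defined by the strict inequality `NDVI > threshold` (pixels
#' exactly at the threshold count as soil). Per-plot thresholds are supported
#' through `plot_map`.
#'
#' @param cube a [hyperspec_cube()] (or an NDVI matrix via `ndvi`).
#' @param threshold scalar threshold in \[-1, 1\], or a named/numbered vector
#'   of per-plot thresholds used with `plot_map`.
#' @param ndvi optional precomputed NDVI image.
#' @param plot_map optional integer matrix assigning each pixel to a plot;
#'   `threshold[plot_map]` is then applied per pixel.
#' @return A `vegetation_mask`: logical matrix with attributes
#'   `threshold_used`, `n_vegetation`, `n_soil`.
#' @export
apply_mask <- function(cube, threshold, ndvi = NULL, plot_map = NULL) {
  if (is.null(ndvi)) ndvi <- compute_ndvi(cube)
  if (any(threshold < -1 | threshold > 1))
    stop("threshold must lie in [-1, 1]", call. = FALSE)
  valid <- if (inherits(cube, "hyperspec_cube")) cube$valid_mask
           else is.finite(ndvi)
  thr_px <- if (is.null(plot_map)) threshold[1]
            else matrix(threshold[plot_map], nrow(ndvi), ncol(ndvi))
  mask <- !is.na(ndvi) & is.finite(ndvi) & ndvi > thr_px & valid
  structure(mask, class = c("vegetation_mask", class(mask)),
            threshold_used = threshold,
            n_vegetation = sum(mask), n_soil = sum(valid) - sum(mask))
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat(sprintf("<vegetation_mask> threshold %s: %d vegetation / %d soil pixels\n",
              paste(signif(attr(x, "threshold_used"), 4), collapse = ", "),
              attr(x, "n_vegetation"), attr(x, "n_soil")))
  invisible(x)
}
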