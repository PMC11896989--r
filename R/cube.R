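#' Hyperspectral cube container
#'
#' A `hyperspec_cube` bundles a rows x cols x bands reflectance array with its
#' wavelength axis (nm, strictly increasing) and a per-pixel validity mask.
#' Reflectance is unitless, expected in roughly \[0, 1.2\].
#'
#' @param reflectance numeric array, rows x cols x bands.
#' @param wavelengths numeric vector of band-center wavelengths in nm; length
#'   must equal the third dimension of `reflectance`.
#' @param valid_mask logical matrix rows x cols; defaults to pixels whose
#'   spectra are entirely finite.
#' @return An object of class `hyperspec_cube`: a list with elements
#'   `reflectance`, `wavelengths`, `valid_mask`.
#' @examples
#' cube <- hyperspec_cube(array(0.5, c(2, 2, 3)), c(500, 600, 700))
#' dim(cube$reflectance)
#' @export
hyperspec_cube <- function(reflectance, wavelengths, valid_mask = NULL) {
  if (length(dim(reflectance)) != 3L)
    stop("`reflectance` must be a rows x cols x bands array", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (dim(reflectance)[3] != length(wavelengths))
    stop(sprintf("cube has %d bands but %d wavelengths were supplied",
                 dim(reflectance)[3], length(wavelengths)), call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  if (is.null(valid_mask)) {
    valid_mask <- apply(is.finite(reflectance), c(1, 2), all)
  }
  stopifnot(is.logical(valid_mask),
            all(dim(valid_mask) == dim(reflectance)[1:2]))
  structure(list(reflectance = reflectance, wavelengths = wavelengths,
                 valid_mask = valid_mask),
            class = "hyperspec_cube")
}

#' @export
print.hyperspec_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hyperspec_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid_mask), d[1] * d[2]))
  invisible(x)
}

#' @export
dim.hyperspec_cube <- function(x) dim(x$reflectance)

#' Find the band nearest a target wavelength
#'
#' Returns the band index minimizing the absolute offset to `target`; ties
#' resolve to the lower index. The achieved offset (nm) is attached as
#' attribute `"offset"`.
#'
#' @param wavelengths numeric vector of band centers (nm), or a
#'   `hyperspec_cube`.
#' @param target target wavelength in nm; must lie within the range of
#'   `wavelengths`.
#' @return Integer band index (1-based) with attribute `offset`.
#' @examples
#' wl <- seq(350, 1000, length.out = 164)
#' nearest_band(wl, 682)
#' @export
nearest_band <- function(wavelengths, target) {
  if (inherits(wavelengths, "hyperspec_cube")) wavelengths <- wavelengths$wavelengths
  if (target < min(wavelengths) || target > max(wavelengths))
    stop(sprintf("band lookup: target %.1f nm outside cube range [%.1f, %.1f]",
                 target, min(wavelengths), max(wavelengths)), call. = FALSE)
  off <- abs(wavelengths - target)
  idx <- which.min(off)  # which.min takes the first (lower) index on ties
  structure(as.integer(idx), offset = wavelengths[idx] - target)
}

# Extract one band as a matrix (dimensions preserved even for 1x1 scenes).
band_image <- function(cube, target) {
  m <- cube$reflectance[, , nearest_band(cube$wavelengths, target),
                        drop = FALSE]
  dim(m) <- dim(cube$reflectance)[1:2]
  m
}
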