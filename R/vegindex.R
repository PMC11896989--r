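# Vegetation-index registry ---------------------------------------------------
#
# Twenty chlorophyll-oriented indices: 11 built from blue/green/red/NIR bands
# (VI_org) and 9 red-edge variants (VI_re). Band slots are wavelength-resolved
# reflectances at the nominal centers listed per index; `re` marks the
# red-edge slot that the band sweep may substitute. Formulas follow the
# canonical published forms: MSR/MSR_re carry the square-root denominator
# (Chen 1996), the MDVI family is the renormalized difference
# (N - X)/sqrt(N + X), and the OSAVI family is the Rondeaux soil-adjusted form
# (1 + 0.16)(N - X)/(N + X + 0.16). RDVI here is the plain difference
# Rnir - Rred, as this registry defines it (not the classical renormalized
# DVI). CI_green uses 770/510 nm.

vi_defs <- local({
  def <- function(name, class, bands, fun, re = NA_character_)
    list(name = name, class = class, bands = bands, fun = fun, re = re)
  list(
    def("SR",        "VI_org", c(nir = 802, red = 682),
        function(b) b$nir / b$red),
    def("NDVI",      "VI_org", c(nir = 802, red = 682),
        function(b) (b$nir - b$red) / (b$nir + b$red)),
    def("GDVI",      "VI_org", c(green = 550, red = 682),
        function(b) b$green - b$red),
    def("RDVI",      "VI_org", c(nir = 802, red = 682),
        function(b) b$nir - b$red),
    def("MDVI",      "VI_org", c(nir = 802, red = 682),
        function(b) (b$nir - b$red) / sqrt(b$nir + b$red)),
    def("MSR",       "VI_org", c(nir = 802, red = 682),
        function(b) (b$nir / b$red - 1) / sqrt(b$nir / b$red + 1)),
    def("mNDVI",     "VI_org", c(nir = 802, red = 682, blue = 446),
        function(b) (b$nir - b$red) / (b$nir + b$red - 2 * b$blue)),
    def("CI_green",  "VI_org", c(nir = 770, green = 510),
        function(b) b$nir / b$green - 1),
    def("OSAVI",     "VI_org", c(nir = 802, red = 682),
        function(b) 1.16 * (b$nir - b$red) / (b$nir + b$red + 0.16)),
    def("OSAVI_green", "VI_org", c(nir = 802, green = 550),
        function(b) 1.16 * (b$nir - b$green) / (b$nir + b$green + 0.16)),
    def("SIPI",      "VI_org", c(nir = 802, blue = 446, red = 682),
        function(b) (b$nir - b$blue) / (b$nir - b$red)),
    def("SR_re",     "VI_re", c(nir = 802, re = 706),
        function(b) b$nir / b$re, re = "re"),
    def("NDVI_re",   "VI_re", c(nir = 802, re = 706),
        function(b) (b$nir - b$re) / (b$nir + b$re), re = "re"),
    def("REDVI",     "VI_re", c(re = 710, red = 682),
        function(b) b$re - b$red, re = "re"),
    def("MDVI_re",   "VI_re", c(nir = 802, re = 710),
        function(b) (b$nir - b$re) / sqrt(b$nir + b$re), re = "re"),
    def("MSR_re",    "VI_re", c(nir = 802, re = 710),
        function(b) (b$nir / b$re - 1) / sqrt(b$nir / b$re + 1), re = "re"),
    def("mNDVI_re",  "VI_re", c(nir = 802, re = 710, blue = 446),
        function(b) (b$nir - b$re) / (b$nir + b$re - 2 * b$blue), re = "re"),
    def("CI_re",     "VI_re", c(nir = 770, re = 710),
        function(b) b$nir / b$re - 1, re = "re"),
    def("OSAVI_re",  "VI_re", c(nir = 802, re = 706),
        function(b) 1.16 * (b$nir - b$re) / (b$nir + b$re + 0.16), re = "re"),
    def("MTCI",      "VI_re", c(nir = 802, re = 710, red = 682),
        function(b) (b$nir - b$re) / (b$re - b$red), re = "re")
  )
})

#' Registry of the 20 vegetation indices
#'
#' @return data.frame with one row per index: `name`, `class` (`VI_org` /
#'   `VI_re`), `bands` (comma-separated "slot=nm" list), `has_red_edge_slot`.
#' @examples
#' table(vi_registry()$class)  # 11 original, 9 red-edge
#' @export
vi_registry <- function() {
  do.call(rbind, lapply(vi_defs, function(d)
    data.frame(name = d$name, class = d$class,
               bands = paste(sprintf("%s=%g", names(d$bands), d$bands),
                             collapse = ", "),
               has_red_edge_slot = !is.na(d$re),
               stringsAsFactors = FALSE)))
}

vi_lookup <- function(name) {
  i <- match(name, vapply(vi_defs, `[[`, "", "name"))
  if (is.na(i))
    stop(sprintf("unknown vegetation index '%s'; valid names: %s", name,
                 paste(vapply(vi_defs, `[[`, "", "name"), collapse = ", ")),
         call. = FALSE)
  vi_defs[[i]]
}

#' Evaluate a vegetation index
#'
#' Computes one registered index from a cube (per pixel) or from a named
#' reflectance list/vector. Division by zero yields `NaN`, never an error or
#' a silent drop. The red-edge slot of a `VI_re` can be substituted via
#' `red_edge` (used by the band sweep).
#'
#' @param x a [hyperspec_cube()], or a named numeric vector/list of
#'   reflectances keyed by band slot (`nir`, `red`, `green`, `blue`, `re`).
#' @param name registered index name (see [vi_registry()]).
#' @param red_edge optional replacement wavelength (nm) for the red-edge slot.
#' @param mask optional logical matrix; pixels outside it are `NA` in the
#'   returned image.
#' @return Matrix (cube input) or numeric value.
#' @examples
#' compute_vi(c(nir = 0.8, red = 0.1), "SR")  # 8
#' @export
compute_vi <- function(x, name, red_edge = NULL, mask = NULL) {
  d <- vi_lookup(name)
  bands <- d$bands
  if (!is.null(red_edge)) {
    if (is.na(d$re))
      stop(sprintf("'%s' has no red-edge slot to substitute", name), call. = FALSE)
    bands[[d$re]] <- red_edge
  }
  if (inherits(x, "hyperspec_cube")) {
    vals <- lapply(bands, function(w) band_image(x, w))
    out <- d$fun(vals)
    out[!is.finite(out)] <- NaN
    if (!is.null(mask)) out[!mask] <- NA_real_
    out
  } else {
    x <- as.list(x)
    missing <- setdiff(names(bands), names(x))
    if (length(missing))
      stop(sprintf("'%s' needs reflectance slots: %s", name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    v <- d$fun(x)
    v[!is.finite(v)] <- NaN
    v
  }
}

#' Compute all 20 VI images of a cube
#'
#' @param cube a [hyperspec_cube()].
#' @param mask logical vegetation mask; indices are evaluated on vegetation
#'   pixels only (others are `NA`).
#' @param names subset of registry names (default: all 20).
#' @return Named list of matrices.
#' @export
vi_images <- function(cube, mask = NULL, names = vi_registry()$name) {
  out <- lapply(names, function(nm) compute_vi(cube, nm, mask = mask))
  stats::setNames(out, names)
}
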