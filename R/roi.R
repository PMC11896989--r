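#' Extract the region of interest around a ground point
#'
#' Ground features are averaged over a `size` x `size` pixel window centered
#' on the measurement point. An even window has no exact center pixel: the
#' convention here is rows `[r - size/2, r + size/2 - 1]` and likewise for
#' columns (so a 50-window spans 25 pixels above and 24 below the point),
#' clipped at the image borders. Only pixels inside `mask` are retained.
#'
#' @param dim image size `c(rows, cols)`, or a [hyperspec_cube()].
#' @param point list/row with elements `row`, `col` (1-based).
#' @param size window edge length in pixels (default 50).
#' @param mask optional logical matrix; `NULL` keeps every in-window pixel.
#' @return Integer vector of linear (column-major) pixel indices, with
#'   attributes `n_window` (window pixels inside the image) and `n_retained`.
#' @section Errors: an all-masked window raises an `empty ROI` error; callers
#'   building feature tables catch it and exclude the point.
#' @export
extract_roi <- function(dim, point, size = 50L, mask = NULL) {
  if (inherits(dim, "hyperspec_cube")) dim <- dim(dim$reflectance)[1:2]
  stopifnot(size >= 1)
  half_lo <- size %/% 2L
  half_hi <- size - half_lo - 1L
  r <- as.integer(point$row); c <- as.integer(point$col)
  rows <- max(1L, r - half_lo):min(dim[1], r + half_hi)
  cols <- max(1L, c - half_lo):min(dim[2], c + half_hi)
  idx <- as.vector(outer(rows, (cols - 1L) * dim[1], "+"))
  n_window <- length(idx)
  if (!is.null(mask)) idx <- idx[mask[idx]]
  if (length(idx) == 0L)
    stop(sprintf("empty ROI: no retained pixels around point (%d, %d)", r, c),
         call. = FALSE)
  structure(idx, n_window = n_window, n_retained = length(idx))
}

#' Average feature images over ground-point ROIs
#'
#' Builds the point x feature table: for every ground point, each feature
#' image is averaged over the masked-in pixels of its 50 x 50 ROI (non-finite
#' pixels are excluded and counted). Points with an empty ROI are dropped and
#' reported.
#'
#' @param features named list of numeric matrices (feature images), or a
#'   single matrix.
#' @param points ground-point data.frame (columns id, row, col, spad, plot).
#' @param mask logical vegetation mask matrix (or `NULL`).
#' @param size ROI edge length, default 50.
#' @param provenance optional character vector (one per feature) recorded as
#'   the `provenance` attribute, e.g. `"VI"` or `"TF-PC1"`.
#' @return A `feature_table`: data.frame with one row per retained point,
#'   columns `id`, `spad`, `plot`, then one column per feature; attributes
#'   `provenance` (named), `dropped` (data.frame of excluded points) and
#'   `roi_pixels` (retained pixel counts).
#' @export
roi_feature_means <- function(features, points, mask = NULL, size = 50L,
                              provenance = NULL) {
  if (is.matrix(features)) features <- list(feature = features)
  stopifnot(length(features) > 0, !is.null(names(features)))
  if (anyDuplicated(names(features)))
    stop("feature names must be unique", call. = FALSE)
  dim <- dim(features[[1]])
  vals <- matrix(NA_real_, nrow(points), length(features),
                 dimnames = list(points$id, names(features)))
  keep <- logical(nrow(points))
  npix <- integer(nrow(points))
  drop_reason <- character(0); drop_id <- character(0)
  for (i in seq_len(nrow(points))) {
    idx <- tryCatch(extract_roi(dim, points[i, ], size = size, mask = mask),
                    error = function(e) NULL)
    if (is.null(idx)) {
      drop_id <- c(drop_id, points$id[i])
      drop_reason <- c(drop_reason, "empty ROI")
      next
    }
    keep[i] <- TRUE
    npix[i] <- attr(idx, "n_retained")
    for (f in seq_along(features)) {
      v <- features[[f]][idx]
      vals[i, f] <- mean(v[is.finite(v)])
    }
  }
  out <- cbind(points[keep, c("id", "spad", "plot")],
               as.data.frame(vals[keep, , drop = FALSE]))
  rownames(out) <- NULL
  if (anyNA(out[-(1:3)]))
    warning("some ROI means are NaN (all pixels non-finite for a feature)")
  prov <- provenance %||% rep("feature", length(features))
  structure(out, class = c("feature_table", "data.frame"),
            provenance = stats::setNames(prov, names(features)),
            dropped = data.frame(id = drop_id, reason = drop_reason,
                                 stringsAsFactors = FALSE),
            roi_pixels = npix[keep])
}

# Feature columns of a feature_table (everything after id/spad/plot).
feature_columns <- function(table) {
  setdiff(names(table), c("id", "spad", "plot"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d points x %d features\n",
              nrow(x), length(feature_columns(x))))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    for (p in unique(prov))
      cat(sprintf("  %s: %d\n", p, sum(prov == p)))
  }
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped))
    cat(sprintf("  dropped points: %s\n", paste(dropped$id, collapse = ", ")))
  invisible(x)
}
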