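#' Principal-component transform of a hyperspectral cube
#'
#' PCA is fit on the covariance of mean-centered spectra of the masked-in
#' (vegetation) pixels and the leading component images are rendered for all
#' valid pixels. Sign convention: the largest-magnitude element of each
#' loading vector is positive.
#'
#' @param cube a [hyperspec_cube()].
#' @param mask logical matrix of fit pixels (>= 3 required); default all
#'   valid pixels.
#' @param n_components number of component images to render (default 3).
#' @return List of class `pca_result`: `pc_images` (rows x cols x k array,
#'   `NA` outside the valid mask), `explained_variance_ratio` (all bands),
#'   `loadings` (bands x k), `center`, `n_fit`.
#' @export
pca_transform <- function(cube, mask = NULL, n_components = 3L) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  d <- dim(cube$reflectance)
  if (d[3] < 3) stop("PCA needs at least 3 bands", call. = FALSE)
  mask <- mask %||% cube$valid_mask
  idx <- which(mask & cube$valid_mask)
  if (length(idx) < 3) stop("PCA needs at least 3 masked-in pixels", call. = FALSE)
  X <- matrix(cube$reflectance, d[1] * d[2], d[3])[idx, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (sum(ev > max(ev) * 1e-12) < n_components)
    stop("rank error: cube covariance is degenerate (constant cube?)", call. = FALSE)
  W <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(W))) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  valid_idx <- which(cube$valid_mask)
  scores <- sweep(matrix(cube$reflectance, d[1] * d[2], d[3])[valid_idx, ,
                                                             drop = FALSE],
                  2, ctr) %*% W
  pc <- array(NA_real_, c(d[1], d[2], n_components))
  for (k in seq_len(n_components))
    pc[, , k][valid_idx] <- scores[, k]
  structure(list(pc_images = pc,
                 explained_variance_ratio = ev / sum(ev),
                 loadings = W, center = ctr, n_fit = length(idx)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  r <- x$explained_variance_ratio
  cat(sprintf("<pca_result> fit on %d pixels; first %d components rendered\n",
              x$n_fit, dim(x$pc_images)[3]))
  cat(sprintf("  explained variance: %s (cumulative %.2f%%)\n",
              paste(sprintf("%.1f%%", 100 * r[1:3]), collapse = ", "),
              100 * sum(r[1:3])))
  invisible(x)
}

#' Quantize an image to G gray levels
#'
#' Linear min-max binning over the masked pixels: level
#' `floor((x - min) / (max - min) * G)` capped at `G - 1`, so the maximum
#' maps to `G - 1` and bin edges are right-closed at the top. Pixels outside
#' the mask (or non-finite) are `NA`.
#'
#' @param image numeric matrix.
#' @param levels number of gray levels G >= 2 (default 32).
#' @param mask optional logical matrix.
#' @param bounds optional `c(min, max)` quantization bounds, e.g. reused from
#'   a training scene so features stay comparable at map time.
#' @return Integer matrix with values in `0:(G-1)` and attribute `bounds`.
#' @export
quantize <- function(image, levels = 32L, mask = NULL, bounds = NULL) {
  stopifnot(levels >= 2)
  sel <- is.finite(image) & (if (is.null(mask)) TRUE else mask)
  if (!any(sel)) stop("no finite masked pixels to quantize", call. = FALSE)
  if (is.null(bounds)) bounds <- range(image[sel])
  lo <- bounds[1]; hi <- bounds[2]
  out <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi <= lo) {
    warning("constant image: all gray levels set to 0")
    out[sel] <- 0L
  } else {
    g <- floor((image[sel] - lo) / (hi - lo) * levels)
    out[sel] <- as.integer(pmin(pmax(g, 0), levels - 1L))
  }
  structure(out, bounds = bounds)
}

# The four distance-1 offsets (0, 45, 90, 135 degrees) as (drow, dcol).
glcm_offsets <- function() cbind(dr = c(0L, -1L, -1L, -1L), dc = c(1L, 1L, 0L, -1L))

#' Gray-level co-occurrence matrix of one window
#'
#' Accumulates co-occurring gray-level pairs for each offset within the
#' `window` x `window` neighborhood of `center`, adds the transposed pairs
#' when `symmetric`, and normalizes to sum 1. Pairs touching off-image or
#' `NA` (masked) pixels are skipped.
#'
#' @param gray integer matrix of gray levels `0:(G-1)` (`NA` = masked).
#' @param center `c(row, col)` of the window center (1-based).
#' @param levels number of gray levels G.
#' @param window odd window edge length (default 3).
#' @param offsets integer matrix of (drow, dcol) offsets; default the four
#'   distance-1 directions.
#' @param symmetric accumulate transposed pairs too (default TRUE).
#' @return A `glcm_matrix`: G x G matrix `P` of relative frequencies with
#'   attribute `n_pairs`; all-zero accumulation raises an undefined-texture
#'   error.
#' @export
glcm_window <- function(gray, center, levels = max(gray, na.rm = TRUE) + 1L,
                        window = 3L, offsets = glcm_offsets(),
                        symmetric = TRUE) {
  stopifnot(window %% 2 == 1)
  h <- window %/% 2
  r0 <- center[1]; c0 <- center[2]
  P <- matrix(0, levels, levels)
  n <- 0L
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in (r0 - h):(r0 + h)) for (c in (c0 - h):(c0 + h)) {
      r2 <- r + dr; c2 <- c + dc
      if (r < 1 || c < 1 || r > nrow(gray) || c > ncol(gray)) next
      if (r2 < r0 - h || r2 > r0 + h || c2 < c0 - h || c2 > c0 + h) next
      if (r2 < 1 || c2 < 1 || r2 > nrow(gray) || c2 > ncol(gray)) next
      a <- gray[r, c]; b <- gray[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a + 1L, b + 1L] <- P[a + 1L, b + 1L] + 1
      if (symmetric) P[b + 1L, a + 1L] <- P[b + 1L, a + 1L] + 1
      n <- n + 1L
    }
  }
  if (n == 0L)
    stop("undefined texture: no accumulable pairs in window", call. = FALSE)
  structure(P / sum(P), class = "glcm_matrix", n_pairs = n)
}

#' Haralick features of a co-occurrence distribution
#'
#' The eight statistics used throughout the package, computed from a
#' normalized G x G co-occurrence matrix `P` (entries p(i, j), levels indexed
#' from 0): MEA = sum i p; VAR = sum (i - MEA)^2 p; HOM = sum p / (1 + (i-j)^2);
#' CON = sum (i-j)^2 p; DIS = sum p |i-j|; ENT = -sum p log2 p (0 log 0 := 0);
#' SEC = sum p^2; COR = sum (i - u_i)(j - u_j) p / sqrt(VAR_i VAR_j), with
#' COR := 1 when either marginal variance is zero.
#'
#' @param P normalized co-occurrence matrix (class `glcm_matrix` or plain).
#' @return Named numeric vector MEA, VAR, HOM, CON, DIS, ENT, SEC, COR.
#' @export
haralick_features <- function(P) {
  P <- unclass(P)
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalized to sum 1", call. = FALSE)
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  mea <- sum(i * P)
  vr <- sum((i - mea)^2 * P)
  hom <- sum(P / (1 + (i - j)^2))
  con <- sum((i - j)^2 * P)
  dis <- sum(P * abs(i - j))
  ent <- -sum(ifelse(P > 0, P * log2(P), 0))
  sec <- sum(P^2)
  pi_ <- rowSums(P); pj <- colSums(P)
  ui <- sum((0:(G - 1)) * pi_); uj <- sum((0:(G - 1)) * pj)
  vi <- sum(((0:(G - 1)) - ui)^2 * pi_); vj <- sum(((0:(G - 1)) - uj)^2 * pj)
  cor <- if (vi <= 0 || vj <= 0) 1 else sum((i - ui) * (j - uj) * P) / sqrt(vi * vj)
  c(MEA = mea, VAR = vr, HOM = hom, CON = con, DIS = dis, ENT = ent,
    SEC = sec, COR = cor)
}

texture_feature_names <- function() c("MEA", "VAR", "HOM", "CON", "DIS",
                                      "ENT", "SEC", "COR")

#' Sliding-window texture feature images
#'
#' Computes the eight Haralick features in a sliding `window` x `window`
#' co-occurrence window at every masked-in pixel of a quantized image
#' (C++ fast path). Pixels whose window yields no accumulable pair are `NaN`.
#'
#' @param gray quantized integer matrix (see [quantize()]), `NA` = masked.
#' @param levels number of gray levels G.
#' @param window odd window size (default 3).
#' @param symmetric symmetric accumulation (default TRUE).
#' @return Named list of eight matrices (MEA, VAR, HOM, CON, DIS, ENT, SEC,
#'   COR).
#' @export
texture_images <- function(gray, levels = max(gray, na.rm = TRUE) + 1L,
                           window = 3L, symmetric = TRUE) {
  stopifnot(window %% 2 == 1)
  g <- matrix(as.integer(gray), nrow(gray), ncol(gray))
  out <- glcm_texture_images_cpp(g, as.integer(levels), as.integer(window),
                                 isTRUE(symmetric))
  stats::setNames(out, texture_feature_names())
}

#' Texture features of the first principal-component images
#'
#' Convenience wrapper: quantizes each PC image over the vegetation pixels of
#' the whole scene (global bounds, so ROI means are comparable across points)
#' and computes the eight texture images per component - 24 images for three
#' components.
#'
#' @param pca a [pca_transform()] result.
#' @param mask logical vegetation mask.
#' @param levels gray levels (default 32).
#' @param window odd GLCM window (default 3).
#' @param bounds optional list of per-component quantization bounds to reuse.
#' @return List with `images` (named list, e.g. `PC1_MEA`, ... 24 entries),
#'   `provenance` (e.g. `TF-PC1`), `bounds`.
#' @export
pc_texture_images <- function(pca, mask, levels = 32L, window = 3L,
                              bounds = NULL) {
  k <- dim(pca$pc_images)[3]
  images <- list(); prov <- character(0); used_bounds <- list()
  for (p in seq_len(k)) {
    q <- quantize(pca$pc_images[, , p], levels = levels, mask = mask,
                  bounds = bounds[[p]] %||% NULL)
    used_bounds[[p]] <- attr(q, "bounds")
    tex <- texture_images(q, levels = levels, window = window)
    names(tex) <- sprintf("PC%d_%s", p, names(tex))
    images <- c(images, tex)
    prov <- c(prov, rep(sprintf("TF-PC%d", p), length(tex)))
  }
  list(images = images, provenance = stats::setNames(prov, names(images)),
       bounds = used_bounds)
}
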