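#' Pearson correlation against chlorophyll
#'
#' Thin validated wrapper around [stats::cor()]: requires at least three
#' pairs and non-constant inputs (a constant feature has no defined linear
#' correlation and is an error rather than `NA`).
#'
#' @param x,y numeric vectors of equal length.
#' @return Sample Pearson correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("pearson_r needs n >= 3 finite pairs", call. = FALSE)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  cor(x[ok], y[ok])
}

#' Screen features against chlorophyll by |r| and MIC
#'
#' Ranks every feature of a feature table against the point SPAD values by
#' the absolute Pearson correlation and by MIC, and flags those exceeding the
#' selection thresholds. "Higher than 0.8" is a strict inequality: a feature
#' at exactly the threshold is not selected.
#'
#' @param table a [roi_feature_means()] feature table (needs a `spad`
#'   column).
#' @param threshold_r,threshold_mic strict selection cutoffs (default 0.8).
#' @param alpha,c MIC hyperparameters (MINE defaults).
#' @return A `screening_result` data.frame: feature, provenance, r, abs_r,
#'   mic, selected_r, selected_mic; attributes `thresholds` and `selected`
#'   (named list of selections split by provenance, mirroring the
#'   VI / TF-per-PC reporting layout).
#' @export
select_features <- function(table, threshold_r = 0.8, threshold_mic = 0.8,
                            alpha = 0.6, c = 15) {
  feats <- feature_columns(table)
  if (!length(feats)) stop("feature table has no feature columns", call. = FALSE)
  prov <- attr(table, "provenance") %||%
    stats::setNames(rep("feature", length(feats)), feats)
  spad <- table$spad
  r <- vapply(feats, function(f) pearson_r(table[[f]], spad), numeric(1))
  m <- vapply(feats, function(f) mic(table[[f]], spad, alpha = alpha, c = c),
              numeric(1))
  res <- data.frame(feature = feats,
                    provenance = unname(prov[feats]),
                    r = unname(r), abs_r = unname(abs(r)), mic = unname(m),
                    selected_r = unname(abs(r) > threshold_r),
                    selected_mic = unname(m > threshold_mic),
                    stringsAsFactors = FALSE)
  # deterministic ranking: descending |r|, ties alphabetical
  res <- res[order(-res$abs_r, res$feature), ]
  rownames(res) <- NULL
  if (!any(res$selected_r) && !any(res$selected_mic))
    warning("no feature exceeds either selection threshold")
  sel_by <- function(flag) {
    s <- res[res[[flag]], ]
    split(s$feature, s$provenance)
  }
  structure(res, class = c("screening_result", "data.frame"),
            thresholds = c(r = threshold_r, mic = threshold_mic),
            selected = list(r = sel_by("selected_r"),
                            mic = sel_by("selected_mic")))
}

#' @export
print.screening_result <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("<screening_result> %d features (|r| > %.2f: %d, MIC > %.2f: %d)\n",
              nrow(x), thr["r"], sum(x$selected_r), thr["mic"],
              sum(x$selected_mic)))
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}
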