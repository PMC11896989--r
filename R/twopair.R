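#' Combine a vegetation index with a texture feature
#'
#' The three classic two-feature forms, applied to a VI/TF pair:
#' ratio `SR = TF / VI`, normalized difference
#' `NDVI = (VI - TF) / (VI + TF)`, and difference `DVI = VI - TF`.
#' Division by zero yields `NaN`.
#'
#' @param vi,tf numeric values, vectors or matrices (recycled/elementwise).
#' @param type one of `"SR"`, `"NDVI"`, `"DVI"`.
#' @return Combined value(s), same shape as the inputs.
#' @export
build_combination <- function(vi, tf, type = c("SR", "NDVI", "DVI")) {
  type <- match.arg(type)
  out <- switch(type,
                SR = tf / vi,
                NDVI = (vi - tf) / (vi + tf),
                DVI = vi - tf)
  out[!is.finite(out) & !is.na(out)] <- NaN
  out
}

combination_types <- function() c("SR", "NDVI", "DVI")

#' Simple linear fit of chlorophyll on a combined feature
#'
#' Ordinary least squares of `lcc` on `combo` with the conventional goodness
#' measures: `r2 = 1 - SS_res / SS_tot` and `rmse = sqrt(SS_res / n)`
#' (population denominator). Non-finite pairs are dropped and counted.
#'
#' @param combo,lcc numeric vectors.
#' @return List: slope, intercept, r2, rmse, n_used, n_dropped.
#' @export
fit_linear <- function(combo, lcc) {
  ok <- is.finite(combo) & is.finite(lcc)
  n <- sum(ok)
  if (n < 3) stop("fit_linear needs n >= 3 finite pairs", call. = FALSE)
  x <- combo[ok]; y <- lcc[ok]
  sx <- sd(x)
  if (sx == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                rmse = NA_real_, n_used = n, n_dropped = length(combo) - n))
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  ss_res <- sum(res^2); ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / n),
       n_used = n, n_dropped = length(combo) - n)
}

#' Exhaustive two-pair VI x TF combination search
#'
#' Fits every (type, VI, TF) combination linearly against chlorophyll: with
#' the full registries this is 20 VIs x 8 TFs = 160 combinations per type
#' per PC image. Fits retaining fewer than 80% of points (after dropping
#' non-finite combination values) are flagged; constant combinations are
#' recorded with undefined `r2`.
#'
#' @param table a feature table with `spad` plus VI and TF columns, or
#'   explicit `vis`/`tfs` data.frames via those arguments.
#' @param vis,tfs optional character vectors naming the VI and TF columns;
#'   default: columns with provenance `"VI"` vs `"TF-*"`.
#' @param types combination types to search (default all three).
#' @return A `twopair_search` data.frame, one row per (type, pc, vi, tf):
#'   slope, intercept, r2, rmse, n_used, flagged; sorted by descending r2
#'   with ties broken by (type, vi, tf). The PC image of each TF is parsed
#'   from its `PCk_` name prefix (`"-"` when absent).
#' @export
twopair_search <- function(table, vis = NULL, tfs = NULL,
                           types = combination_types()) {
  prov <- attr(table, "provenance")
  feats <- feature_columns(table)
  if (is.null(vis)) vis <- feats[prov[feats] == "VI"]
  if (is.null(tfs)) tfs <- feats[startsWith(prov[feats] %||% "", "TF")]
  if (!length(vis) || !length(tfs))
    stop("need at least one VI and one TF column", call. = FALSE)
  lcc <- table$spad
  rows <- vector("list", length(vis) * length(tfs) * length(types))
  ix <- 0L
  for (type in types) for (v in vis) for (tf in tfs) {
    combo <- build_combination(table[[v]], table[[tf]], type)
    fit <- tryCatch(fit_linear(combo, lcc), error = function(e) NULL)
    ix <- ix + 1L
    pc <- if (grepl("^PC[0-9]+_", tf)) sub("^(PC[0-9]+)_.*", "\\1", tf) else "-"
    if (is.null(fit)) {
      rows[[ix]] <- data.frame(type = type, pc = pc, vi = v, tf = tf,
                               slope = NA, intercept = NA, r2 = NA, rmse = NA,
                               n_used = 0L, flagged = TRUE,
                               stringsAsFactors = FALSE)
    } else {
      rows[[ix]] <- data.frame(type = type, pc = pc, vi = v, tf = tf,
                               slope = fit$slope, intercept = fit$intercept,
                               r2 = fit$r2, rmse = fit$rmse,
                               n_used = fit$n_used,
                               flagged = fit$n_used < 0.8 * length(lcc) ||
                                 is.na(fit$r2),
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(-ifelse(is.na(res$r2), -Inf, res$r2),
                   res$type, res$vi, res$tf), ]
  rownames(res) <- NULL
  structure(res, class = c("twopair_search", "data.frame"),
            n_points = length(lcc))
}

#' Best two-pair combination per type
#'
#' The argmax-r2 combination for each type (across PC images), with the
#' fitted model in the reporting convention `y = a x + b` where x is the
#' combination and y chlorophyll. Ties in r2 resolve lexicographically by
#' (type, vi, tf) - deterministic across runs.
#'
#' @param results a [twopair_search()] result.
#' @param per_type one best row per type (default) or the single overall
#'   best.
#' @return A `twopair_best` data.frame with a `model` column.
#' @export
best_combination <- function(results, per_type = TRUE) {
  stopifnot(inherits(results, "twopair_search"), nrow(results) > 0)
  res <- results[!is.na(results$r2), ]
  # results are sorted by descending r2 with lexicographic tie-break
  best <- if (per_type) res[!duplicated(res$type), ] else res[1, ]
  best$model <- sprintf("y = %.4g*x + %.4g", best$slope, best$intercept)
  rownames(best) <- NULL
  structure(best, class = c("twopair_best", "data.frame"))
}

#' @export
print.twopair_search <- function(x, ...) {
  cat(sprintf("<twopair_search> %d combinations (%d points)\n",
              nrow(x), attr(x, "n_points")))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 3)
  invisible(x)
}

#' @export
print.twopair_best <- function(x, ...) {
  cat("Optimal two-pair feature combinations:\n")
  df <- as.data.frame(x)[, c("type", "pc", "vi", "tf", "model", "r2", "rmse")]
  print.data.frame(df, digits = 3)
  invisible(x)
}

#' Predict chlorophyll from a best two-pair fit
#'
#' @param object a `twopair_best` row (the first row is used).
#' @param vi,tf feature values (vectors or matrices).
#' @param ... unused.
#' @return Predicted chlorophyll, `slope * combination + intercept`.
#' @export
predict.twopair_best <- function(object, vi, tf, ...) {
  b <- object[1, ]
  b$slope * build_combination(vi, tf, b$type) + b$intercept
}

#' @export
coef.twopair_best <- function(object, ...) {
  stats::setNames(c(object$slope[1], object$intercept[1]),
                  c("slope", "intercept"))
}

#' R-squared grid heatmap of a two-pair search
#'
#' One panel per combination type: VIs on the x axis, TFs on the y axis,
#' cell color = r2 of the linear chlorophyll fit (the layout of the
#' grid-search figures in this line of work).
#'
#' @param x a [twopair_search()] result.
#' @param type combination type to draw (default `"SR"`).
#' @param ... passed to [graphics::image()].
#' @export
plot.twopair_search <- function(x, type = "SR", ...) {
  d <- x[x$type == type & !is.na(x$r2), ]
  vis <- sort(unique(d$vi)); tfs <- sort(unique(d$tf))
  z <- matrix(NA_real_, length(vis), length(tfs),
              dimnames = list(vis, tfs))
  z[cbind(match(d$vi, vis), match(d$tf, tfs))] <- d$r2
  image(seq_along(vis), seq_along(tfs), z, axes = FALSE,
        xlab = "vegetation index", ylab = "texture feature",
        main = sprintf("%s-type combinations: r2 vs chlorophyll", type),
        col = hcl.colors(64, "viridis"), ...)
  axis(1, seq_along(vis), vis, las = 2, cex.axis = 0.6)
  axis(2, seq_along(tfs), tfs, las = 2, cex.axis = 0.6)
  invisible(z)
}
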