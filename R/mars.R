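# Adaptive regression splines (piecewise-linear, additive).
#
# Forward pass: starting from the intercept, repeatedly add the reflected
# hinge pair (max(x_v - t, 0), max(t - x_v, 0)) that most reduces the
# residual sum of squares, over all variables and candidate knots at
# observed-value quantiles, until `max_terms` basis functions or no useful
# improvement. Backward pass: greedily delete single terms, keeping the
# model with the lowest GCV = RSS / (n (1 - C(M)/n)^2), with effective
# parameter count C(M) = M + penalty * (M - 1) / 2.

ars_design <- function(X, terms) {
  D <- matrix(1, nrow(X), 1 + length(terms))
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    v <- X[, tm$var]
    D[, i + 1] <- if (tm$dir > 0) pmax(v - tm$knot, 0) else pmax(tm$knot - v, 0)
  }
  D
}

ars_rss <- function(D, y) {
  fit <- tryCatch(lm.fit(D, y), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  sum(fit$residuals^2)
}

#' Fit adaptive regression splines
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response.
#' @param max_terms maximum number of basis functions including the
#'   intercept (default 21).
#' @param penalty GCV penalty per knot (default 2, the usual additive-model
#'   value).
#' @param n_knots maximum candidate knots per variable (quantiles of the
#'   observed values; default 15).
#' @return Object of class `ars_fit` with the selected hinge terms and
#'   coefficients.
#' @export
ars_fit <- function(X, y, max_terms = 21L, penalty = 2, n_knots = 15L) {
  X <- as.matrix(X); n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  terms <- list()
  rss <- sum((y - mean(y))^2)
  knots <- lapply(seq_len(ncol(X)), function(v) {
    u <- sort(unique(X[, v]))
    u <- u[-length(u)]                       # a hinge at the max is constant
    if (length(u) > n_knots) u <- unique(quantile(u, seq(0.05, 0.95,
                                                         length.out = n_knots)))
    u
  })
  # forward pass
  while (length(terms) + 1 + 2 <= max_terms) {
    best <- NULL
    D0 <- ars_design(X, terms)
    for (v in seq_len(ncol(X))) {
      for (t in knots[[v]]) {
        h1 <- pmax(X[, v] - t, 0); h2 <- pmax(t - X[, v], 0)
        r <- ars_rss(cbind(D0, h1, h2), y)
        if (is.null(best) || r < best$rss) best <- list(v = v, t = t, rss = r)
      }
    }
    if (is.null(best) || !is.finite(best$rss) ||
        best$rss > (1 - 1e-4) * rss) break
    terms <- c(terms, list(list(var = best$v, knot = best$t, dir = 1),
                           list(var = best$v, knot = best$t, dir = -1)))
    rss <- best$rss
  }
  # backward pruning by GCV
  gcv <- function(rss, m) {
    cm <- m + penalty * (m - 1) / 2
    if (cm >= n) return(Inf)
    rss / (n * (1 - cm / n)^2)
  }
  cur <- terms
  best_terms <- cur
  best_gcv <- gcv(ars_rss(ars_design(X, cur), y), length(cur) + 1)
  while (length(cur) > 0) {
    cand_gcv <- Inf; cand <- NULL
    for (i in seq_along(cur)) {
      tr <- cur[-i]
      g <- gcv(ars_rss(ars_design(X, tr), y), length(tr) + 1)
      if (g < cand_gcv) { cand_gcv <- g; cand <- tr }
    }
    cur <- cand
    if (cand_gcv < best_gcv) { best_gcv <- cand_gcv; best_terms <- cur }
  }
  D <- ars_design(X, best_terms)
  fit <- lm.fit(D, y)
  structure(list(terms = best_terms, coef = fit$coefficients,
                 gcv = best_gcv, vars = colnames(X)),
            class = "ars_fit")
}

#' @export
predict.ars_fit <- function(object, newdata, ...) {
  D <- ars_design(as.matrix(newdata), object$terms)
  cf <- object$coef; cf[is.na(cf)] <- 0
  as.vector(D %*% cf)
}

#' @export
print.ars_fit <- function(x, ...) {
  cat(sprintf("<ars_fit> %d hinge terms (+ intercept), GCV %.4g\n",
              length(x$terms), x$gcv))
  for (tm in x$terms)
    cat(sprintf("  %s h(%s%s %s %.4g)\n", "", if (tm$dir > 0) "" else "-",
                x$vars[tm$var], if (tm$dir > 0) "-" else "+", tm$knot))
  invisible(x)
}
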