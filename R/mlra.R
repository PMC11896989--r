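#' Seeded k-fold assignment
#'
#' Shuffle then round-robin: fold sizes differ by at most one, the folds
#' partition `1:n`, and identical seeds give identical folds.
#'
#' @param n number of samples (must be >= k).
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold labels in `1:k`.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop(sprintf("cannot make %d folds from %d samples", k, n),
                  call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(n)
    folds <- integer(n)
    folds[idx] <- rep_len(seq_len(k), n)
    folds
  })
}

mlra_models <- function() c("PLSR", "ARS", "SVR", "GPR")

# Standardization learned on the training fold only.
std_fit <- function(X) {
  mu <- colMeans(X); s <- apply(X, 2, sd); s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, s = s)
}
std_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$s, "/")

#' Train one regression family
#'
#' Dispatches to the four supported model families. Features are
#' z-standardized with training statistics for every family; PLSR chooses
#' its latent-variable count by inner 5-fold cross-validation, SVR tunes
#' (C, gamma, epsilon) on an inner grid, ARS uses the forward/backward
#' spline search of [ars_fit()], and GPR maximizes the marginal likelihood
#' ([gpr_fit()]).
#'
#' @param model one of `"PLSR"`, `"ARS"`, `"SVR"`, `"GPR"`.
#' @param X,y training data (matrix / vector, no NA).
#' @param seed seed for inner CV splits and GPR restarts.
#' @param features optional feature names recorded for map-time checks.
#' @return Object of class `mlra_fit` usable with `predict()` and
#'   [predict_map()].
#' @export
mlra_train <- function(model = mlra_models(), X, y, seed = 1L,
                       features = colnames(X)) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y))
    stop(sprintf("%s: NA in model inputs", model), call. = FALSE)
  st <- std_fit(X)
  Xtr <- std_apply(X, st)
  colnames(Xtr) <- paste0("f", seq_len(ncol(Xtr)))
  n <- nrow(Xtr)
  engine <- switch(model,
    PLSR = {
      ncomp_max <- max(1L, min(10L, ncol(Xtr), n - 2L))
      nc <- if (ncomp_max == 1L) 1L else {
        folds <- make_folds(n, k = min(5L, n), seed = seed)
        errs <- matrix(NA_real_, max(folds), ncomp_max)
        for (f in seq_len(max(folds))) {
          tr <- folds != f
          m <- mixOmics::pls(Xtr[tr, , drop = FALSE], y[tr],
                             ncomp = min(ncomp_max, sum(tr) - 2L),
                             mode = "regression", scale = FALSE)
          p <- predict(m, Xtr[!tr, , drop = FALSE])$predict
          for (cc in seq_len(dim(p)[3]))
            errs[f, cc] <- mean((p[, 1, cc] - y[!tr])^2)
        }
        which.min(colMeans(errs, na.rm = TRUE))
      }
      list(fit = mixOmics::pls(Xtr, y, ncomp = nc, mode = "regression",
                               scale = FALSE), ncomp = nc)
    },
    ARS = list(fit = ars_fit(Xtr, y)),
    SVR = {
      grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                          gamma = (1 / ncol(Xtr)) * c(0.1, 1, 10),
                          epsilon = c(0.01, 0.1, 1))
      folds <- make_folds(n, k = min(5L, n), seed = seed)
      cvmse <- vapply(seq_len(nrow(grid)), function(i) {
        se <- 0
        for (f in seq_len(max(folds))) {
          tr <- folds != f
          m <- e1071::svm(Xtr[tr, , drop = FALSE], y[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = grid$cost[i], gamma = grid$gamma[i],
                          epsilon = grid$epsilon[i], scale = FALSE)
          se <- se + sum((predict(m, Xtr[!tr, , drop = FALSE]) - y[!tr])^2)
        }
        se / n
      }, numeric(1))
      g <- grid[which.min(cvmse), ]
      list(fit = e1071::svm(Xtr, y, type = "eps-regression",
                            kernel = "radial", cost = g$cost,
                            gamma = g$gamma, epsilon = g$epsilon,
                            scale = FALSE), tuning = g)
    },
    GPR = list(fit = gpr_fit(Xtr, y, restarts = 5L, seed = seed)))
  structure(list(model = model, std = st, engine = engine,
                 features = features),
            class = "mlra_fit")
}

#' @export
predict.mlra_fit <- function(object, newdata, ...) {
  Xte <- std_apply(as.matrix(newdata), object$std)
  colnames(Xte) <- paste0("f", seq_len(ncol(Xte)))
  fit <- object$engine$fit
  switch(object$model,
    PLSR = data.frame(mean = as.vector(
      predict(fit, Xte)$predict[, 1, object$engine$ncomp]), sd = NA_real_),
    ARS = data.frame(mean = predict(fit, Xte), sd = NA_real_),
    SVR = data.frame(mean = as.vector(predict(fit, Xte)), sd = NA_real_),
    GPR = predict(fit, Xte))
}

#' @export
print.mlra_fit <- function(x, ...) {
  cat(sprintf("<mlra_fit> %s on %d features\n", x$model,
              length(x$features %||% x$std$mu)))
  invisible(x)
}

#' Fit one regression family and predict held-out samples
#'
#' One-shot wrapper around [mlra_train()] and its predict method.
#'
#' @param model model family name.
#' @param X_train,y_train training data (no NA).
#' @param X_test matrix of prediction points.
#' @param seed seed for inner CV splits and GPR restarts.
#' @return List with `pred` (vector) and `sd` (vector for GPR, else `NULL`).
#' @export
fit_predict <- function(model = mlra_models(), X_train, y_train, X_test,
                        seed = 1L) {
  m <- mlra_train(model, X_train, y_train, seed = seed)
  p <- predict(m, as.matrix(X_test))
  list(pred = p$mean, sd = if (all(is.na(p$sd))) NULL else p$sd)
}

#' Feature groups for multivariable modelling
#'
#' Builds the variable groups evaluated against each other: all 20 VIs, the
#' 9 red-edge VIs, all VIs plus the texture features of each PC image
#' (28 features each with full registries), and - when a screening result is
#' supplied - the groups of selected VIs plus selected TFs per PC image
#' under each criterion (|r| and MIC). Empty groups are omitted.
#'
#' @param table a feature table (for column availability).
#' @param screening optional [select_features()] result.
#' @return Named list of character vectors of feature names, with attribute
#'   `n_features`.
#' @export
feature_groups <- function(table, screening = NULL) {
  feats <- feature_columns(table)
  prov <- attr(table, "provenance")
  vis <- feats[prov[feats] == "VI"]
  reg <- vi_registry()
  vire <- intersect(vis, reg$name[reg$class == "VI_re"])
  pcs <- sort(unique(sub("^TF-", "", prov[startsWith(prov, "TF-")])))
  groups <- list()
  if (length(vis)) groups[["All VIs"]] <- vis
  if (length(vire)) groups[["All VI_re"]] <- vire
  for (pc in pcs) {
    tf <- feats[prov[feats] == paste0("TF-", pc)]
    groups[[sprintf("All VIs+TFs-%s", pc)]] <- c(vis, tf)
  }
  if (!is.null(screening)) {
    sel <- attr(screening, "selected")
    for (crit in c("r", "mic")) {
      sv <- sel[[crit]][["VI"]] %||% character(0)
      for (pc in pcs) {
        stf <- sel[[crit]][[paste0("TF-", pc)]] %||% character(0)
        if (length(stf) == 0) next
        lab <- sprintf("Selected(%s) VIs+TFs-%s",
                       if (crit == "r") "r" else "MIC", pc)
        groups[[lab]] <- c(sv, stf)
      }
    }
  }
  groups <- groups[lengths(groups) > 0]
  structure(groups, n_features = lengths(groups))
}

pooled_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  c(r2 = 1 - ss_res / sum((obs - mean(obs))^2),
    rmse = sqrt(ss_res / length(obs)))
}

#' Cross-validated evaluation of one model on one feature group
#'
#' k-fold cross-validation with pooled out-of-fold metrics: every sample is
#' predicted exactly once by a model that never saw it, and `r2`/`rmse` are
#' computed on the concatenated held-out predictions.
#'
#' @param model model family name (see [fit_predict()]).
#' @param features character vector of feature columns.
#' @param table a feature table with those columns and `spad`.
#' @param k folds (default 10).
#' @param seed CV seed (default 20240426).
#' @param group_name label recorded in the result (defaults to "custom").
#' @return Object of class `cv_result`: model, group, k, seed, r2, rmse,
#'   `predictions` (id, observed, predicted, sd, fold), per-fold metrics.
#' @export
evaluate_model <- function(model, features, table, k = 10L, seed = 20240426L,
                           group_name = NULL) {
  stopifnot(all(features %in% names(table)))
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$spad
  folds <- make_folds(nrow(X), k = k, seed = seed)
  pred <- rep(NA_real_, nrow(X)); psd <- rep(NA_real_, nrow(X))
  for (f in seq_len(k)) {
    te <- folds == f
    fp <- fit_predict(model, X[!te, , drop = FALSE], y[!te],
                      X[te, , drop = FALSE], seed = seed + f)
    pred[te] <- fp$pred
    if (!is.null(fp$sd)) psd[te] <- fp$sd
  }
  m <- pooled_metrics(y, pred)
  per_fold <- t(vapply(seq_len(k), function(f)
    pooled_metrics(y[folds == f], pred[folds == f]), numeric(2)))
  structure(list(model = model, group = group_name %||% "custom",
                 k = k, seed = seed, r2 = unname(m["r2"]),
                 rmse = unname(m["rmse"]),
                 predictions = data.frame(id = table$id, observed = y,
                                          predicted = pred, sd = psd,
                                          fold = folds),
                 fold_metrics = per_fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on '%s' (%d-fold, seed %d): r2 = %.3f, rmse = %.3f\n",
              x$model, x$group, x$k, x$seed, x$r2, x$rmse))
  invisible(x)
}

#' Cross-validated model x feature-group comparison
#'
#' Evaluates every model family on every feature group under a common fold
#' assignment and assembles the results matrix (groups as rows, model
#' r2/rmse as columns).
#'
#' @param table a feature table.
#' @param groups named list from [feature_groups()] (or any named list of
#'   feature-name vectors).
#' @param models model families (default all four).
#' @param k,seed cross-validation settings.
#' @return Object of class `mlra_cv`: `results` (long data.frame), `matrix`
#'   (wide), and the per-cell `cv_result` objects in `fits`.
#' @export
mlra_cv <- function(table, groups = feature_groups(table),
                    models = mlra_models(), k = 10L, seed = 20240426L) {
  fits <- list()
  rows <- list()
  for (g in names(groups)) {
    for (m in models) {
      cv <- evaluate_model(m, groups[[g]], table, k = k, seed = seed,
                           group_name = g)
      fits[[paste(g, m, sep = " / ")]] <- cv
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, n_features = length(groups[[g]]), model = m,
                   r2 = cv$r2, rmse = cv$rmse, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  wide <- stats::reshape(res[, c("group", "n_features", "model", "r2", "rmse")],
                         direction = "wide", idvar = c("group", "n_features"),
                         timevar = "model")
  rownames(wide) <- NULL
  structure(list(results = res, matrix = wide, fits = fits, k = k,
                 seed = seed),
            class = "mlra_cv")
}

#' @export
print.mlra_cv <- function(x, ...) {
  cat(sprintf("<mlra_cv> %d-fold CV (seed %d), pooled out-of-fold metrics\n",
              x$k, x$seed))
  print.data.frame(x$matrix, digits = 3)
  invisible(x)
}

#' @export
summary.mlra_cv <- function(object, ...) {
  best <- object$results[which.max(object$results$r2), ]
  cat(sprintf("Best: %s on '%s' (r2 = %.3f, rmse = %.3f)\n",
              best$model, best$group, best$r2, best$rmse))
  invisible(best)
}

#' Measured-vs-predicted scatter of one evaluated cell
#'
#' @param x an `mlra_cv` object.
#' @param which name of a fitted cell (`"<group> / <model>"`); default the
#'   highest-r2 cell.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mlra_cv <- function(x, which = NULL, ...) {
  if (is.null(which)) {
    best <- x$results[which.max(x$results$r2), ]
    which <- paste(best$group, best$model, sep = " / ")
  }
  cv <- x$fits[[which]]
  p <- cv$predictions
  plot(p$observed, p$predicted, xlab = "measured SPAD",
       ylab = "predicted SPAD (out-of-fold)",
       main = sprintf("%s (r2 = %.3f, rmse = %.3f)", which, cv$r2, cv$rmse),
       ...)
  abline(0, 1, lty = 2)
  invisible(cv)
}
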