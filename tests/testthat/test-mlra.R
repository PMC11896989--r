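linear_fixture <- function(n = 36, p = 3, noise = 0, seed = 21) {
  set.seed(seed)
  X <- matrix(runif(n * p, -1, 1), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  y <- 55 + 4 * X[, 1] + noise * rnorm(n)
  list(X = X, y = y)
}

test_that("fold assignment partitions samples into near-equal folds", {
  f <- make_folds(74, 10, seed = 1)
  expect_length(f, 74L)
  expect_setequal(unique(f), 1:10)
  sizes <- tabulate(f)
  expect_equal(sort(unique(sizes)), c(7L, 8L))
  expect_equal(sum(sizes == 8), 4L)  # 74 = 4*8 + 6*7
  # leave-one-out at n = k
  expect_equal(sort(tabulate(make_folds(10, 10, 1))), rep(1L, 10))
  expect_identical(make_folds(50, 10, 99), make_folds(50, 10, 99))
  expect_false(identical(make_folds(50, 10, 1), make_folds(50, 10, 2)))
  expect_error(make_folds(5, 10), "folds")
})

test_that("full-rank PLSR predictions equal ordinary least squares", {
  d <- linear_fixture(30, 5, noise = 0.3)
  y <- 55 + d$X %*% c(4, -2, 1, 0.5, 3) + 0.1 * rnorm(30)
  m <- mlra_train("PLSR", d$X, as.vector(y), seed = 1)
  # force all components: refit engine directly at p components
  Xs <- chlorotex:::std_apply(d$X, m$std)
  colnames(Xs) <- paste0("f", 1:5)
  full <- mixOmics::pls(Xs, as.vector(y), ncomp = 5, mode = "regression",
                        scale = FALSE)
  pred <- predict(full, Xs)$predict[, 1, 5]
  ols <- cbind(1, Xs) %*% qr.solve(cbind(1, Xs), y)
  expect_equal(as.vector(pred), as.vector(ols), tolerance = 1e-8)
})

test_that("all four families recover a noiseless linear signal", {
  d <- linear_fixture(40, 3, noise = 0)
  folds <- make_folds(40, 5, seed = 3)
  for (model in mlra_models()) {
    pred <- rep(NA_real_, 40)
    for (f in 1:5) {
      te <- folds == f
      fp <- fit_predict(model, d$X[!te, ], d$y[!te], d$X[te, ], seed = f)
      pred[te] <- fp$pred
      if (model == "GPR") expect_true(all(fp$sd >= 0))
    }
    r2 <- 1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2)
    expect_gt(r2, 0.99)
  }
})

test_that("cross-validation pools out-of-fold predictions exactly once", {
  sc <- small_scene()
  ft <- scene_features(sc, "small7")$table
  cv <- evaluate_model("PLSR", c("NDVI", "MSR_re", "PC1_MEA"), ft, k = 6,
                       seed = 11, group_name = "toy")
  expect_equal(nrow(cv$predictions), nrow(ft))
  expect_false(anyNA(cv$predictions$predicted))
  expect_setequal(unique(cv$predictions$fold), 1:6)
  m <- chlorotex:::pooled_metrics(cv$predictions$observed,
                                  cv$predictions$predicted)
  expect_equal(cv$r2, unname(m["r2"]))
  # out-of-fold predictions invariant to feature column order
  cv2 <- evaluate_model("PLSR", c("PC1_MEA", "NDVI", "MSR_re"), ft, k = 6,
                        seed = 11)
  expect_equal(cv2$predictions$predicted, cv$predictions$predicted,
               tolerance = 1e-9)
})

test_that("shuffled targets yield no spurious cross-validated skill", {
  set.seed(44)
  X <- matrix(rnorm(74 * 10), 74, 10,
              dimnames = list(NULL, paste0("X", 1:10)))
  r2s <- vapply(1:5, function(i) {
    y <- sample(runif(74, 45, 70))
    tab <- data.frame(id = as.character(1:74), spad = y, plot = 1L, X)
    tab <- structure(tab, class = c("feature_table", "data.frame"),
                     provenance = stats::setNames(rep("VI", 10),
                                                  colnames(X)))
    evaluate_model("PLSR", colnames(X), tab, k = 10, seed = i)$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("feature groups mirror the variable-group design", {
  sc <- small_scene()
  ft <- scene_features(sc, "small7")$table
  g <- feature_groups(ft)
  expect_equal(length(g[["All VIs"]]), 20L)
  expect_equal(length(g[["All VI_re"]]), 9L)
  expect_equal(length(g[["All VIs+TFs-PC1"]]), 28L)
  expect_equal(length(g[["All VIs+TFs-PC3"]]), 28L)
  expect_true(all(unlist(g) %in% names(ft)))
  # with screening, selected groups combine selected VIs + selected TFs-PCk
  scr <- structure(data.frame(),
                   selected = list(r = list(VI = c("NDVI", "MSR_re"),
                                            `TF-PC1` = c("PC1_MEA")),
                                   mic = list(VI = c("SR"))))
  g2 <- feature_groups(ft, screening = scr)
  expect_equal(g2[["Selected(r) VIs+TFs-PC1"]],
               c("NDVI", "MSR_re", "PC1_MEA"))
  expect_false("Selected(MIC) VIs+TFs-PC1" %in% names(g2))  # no TFs selected
})

test_that("GPR predictive intervals cover draws from its own prior", {
  cover <- vapply(1:4, function(s) {
    set.seed(s)
    n <- 60
    X <- matrix(runif(n, -2, 2), n, 1)
    D2 <- as.matrix(dist(X))^2
    K <- 4 * exp(-0.5 * D2 / 0.5^2) + diag(0.2, n)
    y <- 55 + as.vector(t(chol(K)) %*% rnorm(n))
    tr <- 1:40; te <- 41:60
    m <- gpr_fit(X[tr, , drop = FALSE], y[tr], seed = s)
    p <- predict(m, X[te, , drop = FALSE])
    mean(abs(y[te] - p$mean) <= 1.96 * p$sd)
  }, numeric(1))
  expect_gt(mean(cover), 0.85)
  expect_lte(mean(cover), 1)
})

test_that("the model x group matrix assembles in evaluation shape", {
  sc <- small_scene()
  ft <- scene_features(sc, "small7")$table
  groups <- list(vi3 = c("NDVI", "MSR_re", "CI_re"),
                 vi3tf = c("NDVI", "MSR_re", "CI_re", "PC1_MEA"))
  cv <- mlra_cv(ft, groups, models = c("PLSR", "GPR"), k = 5, seed = 2)
  expect_equal(nrow(cv$results), 4L)
  expect_setequal(cv$results$model, c("PLSR", "GPR"))
  expect_equal(nrow(cv$matrix), 2L)
  expect_true(all(c("r2.PLSR", "rmse.GPR") %in% names(cv$matrix)))
})
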