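# A compact synthetic feature table with controlled signal: MEA is the most
# informative texture by construction.
twopair_table <- function(n = 40, seed = 17) {
  set.seed(seed)
  spad <- runif(n, 45, 70)
  tab <- data.frame(id = sprintf("p%02d", 1:n), spad = spad, plot = 1L)
  tab$VI_a <- 1 / (spad + rnorm(n, 0, 2))          # ratio-style VI
  tab$VI_b <- spad * 0.02 + rnorm(n, 0, 0.2)
  tab$PC1_MEA <- spad * 0.3 + rnorm(n, 0, 0.4)     # strongest TF
  tab$PC1_CON <- rnorm(n, 5, 1)
  tab$PC1_ENT <- 0.05 * spad + rnorm(n, 0, 1.5)
  prov <- c(VI_a = "VI", VI_b = "VI", PC1_MEA = "TF-PC1", PC1_CON = "TF-PC1",
            PC1_ENT = "TF-PC1")
  structure(tab, class = c("feature_table", "data.frame"), provenance = prov)
}

test_that("combination forms follow their defining algebra", {
  expect_equal(build_combination(2, 4, "SR"), 2)      # TF / VI
  expect_equal(build_combination(0.3, 0.3, "NDVI"), 0)
  expect_equal(build_combination(0.9, 0.2, "DVI"), 0.7)
  expect_true(is.nan(build_combination(0, 1, "SR")))
  expect_true(is.nan(build_combination(0.5, -0.5, "NDVI")))
  expect_error(build_combination(1, 2, "XXX"))
})

test_that("linear fits agree with the normal-equation oracle", {
  expect_equal(fit_linear(c(1, 2, 3), c(2, 4, 6))[c("slope", "intercept")],
               list(slope = 2, intercept = 0))
  f <- fit_linear(c(1, 2, 3), c(5, 7, 9))
  expect_equal(f$r2, 1); expect_equal(f$rmse, 0)
  set.seed(2)
  x <- c(0.3, 1.1, 2.7, 3.2, 4.9); y <- 50 + 2 * x + rnorm(5)
  f2 <- fit_linear(x, y)
  ref <- oracle_ols(x, y)
  expect_equal(f2$intercept, ref[1], tolerance = 1e-10)
  expect_equal(f2$slope, ref[2], tolerance = 1e-10)
  res <- y - (f2$slope * x + f2$intercept)
  expect_equal(f2$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(f2$rmse, sqrt(mean(res^2)), tolerance = 1e-12)
  # NaN pairs are dropped and counted
  f3 <- fit_linear(c(x, NaN), c(y, 60))
  expect_equal(f3$n_used, 5L); expect_equal(f3$n_dropped, 1L)
})

test_that("the exhaustive search enumerates every pair, type and PC", {
  tab <- twopair_table()
  res <- twopair_search(tab)
  expect_equal(nrow(res), 2 * 3 * 3)  # 2 VIs x 3 TFs x 3 types
  expect_setequal(unique(res$type), c("SR", "NDVI", "DVI"))
  expect_true(all(res$pc == "PC1"))
  # every fit equals an independent recomputation
  for (i in sample(nrow(res), 6)) {
    combo <- build_combination(tab[[res$vi[i]]], tab[[res$tf[i]]],
                               res$type[i])
    ref <- fit_linear(combo, tab$spad)
    expect_equal(res$r2[i], ref$r2, tolerance = 1e-12)
    expect_equal(res$slope[i], ref$slope, tolerance = 1e-12)
  }
  # one VI x one TF gives exactly one fit per type
  res1 <- twopair_search(tab, vis = "VI_b", tfs = "PC1_MEA")
  expect_equal(nrow(res1), 3L)
})

test_that("ranked output is invariant to column order and rescaling", {
  tab <- twopair_table()
  feats <- setdiff(names(tab), c("id", "spad", "plot"))
  tab2 <- tab[, c("id", "spad", "plot", rev(feats))]
  attr(tab2, "provenance") <- attr(tab, "provenance")[rev(feats)]
  class(tab2) <- class(tab)
  r1 <- twopair_search(tab); r2 <- twopair_search(tab2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # SR-type r2 is invariant to positive rescaling of the TF column
  tab3 <- tab; tab3$PC1_MEA <- tab3$PC1_MEA * 37.5
  r3 <- twopair_search(tab3)
  sr1 <- r1[r1$type == "SR" & r1$tf == "PC1_MEA", ]
  sr3 <- r3[r3$type == "SR" & r3$tf == "PC1_MEA", ]
  expect_equal(sr1$r2[order(sr1$vi)], sr3$r2[order(sr3$vi)],
               tolerance = 1e-10)
})

test_that("the best combination reports the constructed winner", {
  tab <- twopair_table()
  res <- twopair_search(tab)
  best <- best_combination(res)
  expect_equal(nrow(best), 3L)  # one per type
  expect_true(all(best$tf == "PC1_MEA"))  # MEA built most informative
  expect_match(best$model[1], "^y = ")
  # per_type = FALSE returns the single best row
  overall <- best_combination(res, per_type = FALSE)
  expect_equal(overall$r2, max(res$r2, na.rm = TRUE))
  # deterministic lexicographic tie-break
  t2 <- data.frame(type = c("SR", "SR"), pc = "PC1",
                   vi = c("B_vi", "A_vi"), tf = "T", slope = 1,
                   intercept = 0, r2 = 0.5, rmse = 1, n_used = 10L,
                   flagged = FALSE)
  t2 <- t2[order(-t2$r2, t2$type, t2$vi, t2$tf), ]
  t2 <- structure(t2, class = c("twopair_search", "data.frame"),
                  n_points = 10L)
  expect_equal(best_combination(t2)$vi, "A_vi")
  # prediction is the closed-form line
  expect_equal(predict(best, vi = 2, tf = 4),
               best$slope[1] * build_combination(2, 4, best$type[1]) +
                 best$intercept[1])
})

test_that("constant combinations are skipped with undefined r2", {
  tab <- twopair_table()
  tab$VI_b <- 0.4; tab$PC1_CON <- 4.2  # constant pair -> constant combos
  res <- twopair_search(tab)
  bad <- res[res$tf == "PC1_CON" & res$vi == "VI_b", ]
  expect_true(all(is.na(bad$r2)))
  expect_true(all(bad$flagged))
})
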