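test_that("PCA reproduces variance structure and conventions", {
  # rank-1 cube: one spectral shape scaled by a brightness field
  set.seed(2)
  shape <- runif(6)
  bright <- matrix(runif(100, 0.5, 1.5), 10, 10)
  arr <- array(0, c(10, 10, 6))
  for (b in 1:6) arr[, , b] <- bright * shape[b]
  cube <- hyperspec_cube(arr, seq(400, 900, length.out = 6))
  p <- pca_transform(cube, n_components = 1L)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-10)
  # orthonormal loadings, largest-magnitude element positive
  sc <- small_scene()
  p3 <- pca_transform(sc$cube, mask = sc$truth$vegetation_mask_true)
  expect_equal(crossprod(p3$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (k in 1:3)
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, k])), k], 0)
  expect_equal(sum(p3$explained_variance_ratio), 1, tolerance = 1e-10)
  # constant cube has no principal directions
  flat <- hyperspec_cube(array(0.4, c(5, 5, 4)), c(1, 2, 3, 4) * 100 + 300)
  expect_error(pca_transform(flat), "rank error")
})

test_that("quantization bins linearly with a right-closed top bin", {
  q <- quantize(matrix(c(0, 0.5, 1), 1, 3), levels = 2)
  expect_equal(as.vector(q), c(0L, 1L, 1L))
  expect_warning(q2 <- quantize(matrix(5, 2, 2), 8), "constant")
  expect_true(all(q2 == 0L))
  set.seed(1)
  q3 <- quantize(matrix(rnorm(100), 10, 10), levels = 16)
  expect_true(all(q3 >= 0 & q3 <= 15))
  expect_equal(max(q3), 15L)  # the maximum maps to G-1
  # reused bounds shift levels consistently
  q4 <- quantize(matrix(0.5, 1, 1), 4, bounds = c(0, 1))
  expect_equal(as.vector(q4), 2L)
})

test_that("single-window co-occurrence matrices count pairs correctly", {
  g <- matrix(3L, 3, 3)
  P <- glcm_window(g, c(2, 2), levels = 8)
  expect_equal(sum(P), 1)
  expect_equal(P[4, 4], 1)
  # vertical stripes, horizontal offset only: p(0,1) = p(1,0) = 1/2
  stripes <- matrix(rep(c(0L, 1L, 0L), each = 3), 3, 3)
  Ph <- glcm_window(stripes, c(2, 2), levels = 2,
                    offsets = cbind(0L, 1L))
  expect_equal(Ph[1, 2], 0.5)
  expect_equal(Ph[2, 1], 0.5)
  expect_equal(attr(Ph, "n_pairs"), 6L)
  # fully masked window is undefined texture
  expect_error(glcm_window(matrix(NA_integer_, 3, 3), c(2, 2), levels = 2),
               "undefined texture")
  # random windows always normalize
  set.seed(3)
  for (i in 1:20) {
    g <- matrix(sample(0:3, 25, TRUE), 5, 5)
    expect_equal(sum(glcm_window(g, c(3, 3), levels = 4)), 1)
  }
})

test_that("Haralick statistics match hand-computed distributions", {
  # constant window: degenerate single-cell distribution
  gconst <- matrix(2L, 3, 3)
  f <- haralick_features(glcm_window(gconst, c(2, 2), levels = 8))
  expect_equal(unname(f), c(2, 0, 1, 0, 0, 0, 1, 1),
               tolerance = 1e-12)
  # two-cell symmetric distribution p(0,1) = p(1,0) = 1/2
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  f2 <- haralick_features(P)
  expect_equal(f2[["CON"]], 1); expect_equal(f2[["DIS"]], 1)
  expect_equal(f2[["HOM"]], 0.5); expect_equal(f2[["ENT"]], 1)  # 1 bit
  expect_equal(f2[["SEC"]], 0.5); expect_equal(f2[["MEA"]], 0.5)
  expect_equal(f2[["VAR"]], 0.25); expect_equal(f2[["COR"]], -1)
  # uniform distribution: SEC = 1/G^2, ENT maximal = 2 log2 G
  G <- 4
  U <- matrix(1 / G^2, G, G)
  fu <- haralick_features(U)
  expect_equal(fu[["SEC"]], 1 / G^2)
  expect_equal(fu[["ENT"]], 2 * log2(G))
  expect_error(haralick_features(matrix(1, 2, 2)), "normalized")
})

test_that("sliding-window images equal the naive pairwise-count oracle", {
  set.seed(9)
  g <- matrix(sample(0:7, 15 * 12, TRUE), 15, 12)
  g[sample(length(g), 20)] <- NA
  imgs <- texture_images(g, levels = 8)
  for (trial in 1:60) {
    r <- sample(nrow(g), 1); c <- sample(ncol(g), 1)
    if (is.na(g[r, c])) next
    ref <- oracle_window_features(g, c(r, c), levels = 8)
    got <- vapply(imgs, function(m) m[r, c], numeric(1))
    expect_equal(unname(got), unname(ref), tolerance = 1e-10)
  }
  # the per-window R path agrees with the C++ image path
  r <- 7; c <- 6
  f <- haralick_features(glcm_window(g, c(r, c), levels = 8))
  expect_equal(unname(vapply(imgs, function(m) m[r, c], numeric(1))),
               unname(f), tolerance = 1e-10)
})

test_that("texture inequalities hold on random windows", {
  set.seed(4)
  for (i in 1:50) {
    g <- matrix(sample(0:5, 9, TRUE), 3, 3)
    f <- haralick_features(glcm_window(g, c(2, 2), levels = 6))
    expect_gte(f[["CON"]], f[["DIS"]])
    expect_gte(f[["DIS"]], 0)
    expect_true(f[["HOM"]] > 0 && f[["HOM"]] <= 1)
    expect_true(f[["SEC"]] > 0 && f[["SEC"]] <= 1)
  }
})

test_that("finer quantization does not decrease entropy on average", {
  set.seed(8)
  ents <- sapply(c(4, 8, 16, 32), function(G) {
    mean(replicate(30, {
      img <- matrix(rnorm(49), 7, 7)
      q <- quantize(img, G)
      f <- haralick_features(glcm_window(q, c(4, 4), levels = G))
      f[["ENT"]]
    }))
  })
  expect_true(all(diff(ents) > 0))
})

test_that("per-component texture stacks produce 24 named images", {
  sc <- small_scene()
  sf <- scene_features(sc, "small7")
  tex <- sf$tex
  expect_length(tex$images, 24L)
  expect_setequal(unique(sub("_.*", "", names(tex$images))),
                  c("PC1", "PC2", "PC3"))
  expect_equal(unname(tex$provenance[c("PC1_MEA", "PC3_COR")]),
               c("TF-PC1", "TF-PC3"))
  # constant PC gives constant MEA
  expect_warning(qa <- quantize(matrix(1, 6, 6), 8))
  mea <- texture_images(qa, 8)$MEA
  expect_true(all(mea == 0))
})
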