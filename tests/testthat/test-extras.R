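test_that("ethanol-extract chlorophyll equations are linear in absorbance", {
  expect_equal(chlorophyll_from_absorbance(0, 0)$total, 0)
  one <- chlorophyll_from_absorbance(0.3, 0.5)
  expect_equal(one$ca, 13.95 * 0.5 - 6.88 * 0.3)
  expect_equal(one$cb, 24.96 * 0.3 - 7.32 * 0.5)
  expect_equal(one$total, 8.739)
  two <- chlorophyll_from_absorbance(0.6, 1.0)
  expect_equal(two$total, 2 * one$total)
  expect_warning(chlorophyll_from_absorbance(0.5, 0.1), "inconsistent")
  expect_error(chlorophyll_from_absorbance(-0.1, 0.2), ">= 0")
})

test_that("exponential calibration recovers exact and noisy parameters", {
  spad <- seq(40, 70, length.out = 12)
  cal <- fit_exponential(spad, 2 * exp(0.05 * spad))
  expect_equal(cal$a, 2, tolerance = 1e-6)
  expect_equal(cal$b, 0.05, tolerance = 1e-6)
  expect_equal(cal$r2, 1, tolerance = 1e-9)
  expect_error(fit_exponential(rep(50, 5), rep(3, 5)), "unidentifiable")
  expect_error(fit_exponential(spad, -2 * exp(0.05 * spad)), "> 0")
  # parameter recovery at the lab sample size across seeds
  hits <- vapply(1:6, function(s) {
    d <- simulate_lab_calibration(n = 18, a = 3.5, b = 0.05, seed = s)
    cal <- fit_exponential(d$spad, d$lcc_lab)
    abs(cal$b - 0.05) <= 3 * cal$se_b && abs(cal$a - 3.5) <= 3 * cal$se_a
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("red-edge sweep reproduces unswept fits and covers the grid", {
  sc <- small_scene()
  mask <- sc$truth$vegetation_mask_true
  pts <- sc$truth$points
  wl <- sc$cube$wavelengths
  in_range <- wl[wl >= 702 & wl <= 742]
  sw <- rededge_sweep(sc$cube, pts, mask = mask, vis = c("MSR_re", "CI_re"))
  expect_setequal(unique(sw$wavelength), in_range)
  # identity substitution: sweeping at the index's own resolved band equals
  # the unswept fit
  own <- wl[nearest_band(wl, 710)]
  img <- compute_vi(sc$cube, "MSR_re", mask = mask)
  ft <- roi_feature_means(list(x = img), pts, mask = mask)
  ref <- fit_linear(ft$x, ft$spad)$r2
  expect_equal(sw$r2[sw$vi == "MSR_re" & sw$wavelength == own], ref,
               tolerance = 1e-12)
  # r2 surface invariant to affine rescaling of the response
  pts2 <- pts; pts2$spad <- 2.5 * pts$spad - 30
  sw2 <- rededge_sweep(sc$cube, pts2, mask = mask, vis = "MSR_re")
  expect_equal(sw2$r2, sw$r2[sw$vi == "MSR_re"], tolerance = 1e-9)
  expect_error(rededge_sweep(sc$cube, pts, mask, range = c(1500, 1600)),
               "no cube bands")
})

test_that("two-pair chlorophyll maps are the closed-form line", {
  sc <- small_scene()
  sf <- scene_features(sc, "small7")
  mask <- sc$truth$vegetation_mask_true
  best <- best_combination(twopair_search(sf$table), per_type = FALSE)
  vi_img <- compute_vi(sc$cube, best$vi[1], mask = mask)
  tf_img <- sf$tex$images[[best$tf[1]]]
  map <- predict_map(best, vi_img, tf_img, mask = mask)
  expect_true(all(is.na(map[!mask])))
  combo <- build_combination(vi_img, tf_img, best$type[1])
  expect_equal(map[mask], (best$slope[1] * combo + best$intercept[1])[mask],
               tolerance = 1e-12)
})

test_that("model-based maps validate features and emit GPR uncertainty", {
  sc <- small_scene()
  sf <- scene_features(sc, "small7")
  mask <- sc$truth$vegetation_mask_true
  feats <- c("NDVI", "MSR_re", "PC1_MEA")
  fit <- mlra_train("GPR", as.matrix(sf$table[, feats]), sf$table$spad,
                    seed = 3, features = feats)
  imgs <- c(vi_images(sc$cube, mask = mask, names = c("NDVI", "MSR_re")),
            sf$tex$images["PC1_MEA"])
  maps <- predict_map(fit, imgs, mask = mask)
  expect_true(all(is.na(maps$map[!mask])))
  expect_true(all(maps$sd_map[mask & is.finite(maps$map)] >= 0, na.rm = TRUE))
  expect_error(predict_map(fit, imgs[1:2], mask = mask), "feature mismatch")
  # mapping the training scene is internally consistent with the points
  ft_map <- roi_feature_means(list(m = maps$map), sc$truth$points,
                              mask = mask)
  expect_gt(cor(ft_map$m, ft_map$spad)^2, 0.5)
})

test_that("chlorophyll maps of the training scene track the ground truth", {
  sc <- small_scene()
  sf <- scene_features(sc, "small7")
  mask <- sc$truth$vegetation_mask_true
  best <- best_combination(twopair_search(sf$table), per_type = FALSE)
  cv <- evaluate_model(
    "PLSR", best_features <- c(best$vi[1], best$tf[1]), sf$table,
    k = 8, seed = 5)
  vi_img <- compute_vi(sc$cube, best$vi[1], mask = mask)
  map <- predict_map(best, vi_img, sf$tex$images[[best$tf[1]]], mask = mask)
  ft_map <- roi_feature_means(list(m = map), sc$truth$points, mask = mask)
  r2_map <- cor(ft_map$m, ft_map$spad)^2
  expect_equal(r2_map, max(cv$r2, 0), tolerance = 0.08)
})
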