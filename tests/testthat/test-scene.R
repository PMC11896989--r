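test_that("leaf reflectance obeys the chlorophyll physics it encodes", {
  wl <- seq(350, 1000, length.out = 164)
  lccs <- seq(40, 75, by = 5)
  spectra <- leaf_reflectance(lccs, wl)
  expect_true(all(spectra >= 0 & spectra <= 1))
  # red absorption strictly deepens with chlorophyll
  r682 <- spectra[, nearest_band(wl, 682)]
  expect_true(all(diff(r682) < 0))
  # NIR plateau
  expect_true(all(spectra[, wl > 780] >= 0.35))
  # red-edge inflection shifts to longer wavelengths with chlorophyll;
  # finite differences on a fine grid resolve the strict monotonicity
  fine <- seq(680, 760, by = 0.25)
  infl <- vapply(lccs, function(l)
    red_edge_inflection(leaf_reflectance(l, fine), fine), numeric(1))
  expect_true(all(diff(infl) > 0))
  # and the spec-scale coarse-grid contrast
  i45 <- red_edge_inflection(leaf_reflectance(45, wl), wl)
  i65 <- red_edge_inflection(leaf_reflectance(65, wl), wl)
  expect_gt(i65 - i45, 0)
  expect_error(leaf_reflectance(-1, wl), "domain error")
  expect_error(leaf_reflectance(50, c(300, 500)), "domain error")
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generate_scene(small_scene_config(3L))
  b <- generate_scene(small_scene_config(3L))
  expect_identical(a$cube$reflectance, b$cube$reflectance)
  expect_identical(a$truth$points, b$truth$points)
  # and a different seed differs
  c <- generate_scene(small_scene_config(4L))
  expect_false(identical(a$cube$reflectance, c$cube$reflectance))
})

test_that("generated soil and vegetation are NDVI-separable", {
  sc <- small_scene()
  ndvi <- compute_ndvi(sc$cube)
  veg <- sc$truth$vegetation_mask_true
  expect_gt(min(ndvi[veg]), max(ndvi[!veg]))
  expect_gt(min(ndvi[veg]), 0.55)
  expect_lt(max(ndvi[!veg]), 0.3)
})

test_that("ground points match the two-plot study design", {
  sc <- default_scene(42L)
  pts <- sc$truth$points
  expect_equal(nrow(pts), 74L)
  expect_equal(sum(pts$plot == 1), 30L)
  expect_equal(sum(pts$plot == 2), 44L)
  expect_false(anyDuplicated(pts$id) > 0)
  # point SPAD aggregates its footprint-mean chlorophyll (up to meter noise)
  lcc <- sc$truth$lcc_map
  foot <- vapply(seq_len(nrow(pts)), function(i) {
    idx <- extract_roi(dim(lcc), pts[i, ], size = 50,
                       mask = sc$truth$vegetation_mask_true)
    mean(lcc[idx], na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(abs(foot - pts$spad)), 5 * sc$config$spad_noise_sd)
  expect_gt(cor(foot, pts$spad), 0.95)
  # the two growth stages occupy distinct chlorophyll sub-ranges
  expect_lt(mean(pts$spad[pts$plot == 1]), mean(pts$spad[pts$plot == 2]))
})

test_that("soil pixels have undefined chlorophyll and plots split spatially", {
  sc <- small_scene()
  expect_true(all(is.na(sc$truth$lcc_map[!sc$truth$vegetation_mask_true])))
  expect_true(all(is.finite(sc$truth$lcc_map[sc$truth$vegetation_mask_true])))
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(lcc_range = c(70, 45)), "config error")
  expect_error(scene_config(n_points = 1), "config error")
  expect_error(scene_config(noise_sd = -1), "config error")
  expect_error(scene_config(texture_corr = 1.5), "config error")
  expect_error(scene_config(soil_fraction = 1), "config error")
  # too small to host the requested ROIs
  expect_error(generate_scene(scene_config(n_rows = 60, n_cols = 60,
                                           n_points = 10)),
               "configuration error")
})

test_that("brightness field correlation tracks texture_corr", {
  sc <- small_scene()
  veg <- sc$truth$vegetation_mask_true
  r <- cor(as.vector(sc$truth$brightness[veg]), sc$truth$lcc_map[veg])
  expect_equal(r, sc$config$texture_corr, tolerance = 0.12)
})

test_that("uncorrelated brightness leaves PC1 mean texture uninformative", {
  # no-leakage contract: with texture_corr = 0 the ROI-mean MEA of PC1 must
  # not predict point SPAD
  rs <- vapply(1:6, function(s) {
    sc <- generate_scene(small_scene_config(100L + s, texture_corr = 0))
    mask <- sc$truth$vegetation_mask_true
    pca <- pca_transform(sc$cube, mask = mask)
    q <- quantize(pca$pc_images[, , 1], 32, mask = mask)
    mea <- texture_images(q, 32)$MEA
    ft <- roi_feature_means(list(MEA = mea), sc$truth$points, mask = mask)
    cor(ft$MEA, ft$spad)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.3)
})

test_that("laboratory calibration data follow the exponential SPAD link", {
  d <- simulate_lab_calibration(n = 18, a = 3.5, b = 0.05, noise_cv = 0,
                                seed = 2)
  expect_equal(nrow(d), 18L)
  expect_equal(d$lcc_lab, 3.5 * exp(0.05 * d$spad), tolerance = 1e-12)
})
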