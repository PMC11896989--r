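test_that("registry holds the 20 indices split into original and red-edge", {
  reg <- vi_registry()
  expect_equal(nrow(reg), 20L)
  expect_equal(sum(reg$class == "VI_org"), 11L)
  expect_equal(sum(reg$class == "VI_re"), 9L)
  expect_equal(sum(reg$has_red_edge_slot), 9L)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("nearest band resolves targets with lower-index tie-breaking", {
  wl <- seq(350, 1000, length.out = 164)
  i <- nearest_band(wl, wl[50])
  expect_equal(as.integer(i), 50L)
  expect_equal(attr(i, "offset"), 0)
  # 682 nm on the uniform grid: 1-based index 84 (zero-based 83)
  i682 <- nearest_band(wl, 682)
  expect_equal(as.integer(i682), 84L)
  expect_lte(abs(attr(i682, "offset")), (wl[2] - wl[1]) / 2)
  # equidistant target -> lower index
  expect_equal(as.integer(nearest_band(c(400, 500), 450)), 1L)
  expect_error(nearest_band(wl, 1050), "band lookup")
})

test_that("index formulas evaluate their algebraic forms", {
  expect_equal(compute_vi(c(nir = 0.8, red = 0.1), "SR"), 8)
  expect_equal(compute_vi(c(nir = 0.5, re = 0.5, red = 0.1), "MTCI"), 0)
  # soil-adjusted form (1 + 0.16)(N - R)/(N + R + 0.16)
  expect_equal(compute_vi(c(nir = 0.5, red = 0.1), "OSAVI"),
               1.16 * 0.4 / 0.76, tolerance = 1e-12)
  expect_equal(compute_vi(c(nir = 0.8, red = 0.2), "MSR"),
               (0.8 / 0.2 - 1) / sqrt(0.8 / 0.2 + 1))
  expect_equal(compute_vi(c(nir = 0.6, red = 0.1), "MDVI"),
               0.5 / sqrt(0.7))
  expect_equal(compute_vi(c(nir = 0.6, green = 0.15), "CI_green"), 3)
  # division by zero is NaN, not an error
  expect_true(is.nan(compute_vi(c(nir = 0.3, re = 0.3, red = 0.3), "MTCI")))
  expect_error(compute_vi(c(nir = 1), "NOPE"), "valid names")
  expect_error(compute_vi(c(nir = 1), "NDVI"), "slots")
})

test_that("normalized forms are scale-invariant, difference forms linear", {
  b <- c(nir = 0.52, red = 0.08, green = 0.13, blue = 0.06, re = 0.2)
  k <- 3.7
  for (nm in c("NDVI", "mNDVI", "MSR", "SIPI", "MTCI", "SR", "CI_green",
               "NDVI_re", "MSR_re", "mNDVI_re", "CI_re", "SR_re")) {
    expect_equal(compute_vi(k * b, nm), compute_vi(b, nm), tolerance = 1e-12,
                 label = nm)
  }
  for (nm in c("GDVI", "RDVI", "REDVI")) {
    expect_equal(compute_vi(k * b, nm), k * compute_vi(b, nm),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("red-edge variants equal their original forms at the same bands", {
  b <- c(nir = 0.5, red = 0.11, blue = 0.05, re = 0.11)
  pairs <- rbind(c("SR", "SR_re"), c("NDVI", "NDVI_re"),
                 c("MSR", "MSR_re"), c("mNDVI", "mNDVI_re"),
                 c("MDVI", "MDVI_re"), c("OSAVI", "OSAVI_re"))
  for (i in seq_len(nrow(pairs)))
    expect_equal(compute_vi(b, pairs[i, 1]), compute_vi(b, pairs[i, 2]),
                 tolerance = 1e-12, label = paste(pairs[i, ], collapse = "="))
})

test_that("cube evaluation respects the vegetation mask", {
  sc <- small_scene()
  mask <- sc$truth$vegetation_mask_true
  img <- compute_vi(sc$cube, "NDVI", mask = mask)
  expect_true(all(is.na(img[!mask])))
  expect_true(all(is.finite(img[mask])))
  # matches the dedicated NDVI path on vegetation pixels
  expect_equal(img[mask], compute_ndvi(sc$cube)[mask], tolerance = 1e-12)
  # red-edge substitution at the nominal band is an identity
  reg <- vi_registry()
  expect_equal(compute_vi(sc$cube, "MSR_re", red_edge = 710, mask = mask),
               compute_vi(sc$cube, "MSR_re", mask = mask), tolerance = 1e-12)
  expect_error(compute_vi(sc$cube, "NDVI", red_edge = 720), "red-edge slot")
})

test_that("the full feature table has the expected shape", {
  sc <- small_scene()
  sf <- scene_features(sc, "small7")
  ft <- sf$table
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 24L)
  feats <- setdiff(names(ft), c("id", "spad", "plot"))
  expect_length(feats, 44L)  # 20 VIs + 24 texture features
  prov <- attr(ft, "provenance")
  expect_equal(sum(prov == "VI"), 20L)
  expect_equal(sum(startsWith(prov, "TF-")), 24L)
  expect_false(anyNA(ft[feats]))
})
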