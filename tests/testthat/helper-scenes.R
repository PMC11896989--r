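# Scene fixtures are generated in code and memoised across test files
# (helpers are sourced once per test run).

.scene_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, builder(), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

# A 150 x 500 scene with 24 points: same structure as the default study
# conditions, small enough for fast unit tests.
small_scene_config <- function(seed = 7L, ...) {
  scene_config(seed = seed, n_rows = 150L, n_cols = 500L, n_points = 24L, ...)
}

small_scene <- function(seed = 7L) {
  cache_get(paste0("small_", seed),
            function() generate_scene(small_scene_config(seed)))
}

default_scene <- function(seed = 42L) {
  cache_get(paste0("default_", seed),
            function() generate_scene(scene_config(seed = seed)))
}

# Full feature table (20 VIs + 24 TFs) of a scene, memoised.
scene_features <- function(scene, key) {
  cache_get(paste0("feat_", key), function() {
    mask <- scene$truth$vegetation_mask_true
    vimgs <- vi_images(scene$cube, mask = mask)
    pca <- pca_transform(scene$cube, mask = mask)
    tex <- pc_texture_images(pca, mask)
    ft <- roi_feature_means(c(vimgs, tex$images), scene$truth$points,
                            mask = mask,
                            provenance = c(rep("VI", length(vimgs)),
                                           tex$provenance))
    list(table = ft, pca = pca, tex = tex)
  })
}
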