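#' Pipeline configuration
#'
#' One JSON-serializable object holds every tunable of the end-to-end
#' analysis; each run writes the resolved configuration and a log beside its
#' outputs, so results are reproducible from the config alone.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param scene a [scene_config()] (or list of its arguments) for the
#'   simulate stage; `NULL` when working from an existing cube.
#' @param cube_path,points_path input paths used when `scene` is `NULL`.
#' @param ndvi_threshold fixed segmentation threshold(s); `NULL` derives one
#'   from class samples (generator truth when available, NDVI quantile
#'   pseudo-labels otherwise).
#' @param roi_size ROI edge length (50).
#' @param glcm_levels,glcm_window gray levels (32) and window (3).
#' @param screen_threshold_r,screen_threshold_mic strict selection cutoffs
#'   (0.8).
#' @param mic_alpha,mic_c MIC hyperparameters (0.6, 15).
#' @param cv_k,cv_seed cross-validation settings (10, 20240426).
#' @param models model families for the train stage.
#' @param sweep_range red-edge sweep window in nm.
#' @param map_model `"twopair"` (closed-form best combination) or one of the
#'   model families (mapped from its best feature group).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("chlorotex_run_"),
                            scene = scene_config(),
                            cube_path = NULL, points_path = NULL,
                            ndvi_threshold = NULL,
                            roi_size = 50L,
                            glcm_levels = 32L, glcm_window = 3L,
                            screen_threshold_r = 0.8,
                            screen_threshold_mic = 0.8,
                            mic_alpha = 0.6, mic_c = 15,
                            cv_k = 10L, cv_seed = 20240426L,
                            models = mlra_models(),
                            sweep_range = c(702, 742),
                            map_model = "twopair") {
  cfg <- list(out_dir = out_dir, scene = scene, cube_path = cube_path,
              points_path = points_path, ndvi_threshold = ndvi_threshold,
              roi_size = as.integer(roi_size),
              glcm_levels = as.integer(glcm_levels),
              glcm_window = as.integer(glcm_window),
              screen_threshold_r = screen_threshold_r,
              screen_threshold_mic = screen_threshold_mic,
              mic_alpha = mic_alpha, mic_c = mic_c,
              cv_k = as.integer(cv_k), cv_seed = as.integer(cv_seed),
              models = models, sweep_range = sweep_range,
              map_model = map_model)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config` to serialize.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (inherits(x$scene, "scene_config")) x$scene <- unclass(x$scene)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$scene)) x$scene <- do.call(scene_config, x$scene)
  cfg <- do.call(pipeline_config, x[setdiff(names(x), character(0))])
  cfg
}

pipeline_stages <- function() c("simulate", "segment", "features", "screen",
                                "twopair", "train", "sweep", "map")

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

update_manifest <- function(cfg, files, stage) {
  mf <- stage_path(cfg, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::fromJSON(mf) else list()
  for (f in files)
    man[[basename(f)]] <- list(stage = stage,
                               md5 = unname(tools::md5sum(f)))
  jsonlite::write_json(man, mf, auto_unbox = TRUE)
  invisible(man)
}

log_line <- function(cfg, fmt, ...) {
  cat(sprintf(paste0("[%s] ", fmt, "\n"), format(Sys.time(), "%H:%M:%S"), ...),
      file = stage_path(cfg, "run.log"), append = TRUE)
}

need_artifact <- function(cfg, file, producer) {
  p <- stage_path(cfg, file)
  if (!file.exists(p))
    stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                 file, producer), call. = FALSE)
  p
}

load_feature_table <- function(cfg) {
  df <- read.csv(need_artifact(cfg, "feature_table.csv", "features"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  side <- jsonlite::fromJSON(need_artifact(cfg, "feature_sidecar.json",
                                           "features"))
  structure(df, class = c("feature_table", "data.frame"),
            provenance = unlist(side$provenance))
}

#' Run one pipeline stage (or all)
#'
#' Stages communicate through files under `cfg$out_dir` (cube as ENVI,
#' tables as CSV, reports as JSON) and a content-hash manifest, so a rerun
#' with unchanged inputs reproduces identical artifacts and a missing
#' upstream artifact is reported with the stage that builds it.
#'
#' @param stage one of simulate, segment, features, screen, twopair, train,
#'   sweep, map, or `"all"`.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a named list of the stage's main in-memory results.
#' @export
run_stage <- function(stage = c("all", pipeline_stages()), cfg) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(cfg, stage_path(cfg, "config.json"))
  if (stage == "all") {
    out <- lapply(pipeline_stages(), run_stage, cfg = cfg)
    return(invisible(stats::setNames(out, pipeline_stages())))
  }
  t0 <- proc.time()[3]
  out <- switch(stage,
    simulate = {
      if (is.null(cfg$scene))
        stop("config error: simulate stage needs a scene config", call. = FALSE)
      sc <- generate_scene(cfg$scene)
      write_cube(sc$cube, stage_path(cfg, "cube"))
      write_ground_points(sc$truth$points, stage_path(cfg, "ground_points.csv"))
      write_image_tiff(sc$truth$lcc_map, stage_path(cfg, "lcc_truth.tif"))
      write_image_tiff(sc$truth$vegetation_mask_true + 0,
                       stage_path(cfg, "mask_truth.tif"))
      update_manifest(cfg, stage_path(cfg, c("cube.img", "cube.hdr",
                                             "ground_points.csv",
                                             "lcc_truth.tif",
                                             "mask_truth.tif")), stage)
      list(scene = sc)
    },
    segment = {
      cube <- read_cube(cfg$cube_path %||%
                          need_artifact(cfg, "cube.img", "simulate"))
      ndvi <- compute_ndvi(cube)
      thr <- cfg$ndvi_threshold
      if (is.null(thr)) {
        tm <- stage_path(cfg, "mask_truth.tif")
        if (file.exists(tm)) {
          truth <- read_image_tiff(tm) > 0.5
          thr <- with_seed(1L, derive_threshold(
            ndvi, sample(which(truth), min(2000, sum(truth))),
            sample(which(!truth), min(2000, sum(!truth)))))
        } else {
          qs <- quantile(ndvi, c(0.1, 0.9), na.rm = TRUE)
          thr <- derive_threshold(ndvi, which(ndvi >= qs[2]),
                                  which(ndvi <= qs[1]))
        }
      }
      mask <- apply_mask(cube, as.numeric(thr)[1], ndvi = ndvi)
      write_image_tiff(mask + 0, stage_path(cfg, "mask.tif"))
      jsonlite::write_json(
        list(threshold = as.numeric(thr)[1],
             n_vegetation = attr(mask, "n_vegetation"),
             n_soil = attr(mask, "n_soil")),
        stage_path(cfg, "threshold.json"), auto_unbox = TRUE, digits = NA)
      update_manifest(cfg, stage_path(cfg, c("mask.tif", "threshold.json")),
                      stage)
      log_line(cfg, "segment: threshold %.4f, %d vegetation pixels",
               as.numeric(thr)[1], attr(mask, "n_vegetation"))
      list(mask = mask, threshold = thr)
    },
    features = {
      cube <- read_cube(cfg$cube_path %||%
                          need_artifact(cfg, "cube.img", "simulate"))
      mask <- read_image_tiff(need_artifact(cfg, "mask.tif", "segment")) > 0.5
      points <- read_ground_points(
        cfg$points_path %||% need_artifact(cfg, "ground_points.csv",
                                           "simulate"),
        dim = dim(cube)[1:2])
      vimgs <- vi_images(cube, mask = mask)
      pca <- pca_transform(cube, mask = mask)
      tex <- pc_texture_images(pca, mask, levels = cfg$glcm_levels,
                               window = cfg$glcm_window)
      imgs <- c(vimgs, tex$images)
      prov <- c(rep("VI", length(vimgs)), tex$provenance)
      ft <- roi_feature_means(imgs, points, mask = mask, size = cfg$roi_size,
                              provenance = prov)
      write.csv(as.data.frame(ft), stage_path(cfg, "feature_table.csv"),
                row.names = FALSE)
      reg <- vi_registry()
      side <- list(
        provenance = as.list(attr(ft, "provenance")),
        n_vi = length(vimgs), n_tf = length(tex$images),
        n_features = length(imgs),
        dropped_points = attr(ft, "dropped"),
        explained_variance_ratio = pca$explained_variance_ratio[1:3],
        quantization_bounds = tex$bounds,
        vi_bands = stats::setNames(as.list(reg$bands), reg$name))
      jsonlite::write_json(side, stage_path(cfg, "feature_sidecar.json"),
                           auto_unbox = TRUE, digits = NA)
      update_manifest(cfg, stage_path(cfg, c("feature_table.csv",
                                             "feature_sidecar.json")), stage)
      log_line(cfg, "features: %d VI + %d TF = %d columns over %d points",
               length(vimgs), length(tex$images), length(imgs), nrow(ft))
      list(table = ft, pca = pca, bounds = tex$bounds)
    },
    screen = {
      ft <- load_feature_table(cfg)
      sc <- select_features(ft, threshold_r = cfg$screen_threshold_r,
                            threshold_mic = cfg$screen_threshold_mic,
                            alpha = cfg$mic_alpha, c = cfg$mic_c)
      write.csv(as.data.frame(sc), stage_path(cfg, "screening.csv"),
                row.names = FALSE)
      jsonlite::write_json(attr(sc, "selected"),
                           stage_path(cfg, "screening_selected.json"),
                           auto_unbox = TRUE)
      update_manifest(cfg, stage_path(cfg, c("screening.csv",
                                             "screening_selected.json")),
                      stage)
      list(screening = sc)
    },
    twopair = {
      ft <- load_feature_table(cfg)
      res <- twopair_search(ft)
      best <- best_combination(res)
      write.csv(as.data.frame(res), stage_path(cfg, "twopair.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(best), stage_path(cfg, "twopair_best.csv"),
                row.names = FALSE)
      update_manifest(cfg, stage_path(cfg, c("twopair.csv",
                                             "twopair_best.csv")), stage)
      log_line(cfg, "twopair: %d combinations, best %s %s/%s r2 = %.3f",
               nrow(res), best$type[1], best$tf[1], best$vi[1], best$r2[1])
      list(results = res, best = best)
    },
    train = {
      ft <- load_feature_table(cfg)
      sc <- tryCatch({
        df <- read.csv(need_artifact(cfg, "screening.csv", "screen"),
                       stringsAsFactors = FALSE)
        sel <- jsonlite::fromJSON(need_artifact(cfg, "screening_selected.json",
                                                "screen"))
        structure(df, selected = sel)
      }, error = function(e) NULL)
      groups <- feature_groups(ft, screening = sc)
      cv <- mlra_cv(ft, groups, models = cfg$models, k = cfg$cv_k,
                    seed = cfg$cv_seed)
      write.csv(cv$results, stage_path(cfg, "mlra_results.csv"),
                row.names = FALSE)
      preds <- do.call(rbind, lapply(names(cv$fits), function(nm)
        cbind(cell = nm, cv$fits[[nm]]$predictions)))
      write.csv(preds, stage_path(cfg, "mlra_predictions.csv"),
                row.names = FALSE)
      update_manifest(cfg, stage_path(cfg, c("mlra_results.csv",
                                             "mlra_predictions.csv")), stage)
      log_line(cfg, "train: %d model x group cells", nrow(cv$results))
      list(cv = cv, groups = groups)
    },
    sweep = {
      cube <- read_cube(cfg$cube_path %||%
                          need_artifact(cfg, "cube.img", "simulate"))
      mask <- read_image_tiff(need_artifact(cfg, "mask.tif", "segment")) > 0.5
      points <- read_ground_points(
        cfg$points_path %||% need_artifact(cfg, "ground_points.csv",
                                           "simulate"))
      sw <- rededge_sweep(cube, points, mask = mask, range = cfg$sweep_range,
                          roi_size = cfg$roi_size)
      write.csv(as.data.frame(sw), stage_path(cfg, "sweep.csv"),
                row.names = FALSE)
      update_manifest(cfg, stage_path(cfg, "sweep.csv"), stage)
      list(sweep = sw)
    },
    map = {
      cube <- read_cube(cfg$cube_path %||%
                          need_artifact(cfg, "cube.img", "simulate"))
      mask <- read_image_tiff(need_artifact(cfg, "mask.tif", "segment")) > 0.5
      ft <- load_feature_table(cfg)
      best <- read.csv(need_artifact(cfg, "twopair_best.csv", "twopair"),
                       stringsAsFactors = FALSE)
      best <- structure(best, class = c("twopair_best", "data.frame"))
      side <- jsonlite::fromJSON(need_artifact(cfg, "feature_sidecar.json",
                                               "features"))
      pca <- pca_transform(cube, mask = mask)
      qb <- side$quantization_bounds
      bounds <- if (is.matrix(qb)) lapply(seq_len(nrow(qb)), function(i) qb[i, ])
                else lapply(qb, unlist)
      tex <- pc_texture_images(pca, mask, levels = cfg$glcm_levels,
                               window = cfg$glcm_window, bounds = bounds)
      if (identical(cfg$map_model, "twopair")) {
        vi_img <- compute_vi(cube, best$vi[1], mask = mask)
        map <- predict_map(best, vi_img, tex$images[[best$tf[1]]],
                           mask = mask)
        maps <- list(map = map)
      } else {
        groups <- feature_groups(ft)
        grp <- groups[[grep("TFs-PC1", names(groups), value = TRUE)[1]]]
        fit <- mlra_train(cfg$map_model,
                          as.matrix(ft[, grp, drop = FALSE]), ft$spad,
                          seed = cfg$cv_seed, features = grp)
        imgs <- c(vi_images(cube, mask = mask), tex$images)
        maps <- predict_map(fit, imgs, mask = mask)
      }
      write_image_tiff(maps$map, stage_path(cfg, "lcc_map.tif"))
      if (!is.null(maps$sd_map))
        write_image_tiff(maps$sd_map, stage_path(cfg, "lcc_map_sd.tif"))
      update_manifest(cfg, stage_path(cfg, "lcc_map.tif"), stage)
      log_line(cfg, "map: %s model, range %.1f-%.1f SPAD", cfg$map_model,
               min(maps$map, na.rm = TRUE), max(maps$map, na.rm = TRUE))
      maps
    })
  log_line(cfg, "stage %s done in %.1f s", stage, proc.time()[3] - t0)
  invisible(out)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg) run_stage("all", cfg)
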