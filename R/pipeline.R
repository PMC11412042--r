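#' Generate a mixed synthetic tile set for segmenter training
#'
#' Renders scenes cycling over sowing method, growth stage and plant
#' density, with per-scene weed cover drawn uniformly in
#' `weed_cover_range` and stage/density-default occlusion, then tiles them
#' and returns the first `n_tiles` tiles (RGB + mask, no cube).
#'
#' @param n_tiles number of tiles to return.
#' @param tile_px tile side in pixels (scenes are rendered at
#'   `2 * tile_px`, i.e. 4 tiles per scene).
#' @param seed integer seed controlling scene seeds and weed covers.
#' @param library a `spectra_library`.
#' @param weed_cover_range range of per-scene weed cover targets.
#' @return a `tile_set`.
#' @export
synth_tile_set <- function(n_tiles = 500, tile_px = 96, seed = 1,
                           library = make_endmember_library(),
                           weed_cover_range = c(0.08, 0.25)) {
  n_scenes <- ceiling(n_tiles / 4)
  set.seed(as.integer(seed))
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  covers <- stats::runif(n_scenes, weed_cover_range[1], weed_cover_range[2])
  sow <- c("drill", "broadcast")
  stg <- c("wintering", "jointing")
  den <- c("low", "high")
  sets <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    cfg <- scene_config(height_px = 2 * tile_px, width_px = 2 * tile_px,
                        sowing = sow[(i %% 2) + 1],
                        stage = stg[((i %/% 2) %% 2) + 1],
                        density = den[((i %/% 4) %% 2) + 1],
                        weed_cover_target = covers[i],
                        seed = scene_seeds[i])
    sc <- render_scene(cfg, library, include_cube = FALSE)
    sets[[i]] <- tile_scene(sc, tile_size = tile_px,
                            scene_id = sprintf("s%04d", i))
  }
  all <- combine_tilesets(sets)
  all$tiles <- all$tiles[seq_len(n_tiles)]
  all
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles stage toggles, module configurations, the global seed and the
#' output directory. Round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed; every stage derives its seed from it and the
#'   derived seeds are recorded in the run manifest.
#' @param stages character vector among simulate, preprocess, train,
#'   segment, evaluate, biomass, impact (or "all").
#' @param preset segmenter preset, "desk" or "full".
#' @param n_tiles,tile_px training set size and tile side.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param campaign a `campaign_config` for the trial simulation.
#' @param write_cubes also write ENVI cubes for a few scenes during
#'   simulate (off by default; cubes are bulky).
#' @param log_level "info" or "quiet".
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, stages = "all",
                       preset = "desk", n_tiles = 64, tile_px = 96,
                       epochs = 3, batch_size = 8, learning_rate = 1e-3,
                       campaign = campaign_config(), write_cubes = FALSE,
                       log_level = c("info", "quiet")) {
  all_stages <- c("simulate", "preprocess", "train", "segment", "evaluate",
                  "biomass", "impact")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages)) {
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, all_stages), collapse = ", ")))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, preset = preset,
                 n_tiles = as.integer(n_tiles), tile_px = as.integer(tile_px),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, campaign = campaign,
                 write_cubes = isTRUE(write_cubes),
                 log_level = match.arg(log_level)), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  camp <- unclass(lst$campaign)
  # named vectors serialize as YAML maps so their names survive the trip
  for (nm in c("control_yield", "control_dry_weight", "weed_biomass_max")) {
    camp[[nm]] <- as.list(camp[[nm]])
  }
  lst$campaign <- camp
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  camp <- lst$campaign
  lst$campaign <- campaign_config(
    reps = camp$reps, weed_levels = camp$weed_levels,
    noise_sd = camp$noise_sd,
    control_yield = unlist(camp$control_yield),
    control_dry_weight = unlist(camp$control_dry_weight),
    max_reduction_dry_weight = camp$max_reduction_dry_weight,
    max_reduction_yield = camp$max_reduction_yield,
    factor_drill = camp$factor_drill,
    factor_low_density = camp$factor_low_density,
    factor_jointing = camp$factor_jointing,
    weed_biomass_max = unlist(camp$weed_biomass_max))
  do.call(run_config, lst[setdiff(names(lst), character(0))])
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate -> preprocess -> train -> segment -> evaluate;
#' simulate -> biomass; simulate -> impact), writing artifacts under
#' `config$out_dir` and returning a manifest that records inputs, outputs,
#' per-stage seeds, metric summaries and wall-clock times (informational).
#' A stage whose upstream artifact is missing raises an error naming the
#' stage.
#'
#' @param config a `run_config`.
#' @return the manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logi <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  manifest <- list(seed = config$seed, stages = list(),
                   config_yaml = file.path(config$out_dir, "config.yaml"))
  write_run_config(config, manifest$config_yaml)
  art <- new.env(parent = emptyenv())
  need <- function(what, stage) {
    if (is.null(art[[what]])) {
      stop(sprintf("stage '%s' requires upstream stage '%s'", stage,
                   c(tiles = "simulate", splits = "preprocess",
                     trained = "train", plots = "simulate")[[what]]))
    }
    art[[what]]
  }
  tick <- function() proc.time()[["elapsed"]]
  library <- make_endmember_library(seed = config$seed)

  for (stage in config$stages) {
    t0 <- tick()
    info <- list(seed = config$seed + match(stage, config$stages))
    logi("stage %s ...", stage)
    switch(stage,
      simulate = {
        art$tiles <- synth_tile_set(config$n_tiles, config$tile_px,
                                    seed = info$seed, library = library)
        art$plots <- simulate_plot_trials(config$campaign, seed = info$seed)
        plot_csv <- file.path(config$out_dir, "plots.csv")
        utils::write.csv(art$plots, plot_csv, row.names = FALSE)
        info$outputs <- plot_csv
        if (config$write_cubes) {
          sc <- render_scene(scene_config(seed = info$seed), library)
          write_envi_cube(sc$cube, sc$wavelengths_nm,
                          file.path(config$out_dir, "scene0001"))
          write_rgb_png(sc$rgb, file.path(config$out_dir, "scene0001.png"))
          write_mask_png(sc$mask,
                         file.path(config$out_dir, "scene0001_mask.png"))
        }
        info$n_tiles <- length(art$tiles$tiles)
        info$n_plots <- nrow(art$plots)
      },
      preprocess = {
        tiles <- need("tiles", stage)
        art$splits <- split_tiles(tiles, 0.7, seed = info$seed)
        man_csv <- file.path(config$out_dir, "tiles.csv")
        write_tile_manifest(art$splits, man_csv)
        info$outputs <- man_csv
        info$n_train <- length(art$splits$train$tiles)
        info$n_val <- length(art$splits$val$tiles)
      },
      train = {
        splits <- need("splits", stage)
        seg <- build_segmenter(segmenter_config(preset = config$preset,
                                                input_size = config$tile_px,
                                                seed = info$seed))
        art$trained <- train_segmenter(
          seg, splits$train, splits$val,
          train_config(epochs = config$epochs,
                       batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       seed = info$seed))
        ckpt <- file.path(config$out_dir, "segmenter.rds")
        save_segmenter(art$trained, ckpt)
        info$outputs <- ckpt
        info$best_epoch <- art$trained$best_epoch
        info$val_miou <- max(art$trained$history$val_miou)
        info$history <- art$trained$history
      },
      segment = {
        trained <- need("trained", stage)
        splits <- need("splits", stage)
        preds <- lapply(splits$val$tiles, function(tl) {
          infer_mask(trained, tl$rgb)
        })
        art$pred_masks <- preds
        mask_dir <- file.path(config$out_dir, "pred_masks")
        dir.create(mask_dir, showWarnings = FALSE)
        for (i in seq_len(min(4, length(preds)))) {
          write_mask_png(preds[[i]],
                         file.path(mask_dir, sprintf("val%03d.png", i)))
        }
        info$n_predicted <- length(preds)
      },
      evaluate = {
        trained <- need("trained", stage)
        splits <- need("splits", stage)
        preds <- if (!is.null(art$pred_masks)) art$pred_masks else
          lapply(splits$val$tiles, function(tl) infer_mask(trained, tl$rgb))
        tensor <- matrix(0, 3, 3)
        for (i in seq_along(preds)) {
          tensor <- tensor + unclass(
            confusion_counts(preds[[i]], splits$val$tiles[[i]]$mask))
        }
        class(tensor) <- c("confusion_tensor", class(tensor))
        mi <- iou_and_miou(tensor)
        metrics <- list(miou = mi$miou, iou = as.list(mi$iou))
        for (cl in 0:2) {
          prf <- precision_recall_f1(tensor, cl)
          metrics[[c("soil", "wheat", "weed")[cl + 1]]] <- as.list(prf)
        }
        metrics_json <- file.path(config$out_dir, "metrics.json")
        jsonlite::write_json(metrics, metrics_json, auto_unbox = TRUE,
                             digits = NA)
        utils::write.csv(as.data.frame(unclass(tensor)),
                         file.path(config$out_dir, "confusion.csv"))
        info$outputs <- metrics_json
        info$miou <- mi$miou
      },
      biomass = {
        plots <- need("plots", stage)
        feats <- simulate_plot_features(plots, library, seed = info$seed)
        feats_w <- feats[feats$weed_biomass > 0, ]
        fit <- fit_biomass_model(
          feats_w[c("cc_weed", "ndvi", "rvi", "savi", "nb_ndvi")],
          feats_w$weed_biomass, split_seed = info$seed)
        utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                         row.names = FALSE)
        save_biomass_model(fit, file.path(config$out_dir, "biomass_model.rds"))
        sw_sel <- plots$stage == "W" & plots$weed_biomass > 0
        spec <- simulate_mean_spectra(library, "weed", "wintering",
                                      plots$weed_biomass[sw_sel],
                                      bmax = max(plots$weed_biomass[sw_sel]),
                                      seed = info$seed)
        sweep <- band_pair_sweep(spec, plots$weed_biomass[sw_sel],
                                 library$wavelengths_nm)
        write_band_pair_corr(sweep,
                             csv_path = file.path(config$out_dir,
                                                  "band_corr.csv"),
                             png_path = file.path(config$out_dir,
                                                  "band_corr.png"))
        info$modeling_r2 <- fit$modeling$r2
        info$validation_r2 <- fit$validation$r2
        info$best_pair <- as.list(sweep$best_pair)
        info$best_r <- sweep$best_r
      },
      impact = {
        plots <- need("plots", stage)
        for (resp in c("wheat_dry_weight", "grain_yield")) {
          rt <- reductions_vs_control(plots, resp)
          utils::write.csv(rt, file.path(config$out_dir,
                                         paste0("reductions_", resp, ".csv")),
                           row.names = FALSE)
          plot_reductions(rt, file.path(config$out_dir,
                                        paste0("reductions_", resp, ".png")))
          info[[resp]] <- list(
            max_relative = max_reduction(rt, "relative")$value,
            max_absolute = max_reduction(rt, "absolute")$value)
        }
        info$contrasts <- factor_contrasts(
          reductions_vs_control(plots, "wheat_dry_weight"))
      })
    info$wall_clock_s <- round(tick() - t0, 2)
    manifest$stages[[stage]] <- info
    logi("stage %s done in %.1fs", stage, info$wall_clock_s)
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
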