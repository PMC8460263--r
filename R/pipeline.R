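pipeline_stages <- c("simulate", "segment", "quantify", "coloc", "timecourse")

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config[["seed"]])) stop("config must set a seed")
  if (is.null(config[["output_dir"]])) stop("config must set output_dir")
  if (is.null(config[["stages"]])) config[["stages"]] <- pipeline_stages
  k <- length(config[["stages"]])
  if (k == 0 || !identical(as.character(config[["stages"]]), pipeline_stages[1:k])) {
    stop("stages must be a prefix of: ", paste(pipeline_stages, collapse = " > "))
  }
  for (p in config[["input_paths"]]) {
    if (!file.exists(p)) stop("validation error: missing input path: ", p)
  }
  config
}

scene_grid <- function(cfg) {
  sim <- cfg[["simulate"]]
  times <- as.numeric(sim[["time_points"]] %||% c(0.75, 2.5, 4.5, 6.5, 8.5, 16, 22, 30))
  kinds <- as.character(sim[["schedules"]] %||% c("plin3_like", "plin2_like"))
  n_rep <- sim[["scenes_per_point"]] %||% 2L
  expand.grid(kind = kinds, time_hr = times, rep = seq_len(n_rep),
              stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate, segment, quantify, coloc and timecourse as one
#' reproducible run: synthetic two-channel scenes are generated with recorded
#' ground truth, droplets are segmented with a pixel classifier trained on
#' truth-labeled example scenes, rim-expanded compartment means and
#' colocalization coefficients are measured per scene, and windowed
#' regressions with per-genotype normalization summarize the time course.
#' Every output table lands under `output_dir` together with the echoed
#' configuration and a checksum manifest; identical configurations reproduce
#' identical outputs.
#'
#' @param config path to a YAML configuration or an equivalent list. Required
#'   fields: `seed`, `output_dir`; optional: `stages` (a prefix of
#'   simulate > segment > quantify > coloc > timecourse) and one parameter
#'   block per stage.
#' @return Invisibly, the run manifest `data.frame` (file, stage, md5).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg[["output_dir"]]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config_echo.yaml"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()),
                                       paste0(...)))
  }
  artifacts <- list()
  add_artifact <- function(path, stage) {
    artifacts[[length(artifacts) + 1L]] <<- data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }

  # -- simulate ---------------------------------------------------------------
  grid <- scene_grid(cfg)
  sp_args <- cfg[["simulate"]][["scene"]] %||% list()
  scenes <- vector("list", nrow(grid))
  note("simulate: ", nrow(grid), " scenes")
  # droplet numbers decline at late chase times (few, larger droplets remain)
  n0 <- sp_args[["n_droplets"]] %||% 25L
  n_late <- cfg[["simulate"]][["n_droplets_late"]] %||% 8L
  n_at <- function(t) round(n0 - (n0 - n_late) * min(max((t - 10) / 20, 0), 1))
  for (i in seq_len(nrow(grid))) {
    sp <- do.call(scene_params,
                  c(sp_args[setdiff(names(sp_args), "n_droplets")],
                    list(n_droplets = n_at(grid$time_hr[i]),
                         seed = cfg[["seed"]] + 13L * i)))
    scenes[[i]] <- make_droplet_scene(
      sp, protein_schedule(grid$kind[i]), grid$time_hr[i],
      subject_id = sprintf("%s_t%05.2f_r%d", grid$kind[i], grid$time_hr[i],
                           grid$rep[i]))
  }
  truth_df <- do.call(rbind, lapply(scenes, function(s) {
    data.frame(subject_id = s$dye$subject_id,
               genotype_label = s$dye$genotype_label,
               time_hr = s$truth$time_hr,
               n_droplets = length(s$truth$radii),
               true_rim_mean = s$truth$true_rim_mean,
               true_cyto_mean = s$truth$true_cyto_mean,
               seed = s$truth$seed, stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth_df, file.path(out, "scene_truth.csv"),
                   row.names = FALSE)
  add_artifact(file.path(out, "scene_truth.csv"), "simulate")
  if (isTRUE(cfg[["simulate"]][["write_images"]])) {
    img_dir <- file.path(out, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (s in scenes) {
      for (ch in c("dye", "protein")) {
        p <- file.path(img_dir, paste0(s[[ch]]$subject_id, "_", ch, ".tif"))
        write_micrograph(s[[ch]], p)
        add_artifact(p, "simulate")
      }
    }
  }
  if (length(cfg[["stages"]]) == 1L) {
    return(finish_run(out, artifacts, log_lines))
  }

  # -- segment ----------------------------------------------------------------
  seg <- cfg[["segment"]] %||% list()
  n_train <- seg[["n_training_scenes"]] %||% 2L
  n_lab <- seg[["labels_per_class"]] %||% 400L
  train_idx <- unique(round(seq(1, nrow(grid), length.out = n_train)))
  note("segment: training on ", length(train_idx), " scenes")
  banks <- list(); labs <- list()
  fbc <- feature_bank_config()
  for (j in seq_along(train_idx)) {
    s <- scenes[[train_idx[j]]]
    banks[[j]] <- compute_feature_bank(s$dye, fbc)
    labs[[j]] <- local_seed(cfg[["seed"]] + j, {
      lab <- matrix(NA_character_, nrow(s$dye$pixels), ncol(s$dye$pixels))
      dr <- which(s$truth$droplet_mask)
      bg <- which(!s$truth$droplet_mask & s$truth$roi$mask)
      lab[sample(dr, min(n_lab, length(dr)))] <- "droplet"
      lab[sample(bg, min(n_lab, length(bg)))] <- "background"
      lab
    })
  }
  model <- train_pixel_classifier(banks, labs, seed = cfg[["seed"]])
  note(sprintf("segment: hold-out accuracy %.3f", model$holdout_accuracy))
  threshold <- seg[["threshold"]] %||% 0.5
  min_px <- seg[["min_object_px"]] %||% 4L
  seg_results <- lapply(scenes, function(s) {
    segment_image(model, s$dye, threshold = threshold, min_object_px = min_px)
  })
  iou <- vapply(seq_along(scenes), function(i) {
    mask_iou(seg_results[[i]]$droplet_mask, scenes[[i]]$truth$droplet_mask)
  }, numeric(1))
  seg_df <- data.frame(subject_id = truth_df$subject_id,
                       iou_vs_truth = iou,
                       area_fraction = vapply(seq_along(scenes), function(i) {
                         area_fraction(seg_results[[i]]$droplet_mask,
                                       scenes[[i]]$truth$roi)
                       }, numeric(1)),
                       stringsAsFactors = FALSE)
  utils::write.csv(seg_df, file.path(out, "segmentation.csv"),
                   row.names = FALSE)
  add_artifact(file.path(out, "segmentation.csv"), "segment")
  if (length(cfg[["stages"]]) == 2L) {
    return(finish_run(out, artifacts, log_lines))
  }

  # -- quantify ---------------------------------------------------------------
  q <- cfg[["quantify"]] %||% list()
  rp <- rim_params(q[["dilation_px"]] %||% 3L,
                   pixel_size_nm = scenes[[1]]$dye$pixel_size_nm,
                   metric = q[["metric"]] %||% "chebyshev")
  meas <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    rim <- dilate_mask(seg_results[[i]]$droplet_mask, rp)
    compartment_means(scenes[[i]]$protein, rim, scenes[[i]]$truth$roi)
  }))
  if (anyNA(meas$mean_ld)) note("quantify: undefined mean_ld in ",
                                sum(is.na(meas$mean_ld)), " scene(s)")
  utils::write.csv(meas, file.path(out, "measurements.csv"),
                   row.names = FALSE)
  add_artifact(file.path(out, "measurements.csv"), "quantify")
  if (length(cfg[["stages"]]) == 3L) {
    return(finish_run(out, artifacts, log_lines))
  }

  # -- coloc ------------------------------------------------------------------
  coloc <- do.call(rbind, lapply(scenes, function(s) {
    coloc_analysis(s$dye, s$protein, s$truth$roi)
  }))
  if (any(!coloc$converged)) note("coloc: ", sum(!coloc$converged),
                                  " non-converged threshold search(es)")
  utils::write.csv(coloc, file.path(out, "coloc.csv"), row.names = FALSE)
  add_artifact(file.path(out, "coloc.csv"), "coloc")
  if (length(cfg[["stages"]]) == 4L) {
    return(finish_run(out, artifacts, log_lines))
  }

  # -- timecourse -------------------------------------------------------------
  tc <- cfg[["timecourse"]] %||% list()
  early <- as.numeric(tc[["early_window"]] %||% c(0.75, 8.5))
  late <- as.numeric(tc[["late_window"]] %||% c(16, 30))
  norm <- normalize_by_group_mean(meas)
  norm$smooth_ld <- NA_real_
  for (g in unique(norm$genotype_label)) {
    i <- which(norm$genotype_label == g & is.finite(norm$mean_ld))
    if (length(i) >= 5) {
      norm$smooth_ld[i] <- lowess_smooth(norm$time_hr[i], norm$mean_ld[i],
                                         frac = tc[["lowess_frac"]] %||% 0.35)
    }
  }
  utils::write.csv(norm, file.path(out, "normalized.csv"), row.names = FALSE)
  add_artifact(file.path(out, "normalized.csv"), "timecourse")
  fits <- list()
  for (g in unique(meas$genotype_label)) {
    sub <- meas[meas$genotype_label == g, ]
    for (comp in c("mean_ld", "mean_cyto")) {
      for (w in list(early = early, late = late)) {
        fit <- tryCatch(linear_fit(sub$time_hr, sub[[comp]], w),
                        error = function(e) NULL)
        if (is.null(fit)) next
        fits[[length(fits) + 1L]] <- data.frame(
          genotype_label = g, compartment = comp,
          window_start = w[1], window_end = w[2],
          slope = fit$slope, intercept = fit$intercept, r = fit$r,
          n = fit$n, stringsAsFactors = FALSE)
      }
    }
  }
  fits <- do.call(rbind, fits)
  utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
  add_artifact(file.path(out, "fits.csv"), "timecourse")
  finish_run(out, artifacts, log_lines)
}

finish_run <- function(out, artifacts, log_lines) {
  manifest <- do.call(rbind, artifacts)
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(manifest)
}
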