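# Thin orchestration layer tying the modules into the analysis tracks
# (simulate, roi, coloc, rings, rings-trend, attachment-stats), with YAML
# config, seeding, provenance and an output manifest.

#' Run an analysis pipeline from a configuration
#'
#' The configuration (a YAML file path or an equivalent named list) selects
#' a `track` and supplies its parameter block. Every run is deterministic
#' given the config (all randomness flows from `seed`), echoes the resolved
#' parameters into `provenance.json` next to the outputs, and returns a
#' manifest listing every file written with its MD5 hash. On error no
#' partial outputs are left behind (outputs are staged in a temporary
#' directory and moved into place on success).
#'
#' Tracks:
#' * `simulate`: `kind` in `coloc`, `rings`, `attachment`, `profiles`;
#'   writes TIFF/CSV plus a ground-truth JSON.
#' * `roi`: builds the embryo ROI from a Filamin-channel TIFF; writes the
#'   ROI and spot masks as PNG.
#' * `coloc`: end-to-end colocalization over image pairs listed in a CSV
#'   (`sample`, `image_a`, `image_b`, optional `roi`), with control images
#'   for thresholding; writes per-image, per-sample and population CSVs.
#' * `rings`: ring trajectory from a time-lapse TIFF; writes per-frame CSV.
#' * `rings-trend`: trend fit over trajectory CSVs; writes the fitted grid.
#' * `attachment-stats`: gamma GLMM + Wald contrasts from a length table.
#'
#' @param config YAML file path or named list.
#' @return A list of class `pipeline_manifest` with `track`, `out_dir`,
#'   `files` (data.frame of paths and MD5 hashes), invisibly-used
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  tracks <- c("simulate", "roi", "coloc", "rings", "rings-trend", "attachment-stats")
  if (is.null(config$track) || !config$track %in% tracks) {
    stop(sprintf("config field `track` must be one of: %s",
                 paste(tracks, collapse = ", ")))
  }
  if (is.null(config$out_dir)) stop("config field `out_dir` is required")
  seed <- config$seed %||% 1L
  stage <- file.path(tempfile("flico_stage_"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  runner <- switch(config$track,
    "simulate" = pipeline_simulate,
    "roi" = pipeline_roi,
    "coloc" = pipeline_coloc,
    "rings" = pipeline_rings,
    "rings-trend" = pipeline_rings_trend,
    "attachment-stats" = pipeline_attachment)
  runner(config, stage, seed)
  # provenance echoes the resolved parameters; the output location is not a
  # parameter of the computation, so it is left out to keep runs of the same
  # analysis hash-identical
  config_echo <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(list(track = config$track, seed = seed, config = config_echo),
                       file.path(stage, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(stage, full.names = TRUE)
  ok <- file.copy(files, config$out_dir, overwrite = TRUE)
  if (!all(ok)) stop("failed to move outputs into place")
  out_files <- file.path(config$out_dir, basename(files))
  manifest <- data.frame(file = basename(out_files),
                         md5 = as.character(tools::md5sum(out_files)),
                         row.names = NULL)
  structure(list(track = config$track, out_dir = config$out_dir,
                 files = manifest[order(manifest$file), ]),
            class = "pipeline_manifest")
}

pipeline_simulate <- function(config, stage, seed) {
  kind <- config$kind %||% "coloc"
  p <- config$params %||% list()
  if (kind == "coloc") {
    spec <- do.call(coloc_field_spec, c(p, list(seed = seed)))
    field <- gen_coloc_field(spec)
    write_stack(field$channel_a, file.path(stage, "channel_a.tif"))
    write_stack(field$channel_b, file.path(stage, "channel_b.tif"))
    write_stack(gen_control_field(spec, "a"), file.path(stage, "control_a.tif"))
    write_stack(gen_control_field(spec, "b"), file.path(stage, "control_b.tif"))
    write_mask(field$truth$network, file.path(stage, "truth_network.png"))
    write_mask(field$truth$nuclei, file.path(stage, "truth_nuclei.png"))
    write_mask(field$truth$spots, file.path(stage, "truth_spots.png"))
    jsonlite::write_json(list(coloc_fraction = field$truth$coloc_fraction,
                              centers = field$truth$centers,
                              radii = field$truth$radii),
                         file.path(stage, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else if (kind == "rings") {
    spec <- do.call(ring_series_spec, c(p, list(seed = seed)))
    series <- gen_ring_series(spec)
    write_stack(series$stack, file.path(stage, "rings.tif"))
    write_table(series$truth, file.path(stage, "truth_rings.csv"))
  } else if (kind == "attachment") {
    spec <- do.call(attachment_sim_spec, c(p, list(seed = seed)))
    tab <- gen_attachment_table(spec)
    write_table(tab, file.path(stage, "lengths.csv"))
    jsonlite::write_json(attr(tab, "truth"), file.path(stage, "truth_attachment.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (kind == "profiles") {
    sim <- do.call(gen_intensity_series, c(p, list(seed = seed)))
    curves <- lapply(seq_along(sim$signal), function(s) {
      ci <- cortical_intensity(sim$signal[[s]], sim$control[[s]], sample_id = s)
      data.frame(sample = s, time = ci$times, value = ci$values)
    })
    write_table(do.call(rbind, curves), file.path(stage, "cortical_curves.csv"))
    write_table(data.frame(time = seq_along(sim$truth$recruitment_curve),
                           truth = sim$truth$recruitment_curve),
                file.path(stage, "truth_profiles.csv"))
  } else {
    stop(sprintf("unknown simulate kind: %s", kind))
  }
  invisible(NULL)
}

pipeline_roi <- function(config, stage, seed) {
  if (is.null(config$filamin)) stop("roi track needs `filamin` (TIFF path)")
  stk <- suppressWarnings(read_stack(config$filamin))
  filamin <- get_plane(stk)
  channels <- lapply(config$channels %||% list(config$filamin), function(pth) {
    get_plane(suppressWarnings(read_stack(pth)))
  })
  manual <- if (!is.null(config$manual_exclude)) read_mask(config$manual_exclude)
  params <- do.call(roi_params, config$roi_params %||% list())
  res <- build_embryo_roi(filamin, params, spot_channels = channels,
                          manual_exclusion = manual,
                          background_value = config$background_value %||% 0)
  write_mask(res$roi, file.path(stage, "roi.png"))
  for (i in seq_along(res$spot_masks)) {
    write_mask(res$spot_masks[[i]], file.path(stage, sprintf("spots_ch%d.png", i)))
  }
  invisible(NULL)
}

pipeline_coloc <- function(config, stage, seed) {
  if (is.null(config$pairs)) stop("coloc track needs `pairs` (CSV path)")
  pairs <- read_table(config$pairs, c("sample", "image_a", "image_b"))
  ctl_imgs <- function(paths) lapply(paths, function(p) {
    get_plane(suppressWarnings(read_stack(p)))
  })
  t_a <- estimate_threshold(ctl_imgs(config$controls_a))
  t_b <- estimate_threshold(ctl_imgs(config$controls_b))
  per_image <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- get_plane(suppressWarnings(read_stack(pairs$image_a[i])))
    b <- get_plane(suppressWarnings(read_stack(pairs$image_b[i])))
    roi <- if ("roi" %in% names(pairs) && nzchar(pairs$roi[i])) read_mask(pairs$roi[i])
    res <- compute_coloc(channel_pair(a, b, roi, t_a = t_a, t_b = t_b))
    per_image[[i]] <- data.frame(sample = pairs$sample[i], image = i,
                                 m1 = res$m1, m2 = res$m2, tpcc = res$tpcc,
                                 n_a = res$n_a, n_b = res$n_b, n_ab = res$n_ab)
  }
  per_image_df <- do.call(rbind, per_image)
  write_table(per_image_df, file.path(stage, "coloc_per_image.csv"))
  summaries <- lapply(split(seq_len(nrow(pairs)), pairs$sample), function(idx) {
    aggregate_sample(lapply(idx, function(i) {
      r <- per_image_df[i, ]
      structure(list(m1 = r$m1, m2 = r$m2, tpcc = r$tpcc,
                     n_a = r$n_a, n_b = r$n_b, n_ab = r$n_ab),
                class = "coloc_result")
    }), sample_id = pairs$sample[idx[1]])
  })
  write_table(do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample = s$sample_id, m1_w = s$m1_w, m2_w = s$m2_w,
               tpcc_w = s$tpcc_w, n_images = s$n_images)
  })), file.path(stage, "coloc_per_sample.csv"))
  if (length(summaries) >= 2) {
    pops <- lapply(c("m1", "m2", "tpcc"), function(st) {
      pi_ <- population_inference(summaries, st)
      data.frame(statistic = st, mean = pi_$mean, ci_low = pi_$ci_low,
                 ci_high = pi_$ci_high, p = pi_$p, n_samples = pi_$n_samples)
    })
    write_table(do.call(rbind, pops), file.path(stage, "coloc_population.csv"))
  }
  invisible(NULL)
}

pipeline_rings <- function(config, stage, seed) {
  if (is.null(config$stack)) stop("rings track needs `stack` (TIFF path)")
  n_frames <- config$n_frames %||% NULL
  stk <- suppressWarnings(read_stack(config$stack,
    shape = if (!is.null(n_frames)) c(n_frames, 1L, 1L),
    time_interval_s = (config$interval_min %||% 1) * 60))
  tr <- build_trajectory(stk, time_zero_frame = config$time_zero %||% 1L,
                         sample_id = config$sample_id %||% "s1",
                         genotype = config$genotype %||% "wt")
  out <- cbind(tr$frames, sample = tr$sample_id, genotype = tr$genotype,
               included = tr$included)
  write_table(out, file.path(stage, "trajectory.csv"))
  invisible(NULL)
}

pipeline_rings_trend <- function(config, stage, seed) {
  if (is.null(config$trajectories)) stop("rings-trend track needs `trajectories` (CSV paths)")
  dat <- do.call(rbind, lapply(config$trajectories, function(p) {
    read_table(p, c("time_min", "circularity", "sample", "genotype"))
  }))
  names(dat)[names(dat) == "time_min"] <- "time"
  fit <- fit_circularity_trend(dat)
  write_table(fit$curves, file.path(stage, "trend.csv"))
  invisible(NULL)
}

pipeline_attachment <- function(config, stage, seed) {
  if (is.null(config$table)) stop("attachment-stats track needs `table` (CSV path)")
  dat <- read_table(config$table, c("length", "genotype", "sample", "image"))
  fit <- fit_gamma_glmm(dat, reference = config$reference %||% NULL)
  res <- wald_contrasts(fit)
  write_table(res, file.path(stage, "contrasts.csv"))
  write_table(data.frame(coefficient = names(fit$beta), estimate = fit$beta,
                         se = fit$se_beta), file.path(stage, "fixed_effects.csv"))
  invisible(NULL)
}
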