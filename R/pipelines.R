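# End-to-end drivers for the two experiments: real-time oxygen-probe
# monitoring, and the dive (monitoring -> decompression simulation ->
# time-lapse imaging -> trajectory analysis).

#' Run the probe-monitoring pipeline
#'
#' For each configured cell density, runs the virtual probe experiment
#' (replicate simulations with density jitter, sensor-window averaging)
#' and, if `out_dir` is given, writes one series CSV per density
#' (`probe_<density>.csv`: `time_s, mean_ppO2_mmHg, sd_ppO2_mmHg`), a
#' summary CSV, and a provenance sidecar (schema version, config hash,
#' seed).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created), or `NULL` to skip writing.
#' @return Named list of per-density series tibbles, with the summary
#'   tibble as attribute `summary`.
#' @export
run_probe_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  densities <- cfg$densities_cells_per_ml
  if (length(densities) == 0) stop("config lists no cell densities")
  geom <- config_geometry(cfg)
  species <- config_species(cfg)
  mm <- mm_params(cfg$kinetics$V_max, cfg$kinetics$K_m)
  win <- probe_window(geom, radius = cfg$probe$window$radius_m,
                      height = cfg$probe$window$height_m)
  series <- lapply(seq_along(densities), function(i) {
    probe_experiment(geom, species, mm, densities[i], window = win,
                     reps = cfg$probe$reps, jitter = cfg$probe$jitter,
                     duration = cfg$probe$duration_s,
                     sample_dt = cfg$probe$sample_dt_s,
                     dt = cfg$solver$dt_s,
                     seed = cfg$seed + i)
  })
  names(series) <- format(densities, scientific = FALSE, trim = TRUE)
  final <- vapply(series, function(s) s$mean_ppO2_mmHg[nrow(s)], numeric(1))
  summary <- tibble::tibble(
    density_cells_per_ml = densities,
    ppO2_final_mmHg = final,
    ppO2_min_mmHg = vapply(series, function(s) min(s$mean_ppO2_mmHg),
                           numeric(1)),
    n_samples = vapply(series, nrow, integer(1))
  )
  attr(series, "summary") <- summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(series))
      write_csv_plain(series[[nm]],
                      file.path(out_dir, paste0("probe_", nm, ".csv")))
    write_csv_plain(summary, file.path(out_dir, "probe_summary.csv"))
    write_metadata(out_dir, cfg, list(stage = "probe",
                                      units = list(time = "s",
                                                   ppO2 = "mmHg")))
  }
  series
}

#' Run the dive pipeline
#'
#' Chains the full decompression experiment: (1) an 8 h monitoring
#' simulation under well-plate boundary conditions; (2) the dive simulation
#' (compression, hold, decompression) whose initial state is the final
#' monitoring field and whose side and top faces follow the chamber
#' pressure; (3) the mid-plane dissolved-gas tension section just prior to
#' decompression; (4) segmentation, tracking, plateau fits and nucleation
#' counts on the time-lapse stack (a synthetic stack with ground truth is
#' generated when none is supplied).
#'
#' @param cfg A [run_config()].
#' @param stack An `image_stack`, or `NULL` to synthesise one from the
#'   config's `synth` section.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param synth Allow synthesising a stack when `stack` is `NULL`.
#' @return List: `monitoring_final` and `dive_start` (gas fields),
#'   `pre_decompression_map` (non-dimensional mid-plane tension),
#'   `detections`, `tracks`, `trajectories`, `fits`, `counts`,
#'   `stack_truth` (when synthetic).
#' @export
run_dive_pipeline <- function(cfg = run_config(), stack = NULL,
                              out_dir = NULL, synth = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(stack) && !synth)
    stop("no image stack supplied and synthetic generation disabled")
  geom <- config_geometry(cfg)
  species <- config_species(cfg)
  mm <- mm_params(cfg$kinetics$V_max, cfg$kinetics$K_m)
  sigma <- cell_density(cfg$dive$cell_density_cells_per_ml)
  dt <- cfg$solver$dt_s

  monitoring <- simulate_gas(geom, species, mm, sigma,
                             pressure = atm_mmHg(), bc = monitoring_bc(),
                             t_end = cfg$probe$duration_s, dt = dt,
                             snapshot_times = cfg$probe$duration_s)
  final_field <- monitoring[[length(monitoring)]]

  profile <- config_profile(cfg)
  t_pre_decomp <- sum(profile$segments$duration_s[1:2])  # end of hold
  dive <- simulate_gas(geom, species, mm, sigma, pressure = profile,
                       bc = dive_bc(), t_end = profile_duration(profile),
                       dt = dt,
                       snapshot_times = c(0, t_pre_decomp,
                                          profile_duration(profile)),
                       init = final_field)
  pre_map <- midplane_section(dive[[2]], axis = "y")

  if (is.null(stack)) {
    gen <- gen_trajectories(cfg$synth$n_bubbles,
                            rp_median = cfg$synth$rp_median_um,
                            rp_gsd = cfg$synth$rp_gsd,
                            k_median = cfg$synth$k_median_per_s,
                            k_gsd = cfg$synth$k_gsd,
                            noise_sd = 0,
                            seed = cfg$seed + 100L)
    stack <- gen_image_stack(gen$truth,
                             frame_dim = rep(cfg$synth$frame_px, 2),
                             pixel_size = cfg$segmentation$pixel_size_um,
                             psf_sigma = cfg$synth$psf_sigma_px,
                             noise_sd = cfg$synth$image_noise_sd,
                             seed = cfg$seed + 101L)
    stack_truth <- gen$truth
  } else stack_truth <- NULL

  sp <- seg_params(min_radius_px = cfg$segmentation$min_radius_px,
                   min_circularity = cfg$segmentation$min_circularity,
                   min_contrast = cfg$segmentation$min_contrast)
  detections <- segment_stack(stack, sp)
  tracks <- track_bubbles(detections, stack$frame_times,
                          max_disp = cfg$segmentation$max_disp_px)
  trajectories <- to_trajectories(tracks, stack$pixel_size)
  fits <- fit_trajectories(trajectories)
  counts <- count_bubbles(tracks, stack$frame_times)

  out <- list(monitoring_final = final_field, dive_start = dive[[1]],
              pre_decompression_map = pre_map, detections = detections,
              tracks = tracks, trajectories = trajectories, fits = fits,
              counts = counts, stack_truth = stack_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_plain(detections, file.path(out_dir, "detections.csv"))
    write_csv_plain(trajectories, file.path(out_dir, "trajectories.csv"))
    write_csv_plain(fits, file.path(out_dir, "fits.csv"))
    write_csv_plain(counts$counts, file.path(out_dir, "nucleation_counts.csv"))
    utils::write.csv(pre_map, file.path(out_dir, "pre_decompression_map.csv"),
                     row.names = FALSE)
    write_metadata(out_dir, cfg,
                   list(stage = "dive", max_bubble_count = counts$max_count,
                        map_time_s = t_pre_decomp))
  }
  out
}
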