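# Run configuration: a validated, hashable description of a full
# experiment (geometry, gas constants, kinetics, pressure profile, solver
# steps, probe window, segmentation, seeds).

SCHEMA_VERSION <- "1.0"

default_config_list <- function() {
  list(
    geometry = list(radius_m = 5.5e-3, height_m = 5.26e-3, dh_m = 0.17e-3),
    species = list(
      O2 = list(k_h = 1.3e-3, D = 2.5e-9, mole_fraction = 0.21),
      N2 = list(k_h = 7.2e-4, D = 2.0e-9, mole_fraction = 0.79)
    ),
    kinetics = list(V_max = 3e-17, K_m = 5.6),
    densities_cells_per_ml = c(5e3, 5e4, 5e5),
    profile = list(comp_rate_psi_s = 1, max_gauge_psi = 80, hold_s = 1800,
                   decomp_rate_psi_s = 8, pressure_is_gauge = TRUE),
    solver = list(dt_s = 2),
    probe = list(reps = 3, jitter = 0.10, duration_s = 8 * 3600,
                 sample_dt_s = 80,
                 window = list(radius_m = 0.25e-3, height_m = 0.5e-3)),
    dive = list(cell_density_cells_per_ml = 5e4),
    segmentation = list(min_radius_px = 2, min_circularity = 0.7,
                        min_contrast = 0.1, max_disp_px = 10,
                        pixel_size_um = 2),
    synth = list(n_bubbles = 8, rp_median_um = 50, rp_gsd = 1.4,
                 k_median_per_s = 0.02, k_gsd = 1.5, noise_sd = 0.05,
                 frame_px = 256, psf_sigma_px = 1, image_noise_sd = 0.02),
    seed = 1L
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown config key: ", here)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("config key ", here, " must be a section")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build a validated run configuration
#'
#' Starts from the package defaults -- the study parameter set (oxygen
#' D = 2.5e-9 m^2 s^-1, V_max = 3e-17 mol cell^-1 s^-1, K_m = 5.6 mmHg,
#' densities 5e3 / 5e4 / 5e5 cells/ml, the 1 psi/s -> 80 psi -> 30 min ->
#' 8 psi/s profile, dt = 2 s, dh = 0.17 mm) -- and applies overrides.
#' Unknown keys are rejected with the offending path. The returned object
#' carries a content hash so outputs can echo their exact provenance.
#'
#' @param overrides Named list (possibly nested) of overrides, or a path
#'   to a YAML file of the same shape.
#' @return A `run_config` list with attribute `hash`.
#' @examples
#' cfg <- run_config(list(geometry = list(dh_m = 0.34e-3)))
#' attr(cfg, "hash")
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- yaml::read_yaml(overrides)
  cfg <- merge_config(default_config_list(), overrides)
  with(cfg$geometry, stopifnot(radius_m > 0, height_m > 0, dh_m > 0))
  stopifnot(cfg$solver$dt_s > 0, cfg$kinetics$K_m > 0,
            cfg$kinetics$V_max >= 0,
            all(cfg$densities_cells_per_ml >= 0))
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Content hash of a configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialisation.
#' @param cfg A config list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  attributes(cfg)[c("class", "hash")] <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Materialise package objects from a configuration
#'
#' Convenience accessors turning a [run_config()] into the objects the
#' solver consumes: the species list, the phantom geometry and the chamber
#' pressure profile.
#' @param cfg A [run_config()].
#' @return A validated species list, a `phantom_geometry`, or a
#'   `pressure_profile` respectively.
#' @export
config_species <- function(cfg) {
  validate_species(lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    gas_species(nm, k_h = s$k_h, D = s$D, mole_fraction = s$mole_fraction)
  }) |> stats::setNames(names(cfg$species)))
}

#' @rdname config_species
#' @export
config_geometry <- function(cfg) {
  phantom_geometry(radius = cfg$geometry$radius_m,
                   height = cfg$geometry$height_m, dh = cfg$geometry$dh_m)
}

#' @rdname config_species
#' @export
config_profile <- function(cfg) {
  build_dive_profile(cfg$profile$comp_rate_psi_s, cfg$profile$max_gauge_psi,
                     cfg$profile$hold_s, cfg$profile$decomp_rate_psi_s,
                     pressure_is_gauge = cfg$profile$pressure_is_gauge)
}

write_metadata <- function(out_dir, cfg, extra = list()) {
  meta <- c(list(schema_version = SCHEMA_VERSION,
                 config_hash = attr(cfg, "hash"),
                 seed = cfg$seed), extra)
  path <- file.path(out_dir, "metadata.json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

write_csv_plain <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
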