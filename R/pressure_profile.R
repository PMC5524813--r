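# Chamber pressure schedules: compression ramp -> isobaric hold ->
# decompression ramp, defined on a 0.5 s grid in absolute mmHg.

PROFILE_DT <- 0.5       # s, definition grid of the chamber controller
MAX_RATE_PSI_S <- 13    # psi/s, hardware cap on |dP/dt|

new_pressure_profile <- function(times, pressure_mmHg, segments) {
  stopifnot(length(times) == length(pressure_mmHg))
  structure(list(times = times, pressure_mmHg = pressure_mmHg,
                 segments = segments),
            class = "pressure_profile")
}

#' Build a square dive profile
#'
#' Piecewise-linear absolute-pressure schedule: compression from 1 atm to
#' 1 atm + `max_gauge` at `comp_rate`, an isobaric hold, then decompression
#' back to 1 atm at `decomp_rate`, sampled on a 0.5 s grid. `max_gauge` is a
#' gauge pressure (regulator read-out above ambient) unless
#' `pressure_is_gauge = FALSE`, in which case it is absolute and must be
#' >= 1 atm.
#'
#' @param comp_rate Compression rate, psi/s (> 0, <= 13).
#' @param max_gauge Maximum pressure, psi (>= 0; gauge by default).
#' @param hold Hold duration at maximum pressure, s (>= 0).
#' @param decomp_rate Decompression rate, psi/s (> 0, <= 13).
#' @param pressure_is_gauge If `FALSE`, interpret `max_gauge` as absolute psi.
#' @return A `pressure_profile`: `times` (s, 0.5 s grid from 0),
#'   `pressure_mmHg` (absolute), and a `segments` table.
#' @examples
#' prof <- build_dive_profile(1, 80, hold = 1800, decomp_rate = 8)
#' range(prof$times)  # 0 .. 1890
#' @export
build_dive_profile <- function(comp_rate = 1, max_gauge = 80, hold = 1800,
                               decomp_rate = 8, pressure_is_gauge = TRUE) {
  if (comp_rate <= 0 || decomp_rate <= 0) stop("ramp rates must be positive")
  if (comp_rate > MAX_RATE_PSI_S || decomp_rate > MAX_RATE_PSI_S)
    stop(sprintf("requested ramp rate exceeds the %d psi/s hardware cap",
                 MAX_RATE_PSI_S))
  if (max_gauge < 0) stop("max_gauge must be non-negative")
  gauge <- if (pressure_is_gauge) max_gauge else max_gauge - PSI_PER_ATM
  if (gauge < 0) stop("absolute maximum pressure must be at least 1 atm")

  t_comp <- gauge / comp_rate
  t_decomp <- gauge / decomp_rate
  # keep the 0.5 s grid uniform: round the end time up to the next grid point
  # (the trailing fraction of a step sits at ambient pressure)
  t_end <- t_comp + hold + t_decomp
  times <- seq(0, ceiling(t_end / PROFILE_DT) * PROFILE_DT, by = PROFILE_DT)

  p_psi <- ifelse(times <= t_comp, PSI_PER_ATM + comp_rate * times,
           ifelse(times <= t_comp + hold, PSI_PER_ATM + gauge,
                  pmax(PSI_PER_ATM,
                       PSI_PER_ATM + gauge - decomp_rate * (times - t_comp - hold))))
  segments <- tibble::tibble(
    kind = c("ramp", "hold", "ramp"),
    rate_psi_s = c(comp_rate, 0, -decomp_rate),
    duration_s = c(t_comp, hold, t_decomp)
  )
  new_pressure_profile(times, psi_to_mmHg(p_psi), segments)
}

#' Sham-dive profile
#'
#' Control schedule: constant 1 atm for the same total duration as the
#' matched dive profile (identical handling, no pressure change).
#' @param duration Total duration, s; defaults to the duration of the
#'   standard (1, 80, 1800, 8) dive.
#' @return A `pressure_profile` at a constant 760 mmHg.
#' @export
sham_profile <- function(duration = NULL) {
  if (is.null(duration)) {
    ref <- build_dive_profile()
    duration <- profile_duration(ref)
  }
  times <- seq(0, duration, by = PROFILE_DT)
  new_pressure_profile(times, rep(MMHG_PER_ATM, length(times)),
                       tibble::tibble(kind = "hold", rate_psi_s = 0,
                                      duration_s = duration))
}

#' Total duration of a profile
#' @param profile A `pressure_profile`.
#' @return Duration in seconds.
#' @export
profile_duration <- function(profile) {
  stopifnot(inherits(profile, "pressure_profile"))
  profile$times[length(profile$times)]
}

#' Query a pressure profile
#'
#' Linear interpolation on the 0.5 s definition grid; exact at grid points.
#' No extrapolation: `t` must lie within the profile.
#'
#' @param profile A `pressure_profile`.
#' @param t Time(s) in seconds, each in `[0, profile_duration(profile)]`.
#' @return Absolute pressure, mmHg.
#' @export
pressure_at <- function(profile, t) {
  stopifnot(inherits(profile, "pressure_profile"))
  t_end <- profile_duration(profile)
  if (any(t < 0 | t > t_end))
    stop(sprintf("t outside profile range [0, %g] s", t_end))
  stats::approx(profile$times, profile$pressure_mmHg, xout = t,
                method = "linear", ties = "ordered")$y
}

#' Read/write pressure profiles as CSV
#'
#' Two-column CSV `time_s, pressure_mmHg`; the importer checks the 0.5 s
#' grid and the 1 atm floor.
#' @param profile A `pressure_profile`.
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a `pressure_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pressure_profile"))
  utils::write.csv(data.frame(time_s = profile$times,
                              pressure_mmHg = profile$pressure_mmHg),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmHg") %in% names(d)))
    stop("profile CSV needs columns time_s, pressure_mmHg")
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (any(d$pressure_mmHg < MMHG_PER_ATM - 1e-6))
    stop("pressure below 1 atm in profile")
  new_pressure_profile(d$time_s, d$pressure_mmHg, segments = NULL)
}
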