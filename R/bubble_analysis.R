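# Exponential-plateau growth fits, nucleation counting, and density
# regressions for bubble radial trajectories.

#' Robust exponential-plateau fit of a radial trajectory
#'
#' Fits the one-phase association model
#' `R(t) = R_plateau * (1 - exp(-k * (t - t0)))`, with `t0` fixed at the
#' first observation time (the bubble grows from zero radius at first
#' detection), by iteratively reweighted least squares with Tukey bisquare
#' weights (c = 4.685), residual scale from the MAD. The half-life
#' `t_half = ln(2) / k` is the time to reach half the plateau radius.
#'
#' @param times Observation times, s (>= 5 points, strictly increasing).
#' @param radii Radii, um (>= 0).
#' @param max_iter Maximum IRLS iterations (default 200).
#' @param tol Relative parameter tolerance (default 1e-8).
#' @param robust If `FALSE`, a single unweighted least-squares fit
#'   (ordinary nonlinear regression, for comparison).
#' @return A `plateau_fit`: list with `R_plateau` (um), `k` (s^-1),
#'   `t_half` (s, = ln2/k), `converged`, `iterations`, `residual_scale`
#'   (MAD, um) and `weights` (final robustness weights; all 1 when
#'   `robust = FALSE`). Degenerate (constant) trajectories return
#'   `converged = FALSE` with `R_plateau` equal to the constant and
#'   `k = t_half = NA`.
#' @examples
#' t <- imaging_schedule()
#' fit_plateau(t, 10 * (1 - exp(-0.1 * t)))
#' @export
fit_plateau <- function(times, radii, max_iter = 200, tol = 1e-8,
                        robust = TRUE) {
  if (length(times) != length(radii)) stop("times and radii lengths differ")
  if (length(times) < 5) stop("need at least 5 points to fit")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(radii < 0)) stop("radii must be non-negative")
  t0 <- times[1]
  if (length(unique(radii)) < 2) {
    return(structure(list(R_plateau = radii[1], k = NA_real_,
                          t_half = NA_real_, converged = FALSE,
                          iterations = 0L, residual_scale = 0,
                          weights = rep(1, length(times))),
                     class = "plateau_fit"))
  }
  ts <- times - t0
  dat <- data.frame(ts = ts, r = radii)

  # initialisation: plateau from the largest radius, rate from the first
  # crossing of half that value
  rp0 <- max(radii)
  cross <- which(radii >= rp0 / 2 & ts > 0)
  k0 <- if (length(cross) > 0) log(2) / ts[cross[1]] else 1 / max(ts)

  wfit <- function(w) {
    tryCatch(
      minpack.lm::nlsLM(r ~ rp * (1 - exp(-k * ts)), data = dat,
                        start = list(rp = rp0, k = k0), weights = w,
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
  }
  w <- rep(1, nrow(dat))
  fit <- wfit(w)
  if (is.null(fit)) {
    return(structure(list(R_plateau = rp0, k = NA_real_, t_half = NA_real_,
                          converged = FALSE, iterations = 0L,
                          residual_scale = NA_real_, weights = w),
                     class = "plateau_fit"))
  }
  cf <- stats::coef(fit)
  iters <- 0L
  scale <- 0
  if (robust) {
    cc <- 4.685
    for (i in seq_len(max_iter)) {
      iters <- i
      res <- dat$r - cf[["rp"]] * (1 - exp(-cf[["k"]] * dat$ts))
      scale <- stats::mad(res, center = 0)
      if (scale < 1e-10) { w <- rep(1, nrow(dat)); break }  # exact fit
      u <- res / (cc * scale)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w > 0) < 3) break
      fit2 <- wfit(w)
      if (is.null(fit2)) break
      cf2 <- stats::coef(fit2)
      delta <- max(abs(cf2 - cf) / pmax(abs(cf), 1e-12))
      cf <- cf2
      fit <- fit2
      if (delta < tol) break
    }
  }
  structure(list(R_plateau = unname(cf[["rp"]]), k = unname(cf[["k"]]),
                 t_half = log(2) / unname(cf[["k"]]), converged = TRUE,
                 iterations = iters, residual_scale = scale, weights = w),
            class = "plateau_fit")
}

#' Fit every trajectory in a table
#'
#' Applies [fit_plateau()] per track. Trajectories shorter than 5 points
#' are excluded from fitting (but still count for nucleation, which is
#' tallied from tracks, not fits).
#'
#' @param trajectories Tibble `track_id, time_s, radius_um`.
#' @param robust Passed to [fit_plateau()].
#' @return Tibble `track_id, n_points, R_plateau_um, k_per_s, t_half_s,
#'   converged`.
#' @export
fit_trajectories <- function(trajectories, robust = TRUE) {
  ids <- unique(trajectories$track_id)
  rows <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$track_id == id, ]
    tr <- tr[order(tr$time_s), ]
    if (nrow(tr) < 5) {
      return(tibble::tibble(track_id = id, n_points = nrow(tr),
                            R_plateau_um = NA_real_, k_per_s = NA_real_,
                            t_half_s = NA_real_, converged = FALSE))
    }
    f <- fit_plateau(tr$time_s, tr$radius_um, robust = robust)
    tibble::tibble(track_id = id, n_points = nrow(tr),
                   R_plateau_um = f$R_plateau, k_per_s = f$k,
                   t_half_s = f$t_half, converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Bubble counts over time
#'
#' Number of active tracks in each frame (the field-of-view bubble count)
#' and the maximum over frames (the nucleation headline metric).
#'
#' @param tracks Tibble from [track_bubbles()].
#' @param frame_times All frame times, s.
#' @return List with `counts` (tibble `frame, time_s, n_bubbles`) and
#'   `max_count`.
#' @export
count_bubbles <- function(tracks, frame_times) {
  n <- vapply(seq_along(frame_times), function(f) {
    sum(tracks$frame == f)
  }, integer(1))
  list(counts = tibble::tibble(frame = seq_along(frame_times),
                               time_s = frame_times, n_bubbles = n),
       max_count = if (length(n) > 0) max(n) else 0L)
}

#' Regress a growth metric against cell density
#'
#' Ordinary least squares of a per-phantom mean metric (plateau radius,
#' half-life, or max bubble count) on log10(cell density) -- densities span
#' decades -- or on the linear density scale.
#'
#' @param metrics Per-phantom metric values (>= 3).
#' @param densities Matching cell densities, cells/ml (> 0).
#' @param log_density Regress on log10(density) (default) or linear.
#' @return Tibble `slope, intercept, r_squared, p_value, n`; `p_value` is
#'   the two-sided slope test.
#' @export
regress_metric_vs_density <- function(metrics, densities,
                                      log_density = TRUE) {
  if (length(metrics) != length(densities)) stop("length mismatch")
  if (length(metrics) < 3) stop("need at least 3 phantoms")
  if (any(densities <= 0)) stop("densities must be positive")
  x <- if (log_density) log10(densities) else densities
  if (stats::var(x) == 0) stop("zero variance in density")
  fit <- stats::lm(metrics ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(metrics))
}
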