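# Seeded generators for every input the pipeline consumes: bubble radial
# trajectories with ground truth, time-lapse image stacks, and noisy
# dissolved-oxygen probe series. Pure functions of (parameters, seed).

#' Time-lapse imaging schedule
#'
#' Frame times from the start of decompression: 100 frames at 1 s, 50 at
#' 30 s, 12 at 5 min, and a final frame at 2 h (163 frames).
#'
#' @return Numeric vector of frame times, s.
#' @export
imaging_schedule <- function() {
  c(0:99,
    seq(99 + 30, 99 + 50 * 30, by = 30),
    seq(1599 + 300, 1599 + 12 * 300, by = 300),
    7200)
}

#' Generate bubble radial trajectories with ground truth
#'
#' Each bubble grows from zero radius at its birth time along the
#' one-phase-association curve `R_p * (1 - exp(-k * (t - t_birth)))`,
#' sampled on the imaging schedule, with multiplicative Gaussian noise.
#' Default parameter distributions (plateau radius lognormal, median 50 um,
#' geometric sd 1.4; rate lognormal, median 0.02 s^-1, geometric sd 1.5;
#' births uniform over the first 100 s) are invented testing defaults with
#' the statistical shape the analysis assumes -- growth to plateau,
#' staggered nucleation, occasional dissolution -- not estimates of any
#' measured bubble population.
#'
#' @param n Number of bubbles (>= 0).
#' @param rp_median,rp_gsd Plateau radius distribution: median (um) and
#'   geometric sd (> 1 for spread, 1 = degenerate).
#' @param k_median,k_gsd Rate-constant distribution: median (s^-1) and
#'   geometric sd.
#' @param birth_window Births drawn uniformly in `[birth_window[1],
#'   birth_window[2]]` s.
#' @param p_dissolve Probability a bubble dissolves; its death time is drawn
#'   uniformly between birth + 100 s and the schedule end.
#' @param noise_sd Multiplicative noise fraction (>= 0).
#' @param schedule Frame times, s (default [imaging_schedule()]).
#' @param seed Integer seed.
#' @return List with `trajectories` (tibble: `bubble_id, time_s, radius_um,
#'   radius_true_um`) and `truth` (tibble: `bubble_id, R_plateau_um,
#'   k_per_s, birth_s, death_s`, `death_s = Inf` if persistent).
#' @export
gen_trajectories <- function(n, rp_median = 50, rp_gsd = 1.4,
                             k_median = 0.02, k_gsd = 1.5,
                             birth_window = c(0, 100), p_dissolve = 0,
                             noise_sd = 0.05, schedule = imaging_schedule(),
                             seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (rp_median <= 0 || k_median <= 0 || rp_gsd < 1 || k_gsd < 1)
    stop("distribution medians must be positive and geometric sds >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (p_dissolve < 0 || p_dissolve > 1) stop("p_dissolve must be in [0, 1]")
  empty <- list(
    trajectories = tibble::tibble(bubble_id = integer(), time_s = numeric(),
                                  radius_um = numeric(),
                                  radius_true_um = numeric()),
    truth = tibble::tibble(bubble_id = integer(), R_plateau_um = numeric(),
                           k_per_s = numeric(), birth_s = numeric(),
                           death_s = numeric()))
  if (n == 0) return(empty)
  t_last <- schedule[length(schedule)]
  with_local_seed(seed, {
    truth <- tibble::tibble(
      bubble_id = seq_len(n),
      R_plateau_um = stats::rlnorm(n, log(rp_median), log(rp_gsd)),
      k_per_s = stats::rlnorm(n, log(k_median), log(k_gsd)),
      birth_s = stats::runif(n, birth_window[1], birth_window[2])
    )
    dies <- stats::runif(n) < p_dissolve
    truth$death_s <- ifelse(dies,
                            stats::runif(n, pmin(truth$birth_s + 100, t_last),
                                         t_last),
                            Inf)
    rows <- lapply(seq_len(n), function(i) {
      tt <- schedule[schedule >= truth$birth_s[i] &
                       schedule < truth$death_s[i]]
      if (length(tt) == 0) return(NULL)
      r_true <- truth$R_plateau_um[i] *
        (1 - exp(-truth$k_per_s[i] * (tt - truth$birth_s[i])))
      r_obs <- r_true * (1 + stats::rnorm(length(tt), 0, noise_sd))
      tibble::tibble(bubble_id = i, time_s = tt,
                     radius_um = pmax(r_obs, 0), radius_true_um = r_true)
    })
    list(trajectories = do.call(rbind, c(rows, list(empty$trajectories))),
         truth = truth)
  })
}

#' Render a synthetic bubble time-lapse stack
#'
#' Renders each bubble as a dark-rimmed disk (dark annular rim, lighter
#' lumen, light background -- the transmitted-light appearance of a gas
#' bubble in a gel), at the scheduled radius for each frame, optionally
#' blurred by a Gaussian PSF and corrupted with additive Gaussian noise.
#' Bubble centres are placed by rejection sampling so that no two bubbles
#' ever overlap (at their final radii plus a margin).
#'
#' @param truth Ground-truth tibble from [gen_trajectories()].
#' @param frame_dim `c(rows, cols)` in pixels.
#' @param pixel_size Physical pixel size, um/px.
#' @param psf_sigma Gaussian blur sd, px (0 = none).
#' @param noise_sd Additive noise sd on the [0, 1] intensity scale.
#' @param schedule Frame times, s.
#' @param rim_width Rim thickness, px.
#' @param intensities Background / lumen / rim intensities on [0, 1].
#' @param margin Minimum gap between bubble perimeters and to the frame
#'   edge, px.
#' @param seed Integer seed.
#' @return An `image_stack`: list with `frames` (rows x cols x n_frames
#'   array), `frame_times` (s), `pixel_size`, plus `centres_px` (tibble
#'   `bubble_id, row_px, col_px`) and `frame_truth` (tibble `frame, time_s,
#'   bubble_id, row_px, col_px, radius_px`, frames where the bubble exists
#'   and its radius >= 1 px).
#' @export
gen_image_stack <- function(truth, frame_dim = c(256, 256), pixel_size = 2,
                            psf_sigma = 1, noise_sd = 0.02,
                            schedule = imaging_schedule(), rim_width = 2.5,
                            intensities = c(background = 0.85, lumen = 0.55,
                                            rim = 0.15),
                            margin = 6, seed = 1L) {
  n <- nrow(truth)
  with_local_seed(seed, {
    r_final_px <- truth$R_plateau_um / pixel_size
    centres <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        lim <- r_final_px[i] + margin
        if (2 * lim >= min(frame_dim)) break
        cand <- c(stats::runif(1, lim, frame_dim[1] - lim),
                  stats::runif(1, lim, frame_dim[2] - lim))
        if (i == 1 || all(sqrt(rowSums(sweep(centres[seq_len(i - 1), ,
                                                     drop = FALSE],
                                             2, cand)^2)) >
                            r_final_px[seq_len(i - 1)] + r_final_px[i] +
                            margin)) {
          centres[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place non-overlapping bubbles in 1000 attempts")
    }
    nf <- length(schedule)
    frames <- array(intensities[["background"]],
                    dim = c(frame_dim[1], frame_dim[2], nf))
    rr <- matrix(seq_len(frame_dim[1]), frame_dim[1], frame_dim[2])
    cc <- matrix(seq_len(frame_dim[2]), frame_dim[1], frame_dim[2],
                 byrow = TRUE)
    ft <- vector("list", nf)
    for (f in seq_len(nf)) {
      t_f <- schedule[f]
      img <- frames[, , f]
      alive <- which(truth$birth_s <= t_f & t_f < truth$death_s)
      keep <- integer(0); radii <- numeric(0)
      for (i in alive) {
        r_px <- truth$R_plateau_um[i] *
          (1 - exp(-truth$k_per_s[i] * (t_f - truth$birth_s[i]))) / pixel_size
        if (r_px < 1) next
        d <- sqrt((rr - centres[i, 1])^2 + (cc - centres[i, 2])^2)
        img[d <= r_px] <- intensities[["lumen"]]
        img[d <= r_px & d >= r_px - rim_width] <- intensities[["rim"]]
        keep <- c(keep, i); radii <- c(radii, r_px)
      }
      if (psf_sigma > 0)
        img <- as.matrix(EBImage::gblur(EBImage::Image(img), psf_sigma))
      if (noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, noise_sd)
      frames[, , f] <- img
      ft[[f]] <- tibble::tibble(frame = f, time_s = t_f,
                                bubble_id = truth$bubble_id[keep],
                                row_px = centres[keep, 1],
                                col_px = centres[keep, 2],
                                radius_px = radii)
    }
    structure(list(frames = frames, frame_times = schedule,
                   pixel_size = pixel_size,
                   centres_px = tibble::tibble(bubble_id = truth$bubble_id,
                                               row_px = centres[, 1],
                                               col_px = centres[, 2]),
                   frame_truth = do.call(rbind, ft)),
              class = "image_stack")
  })
}

#' Add measurement noise to a simulated probe series
#'
#' Emulates probe read-out noise: seeded additive Gaussian noise on the
#' simulated dissolved-oxygen series.
#'
#' @param series Tibble from [probe_experiment()] (or any tibble with a
#'   `mean_ppO2_mmHg` column).
#' @param noise_sd Noise sd, mmHg (>= 0).
#' @param seed Integer seed.
#' @return The series with an added `noisy_ppO2_mmHg` column.
#' @export
gen_probe_series <- function(series, noise_sd = 2, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  series$noisy_ppO2_mmHg <- with_local_seed(seed, {
    series$mean_ppO2_mmHg + stats::rnorm(nrow(series), 0, noise_sd)
  })
  series
}
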