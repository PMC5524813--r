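test_that("noise-free trajectories are fitted to machine precision", {
  t <- imaging_schedule()
  f <- fit_plateau(t, 10 * (1 - exp(-0.1 * t)))
  expect_true(f$converged)
  expect_equal(f$R_plateau, 10, tolerance = 1e-7)
  expect_equal(f$t_half, log(2) / 0.1, tolerance = 1e-4 / 6.93)
  expect_equal(f$t_half * f$k, log(2))
})

test_that("degenerate constant trajectories are flagged, not fitted", {
  f <- fit_plateau(1:10, rep(7, 10))
  expect_false(f$converged)
  expect_equal(f$R_plateau, 7)
  expect_true(is.na(f$k) && is.na(f$t_half))
  expect_error(fit_plateau(1:4, c(1, 2, 3, 4)), "5 points")
  expect_error(fit_plateau(c(1, 2, 2, 3, 4), c(1, 2, 3, 4, 5)), "increasing")
})

test_that("robust fitting resists gross outliers better than least squares", {
  t <- imaging_schedule()
  r_true <- 50 * (1 - exp(-0.02 * t))
  err_rob <- err_ols <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    r <- r_true * (1 + rnorm(length(t), 0, 0.05))
    out <- sample(seq_along(t), 2)
    r[out] <- r[out] * 3
    err_rob[s] <- abs(fit_plateau(t, r)$R_plateau - 50)
    err_ols[s] <- abs(fit_plateau(t, r, robust = FALSE)$R_plateau - 50)
  }
  expect_lt(median(err_rob), median(err_ols))
  expect_lt(median(err_rob) / 50, 0.05)
})

test_that("fits are equivariant under radius scaling", {
  t <- imaging_schedule()
  set.seed(31)
  r <- 40 * (1 - exp(-0.03 * t)) * (1 + rnorm(length(t), 0, 0.03))
  f1 <- fit_plateau(t, r)
  f2 <- fit_plateau(t, 2.5 * r)
  expect_equal(f2$R_plateau, 2.5 * f1$R_plateau, tolerance = 1e-6)
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-6)
})

test_that("parameter recovery meets the accuracy budget at 5% noise", {
  gen <- gen_trajectories(200, noise_sd = 0.05, seed = 77)
  fits <- merge(fit_trajectories(
    tibble::tibble(track_id = gen$trajectories$bubble_id,
                   time_s = gen$trajectories$time_s,
                   radius_um = gen$trajectories$radius_um)),
    gen$truth, by.x = "track_id", by.y = "bubble_id")
  fits <- fits[fits$converged, ]
  expect_gt(nrow(fits), 190)
  rel_rp <- abs(fits$R_plateau_um.x - fits$R_plateau_um.y) /
    fits$R_plateau_um.y
  rel_th <- abs(fits$t_half_s - log(2) / fits$k_per_s.y) /
    (log(2) / fits$k_per_s.y)
  expect_lt(median(rel_rp), 0.03)
  expect_lt(median(rel_th), 0.05)
  # the identity t_half = ln2 / k holds exactly for every converged fit
  expect_equal(fits$t_half_s * fits$k_per_s.x, rep(log(2), nrow(fits)))
})

test_that("bubble counts reproduce track occupancy", {
  ft <- 0:5
  expect_equal(count_bubbles(tibble::tibble(frame = integer(0)), ft)$max_count,
               0L)
  full <- do.call(rbind, lapply(1:3, function(id)
    tibble::tibble(track_id = id, frame = 1:6)))
  cb <- count_bubbles(full, ft)
  expect_true(all(cb$counts$n_bubbles == 3))
  expect_equal(cb$max_count, 3L)
  staggered <- rbind(tibble::tibble(track_id = 1, frame = 1:6),
                     tibble::tibble(track_id = 2, frame = 3:4))
  expect_equal(count_bubbles(staggered, ft)$counts$n_bubbles,
               c(1L, 1L, 2L, 2L, 1L, 1L))
})

test_that("density regression recovers exact linear structure", {
  dens <- c(5e3, 5e4, 5e5, 5e6)
  metric <- 3 + 2 * log10(dens)
  # exact data: lm warns that the fit is "essentially perfect", as intended
  r <- suppressWarnings(regress_metric_vs_density(metric, dens))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  lin <- suppressWarnings(
    regress_metric_vs_density(1 + 0.5 * dens, dens, log_density = FALSE))
  expect_equal(lin$slope, 0.5)
  expect_error(regress_metric_vs_density(c(1, 2), c(5e3, 5e4)), "3 phantoms")
  expect_error(regress_metric_vs_density(c(1, 2, 3), rep(5e4, 3)),
               "variance")
})

test_that("density-independent metrics are rarely declared significant", {
  dens <- rep(c(5e3, 5e4, 5e5), each = 3)
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    metric <- rnorm(9, 50, 5)
    r <- regress_metric_vs_density(metric, dens)
    if (r$p_value > 0.05) hits <- hits + 1L
    expect_lt(r$r_squared, 1)
  }
  expect_gte(hits, 90)
})
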