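test_that("equilibrium field partitions ambient pressure uniformly", {
  g <- tiny_geometry()
  f <- equilibrium_field(g, default_species(), 760)
  expect_equal(unique(f$pp$O2[g$mask]), 159.6)
  expect_equal(unique(f$pp$N2[g$mask]), 600.4)
  expect_equal(stats::var(f$pp$O2[g$mask]), 0)
  f0 <- equilibrium_field(g, default_species(), 0)
  expect_true(all(f0$pp$O2 == 0) && all(f0$pp$N2 == 0))
})

test_that("a uniform field under sealed no-flux faces is a fixed point", {
  g <- tiny_geometry()
  u <- array(0, g$dims); u[g$mask] <- 159.6
  u2 <- ade_step(u, g, D = 2.5e-9, dt = 2, bc = no_flux_bc(), sink = 0)
  expect_lt(max(abs(u2[g$mask] - 159.6)), 1e-12)
  # and a uniform field matching its Dirichlet boundaries likewise
  bc <- boundary_spec("no_flux", "dirichlet", "dirichlet")
  u3 <- ade_step(u, g, 2.5e-9, 2, bc, boundary_pp = 159.6, sink = 0)
  expect_lt(max(abs(u3[g$mask] - 159.6)), 1e-12)
})

test_that("maximum principle holds without a sink", {
  g <- tiny_geometry()
  bc_all_d <- boundary_spec("dirichlet", "dirichlet", "dirichlet")
  # uniform interior below the boundary value: monotone rise, never past it
  u <- array(0, g$dims); u[g$mask] <- 100
  prev <- u
  for (i in 1:200) {
    u <- ade_step(u, g, 2.5e-9, 2, bc_all_d, boundary_pp = 150, sink = 0)
    expect_true(all(u[g$mask] >= prev[g$mask] - 1e-12))
    expect_true(all(u[g$mask] <= 150 + 1e-9))
    prev <- u
  }
  # random field: values stay inside [min, max] of initial and boundary
  set.seed(11)
  u <- array(0, g$dims); u[g$mask] <- runif(sum(g$mask), 40, 200)
  lo <- min(c(u[g$mask], 150)); hi <- max(c(u[g$mask], 150))
  for (i in 1:200) {
    u <- ade_step(u, g, 2.5e-9, 2, bc_all_d, boundary_pp = 150, sink = 0)
    expect_true(all(u[g$mask] >= lo - 1e-9 & u[g$mask] <= hi + 1e-9))
  }
})

test_that("ADE agrees with a fine-step FTCS brute-force oracle", {
  set.seed(2)
  g <- phantom_geometry(radius = 6e-4, height = 1e-3, dh = 2e-4)
  expect_lte(prod(g$dims), 1000)
  u0 <- array(0, g$dims); u0[g$mask] <- runif(sum(g$mask), 0, 100)
  for (bc in list(no_flux_bc(),
                  boundary_spec("no_flux", "dirichlet", "dirichlet"))) {
    ua <- u0
    for (i in 1:50) ua <- ade_step(ua, g, 2.5e-9, 2, bc, boundary_pp = 50)
    uf <- u0
    for (i in 1:5000)
      uf <- ftcs_reference_step(uf, g, 2.5e-9, 0.02, bc, boundary_pp = 50)
    rng <- diff(range(u0[g$mask]))
    expect_lt(max(abs(ua[g$mask] - uf[g$mask])) / rng, 0.005)
  }
})

test_that("sealed-phantom mass drift vanishes quadratically with the step", {
  g <- tiny_geometry()
  co <- expand.grid(x = g$x, y = g$y, z = g$z)
  mk <- function() {
    u <- array(100 * (1 + 0.3 * cos(pi * co$z / (2 * g$height)) *
                        (1 + 0.5 * sin(pi * (co$x + 0.3 * co$y) / g$radius))),
               g$dims)
    u[!g$mask] <- 0
    u
  }
  drift <- vapply(c(2, 0.5, 0.125), function(dt) {
    u <- mk(); s0 <- sum(u[g$mask]); worst <- 0
    for (i in 1:250) {
      u <- ade_step(u, g, 2.5e-9, dt, no_flux_bc(), sink = 0)
      worst <- max(worst, abs(sum(u[g$mask]) - s0) / s0)
    }
    worst
  }, numeric(1))
  # second-order decay in dt (4x step refinement -> ~16x less drift)
  expect_lt(drift[2], drift[1] / 8)
  expect_lt(drift[3], drift[2] / 8)
  # and in the resolved regime the budget closes to 1e-6
  expect_lt(drift[3], 1e-6)
})

test_that("1D column with zero-order sink reaches the parabolic profile", {
  g <- column_geometry(n = 50, dh = 1e-4)
  q <- 0.01                        # mmHg/s, pp >> K_m so the sink saturates
  mm <- mm_params(V_max = 3e-17, K_m = 1e-6)
  sig_ml <- q * 1.3e-3 / 3e-17 / 1e6
  bc <- boundary_spec("no_flux", "no_flux", "dirichlet")
  snaps <- simulate_gas(g, single_o2(), mm, cell_density(sig_ml),
                        pressure = 159.6, bc = bc, t_end = 6e4, dt = 2,
                        snapshot_times = 6e4)
  u <- snaps[[1]]$pp$O2[1, 1, ]
  s <- g$z                         # distance from the base
  closed <- 159.6 - q / (2 * 2.5e-9) * (g$height^2 - s^2)
  expect_lt(max(abs(u - closed) / closed), 0.01)
})

test_that("simulate_gas honours degenerate and loading scenarios", {
  g <- tiny_geometry()
  sp <- default_species(); mm <- mm_params()
  # no cells, fixed ambient, equilibrium start: nothing moves
  snaps <- simulate_gas(g, sp, mm, cell_density(0), pressure = 760,
                        bc = monitoring_bc(), t_end = 400, dt = 2,
                        snapshot_times = c(0, 200, 400))
  for (s in snaps) {
    expect_equal(s$pp$O2[g$mask], rep(159.6, sum(g$mask)), tolerance = 1e-12)
    expect_equal(s$pp$N2[g$mask], rep(600.4, sum(g$mask)), tolerance = 1e-12)
  }
  # compression loads gas: total tension at end of hold exceeds the start
  prof <- build_dive_profile(1, 80, hold = 1800, decomp_rate = 8)
  dive <- simulate_gas(g, sp, mm, cell_density(0), pressure = prof,
                       bc = dive_bc(), t_end = 1890, dt = 2,
                       snapshot_times = c(0, 1880))
  tension <- function(f) mean((f$pp$O2 + f$pp$N2)[g$mask])
  expect_gt(tension(dive[[2]]), tension(dive[[1]]))
  expect_error(simulate_gas(g, sp, mm, cell_density(0), 760,
                            monitoring_bc(), t_end = 100, dt = 2,
                            snapshot_times = 200), "snapshot")
  expect_error(simulate_gas(g, sp, mm, cell_density(0), prof,
                            monitoring_bc(), t_end = 1e5, dt = 2),
               "duration")
})

test_that("ade_step rejects invalid input", {
  g <- tiny_geometry()
  u <- array(0, g$dims); u[g$mask][1] <- NaN
  expect_error(ade_step(u, g, 2.5e-9, 2, no_flux_bc()), "non-finite")
  u <- array(0, g$dims)
  expect_error(ade_step(u, g, 2.5e-9, 2, no_flux_bc(), sink = -1),
               "non-negative")
  expect_error(ade_step(u, g, 2.5e-9, 0, no_flux_bc()), "dt")
})

test_that("virtual probe behaves deterministically and tracks cell density", {
  g <- tiny_geometry()
  sp <- default_species(); mm <- mm_params()
  # acellular: flat at air saturation with zero dispersion
  s0 <- probe_experiment(g, sp, mm, sigma_nominal = 0, reps = 3,
                         duration = 1600, sample_dt = 80, seed = 5)
  expect_equal(nrow(s0), 21)
  expect_equal(unique(round(s0$mean_ppO2_mmHg, 9)), 159.6)
  expect_equal(unique(s0$sd_ppO2_mmHg), 0)
  # zero jitter: replicate series are identical
  s1 <- probe_experiment(g, sp, mm, 5e5, reps = 3, jitter = 0,
                         duration = 1600, sample_dt = 80, seed = 5)
  expect_equal(unique(s1$sd_ppO2_mmHg), 0)
  # same seed reproduces; different seed perturbs
  s2a <- probe_experiment(g, sp, mm, 5e5, reps = 2, duration = 800,
                          sample_dt = 80, seed = 7)
  s2b <- probe_experiment(g, sp, mm, 5e5, reps = 2, duration = 800,
                          sample_dt = 80, seed = 7)
  expect_identical(s2a$mean_ppO2_mmHg, s2b$mean_ppO2_mmHg)
  # window DO is non-increasing in cell density at any fixed time
  series <- lapply(c(5e3, 5e4, 5e5), function(d)
    probe_experiment(g, sp, mm, d, reps = 1, jitter = 0,
                     duration = 7200, sample_dt = 400, seed = 1))
  late <- vapply(series, function(s) s$mean_ppO2_mmHg[nrow(s)], numeric(1))
  expect_true(all(diff(late) < 0))
  for (i in 1:2)
    expect_true(all(series[[i + 1]]$mean_ppO2_mmHg <=
                      series[[i]]$mean_ppO2_mmHg + 1e-9))
})

test_that("probe window selection stays inside the phantom", {
  g <- tiny_geometry()
  w <- probe_window(g)
  expect_true(all(g$mask[w$voxels]))
  expect_error(probe_window(g, centre = c(5e-3, 0, 5e-4)), "outside")
})

test_that("mid-plane sections report non-dimensional tension", {
  g <- tiny_geometry()
  f <- equilibrium_field(g, default_species(), 760)
  m <- midplane_section(f, axis = "y")
  expect_equal(unique(m[!is.na(m)]), 1)
  mz <- midplane_section(f, axis = "z")
  expect_equal(unique(mz[!is.na(mz)]), 1)
  f0 <- equilibrium_field(g, default_species(), 0)
  m0 <- midplane_section(f0)
  expect_true(all(m0[!is.na(m0)] == 0))
})
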