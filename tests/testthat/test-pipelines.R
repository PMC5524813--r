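test_that("run configurations validate, merge and hash", {
  cfg <- run_config()
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$kinetics$V_max, 3e-17)
  expect_equal(cfg$kinetics$K_m, 5.6)
  expect_equal(cfg$densities_cells_per_ml, c(5e3, 5e4, 5e5))
  expect_match(attr(cfg, "hash"), "^[0-9a-f]{32}$")

  over <- run_config(list(geometry = list(dh_m = 0.34e-3), seed = 9L))
  expect_equal(over$geometry$dh_m, 0.34e-3)
  expect_equal(over$geometry$radius_m, 5.5e-3)   # untouched defaults remain
  expect_false(attr(over, "hash") == attr(cfg, "hash"))
  expect_identical(attr(run_config(), "hash"), attr(cfg, "hash"))

  expect_error(run_config(list(geometrie = list(dh_m = 1))), "geometrie")
  expect_error(run_config(list(solver = list(dx = 1))), "solver.dx")
  expect_error(run_config(list(solver = list(dt_s = -1))), "dt_s")
})

test_that("configs load from YAML files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  dh_m: 0.00034", "seed: 4"), path)
  cfg <- run_config(path)
  expect_equal(cfg$geometry$dh_m, 3.4e-4)
  expect_equal(cfg$seed, 4L)
})

test_that("probe pipeline emits one full series per density, reproducibly", {
  cfg <- run_config(list(geometry = list(dh_m = 1.1e-3),
                         densities_cells_per_ml = c(5e3, 5e5)))
  out1 <- withr::local_tempdir()
  series <- run_probe_pipeline(cfg, out_dir = out1)
  expect_length(series, 2)
  # 8 h sampled every 80 s -> 361 samples
  expect_true(all(vapply(series, nrow, integer(1)) == 361))
  smry <- attr(series, "summary")
  expect_lt(smry$ppO2_final_mmHg[2], smry$ppO2_final_mmHg[1])
  expect_true(file.exists(file.path(out1, "probe_5000.csv")))
  expect_true(file.exists(file.path(out1, "metadata.json")))
  meta <- jsonlite::read_json(file.path(out1, "metadata.json"))
  expect_equal(meta$config_hash, unname(attr(cfg, "hash")))

  # bit-identical rerun with the same config and seed
  out2 <- withr::local_tempdir()
  run_probe_pipeline(cfg, out_dir = out2)
  for (f in c("probe_5000.csv", "probe_500000.csv", "probe_summary.csv"))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))

  expect_error(run_probe_pipeline(
    run_config(list(densities_cells_per_ml = numeric(0)))), "densities")
})

test_that("dive pipeline chains fields and recovers synthetic bubbles", {
  cfg <- run_config(list(geometry = list(dh_m = 1.1e-3),
                         probe = list(duration_s = 1200),
                         synth = list(n_bubbles = 4, frame_px = 220)))
  res <- run_dive_pipeline(cfg)
  # the dive's initial state is exactly the final monitoring state
  expect_identical(res$dive_start$pp, res$monitoring_final$pp)
  # gas has loaded by the end of the hold: tension above ambient everywhere
  m <- res$pre_decompression_map
  expect_gt(min(m, na.rm = TRUE), 1)
  # the section shows the inward gradient: boundary-adjacent exceeds core
  edge <- max(m[1, !is.na(m[1, ])])
  core <- m[ceiling(nrow(m) / 2), ceiling(ncol(m) / 2)]
  expect_gt(edge, core)
  # every synthetic bubble is recovered as one track with a sane fit
  expect_equal(length(unique(res$tracks$track_id)), nrow(res$stack_truth))
  expect_equal(res$counts$max_count, nrow(res$stack_truth))
  conv <- res$fits[res$fits$converged, ]
  expect_equal(nrow(conv), nrow(res$stack_truth))
  expect_error(run_dive_pipeline(cfg, stack = NULL, synth = FALSE),
               "stack")
})

test_that("an acellular sham exposure leaves unit tension everywhere", {
  g <- phantom_geometry(dh = 1.1e-3)
  sp <- default_species()
  sham <- sham_profile(600)
  snaps <- simulate_gas(g, sp, mm_params(), cell_density(0),
                        pressure = sham, bc = dive_bc(), t_end = 600,
                        dt = 2, snapshot_times = 600)
  m <- midplane_section(snaps[[1]])
  expect_lt(max(abs(m[!is.na(m)] - 1)), 1e-9)
})
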