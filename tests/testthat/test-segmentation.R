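test_that("well-separated disks are recovered with sub-pixel accuracy", {
  centres <- list(c(50, 45), c(60, 150), c(160, 85))
  radii <- c(12, 8, 20)
  frame <- disk_frame(centres, radii)
  det <- segment_frame(frame)
  expect_equal(nrow(det), 3)
  for (i in 1:3) {
    d <- sqrt((det$row_px - centres[[i]][1])^2 +
                (det$col_px - centres[[i]][2])^2)
    j <- which.min(d)
    expect_lt(d[j], 1)
    expect_lt(abs(det$radius_px[j] - radii[i]), 0.5)
    expect_false(det$low_circularity[j])
  }
})

test_that("noise-only frames yield no detections", {
  set.seed(21)
  blank <- matrix(0.85 + rnorm(200 * 200, 0, 0.02), 200, 200)
  expect_equal(nrow(segment_frame(blank)), 0)
  flat <- matrix(0.85, 50, 50)
  expect_equal(nrow(segment_frame(flat)), 0)
  expect_error(segment_frame(matrix(NA_real_, 5, 5)), "finite")
})

test_that("partially merged bubbles give one flagged detection", {
  # dumbbell: centres 1.8 R apart, a single elongated component
  frame <- disk_frame(list(c(60, 46), c(60, 73)), c(15, 15),
                      dim = c(120, 120))
  det <- segment_frame(frame)
  expect_equal(nrow(det), 1)
  expect_true(det$low_circularity)
  expect_lt(det$circularity, 0.7)
  # the default policy keeps the merged blob; the strict policy drops it
  strict <- segment_frame(frame, seg_params(drop_low_circularity = TRUE))
  expect_equal(nrow(strict), 0)
})

test_that("detection count is monotone under a stricter circularity filter", {
  frame <- disk_frame(list(c(50, 45), c(60, 150), c(160, 85), c(60, 73)),
                      c(12, 8, 20, 12))
  counts <- vapply(c(0, 0.5, 0.7, 0.9, 0.99), function(mc) {
    nrow(segment_frame(frame, seg_params(min_circularity = mc,
                                         drop_low_circularity = TRUE)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic", {
  truth <- gen_trajectories(4, noise_sd = 0, schedule = c(0, 30, 300),
                            seed = 3)$truth
  st <- gen_image_stack(truth, schedule = c(0, 30, 300), seed = 3)
  d1 <- segment_stack(st)
  d2 <- segment_stack(st)
  expect_identical(d1, d2)
})

test_that("stationary objects form one full-length track each", {
  det <- do.call(rbind, lapply(1:4, function(f)
    tibble::tibble(frame = f, row_px = c(10, 40, 80), col_px = c(10, 40, 15),
                   radius_px = 5)))
  tr <- track_bubbles(det, frame_times = c(0, 1, 2, 3), max_disp = 10)
  expect_equal(length(unique(tr$track_id)), 3)
  expect_true(all(table(tr$track_id) == 4))
  # one detection per track per frame
  expect_equal(max(table(tr$track_id, tr$frame)), 1)
})

test_that("a jump beyond max_disp terminates the track and starts another", {
  det <- rbind(
    tibble::tibble(frame = 1, row_px = 20, col_px = 20, radius_px = 5),
    tibble::tibble(frame = 2, row_px = 21, col_px = 20, radius_px = 5),
    tibble::tibble(frame = 3, row_px = 60, col_px = 60, radius_px = 5)
  )
  tr <- track_bubbles(det, frame_times = 0:2, max_disp = 10)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(tr$track_id[tr$frame == 3], 2)
  expect_error(track_bubbles(det, 0:2, max_disp = 0), "positive")
})

test_that("track count matches ground truth for staggered births and deaths", {
  gen <- gen_trajectories(6, noise_sd = 0, p_dissolve = 0.5, seed = 9)
  sched <- imaging_schedule()[seq(1, 163, by = 8)]
  gen <- gen_trajectories(6, noise_sd = 0, p_dissolve = 0.5,
                          schedule = sched, seed = 9)
  st <- gen_image_stack(gen$truth, frame_dim = c(300, 300), schedule = sched,
                        psf_sigma = 0, noise_sd = 0, seed = 9)
  det <- segment_stack(st)
  tr <- track_bubbles(det, st$frame_times, max_disp = 10)
  # every ground-truth bubble that ever reaches detectable size is one track
  detectable <- unique(st$frame_truth$bubble_id[st$frame_truth$radius_px >=
                                                  2.5])
  expect_equal(length(unique(tr$track_id)), length(detectable))
})

test_that("trajectory conversion scales radii by the pixel size", {
  tracks <- tibble::tibble(track_id = 1L, frame = 1:3, time_s = c(0, 1, 2),
                           row_px = 5, col_px = 5, radius_px = c(4, 10, 12))
  expect_equal(to_trajectories(tracks, 1)$radius_um, c(4, 10, 12))
  expect_equal(to_trajectories(tracks, 2.5)$radius_um, c(10, 25, 30))
  expect_error(to_trajectories(tracks, 0), "positive")
})

test_that("round-trip radii land within a pixel of the generator truth", {
  sched <- imaging_schedule()[seq(1, 163, by = 10)]
  gen <- gen_trajectories(5, noise_sd = 0, schedule = sched, seed = 13)
  st <- gen_image_stack(gen$truth, frame_dim = c(300, 300), schedule = sched,
                        seed = 13)
  det <- segment_stack(st)
  m <- match_detections(det, st$frame_truth)
  expect_equal(m$miss, 0)
  expect_equal(m$false_pos, 0)
  expect_lt(sqrt(mean(m$radius_err^2)), 1)
  # physical-unit trajectories carry the same error bound
  tr <- track_bubbles(det, st$frame_times, max_disp = 10)
  traj <- to_trajectories(tr, st$pixel_size)
  expect_lt(sqrt(mean(m$radius_err^2)) * st$pixel_size, 1 * st$pixel_size)
  expect_true(all(traj$radius_um > 0))
})
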