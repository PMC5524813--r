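# Shared fixtures: tiny phantoms, single-species sets, synthetic disk frames.

tiny_geometry <- function(dh = 0.2e-3, radius = 1e-3, height = 1e-3) {
  phantom_geometry(radius = radius, height = height, dh = dh)
}

# Single-species column for 1D analytical comparisons (mole fraction 1 so a
# total pressure maps straight onto the species partial pressure).
column_geometry <- function(n = 50, dh = 1e-4) {
  phantom_geometry(radius = 0.4 * dh, height = n * dh, dh = dh)
}

single_o2 <- function(D = 2.5e-9, k_h = 1.3e-3) {
  list(O2 = gas_species("O2", k_h = k_h, D = D, mole_fraction = 1))
}

no_flux_bc <- function() boundary_spec("no_flux", "no_flux", "no_flux")

# Frame with dark-rimmed disks on a light background, the bubble appearance
# the detector is designed for.
disk_frame <- function(centres, radii, dim = c(200, 200), rim = 2.5,
                       background = 0.85, lumen = 0.55, rim_int = 0.15) {
  img <- matrix(background, dim[1], dim[2])
  rr <- row(img); cc <- col(img)
  for (i in seq_along(radii)) {
    d <- sqrt((rr - centres[[i]][1])^2 + (cc - centres[[i]][2])^2)
    img[d <= radii[i]] <- lumen
    img[d <= radii[i] & d >= radii[i] - rim] <- rim_int
  }
  img
}

# Match detections to per-frame rendered ground truth by centre distance.
# Returns per-frame counts of unambiguous misses/false positives and the
# matched radius errors; truth bubbles below `clear_px` are ambiguous for a
# detector with a 2 px radius floor and are excluded from the miss count.
match_detections <- function(detections, frame_truth, clear_px = 2.5,
                             match_dist = 3) {
  frames <- sort(unique(frame_truth$frame))
  miss <- 0L; false_pos <- 0L; err <- numeric(0)
  for (f in frames) {
    tr <- frame_truth[frame_truth$frame == f, ]
    de <- detections[detections$frame == f, ]
    if (nrow(tr) == 0) { false_pos <- false_pos + nrow(de); next }
    for (j in seq_len(nrow(de))) {
      d <- sqrt((tr$row_px - de$row_px[j])^2 + (tr$col_px - de$col_px[j])^2)
      if (min(d) > match_dist) false_pos <- false_pos + 1L
      else err <- c(err, de$radius_px[j] - tr$radius_px[which.min(d)])
    }
    clear <- tr[tr$radius_px >= clear_px, ]
    for (j in seq_len(nrow(clear))) {
      d <- sqrt((clear$row_px[j] - de$row_px)^2 +
                  (clear$col_px[j] - de$col_px)^2)
      if (length(d) == 0 || min(d) > match_dist) miss <- miss + 1L
    }
  }
  list(miss = miss, false_pos = false_pos, radius_err = err)
}
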