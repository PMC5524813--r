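# Bubble detection and tracking in time-lapse frames. Bubbles image as
# high-contrast rimmed circles; the detector is:
#   background subtraction (median of the first 3 frames) -> intensity
#   normalisation -> gradient-magnitude thresholding (Otsu) -> hole filling
#   -> 1 px erosion (compensates the outward spread of the centred gradient)
#   -> connected components -> circularity filter -> equivalent-disk radius.

#' Segmentation parameters
#'
#' @param min_radius_px Minimum detection radius, px.
#' @param min_circularity Circularity threshold (4*pi*A/P^2); components
#'   below it are kept but flagged `low_circularity` (merged/overlapping
#'   bubbles), or dropped when `drop_low_circularity = TRUE`.
#' @param min_contrast Minimum mean background-subtracted darkening of a
#'   component, in raw intensity units; rejects blobs that thresholding
#'   carves out of pure noise.
#' @param drop_low_circularity Drop rather than flag low-circularity
#'   components.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_radius_px = 2, min_circularity = 0.7,
                       min_contrast = 0.1, drop_low_circularity = FALSE) {
  stopifnot(min_radius_px >= 0, min_circularity >= 0, min_circularity <= 1)
  structure(list(min_radius_px = min_radius_px,
                 min_circularity = min_circularity,
                 min_contrast = min_contrast,
                 drop_low_circularity = drop_low_circularity),
            class = "seg_params")
}

#' Background estimate for a stack
#'
#' Pixelwise median of the first `n` frames (bubbles are absent or tiny at
#' the start of decompression, so early frames approximate the empty field).
#' @param stack An `image_stack` (or plain rows x cols x frames array).
#' @param n Frames to median over (default 3).
#' @return Background matrix.
#' @export
stack_background <- function(stack, n = 3) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  n <- min(n, dim(frames)[3])
  apply(frames[, , seq_len(n), drop = FALSE], c(1, 2), stats::median)
}

#' Detect bubbles in one frame
#'
#' @param frame Grayscale matrix (finite values).
#' @param params A [seg_params()].
#' @param background Background matrix (same shape) to subtract; `NULL`
#'   uses the frame's own median (adequate for sparse bubbles).
#' @return Tibble of detections: `row_px, col_px, radius_px, area_px,
#'   circularity, low_circularity`, ordered by `row_px` then `col_px`.
#'   Deterministic for fixed inputs.
#' @export
segment_frame <- function(frame, params = seg_params(), background = NULL) {
  if (!is.matrix(frame) || length(frame) == 0) stop("frame must be a matrix")
  if (!all(is.finite(frame))) stop("frame contains non-finite values")
  empty <- tibble::tibble(row_px = numeric(), col_px = numeric(),
                          radius_px = numeric(), area_px = numeric(),
                          circularity = numeric(), low_circularity = logical())
  if (is.null(background))
    background <- matrix(stats::median(frame), nrow(frame), ncol(frame))
  # bubbles are darker than background: positive contrast image
  diffimg <- background - frame
  rng <- max(diffimg) - min(diffimg)
  if (rng < 1e-12) return(empty)
  norm <- (diffimg - min(diffimg)) / rng

  sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(norm), sobel_x))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(norm), t(sobel_x)))
  grad <- sqrt(gx^2 + gy^2)
  gmax <- max(grad)
  if (gmax < 1e-12) return(empty)
  thr <- EBImage::otsu(EBImage::Image(grad / gmax), range = c(0, 1)) * gmax
  # Otsu alone under-thresholds when the histogram is noise-dominated
  # (few/small objects); never cut below the robust noise ceiling
  floor_thr <- stats::median(grad) + 5 * stats::mad(grad)
  edges <- grad > max(thr, floor_thr)
  filled <- EBImage::fillHull(EBImage::Image(edges))
  eroded <- EBImage::erode(filled, EBImage::makeBrush(3, "diamond"))
  lab <- EBImage::bwlabel(eroded)
  nobj <- max(lab)
  if (nobj == 0) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shp[, "s.area"]
  # perimeter from the traced 8-connected contour, diagonal steps counted
  # as sqrt(2); EBImage's s.perimeter is a raw boundary-pixel count that
  # understates P and pushes 4*pi*A/P^2 above 1
  contours <- EBImage::ocontour(lab)
  perim <- vapply(contours, function(xy) {
    if (nrow(xy) < 2) return(1)
    steps <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), ])^2))
    sum(steps)
  }, numeric(1))
  circ <- pmin(4 * pi * area / pmax(perim, 1)^2, 1)
  # EBImage images are column-major with x = first index; our frames are
  # (row, col) matrices fed directly, so m.cx indexes rows here.
  det <- tibble::tibble(
    row_px = unname(mom[, "m.cx"]),
    col_px = unname(mom[, "m.cy"]),
    radius_px = sqrt(area / pi),
    area_px = unname(area),
    circularity = unname(circ),
    contrast = vapply(seq_len(nobj),
                      function(i) mean(diffimg[lab == i]), numeric(1))
  )
  det <- det[det$radius_px >= params$min_radius_px &
               det$contrast >= params$min_contrast, ]
  det$low_circularity <- det$circularity < params$min_circularity
  if (params$drop_low_circularity) det <- det[!det$low_circularity, ]
  det$contrast <- NULL
  det[order(det$row_px, det$col_px), ]
}

#' Segment every frame of a stack
#'
#' @param stack An `image_stack`.
#' @param params A [seg_params()].
#' @return Tibble of detections with `frame` and `time_s` columns prepended.
#' @export
segment_stack <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "image_stack"))
  bg <- stack_background(stack)
  nf <- dim(stack$frames)[3]
  rows <- lapply(seq_len(nf), function(f) {
    d <- segment_frame(stack$frames[, , f], params, background = bg)
    if (nrow(d) == 0) return(NULL)
    cbind(tibble::tibble(frame = f, time_s = stack$frame_times[f]), d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- tibble::tibble(frame = integer(), time_s = numeric(),
                          row_px = numeric(), col_px = numeric(),
                          radius_px = numeric(), area_px = numeric(),
                          circularity = numeric(), low_circularity = logical())
  out
}

#' Link detections into bubble tracks
#'
#' Greedy nearest-centroid frame-to-frame linking: in each frame, open
#' tracks claim detections in order of increasing centre distance (ties
#' broken by lowest track id), up to `max_disp` pixels. Unmatched
#' detections start new tracks (nucleation events); tracks with no match
#' terminate (dissolution or loss).
#'
#' @param detections Tibble from [segment_stack()] (needs `frame, time_s,
#'   row_px, col_px, radius_px`).
#' @param frame_times All frame times, s (frames with no detections count).
#' @param max_disp Maximum frame-to-frame centre displacement, px (> 0).
#' @return Tibble of tracked detections: `track_id, frame, time_s, row_px,
#'   col_px, radius_px`, at most one detection per track per frame.
#' @export
track_bubbles <- function(detections, frame_times, max_disp = 10) {
  if (max_disp <= 0) stop("max_disp must be positive")
  out <- vector("list", length(frame_times))
  open_id <- integer(0)          # track ids still alive
  open_pos <- matrix(numeric(0), ncol = 2)
  next_id <- 1L
  for (f in seq_along(frame_times)) {
    det <- detections[detections$frame == f, , drop = FALSE]
    nd <- nrow(det)
    assigned <- rep(NA_integer_, nd)
    if (nd > 0 && length(open_id) > 0) {
      dmat <- outer(open_pos[, 1], det$row_px, `-`)^2 +
        outer(open_pos[, 2], det$col_px, `-`)^2
      dmat[dmat > max_disp^2] <- NA
      repeat {
        if (all(is.na(dmat))) break
        best <- min(dmat, na.rm = TRUE)
        hits <- which(dmat == best, arr.ind = TRUE)
        # tie-break: smallest distance, then lowest existing track id
        hit <- hits[order(open_id[hits[, 1]])[1], , drop = FALSE]
        tr <- hit[1]; de <- hit[2]
        assigned[de] <- open_id[tr]
        dmat[tr, ] <- NA; dmat[, de] <- NA
      }
    }
    if (nd > 0) {
      new <- which(is.na(assigned))
      if (length(new) > 0) {
        assigned[new] <- seq.int(next_id, length.out = length(new))
        next_id <- next_id + length(new)
      }
      out[[f]] <- tibble::tibble(track_id = assigned, frame = f,
                                 time_s = frame_times[f],
                                 row_px = det$row_px, col_px = det$col_px,
                                 radius_px = det$radius_px)
      open_id <- assigned
      open_pos <- cbind(det$row_px, det$col_px)
    } else {
      open_id <- integer(0)
      open_pos <- matrix(numeric(0), ncol = 2)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- tibble::tibble(track_id = integer(), frame = integer(),
                          time_s = numeric(), row_px = numeric(),
                          col_px = numeric(), radius_px = numeric())
  res[order(res$track_id, res$frame), ]
}

#' Convert tracks to radial trajectories in physical units
#'
#' @param tracks Tibble from [track_bubbles()].
#' @param pixel_size Pixel size, um/px (> 0).
#' @return Tibble `track_id, time_s, radius_um`.
#' @export
to_trajectories <- function(tracks, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  tibble::tibble(track_id = tracks$track_id, time_s = tracks$time_s,
                 radius_um = tracks$radius_px * pixel_size)
}
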