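# 3D finite-difference transport of dissolved O2 (Michaelis-Menten sink) and
# N2 (inert) over a masked cylindrical lattice, marched with the
# Barakat-Clark two-sweep ADE scheme (src/ade.cpp).

#' Cylindrical phantom geometry on a Cartesian lattice
#'
#' Builds the voxel lattice of a cylindrical collagen phantom (axis vertical)
#' and the boolean mask of voxels whose centres fall inside the cylinder.
#' Defaults describe a 0.5 ml gel in a 48-well plate: radius 5.5 mm, height
#' 5.26 mm (= 0.5 ml / pi r^2).
#'
#' @param radius Cylinder radius, m.
#' @param height Gel height, m.
#' @param dh Lattice spacing, m (default 0.17 mm).
#' @return A `phantom_geometry` with fields `radius`, `height`, `dh`, `dims`
#'   (nx, ny, nz), `mask` (3D logical array), and voxel-centre coordinate
#'   vectors `x`, `y` (lateral, centred on the axis) and `z` (0 at base
#'   face, increasing upward).
#' @export
phantom_geometry <- function(radius = 5.5e-3, height = 5.26e-3, dh = 0.17e-3) {
  if (radius <= 0 || height <= 0 || dh <= 0)
    stop("radius, height and dh must be positive")
  n_lat <- ceiling(2 * radius / dh)
  nz <- max(1L, round(height / dh))
  x <- (seq_len(n_lat) - (n_lat + 1) / 2) * dh
  z <- (seq_len(nz) - 0.5) * dh
  inside <- outer(x^2, x^2, `+`) <= radius^2
  mask <- array(inside, dim = c(n_lat, n_lat, nz))
  if (!any(mask)) stop("empty mask: dh too coarse for this radius")
  structure(list(radius = radius, height = nz * dh, dh = dh,
                 dims = c(n_lat, n_lat, nz), mask = mask,
                 x = x, y = x, z = z),
            class = "phantom_geometry")
}

#' Per-face boundary conditions
#'
#' One condition per face of the phantom: `base` (z = 0), `sides` (the
#' lateral masked-to-unmasked faces of the cylinder) and `top` (gel surface).
#' Standard sets: monitoring = no-flux base and sides, Dirichlet top (gel
#' under a media layer in a well); dive = no-flux base only (gel lifted into
#' the chamber, gas-exposed sides and top).
#'
#' @param base,sides,top `"no_flux"` or `"dirichlet"`.
#' @return A `boundary_spec`.
#' @export
boundary_spec <- function(base = "no_flux", sides = "no_flux",
                          top = "dirichlet") {
  opts <- c("no_flux", "dirichlet")
  base <- match.arg(base, opts); sides <- match.arg(sides, opts)
  top <- match.arg(top, opts)
  structure(list(base = base, sides = sides, top = top),
            class = "boundary_spec")
}

#' @rdname boundary_spec
#' @export
monitoring_bc <- function() boundary_spec("no_flux", "no_flux", "dirichlet")

#' @rdname boundary_spec
#' @export
dive_bc <- function() boundary_spec("no_flux", "dirichlet", "dirichlet")

bc_code <- function(x) c(no_flux = 0L, dirichlet = 1L)[[x]]

#' Equilibrium gas field
#'
#' Initial condition: the phantom in equilibrium with the ambient pressure,
#' every masked voxel holding `mole_fraction * total_pressure` per species
#' (Dalton partition; dissolved concentration follows by Henry's law).
#'
#' @param geometry A [phantom_geometry()].
#' @param species Named list of [gas_species()] (validated).
#' @param total_pressure Absolute ambient pressure, mmHg (>= 0).
#' @return A `gas_field`: list with `pp` (named list of 3D arrays, mmHg;
#'   zero outside the mask), `t` (s) and `geometry`.
#' @export
equilibrium_field <- function(geometry, species, total_pressure = atm_mmHg()) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  validate_species(species)
  if (total_pressure < 0) stop("total_pressure must be non-negative")
  pp <- lapply(species, function(sp) {
    a <- array(0, dim = geometry$dims)
    a[geometry$mask] <- ambient_pp(total_pressure, sp)
    a
  })
  structure(list(pp = pp, t = 0, geometry = geometry), class = "gas_field")
}

#' One ADE time step for one species
#'
#' Advances a single species' partial-pressure array by `dt` seconds of
#' diffusion (two-sweep ADE average) followed by an explicit sink update and
#' a clamp at zero. No-flux faces use mirrored ghost values; Dirichlet faces
#' hold `boundary_pp` on the voxel face via ghost extrapolation.
#'
#' @param u 3D array of partial pressures, mmHg.
#' @param geometry A [phantom_geometry()].
#' @param D Diffusion coefficient, m^2 s^-1.
#' @param dt Time step, s (> 0).
#' @param bc A [boundary_spec()].
#' @param boundary_pp Dirichlet partial pressure, mmHg.
#' @param sink Consumption rate, mmHg s^-1: scalar 0 or an array matching `u`
#'   (values >= 0).
#' @return Updated 3D array.
#' @export
ade_step <- function(u, geometry, D, dt, bc, boundary_pp = 0, sink = 0) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(bc, "boundary_spec"))
  if (dt <= 0) stop("dt must be positive")
  if (any(sink < 0)) stop("sink must be non-negative")
  lam <- D * dt / geometry$dh^2
  out <- ade_step_cpp(u, geometry$mask, as.integer(geometry$dims), lam,
                      bc_code(bc$base), bc_code(bc$sides), bc_code(bc$top),
                      boundary_pp, as.numeric(sink), dt)
  array(out, dim = geometry$dims)
}

#' March the coupled gas fields through time
#'
#' Time-marches every species from an equilibrium (or supplied) initial
#' field: oxygen carries the Michaelis-Menten sink evaluated pointwise on
#' the current field; all other species diffuse without consumption
#' (V_max = 0). Dirichlet boundary values are recomputed every step from the
#' ambient pressure -- a [build_dive_profile()] schedule or a fixed pressure.
#'
#' @param geometry A [phantom_geometry()].
#' @param species Named list of [gas_species()]; the entry named `"O2"` (if
#'   present) is the consumed species.
#' @param mm [mm_params()] for oxygen consumption.
#' @param sigma [cell_density()].
#' @param pressure A `pressure_profile` or a single fixed pressure, mmHg.
#' @param bc A [boundary_spec()].
#' @param t_end End time, s (> 0). With a profile, must not exceed its
#'   duration.
#' @param dt Time step, s (default 2).
#' @param snapshot_times Times (s) at which to record output; each is
#'   rounded to the nearest step and must lie in `[0, t_end]`.
#' @param init Optional initial `gas_field` (defaults to equilibrium with
#'   the ambient pressure at t = 0).
#' @param snapshot_fn Optional `function(pp_list, t)` applied at each
#'   snapshot; its value is stored instead of the full field.
#' @return List of snapshots (each a `gas_field`, or the value of
#'   `snapshot_fn`), named by time.
#' @export
simulate_gas <- function(geometry, species, mm, sigma, pressure, bc,
                         t_end, dt = 2, snapshot_times = t_end,
                         init = NULL, snapshot_fn = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(bc, "boundary_spec"),
            inherits(mm, "mm_params"), inherits(sigma, "cell_density"))
  validate_species(species)
  if (t_end <= 0) stop("t_end must be positive")
  if (dt <= 0 || dt > t_end) stop("dt must be in (0, t_end]")
  has_profile <- inherits(pressure, "pressure_profile")
  if (has_profile && t_end > profile_duration(pressure) + 1e-9)
    stop("t_end exceeds the pressure profile duration")
  if (any(snapshot_times < 0 | snapshot_times > t_end + 1e-9))
    stop("snapshot times must lie within [0, t_end]")

  p_amb <- function(t) {
    if (has_profile)
      pressure_at(pressure, pmin(t, profile_duration(pressure)))
    else rep(pressure, length(t))
  }
  if (is.null(init)) init <- equilibrium_field(geometry, species, p_amb(0))
  stopifnot(inherits(init, "gas_field"))

  n_steps <- as.integer(round(t_end / dt))
  snap_steps <- sort(unique(pmin(pmax(as.integer(round(snapshot_times / dt)),
                                      0L), n_steps)))
  p_steps <- p_amb(seq_len(n_steps) * dt)

  # species are uncoupled (the O2 sink depends on O2 only), so each is
  # marched for the whole duration in one compiled call
  per_sp <- lapply(names(species), function(nm) {
    sp <- species[[nm]]
    coef <- if (identical(nm, "O2")) mm$V_max * sigma$cells_per_m3 / sp$k_h
            else 0
    march_species_cpp(init$pp[[nm]], geometry$mask,
                      as.integer(geometry$dims), sp$D * dt / geometry$dh^2,
                      bc_code(bc$base), bc_code(bc$sides), bc_code(bc$top),
                      ambient_pp(p_steps, sp), coef, mm$K_m, dt,
                      snap_steps, integer(0))
  })
  names(per_sp) <- names(species)

  out <- lapply(seq_along(snap_steps), function(i) {
    t_now <- snap_steps[i] * dt
    pp <- lapply(per_sp, function(sn) array(sn[[i]], dim = geometry$dims))
    if (is.null(snapshot_fn))
      structure(list(pp = pp, t = t_now, geometry = geometry),
                class = "gas_field")
    else snapshot_fn(pp, t_now)
  })
  names(out) <- format(snap_steps * dt)
  out
}

#' Virtual oxygen-probe sensor window
#'
#' Cylindrical sub-region over which the simulated oxygen field is averaged,
#' emulating the finite sensing window of an invasive fluorescent probe.
#' Defaults: a 0.25 mm radius x 0.5 mm high cylinder at the phantom centre.
#'
#' @param geometry A [phantom_geometry()].
#' @param centre `(x, y, z)` in m; default phantom centre.
#' @param radius Window radius, m.
#' @param height Window height, m.
#' @return A `probe_window` holding the linear indices of the voxels inside
#'   the window (at least the nearest masked voxel).
#' @export
probe_window <- function(geometry, centre = NULL, radius = 0.25e-3,
                         height = 0.5e-3) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (is.null(centre)) centre <- c(0, 0, geometry$height / 2)
  if (sqrt(centre[1]^2 + centre[2]^2) > geometry$radius ||
      centre[3] < 0 || centre[3] > geometry$height)
    stop("probe window centre lies outside the phantom")
  co <- expand.grid(x = geometry$x, y = geometry$y, z = geometry$z)
  inside <- (co$x - centre[1])^2 + (co$y - centre[2])^2 <= radius^2 &
    abs(co$z - centre[3]) <= height / 2
  idx <- which(inside & as.vector(geometry$mask))
  if (length(idx) == 0) {
    d2 <- (co$x - centre[1])^2 + (co$y - centre[2])^2 +
      (co$z - centre[3])^2
    d2[!as.vector(geometry$mask)] <- Inf
    idx <- which.min(d2)
  }
  structure(list(centre = centre, radius = radius, height = height,
                 voxels = idx),
            class = "probe_window")
}

#' Virtual dissolved-oxygen probe experiment
#'
#' Replays the real-time oxygen-monitoring experiment in silico: `reps`
#' repeated simulations of a phantom under monitoring boundary conditions at
#' a fixed ambient pressure, each with the cell density drawn uniformly
#' within `sigma_nominal * (1 +/- jitter)`, the oxygen field averaged over
#' the sensor window at each sample time.
#'
#' @param geometry A [phantom_geometry()].
#' @param species Named list of [gas_species()].
#' @param mm [mm_params()].
#' @param sigma_nominal Nominal cell density, cells/ml.
#' @param window A [probe_window()] (default: centre window).
#' @param reps Number of replicate simulations (>= 1, default 3).
#' @param jitter Fractional density variation (default 0.10).
#' @param duration Monitoring duration, s (default 8 h).
#' @param sample_dt Sampling interval, s (default 80).
#' @param dt Solver time step, s (default 2).
#' @param total_pressure Ambient pressure, mmHg (default 1 atm).
#' @param seed Integer seed for the density draws (local RNG; the global
#'   RNG state is untouched).
#' @return A tibble `time_s, mean_ppO2_mmHg, sd_ppO2_mmHg`, with attributes
#'   `replicates` (samples x reps matrix), `sigmas` (drawn densities,
#'   cells/ml) and `seed`.
#' @export
probe_experiment <- function(geometry, species, mm, sigma_nominal,
                             window = NULL, reps = 3, jitter = 0.10,
                             duration = 8 * 3600, sample_dt = 80, dt = 2,
                             total_pressure = atm_mmHg(), seed = 1L) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(window)) window <- probe_window(geometry)
  stopifnot(inherits(window, "probe_window"))
  if (!all(as.vector(geometry$mask)[window$voxels]))
    stop("probe window lies outside the phantom mask")
  sample_times <- seq(0, duration, by = sample_dt)
  sigmas <- with_local_seed(seed, {
    stats::runif(reps, sigma_nominal * (1 - jitter),
                 sigma_nominal * (1 + jitter))
  })
  # only O2 is observed and the species are uncoupled, so march O2 alone
  # with the window mean computed in compiled code at each sample step
  spO2 <- species[["O2"]]
  if (is.null(spO2)) stop("species set must contain O2")
  validate_species(species)
  u0 <- array(0, dim = geometry$dims)
  u0[geometry$mask] <- ambient_pp(total_pressure, spO2)
  n_steps <- as.integer(round(duration / dt))
  snap_steps <- as.integer(round(sample_times / dt))
  bcm <- monitoring_bc()
  series <- vapply(sigmas, function(sg) {
    coef <- mm$V_max * cell_density(sg)$cells_per_m3 / spO2$k_h
    snaps <- march_species_cpp(u0, geometry$mask, as.integer(geometry$dims),
                               spO2$D * dt / geometry$dh^2,
                               bc_code(bcm$base), bc_code(bcm$sides),
                               bc_code(bcm$top),
                               rep(ambient_pp(total_pressure, spO2), n_steps),
                               coef, mm$K_m, dt, snap_steps,
                               as.integer(window$voxels))
    unlist(snaps, use.names = FALSE)
  }, numeric(length(sample_times)))
  series <- matrix(series, nrow = length(sample_times))
  res <- tibble::tibble(
    time_s = sample_times,
    mean_ppO2_mmHg = rowMeans(series),
    sd_ppO2_mmHg = apply(series, 1, stats::sd)
  )
  attr(res, "replicates") <- series
  attr(res, "sigmas") <- sigmas
  attr(res, "seed") <- seed
  res
}

#' Mid-plane dissolved-gas tension section
#'
#' Total dissolved-gas tension (sum of species partial pressures) on the
#' plane through the phantom centre normal to `axis`, non-dimensionalised by
#' atmospheric pressure. `axis = "y"` (default) gives the vertical section
#' through the cylinder axis; `axis = "z"` the horizontal mid-height section.
#'
#' @param field A `gas_field`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A matrix of dimensionless tension, `NA` outside the mask.
#' @export
midplane_section <- function(field, axis = c("y", "x", "z")) {
  stopifnot(inherits(field, "gas_field"))
  axis <- match.arg(axis)
  tension <- Reduce(`+`, field$pp)
  mask <- field$geometry$mask
  d <- dim(tension)
  ax <- match(axis, c("x", "y", "z"))
  mid <- ceiling(d[ax] / 2)
  sl <- switch(axis,
               x = list(tension[mid, , ], mask[mid, , ]),
               y = list(tension[, mid, ], mask[, mid, ]),
               z = list(tension[, , mid], mask[, , mid]))
  out <- nondimensionalise(sl[[1]])
  out[!sl[[2]]] <- NA_real_
  out
}

#' Brute-force FTCS reference step
#'
#' Forward-time centred-space explicit update of the same masked diffusion
#' problem, written as plain vectorised R. It is a deliberately simple
#' reference integrator (stable only for `D*dt/dh^2 <= 1/6`) used to
#' validate the production ADE scheme on small instances; it shares the
#' boundary-value placement (mirrored no-flux ghosts, face-centred Dirichlet
#' ghosts `2*pb - u`) so both discretise the same continuous problem.
#'
#' @inheritParams ade_step
#' @return Updated 3D array.
#' @export
ftcs_reference_step <- function(u, geometry, D, dt, bc, boundary_pp = 0,
                                sink = 0) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(bc, "boundary_spec"))
  lam <- D * dt / geometry$dh^2
  if (lam > 1 / 6 + 1e-12)
    stop("FTCS unstable: D*dt/dh^2 must be <= 1/6")
  mask <- geometry$mask
  d <- dim(u)
  shift <- function(a, dx, dy, dz, fill) {
    out <- array(fill, dim = d)
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
    ox <- fx >= 1 & fx <= d[1]; oy <- fy >= 1 & fy <= d[2]
    oz <- fz >= 1 & fz <= d[3]
    out[sx[ox], sy[oy], sz[oz]] <- a[fx[ox], fy[oy], fz[oz]]
    out
  }
  lap <- array(0, dim = d)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (dr in dirs) {
    v <- shift(u, dr[1], dr[2], dr[3], fill = 0)
    nb_mask <- shift(mask, dr[1], dr[2], dr[3], fill = FALSE)
    face <- if (dr[3] == 1) bc$base else if (dr[3] == -1) bc$top else bc$sides
    ghost <- if (face == "no_flux") u else 2 * boundary_pp - u
    v[!nb_mask] <- ghost[!nb_mask]
    lap <- lap + (v - u)
  }
  out <- u + lam * lap - sink * dt
  out[out < 0] <- 0
  out[!mask] <- 0
  out
}

# Run a block with a temporary, locally seeded RNG; the caller's RNG state
# is restored on exit.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
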