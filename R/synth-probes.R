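# Overdamped Langevin probe simulator on a region-dependent diffusivity
# field. Emulates small hydrophobic probes (NO-like) partitioning between a
# membrane core and the surrounding headgroup/water region, with known
# ground-truth diffusivities and a Boltzmann-exact equilibrium.

#' Specification of a probe-field Langevin run
#'
#' Probes diffuse in a box of height `box_z` (z in `[-box_z/2, box_z/2]`)
#' containing a hydrophobic core slab `|z| < core_halfwidth`. The diffusivity
#' is `d_core` inside the slab and `d_out` outside (z-diffusivity inside the
#' core is additionally scaled by `anisotropy_core`), with discontinuities
#' smoothed over a 1 Angstrom tanh ramp. A smoothed square well of depth
#' `well_depth_kt` (kT units, positive = core favourable) drives partitioning.
#'
#' @param d_core,d_out Diffusivities, cm^2/s.
#' @param anisotropy_core Ratio of z- to xy-diffusivity inside the core.
#' @param well_depth_kt Well depth in kT; positive values attract probes into
#'   the core so the equilibrium in/out ratio at equal volumes is
#'   `exp(well_depth_kt)`.
#' @param core_halfwidth Core half-thickness, Angstrom; must be < `box_z / 2`.
#' @param box_z Box height, Angstrom.
#' @param box_xy Lateral box length, Angstrom (periodic).
#' @param n_particles Number of probes.
#' @param dt Time step, ps.
#' @param n_steps Number of integration steps.
#' @param record_every Record positions every this many steps.
#' @param z_boundary `"reflecting"` (default) or `"periodic"` in z.
#' @param ramp_width Smoothing width of the diffusivity/potential edges,
#'   Angstrom.
#' @param seed Integer seed.
#' @return A list of class `probe_field_spec`.
#' @export
probe_field_spec <- function(d_core = 1e-5,
                             d_out = 0.5e-5,
                             anisotropy_core = 1,
                             well_depth_kt = 0,
                             core_halfwidth = 20,
                             box_z = 80,
                             box_xy = 60,
                             n_particles = 10,
                             dt = 1,
                             n_steps = 10000,
                             record_every = 1,
                             z_boundary = c("reflecting", "periodic"),
                             ramp_width = 1,
                             seed = 20240563) {
  z_boundary <- match.arg(z_boundary)
  check_number(d_core, "d_core", lower = 0, strict_lower = TRUE)
  check_number(d_out, "d_out", lower = 0, strict_lower = TRUE)
  check_number(n_particles, "n_particles", lower = 1)
  check_number(core_halfwidth, "core_halfwidth", lower = 0,
               upper = box_z / 2 - 1e-12, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  d_max_a2ps <- max(d_core * max(anisotropy_core, 1), d_out) / CM2S_PER_A2PS
  step_sd <- sqrt(2 * d_max_a2ps * dt)
  if (step_sd > core_halfwidth / 4) {
    abort(sprintf(paste0(
      "dt too large for the well steepness: rms step %.2f A exceeds ",
      "core_halfwidth/4 = %.2f A; reduce dt"), step_sd, core_halfwidth / 4))
  }
  structure(
    list(d_core = d_core, d_out = d_out, anisotropy_core = anisotropy_core,
         well_depth_kt = well_depth_kt, core_halfwidth = core_halfwidth,
         box_z = box_z, box_xy = box_xy, n_particles = as.integer(n_particles),
         dt = dt, n_steps = as.integer(n_steps),
         record_every = as.integer(record_every), z_boundary = z_boundary,
         ramp_width = ramp_width, seed = as.integer(seed)),
    class = "probe_field_spec"
  )
}

# Smoothed core indicator and its z-derivative: s(z) in [0, 1], ~1 inside
# |z| < h, ~0 outside, tanh ramps of width w.
core_indicator <- function(z, h, w) {
  0.5 * (tanh((z + h) / w) - tanh((z - h) / w))
}
core_indicator_deriv <- function(z, h, w) {
  0.5 / w * (1 / cosh((z + h) / w)^2 - 1 / cosh((z - h) / w)^2)
}

#' Simulate probe particles by overdamped Langevin dynamics
#'
#' Ito Euler-Maruyama with the divergence-of-D drift correction, so that the
#' stationary density is exactly the Boltzmann weight `exp(-U(z)/kT)`
#' regardless of the diffusivity contrast:
#' `dz = (D'(z) - D(z) U'(z)) dt + sqrt(2 D(z) dt) xi`.
#' xy is periodic; z reflects at the box faces by default.
#'
#' @param spec A [probe_field_spec()].
#' @return A `probe_traj` object: `times` (ps), `coords`
#'   (`n_particles x 3 x n_recorded` array, Angstrom, xy wrapped into the
#'   box), `box` (per-frame Lx, Ly, Lz), `region_boundaries` (z_low, z_high
#'   of the core), and the generating `spec`.
#' @export
simulate_probes <- function(spec) {
  stopifnot(inherits(spec, "probe_field_spec"))
  n <- spec$n_particles
  h <- spec$core_halfwidth
  w <- spec$ramp_width
  half_z <- spec$box_z / 2
  d_core_xy <- spec$d_core / CM2S_PER_A2PS
  d_core_z <- d_core_xy * spec$anisotropy_core
  d_out <- spec$d_out / CM2S_PER_A2PS
  u0 <- spec$well_depth_kt

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)

  # start uniformly in the box: equilibration is part of the run
  x <- runif(n, 0, spec$box_xy)
  y <- runif(n, 0, spec$box_xy)
  z <- runif(n, -half_z, half_z)

  n_rec <- spec$n_steps %/% spec$record_every + 1L
  coords <- array(NA_real_, dim = c(n, 3, n_rec))
  coords[, 1, 1] <- x; coords[, 2, 1] <- y; coords[, 3, 1] <- z
  rec <- 1L
  dt <- spec$dt

  for (step in seq_len(spec$n_steps)) {
    s <- core_indicator(z, h, w)
    ds <- core_indicator_deriv(z, h, w)
    d_xy <- d_out + (d_core_xy - d_out) * s
    d_z <- d_out + (d_core_z - d_out) * s
    dd_z <- (d_core_z - d_out) * ds         # dD_z/dz
    du <- -u0 * ds                          # U(z) = -u0 * s(z), in kT
    drift <- (dd_z - d_z * du) * dt
    x <- x + sqrt(2 * d_xy * dt) * rnorm(n)
    y <- y + sqrt(2 * d_xy * dt) * rnorm(n)
    z <- z + drift + sqrt(2 * d_z * dt) * rnorm(n)
    x <- x %% spec$box_xy
    y <- y %% spec$box_xy
    if (spec$z_boundary == "reflecting") {
      # fold into [-half_z, half_z] by mirror reflection at the faces
      u <- (z + half_z) %% (2 * spec$box_z)
      u <- ifelse(u > spec$box_z, 2 * spec$box_z - u, u)
      z <- u - half_z
    } else {
      z <- (z + half_z) %% spec$box_z - half_z
    }
    if (step %% spec$record_every == 0L) {
      rec <- rec + 1L
      coords[, 1, rec] <- x; coords[, 2, rec] <- y; coords[, 3, rec] <- z
    }
  }

  times <- (seq_len(n_rec) - 1) * dt * spec$record_every
  box <- matrix(rep(c(spec$box_xy, spec$box_xy, spec$box_z), each = n_rec),
                ncol = 3)
  structure(
    list(times = times, coords = coords[, , seq_len(rec), drop = FALSE],
         box = box[seq_len(rec), , drop = FALSE],
         region_boundaries = c(z_low = -h, z_high = h), spec = spec),
    class = "probe_traj"
  )
}

#' Construct a probe trajectory from raw positions
#'
#' Builds the `probe_traj` container consumed by the transport module from
#' user-supplied positions, e.g. probes extracted from an external
#' simulation.
#'
#' @param times Frame times, ps (strictly increasing, uniformly spaced).
#' @param coords Numeric array `n_particles x 3 x n_frames`, Angstrom.
#' @param box Box lengths: length-3 vector or `n_frames x 3` matrix.
#' @param region_boundaries Named vector `c(z_low, z_high)` of the
#'   hydrophobic core.
#' @return A `probe_traj`.
#' @export
probe_trajectory <- function(times, coords, box,
                             region_boundaries = c(z_low = -Inf,
                                                   z_high = Inf)) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort("`coords` must be an n_particles x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (length(times) != nf) abort("`times` must have one entry per frame")
  if (nf > 1L && any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing")
  }
  box <- matrix(as.numeric(box), ncol = 3)
  if (nrow(box) == 1L) box <- box[rep(1L, nf), , drop = FALSE]
  if (region_boundaries[["z_low"]] >= region_boundaries[["z_high"]]) {
    abort("z_low must be < z_high")
  }
  structure(
    list(times = as.numeric(times), coords = coords, box = box,
         region_boundaries = region_boundaries, spec = NULL),
    class = "probe_traj"
  )
}

#' @export
print.probe_traj <- function(x, ...) {
  cat(sprintf("<probe_traj> %d particles, %d frames, dt_rec = %.3g ps\n",
              dim(x$coords)[1], dim(x$coords)[3],
              if (length(x$times) > 1) diff(x$times)[1] else NA_real_))
  cat(sprintf("  core: z in [%.2f, %.2f] A\n",
              x$region_boundaries[["z_low"]], x$region_boundaries[["z_high"]]))
  invisible(x)
}

#' Convert a probe trajectory to a long tibble
#'
#' @param x A `probe_traj`.
#' @param ... Unused.
#' @return Tibble with `particle`, `frame`, `time`, `x`, `y`, `z`.
#' @export
as_tibble.probe_traj <- function(x, ...) {
  n <- dim(x$coords)[1]
  nf <- dim(x$coords)[3]
  tibble(
    particle = rep(seq_len(n), nf),
    frame = rep(seq_len(nf), each = n),
    time = rep(x$times, each = n),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}
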