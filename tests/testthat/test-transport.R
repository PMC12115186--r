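# Transport analysis: region classification, partition coefficient, MSD
# against a brute-force oracle, diffusion regression, permeability plumbing.

make_ptraj <- function(coords, dt = 1, box = c(100, 100, 100),
                       bounds = c(z_low = -25, z_high = 25)) {
  nf <- dim(coords)[3]
  probe_trajectory((seq_len(nf) - 1) * dt, coords, box, bounds)
}

test_that("region classification finds the head/tail crossover", {
  z <- seq(-30, 30, by = 0.25)
  heads <- ifelse(abs(z) >= 15 & abs(z) <= 25, 1.0, 0)
  tails <- ifelse(abs(z) < 16, 1.5, 0)
  prof <- dplyr::bind_rows(
    tibble::tibble(z = z, label = "heads", density = heads),
    tibble::tibble(z = z, label = "tails", density = tails)
  )
  b <- classify_regions(prof)
  expect_equal(unname(b[["z_high"]]), 16, tolerance = 0.3)
  expect_equal(unname(b[["z_low"]]), -b[["z_high"]], tolerance = 0.3)

  none <- prof
  none$density[none$label == "tails"] <- 0
  expect_error(classify_regions(none), "zero mass")

  inverted <- prof
  inverted$density[inverted$label == "heads"] <-
    ifelse(abs(z) < 5, 3.0, heads)
  expect_error(classify_regions(inverted), "no hydrophobic core")
})

test_that("K_p counts probes inside vs outside the core", {
  # 5 probes fixed in the core, 5 fixed outside -> 1.0
  coords <- array(0, dim = c(10, 3, 4))
  coords[1:5, 3, ] <- 0
  coords[6:10, 3, ] <- 40
  pt <- make_ptraj(coords)
  expect_equal(partition_coefficient(pt, 0), 1.0)

  always_in <- make_ptraj(array(0, dim = c(3, 3, 4)))
  expect_error(partition_coefficient(always_in, 0), "never leaves")
})

test_that("uniformly scattered probes recover the volume ratio", {
  set.seed(21)
  n <- 400; nf <- 50
  coords <- array(runif(n * 3 * nf, -50, 50), dim = c(n, 3, nf))
  pt <- make_ptraj(coords, bounds = c(z_low = -50 / 3, z_high = 50 / 3))
  expect_equal(partition_coefficient(pt, 0), 0.5, tolerance = 0.05)
})

test_that("K_p equals the ratio of mean indicator occupancies", {
  set.seed(22)
  coords <- array(runif(20 * 3 * 30, -40, 40), dim = c(20, 3, 30))
  pt <- make_ptraj(coords, bounds = c(z_low = -10, z_high = 15))
  z <- pt$coords[, 3, ]
  inside_frac <- mean(z >= -10 & z <= 15)
  expect_equal(partition_coefficient(pt, 0),
               inside_frac / (1 - inside_frac), tolerance = 1e-12)
})

test_that("Langevin equilibrium matches the Boltzmann ratio at unit well depth", {
  spec <- probe_field_spec(d_core = 1e-5, d_out = 0.5e-5, well_depth_kt = 1,
                           core_halfwidth = 20, box_z = 80,
                           n_particles = 300, dt = 1, n_steps = 40000,
                           record_every = 20, seed = 31)
  pt <- simulate_probes(spec)
  expect_equal(partition_coefficient(pt, 0.2), exp(1), tolerance = 0.15 * exp(1))
})

test_that("MSD: static particles, ballistic drift, and brute-force oracle", {
  static <- make_ptraj(array(5, dim = c(4, 3, 10)))
  curve <- msd(static)
  expect_true(all(curve$msd_3d == 0))
  expect_equal(curve$lag[1], 0)

  # deterministic drift x = v t -> msd_xy = v^2 tau^2
  v <- 0.3; nf <- 16
  coords <- array(0, dim = c(2, 3, nf))
  for (f in seq_len(nf)) coords[, 1, f] <- v * (f - 1)
  coords[, 2, ] <- 7  # constant y
  drift <- make_ptraj(coords, box = c(1e6, 1e6, 100))
  curve_d <- msd(drift)
  expect_equal(curve_d$msd_xy, (v * curve_d$lag)^2, tolerance = 1e-12)

  # brute-force double-loop oracle on a random small trajectory
  set.seed(33)
  n <- 3; nf <- 14
  coords <- array(rnorm(n * 3 * nf, sd = 2), dim = c(n, 3, nf))
  coords[, 1:2, ] <- coords[, 1:2, ] + 500  # keep far from the xy wrap
  pt <- make_ptraj(coords, box = c(1e4, 1e4, 100))
  got <- msd(pt)
  for (li in seq_len(nf %/% 2 + 1)) {
    tau <- li - 1
    acc_z <- acc_xy <- 0; cnt <- 0
    for (p in seq_len(n)) {
      for (t0 in seq_len(nf - tau)) {
        dz <- coords[p, 3, t0 + tau] - coords[p, 3, t0]
        dx <- coords[p, 1, t0 + tau] - coords[p, 1, t0]
        dy <- coords[p, 2, t0 + tau] - coords[p, 2, t0]
        acc_z <- acc_z + dz^2
        acc_xy <- acc_xy + dx^2 + dy^2
        cnt <- cnt + 1
      }
    }
    if (tau == 0) next
    expect_equal(got$msd_z[li], acc_z / cnt, tolerance = 1e-12)
    expect_equal(got$msd_xy[li], acc_xy / cnt, tolerance = 1e-12)
  }
  expect_error(msd(make_ptraj(array(0, dim = c(2, 3, 2)))), "3 frames")
})

test_that("xy unwrapping survives periodic crossings", {
  # steady +x drift 2 A/frame through a 20 A box, stored wrapped
  nf <- 30
  coords <- array(0, dim = c(1, 3, nf))
  for (f in seq_len(nf)) coords[1, 1, f] <- (2 * (f - 1)) %% 20
  pt <- make_ptraj(coords, box = c(20, 20, 100))
  curve <- msd(pt)
  expect_equal(curve$msd_xy, (2 * curve$lag)^2, tolerance = 1e-9)
})

test_that("diffusion regression: exact line recovers the constructed coefficient", {
  d_cm <- 0.41e-5                         # slope 2 * D in A^2/ps
  lag <- seq(0, 12000, by = 100)
  curve <- tibble::tibble(
    lag = lag,
    msd_z = 2 * (d_cm / 1e-4) * lag,
    msd_xy = 4 * (d_cm / 1e-4) * lag,
    msd_3d = 6 * (d_cm / 1e-4) * lag,
    n_origin_pairs = rep(100L, length(lag))
  )
  for (comp in c("z", "xy", "3d")) {
    f <- fit_diffusion(curve, comp)
    expect_equal(f$d, d_cm, tolerance = 1e-9)
    expect_equal(f$window_lo, 2000)       # the 2-10 ns convention
    expect_equal(f$window_hi, 10000)
    expect_false(f$degenerate)
  }
})

test_that("flat MSD gives D = 0 with the degenerate flag", {
  lag <- seq(0, 400, by = 10)
  curve <- tibble::tibble(lag = lag, msd_z = rep(0, length(lag)),
                          msd_xy = rep(0, length(lag)),
                          msd_3d = rep(0, length(lag)),
                          n_origin_pairs = rep(10L, length(lag)))
  f <- fit_diffusion(curve, "z")
  expect_equal(f$d, 0)
  expect_true(f$degenerate)
})

test_that("auto-window on a quadratic MSD restricts the fit and flags it", {
  lag <- seq(0, 1000, by = 10)
  curve <- tibble::tibble(lag = lag, msd_z = (0.05 * lag)^2,
                          msd_xy = 2 * (0.05 * lag)^2,
                          msd_3d = 3 * (0.05 * lag)^2,
                          n_origin_pairs = rep(10L, length(lag)))
  f <- fit_diffusion(curve, "z")
  expect_false(f$degenerate)
  expect_true(f$auto_restricted)
  expect_gte(f$r2, 0.99)
  expect_lt(f$window_hi - f$window_lo, max(lag))
})

test_that("permeability arithmetic and dimensional consistency", {
  expect_equal(permeability(1e-5, 1, 100), 10)
  expect_equal(permeability(1e-5, 0, 100), 0)
  # simultaneous length-unit rescaling: P picks up exactly one factor of s
  p0 <- permeability(0.41e-5, 0.815, 46.42)
  for (s in c(0.1, 2, 10)) {
    expect_equal(permeability(0.41e-5 * s^2, 0.815, 46.42 * s) / s, p0,
                 tolerance = 1e-12)
  }
})

test_that("transport summary wires K_p, D and delta together", {
  spec <- probe_field_spec(d_core = 1e-5, d_out = 1e-5, well_depth_kt = 0,
                           core_halfwidth = 20, box_z = 80,
                           n_particles = 100, dt = 1, n_steps = 5000,
                           record_every = 5, seed = 77)
  pt <- simulate_probes(spec)
  ts <- transport_summary(pt, thickness = 46.42, discard_fraction = 0.2)
  expect_equal(ts$p_m, ts$d_m * ts$k_p / (46.42e-8), tolerance = 1e-12)
  expect_equal(ts$d_m, ts$d_z)            # default estimator
  expect_equal(ts$anisotropy, ts$d_z / ts$d_xy)
  gl <- glance(ts)
  expect_equal(gl$p_m, ts$p_m)
  expect_error(transport_summary(pt, thickness = 0), "thickness")
})
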