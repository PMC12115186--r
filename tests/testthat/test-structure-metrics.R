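# Structural observables: leaflet assignment, density profiles, APL,
# thickness, interdigitation, SCD, hydrogen bonds, summary windowing.

test_that("leaflet assignment splits heads about the midplane, tie goes lower", {
  traj <- head_only_traj(c(20, -20))
  leaf <- assign_leaflets(traj)
  expect_equal(leaf$leaflet, c("upper", "lower"))

  sym <- build_bilayer(small_bilayer_spec())
  leaf_sym <- assign_leaflets(sym)
  expect_equal(sum(leaf_sym$leaflet == "upper"),
               sum(leaf_sym$leaflet == "lower"))

  tie <- head_only_traj(c(0, 20, -20))  # first head exactly at the midplane
  expect_warning(leaf_tie <- assign_leaflets(tie), "midplane")
  expect_equal(leaf_tie$leaflet[1], "lower")
})

test_that("a lipid without head_ref is reported by residue", {
  traj <- head_only_traj(c(20, -20))
  traj$atoms$role[1] <- "other"
  expect_error(assign_leaflets(traj), "head_ref")
})

test_that("density profile conserves selected mass every run", {
  traj <- build_bilayer(small_bilayer_spec(thermal_jitter_sd = 0.4,
                                           n_frames = 5))
  prof <- density_profile(traj, bin_width = 0.5)
  area <- traj$box[1, 1] * traj$box[1, 2]
  bw <- attr(prof, "bin_width")
  for (lab in c("heads", "tails")) {
    sel_mass <- sum(traj$atoms$mass[
      if (lab == "heads") sel_heads(traj$atoms) else sel_tails(traj$atoms)])
    got <- sum(prof$density[prof$label == lab]) * bw * area
    expect_equal(got, sel_mass, tolerance = 1e-3 * sel_mass)
  }
})

test_that("doubling the bin width conserves the profile integral", {
  traj <- build_bilayer(small_bilayer_spec(thermal_jitter_sd = 0.4))
  area <- traj$box[1, 1] * traj$box[1, 2]
  m1 <- density_profile(traj, bin_width = 0.5)
  m2 <- density_profile(traj, bin_width = 1.0)
  i1 <- sum(m1$density[m1$label == "tails"]) * 0.5 * area
  i2 <- sum(m2$density[m2$label == "tails"]) * 1.0 * area
  expect_equal(i1, i2, tolerance = 1e-9 * i1)
})

test_that("head density peaks at the reference planes, tails inside", {
  traj <- build_bilayer(small_bilayer_spec(n_frames = 2))
  geom <- bilayr:::bilayer_geometry(small_bilayer_spec())
  prof <- density_profile(traj, bin_width = 0.5)
  heads <- prof[prof$label == "heads", ]
  tails <- prof[prof$label == "tails", ]
  peak_z <- abs(heads$z[which.max(heads$density)])
  expect_equal(peak_z, geom$z_head, tolerance = 0.5)
  expect_true(max(abs(tails$z[tails$density > 0])) < geom$z_head)
})

test_that("uniformly spread atoms give a flat profile", {
  n <- 20000
  set.seed(3)
  atoms <- tibble::tibble(
    atom_id = seq_len(n), atom_name = "X", element = "X", mass = 1,
    residue_id = seq_len(n), residue_name = "UNI",
    molecule_class = "solvent", role = "other",
    chain = NA_character_, carbon_index = NA_integer_
  )
  coords <- array(0, dim = c(n, 3, 1))
  coords[, 1, 1] <- runif(n, 0, 30)
  coords[, 2, 1] <- runif(n, 0, 30)
  coords[, 3, 1] <- runif(n, -20, 20)
  traj <- trajectory(atoms, coords, c(30, 30, 40), 0)
  prof <- density_profile(traj, selections = list(all = function(a) rep(TRUE, nrow(a))),
                          bin_width = 2, recenter = FALSE)
  inner <- prof[prof$z > -19 & prof$z < 19, ]
  expected <- n / (30 * 30 * 40)
  expect_true(all(abs(inner$density - expected) / expected < 0.15))
})

test_that("APL matches the builder target exactly at zero jitter", {
  traj <- build_bilayer(small_bilayer_spec(target_apl = 42.42))
  apl <- area_per_lipid(traj)
  expect_equal(apl$mean, 42.42, tolerance = 1e-12)
  expect_equal(apl$sd, 0)
})

test_that("asymmetric leaflets fall back to the per-leaflet formula", {
  traj <- head_only_traj(c(20, 21, 22, -20), box = c(50, 50, 80))
  expect_warning(apl <- area_per_lipid(traj), "asymmetric")
  expect_equal(apl$mean[apl$leaflet == "upper"], 2500 / 3)
  expect_equal(apl$mean[apl$leaflet == "lower"], 2500)
})

test_that("thickness reads the reference-plane separation and is translation invariant", {
  traj <- head_only_traj(c(23.21, 23.21, -23.21, -23.21))
  expect_equal(bilayer_thickness(traj)$mean, 46.42, tolerance = 1e-12)
  shifted <- traj
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 5
  expect_equal(bilayer_thickness(shifted)$mean, 46.42, tolerance = 1e-12)
})

test_that("interdigitation fraction closed forms", {
  z <- seq(-1, 4, by = 0.005)
  same <- uniform_profile(z, 0, 2, 0.7)
  expect_equal(interdigitation_fraction(same, same), 1.0)
  expect_equal(
    interdigitation_fraction(uniform_profile(z, 0, 1, 0.7),
                             uniform_profile(z, 2.5, 3.5, 0.7)),
    0.0
  )
  # overlap [1,2] of two unit-length boxes -> 0.5
  expect_equal(
    interdigitation_fraction(uniform_profile(z, 0, 2, 0.7),
                             uniform_profile(z, 1, 3, 0.7)),
    0.5, tolerance = 0.01
  )
  expect_error(
    interdigitation_fraction(uniform_profile(z, 0, 1, 0),
                             uniform_profile(z, 0, 1, 0)),
    "zero total mass"
  )
})

test_that("f_ov matches a brute-force Riemann oracle at 10x finer resolution within 1%", {
  # independent oracle: midpoint Riemann sum of min/sum on the linearly
  # interpolated profiles, evaluated on a 10x finer grid
  riemann_f_ov <- function(prof) {
    up <- prof[prof$label == "upper", ]
    lo <- prof[prof$label == "lower", ]
    zf <- seq(min(up$z), max(up$z), length.out = 10 * nrow(up))
    u <- approx(up$z, up$density, zf)$y
    l <- approx(lo$z, lo$density, zf)$y
    dz <- zf[2] - zf[1]
    sum(pmin(u, l)) * dz / (0.5 * sum(u + l) * dz)
  }
  types <- tibble::tibble(
    name = "DPPC", count_per_leaflet = 25, n_tail_carbons = 6,
    head_mass = 223.1, carbon_mass = 12.011, hydrogen_mass = 1.008
  )
  for (off in c(0.5, 2)) {
    traj <- build_bilayer(small_bilayer_spec(lipid_types = types,
                                             interdigitation_offset = off,
                                             thermal_jitter_sd = 0.8,
                                             n_frames = 10))
    prof <- leaflet_tail_profiles(traj, 0.5)
    expect_equal(interdigitation_fraction(prof), riemann_f_ov(prof),
                 tolerance = 0.01)
  }
})

test_that("interdigitation ratio arithmetic and guard rails", {
  expect_equal(interdigitation_ratio(0.1, 0.1)$d_int, 1.0)
  expect_equal(interdigitation_ratio(0.24, 0.10)$d_int, 2.4)
  expect_error(interdigitation_ratio(0.2, 0), "undefined")
  lo <- build_bilayer(small_bilayer_spec(interdigitation_offset = -0.5,
                                         thermal_jitter_sd = 0.8))
  hi <- build_bilayer(small_bilayer_spec(interdigitation_offset = 3,
                                         thermal_jitter_sd = 0.8))
  d_int <- interdigitation_ratio(
    interdigitation_fraction(leaflet_tail_profiles(hi)),
    interdigitation_fraction(leaflet_tail_profiles(lo))
  )$d_int
  expect_gt(d_int, 1)
})

test_that("SCD closed forms: perpendicular 0.5, magic angle 0, isotropic -> 0", {
  # magic angle: single carbon with two H at 54.7356 degrees from +z
  ma <- 54.7356 * pi / 180
  make_ch <- function(h_dirs) {
    nh <- nrow(h_dirs)
    atoms <- tibble::tibble(
      atom_id = seq_len(nh + 1),
      atom_name = c("C1A", sprintf("H1A%d", seq_len(nh))),
      element = c("C", rep("H", nh)),
      mass = c(12.011, rep(1.008, nh)),
      residue_id = 1L, residue_name = "LIP", molecule_class = "lipid",
      role = c("tail_carbon", rep("tail_hydrogen", nh)),
      chain = "sn-1", carbon_index = 1L
    )
    coords <- array(0, dim = c(nh + 1, 3, 1))
    coords[-1, , 1] <- h_dirs * 1.09
    trajectory(atoms, coords, c(30, 30, 30), 0)
  }
  magic <- make_ch(rbind(c(sin(ma), 0, cos(ma)), c(-sin(ma), 0, cos(ma))))
  expect_equal(order_parameters(magic)$abs_scd, 0, tolerance = 1e-6)

  perp <- make_ch(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(order_parameters(perp)$abs_scd, 0.5, tolerance = 1e-12)

  set.seed(8)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  iso <- make_ch(u)
  expect_lt(order_parameters(iso)$abs_scd, 0.01)
})

test_that("|SCD| is invariant under rotation about z and xy translation", {
  traj <- build_bilayer(small_bilayer_spec(tail_tilt_deg = 20,
                                           thermal_jitter_sd = 0.2,
                                           n_frames = 2))
  base <- order_parameters(traj)
  th <- 0.7
  rot <- traj
  xy <- traj$coords[, 1:2, , drop = FALSE]
  rot$coords[, 1, ] <- cos(th) * xy[, 1, ] - sin(th) * xy[, 2, ]
  rot$coords[, 2, ] <- sin(th) * xy[, 1, ] + cos(th) * xy[, 2, ]
  expect_equal(order_parameters(rot)$scd, base$scd, tolerance = 1e-10)
  shifted <- traj
  shifted$coords[, 1, ] <- shifted$coords[, 1, ] + 12.3
  expect_equal(order_parameters(shifted)$scd, base$scd, tolerance = 1e-12)
})

test_that("hydrogen-bond criterion: distance and angular boundaries", {
  donors <- tibble::tibble(donor = 1L, hydrogen = 2L)
  count <- function(traj) {
    count_hydrogen_bonds(traj, donors, acceptors = 3L)$mean
  }
  expect_equal(count(hbond_pair_traj(2.8, 0)), 1)
  expect_equal(count(hbond_pair_traj(4.0, 0)), 0)
  expect_equal(count(hbond_pair_traj(3.0, 35)), 0)
  expect_equal(count(hbond_pair_traj(3.0, 25)), 1)
})

test_that("hydrogen pairing by proximity finds donors from a predicate", {
  traj <- hbond_pair_traj(2.8, 0)
  got <- count_hydrogen_bonds(traj,
                              donors = function(a) a$element == "O",
                              acceptors = function(a) a$element == "O")
  expect_equal(got$mean, 1)
})

test_that("structure summary applies the discard window correctly", {
  spec <- small_bilayer_spec(n_frames = 100, thermal_jitter_sd = 0.2)
  traj <- build_bilayer(spec)
  ss <- structure_summary(traj)
  expect_equal(ss$n_frames_used, 80)

  ss0 <- structure_summary(traj, discard_fraction = 0)
  expect_equal(ss0$n_frames_used, 100)
  expect_equal(ss0$apl$mean, area_per_lipid(traj)$mean)
  expect_equal(ss0$thickness$mean, bilayer_thickness(traj)$mean)
  expect_error(discard_initial(traj, 0.99), "discard_fraction")
})

test_that("stationary input: summary means equal single-frame values at zero jitter", {
  traj <- build_bilayer(small_bilayer_spec(n_frames = 6))
  one <- build_bilayer(small_bilayer_spec(n_frames = 1))
  ss <- structure_summary(traj, discard_fraction = 0.2)
  expect_equal(ss$apl$mean, area_per_lipid(one)$mean)
  expect_equal(ss$thickness$mean, bilayer_thickness(one)$mean)
  expect_equal(ss$apl$sd, 0)
})

test_that("tidy and glance expose the summary as tibbles", {
  ss <- structure_summary(build_bilayer(small_bilayer_spec()),
                          discard_fraction = 0)
  td <- tidy(ss)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$quantity,
                  c("area_per_lipid", "thickness", "f_ov", "hbond_count"))
  gl <- glance(ss)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$apl_mean, ss$apl$mean)
})
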