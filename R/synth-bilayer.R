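# Geometric bead-chain bilayer generator.
#
# Lipids are idealized: one head bead, two all-trans acyl chains (sn-1/sn-2)
# of point-mass carbons with two geometric hydrogens each, tilted by a fixed
# angle from the membrane normal. Only the analysis operators are under test,
# so no force-field realism is attempted; every structural observable of the
# construction (APL, thickness, interdigitation, SCD) is known in closed form.

C_H_BOND <- 1.09 # Angstrom

#' Specification of a synthetic bilayer
#'
#' Describes an idealized bilayer whose structural observables are known by
#' construction: lipids are bead-chains placed on a lateral grid with spacing
#' `sqrt(target_apl)`, acyl chains run from below the head bead toward the
#' midplane along an axis tilted by `tail_tilt_deg` from the membrane normal,
#' and the chain termini end `interdigitation_offset` Angstrom past the
#' midplane (values <= 0 leave the leaflets separated).
#'
#' @param lipid_types Data frame with columns `name`, `count_per_leaflet`,
#'   `n_tail_carbons` (carbons per chain; each lipid carries an sn-1 and an
#'   sn-2 chain), `head_mass`, `carbon_mass`, `hydrogen_mass` (amu).
#'   Default: a single DPPC-like species, 60 lipids per leaflet, 16 carbons.
#' @param target_apl Target area per lipid, Angstrom^2; the lateral box area
#'   is `N_per_leaflet * target_apl` exactly.
#' @param head_region_halfwidth Gap between the top tail carbon and the head
#'   bead, Angstrom. Ignored when `target_thickness` is given.
#' @param target_thickness Optional head-to-head bilayer thickness, Angstrom;
#'   back-solves `head_region_halfwidth` from the chain geometry.
#' @param tail_tilt_deg Chain tilt from the membrane normal, degrees in
#'   `[0, 90)`.
#' @param interdigitation_offset Distance the tail termini penetrate past the
#'   midplane, Angstrom.
#' @param carbon_spacing C-C spacing along the chain axis, Angstrom (its z
#'   projection is `carbon_spacing * cos(tilt)`).
#' @param n_frames Number of frames to emit.
#' @param thermal_jitter_sd Per-coordinate Gaussian jitter sd per frame,
#'   Angstrom.
#' @param probe_count,drug_count Numbers of single-bead probe (NO-like) and
#'   drug particles.
#' @param drug_insertion_depth Depth below the head plane at which drugs are
#'   placed, Angstrom (the insertion depth is a free parameter).
#' @param probe_mass,drug_mass Particle masses, amu.
#' @param water_margin Water slab half-thickness added above each head plane,
#'   Angstrom; sets the box height.
#' @param frame_dt Frame spacing, ps.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A list of class `bilayer_spec`.
#' @export
bilayer_spec <- function(lipid_types = NULL,
                         target_apl = 60,
                         head_region_halfwidth = 4,
                         target_thickness = NULL,
                         tail_tilt_deg = 0,
                         interdigitation_offset = -2,
                         carbon_spacing = 1.27,
                         n_frames = 5,
                         thermal_jitter_sd = 0.3,
                         probe_count = 0,
                         drug_count = 0,
                         drug_insertion_depth = 0,
                         probe_mass = 30.006,
                         drug_mass = 488.6,
                         water_margin = 15,
                         frame_dt = 10,
                         seed = 20240563) {
  if (is.null(lipid_types)) {
    lipid_types <- tibble(
      name = "DPPC", count_per_leaflet = 60, n_tail_carbons = 16,
      head_mass = 223.1, carbon_mass = 12.011, hydrogen_mass = 1.008
    )
  }
  lipid_types <- as_tibble(lipid_types)
  needed <- c("name", "count_per_leaflet", "n_tail_carbons", "head_mass",
              "carbon_mass", "hydrogen_mass")
  if (!all(needed %in% names(lipid_types))) {
    abort(paste("`lipid_types` needs columns:", paste(needed, collapse = ", ")))
  }
  check_number(target_apl, "target_apl", lower = 0, strict_lower = TRUE)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(thermal_jitter_sd, "thermal_jitter_sd", lower = 0)
  check_number(tail_tilt_deg, "tail_tilt_deg", lower = 0, upper = 90 - 1e-9)
  check_number(carbon_spacing, "carbon_spacing", lower = 0, strict_lower = TRUE)
  if (any(lipid_types$n_tail_carbons < 2)) abort("n_tail_carbons must be >= 2")
  if (any(lipid_types$count_per_leaflet < 1)) {
    abort("count_per_leaflet must be >= 1")
  }

  spec <- structure(
    list(lipid_types = lipid_types, target_apl = target_apl,
         head_region_halfwidth = head_region_halfwidth,
         target_thickness = target_thickness,
         tail_tilt_deg = tail_tilt_deg,
         interdigitation_offset = interdigitation_offset,
         carbon_spacing = carbon_spacing, n_frames = as.integer(n_frames),
         thermal_jitter_sd = thermal_jitter_sd,
         probe_count = as.integer(probe_count),
         drug_count = as.integer(drug_count),
         drug_insertion_depth = drug_insertion_depth,
         probe_mass = probe_mass, drug_mass = drug_mass,
         water_margin = water_margin, frame_dt = frame_dt,
         seed = as.integer(seed)),
    class = "bilayer_spec"
  )

  geom <- bilayer_geometry(spec)
  if (geom$head_region_halfwidth <= 0) {
    abort(sprintf(paste0(
      "negative geometry: target thickness %.2f A places the head plane ",
      "inside the chain region (chain top at %.2f A); increase thickness or ",
      "shorten the chains"), target_thickness %||% NA_real_, geom$z_top))
  }
  spec
}

# Closed-form construction geometry shared by the builder and tests.
bilayer_geometry <- function(spec) {
  n_max <- max(spec$lipid_types$n_tail_carbons)
  dz <- spec$carbon_spacing * cos(spec$tail_tilt_deg * pi / 180)
  z_term <- -spec$interdigitation_offset       # terminal carbon, upper leaflet
  z_top <- z_term + (n_max - 1) * dz           # top carbon, upper leaflet
  if (!is.null(spec$target_thickness)) {
    hw <- spec$target_thickness / 2 - z_top
  } else {
    hw <- spec$head_region_halfwidth
  }
  z_head <- z_top + hw
  n_leaflet <- sum(spec$lipid_types$count_per_leaflet)
  lxy <- sqrt(n_leaflet * spec$target_apl)
  list(dz = dz, z_term = z_term, z_top = z_top, z_head = z_head,
       head_region_halfwidth = hw, thickness = 2 * z_head,
       n_per_leaflet = n_leaflet, lxy = lxy,
       box_z = 2 * (z_head + spec$water_margin))
}

# Atom records and base coordinates for one lipid (upper leaflet), head at
# (x0, y0). Chains point down; hydrogens are perpendicular to the chain axis.
lipid_template <- function(type_row, x0, y0, geom, tilt_rad) {
  n <- type_row$n_tail_carbons
  u <- c(sin(tilt_rad), 0, -cos(tilt_rad))     # chain axis, pointing down
  e1 <- c(cos(tilt_rad), 0, sin(tilt_rad))     # in-plane perpendicular
  rows <- list()
  xyz <- list()
  add <- function(name, element, mass, role, chain, k, pos) {
    rows[[length(rows) + 1L]] <<- list(atom_name = name, element = element,
                                       mass = mass, role = role, chain = chain,
                                       carbon_index = k)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  add("P", "P", type_row$head_mass, "head_ref", NA_character_, NA_integer_,
      c(x0, y0, geom$z_head))
  for (chain_i in 1:2) {
    chain_lab <- c("sn-1", "sn-2")[chain_i]
    x_off <- c(-0.9, 0.9)[chain_i]
    top <- c(x0 + x_off, y0, geom$z_top)
    for (k in seq_len(n)) {
      # carbon k counts from the head end; terminal carbon reaches z_term
      pos <- top + (k - 1) * spec_step(u, geom)
      suffix <- c("A", "B")[chain_i]
      add(sprintf("C%d%s", k, suffix), "C", type_row$carbon_mass,
          "tail_carbon", chain_lab, k, pos)
      add(sprintf("H%d%s1", k, suffix), "H", type_row$hydrogen_mass,
          "tail_hydrogen", chain_lab, k, pos + C_H_BOND * e1)
      add(sprintf("H%d%s2", k, suffix), "H", type_row$hydrogen_mass,
          "tail_hydrogen", chain_lab, k, pos - C_H_BOND * e1)
    }
  }
  list(rows = dplyr::bind_rows(lapply(rows, as_tibble)),
       xyz = do.call(rbind, xyz))
}

spec_step <- function(u, geom) {
  # full 3-D C-C step whose z projection is geom$dz
  u * (geom$dz / abs(u[3]))
}

#' Build a synthetic bilayer trajectory
#'
#' Places the lipids of `spec` on a square-ish lateral grid (smallest
#' enclosing grid, vacancies allowed), mirrors the upper leaflet to form the
#' lower one, adds optional probe and drug particles, and emits `n_frames`
#' frames that differ only by seeded Gaussian thermal jitter. The lateral box
#' area equals `N_per_leaflet * target_apl` exactly, so the measured area per
#' lipid reproduces the spec at zero jitter.
#'
#' @param spec A [bilayer_spec()].
#' @return A [trajectory()].
#' @export
build_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  geom <- bilayer_geometry(spec)
  tilt_rad <- spec$tail_tilt_deg * pi / 180

  n_side <- ceiling(sqrt(geom$n_per_leaflet))
  pitch <- geom$lxy / n_side
  cells <- expand.grid(ix = seq_len(n_side) - 1L, iy = seq_len(n_side) - 1L)
  cells <- cells[seq_len(geom$n_per_leaflet), , drop = FALSE]
  type_of <- rep(seq_len(nrow(spec$lipid_types)),
                 times = spec$lipid_types$count_per_leaflet)

  atoms_list <- list()
  xyz_list <- list()
  res_id <- 0L
  add_molecule <- function(tbl, xyz, residue_name, molecule_class) {
    res_id <<- res_id + 1L
    tbl$residue_id <- res_id
    tbl$residue_name <- residue_name
    tbl$molecule_class <- molecule_class
    atoms_list[[length(atoms_list) + 1L]] <<- tbl
    xyz_list[[length(xyz_list) + 1L]] <<- xyz
  }

  for (leaflet in c("upper", "lower")) {
    for (i in seq_len(geom$n_per_leaflet)) {
      ty <- spec$lipid_types[type_of[i], ]
      x0 <- (cells$ix[i] + 0.5) * pitch
      y0 <- (cells$iy[i] + 0.5) * pitch
      tpl <- lipid_template(ty, x0, y0, geom, tilt_rad)
      xyz <- tpl$xyz
      if (leaflet == "lower") xyz[, 3] <- -xyz[, 3]
      add_molecule(tpl$rows, xyz, ty$name, "lipid")
    }
  }

  particle_tbl <- function(name, element, mass) {
    tibble(atom_name = name, element = element, mass = mass, role = "other",
           chain = NA_character_, carbon_index = NA_integer_)
  }

  rng <- particle_rng(spec$seed)
  if (spec$probe_count > 0) {
    for (p in seq_len(spec$probe_count)) {
      # probes start in the water slab above the upper head plane
      z <- geom$z_head + 2 + rng() * (spec$water_margin - 4)
      add_molecule(particle_tbl("NO", "N", spec$probe_mass),
                   matrix(c(rng() * geom$lxy, rng() * geom$lxy, z), 1),
                   "NO", "probe")
    }
  }
  if (spec$drug_count > 0) {
    for (d in seq_len(spec$drug_count)) {
      side <- if (d %% 2L == 0L) -1 else 1    # alternate leaflets
      z <- side * (geom$z_head - spec$drug_insertion_depth)
      add_molecule(particle_tbl("DRG", "X", spec$drug_mass),
                   matrix(c(rng() * geom$lxy, rng() * geom$lxy, z), 1),
                   "DRG", "drug")
    }
  }

  atoms <- dplyr::bind_rows(atoms_list)
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms <- dplyr::relocate(atoms, "atom_id")
  base <- do.call(rbind, xyz_list)

  nf <- spec$n_frames
  coords <- array(0, dim = c(nrow(base), 3, nf))
  jit <- jitter_stream(spec$seed + 1L, length(base) * nf,
                       spec$thermal_jitter_sd)
  for (f in seq_len(nf)) {
    noise <- matrix(jit[((f - 1) * length(base) + 1):(f * length(base))],
                    ncol = 3)
    coords[, , f] <- base + noise
  }
  box <- matrix(rep(c(geom$lxy, geom$lxy, geom$box_z), each = nf), ncol = 3)
  trajectory(atoms, coords, box, times = (seq_len(nf) - 1) * spec$frame_dt)
}

# Self-contained RNG streams so the builder never touches .Random.seed.
particle_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  state$draws <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    stats::runif(4096)
  })
  state$i <- 0L
  function() {
    state$i <- state$i + 1L
    state$draws[[state$i]]
  }
}

jitter_stream <- function(seed, n, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Total generated mass implied by a bilayer spec
#'
#' Exact mass bookkeeping for the builder: per lipid, one head bead plus two
#' chains of `n_tail_carbons` carbons carrying two hydrogens each, plus any
#' probe and drug particles.
#'
#' @param spec A [bilayer_spec()].
#' @return Mass in amu.
#' @export
expected_total_mass <- function(spec) {
  per_lipid <- spec$lipid_types$head_mass +
    2 * spec$lipid_types$n_tail_carbons *
      (spec$lipid_types$carbon_mass + 2 * spec$lipid_types$hydrogen_mass)
  2 * sum(spec$lipid_types$count_per_leaflet * per_lipid) +
    spec$probe_count * spec$probe_mass + spec$drug_count * spec$drug_mass
}
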