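# Shared fixtures: small synthetic systems built in code.

small_bilayer_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    lipid_types = tibble::tibble(
      name = "DPPC", count_per_leaflet = 16, n_tail_carbons = 6,
      head_mass = 223.1, carbon_mass = 12.011, hydrogen_mass = 1.008
    ),
    target_apl = 60, n_frames = 4, thermal_jitter_sd = 0
  )
  do.call(bilayer_spec, utils::modifyList(defaults, args))
}

# Minimal hand-built trajectory: lipids are a single head bead each.
head_only_traj <- function(z_heads, box = c(50, 50, 80)) {
  n <- length(z_heads)
  atoms <- tibble::tibble(
    atom_id = seq_len(n), atom_name = "P", element = "P", mass = 94.97,
    residue_id = seq_len(n), residue_name = "LIP",
    molecule_class = "lipid", role = "head_ref",
    chain = NA_character_, carbon_index = NA_integer_
  )
  coords <- array(0, dim = c(n, 3, 1))
  coords[, 3, 1] <- z_heads
  trajectory(atoms, coords, box, times = 0)
}

# Water-like triatomic pair for hydrogen-bond geometry: donor oxygen at the
# origin with one H aimed off-axis by `angle_deg`, acceptor oxygen at
# distance `d_oo` along +x.
hbond_pair_traj <- function(d_oo, angle_deg = 0, box = c(60, 60, 60)) {
  h <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0) * 0.96
  atoms <- tibble::tibble(
    atom_id = 1:3,
    atom_name = c("OW", "HW1", "OW"),
    element = c("O", "H", "O"),
    mass = c(15.999, 1.008, 15.999),
    residue_id = c(1L, 1L, 2L),
    residue_name = "SOL",
    molecule_class = "solvent",
    role = "other",
    chain = NA_character_,
    carbon_index = NA_integer_
  )
  coords <- array(0, dim = c(3, 3, 1))
  coords[1, , 1] <- c(0, 0, 0)
  coords[2, , 1] <- h
  coords[3, , 1] <- c(d_oo, 0, 0)
  trajectory(atoms, coords, box, times = 0)
}

# Uniform box-profile pair on a shared grid for interdigitation closed forms.
uniform_profile <- function(z, lo, hi, height) {
  tibble::tibble(z = z, density = ifelse(z >= lo & z <= hi, height, 0))
}
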