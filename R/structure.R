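# Bilayer structural observables: leaflet assignment, mass-density profiles,
# area per lipid, thickness, leaflet interdigitation, order parameters,
# geometric hydrogen bonds, and the summary record that gathers them.

#' Standard atom selections
#'
#' Predicates (functions of the atom table returning a logical vector) for
#' the selections used throughout: lipid headgroups and lipid tails.
#'
#' @name selections
#' @return A logical vector of length `nrow(atoms)`.
NULL

#' @rdname selections
#' @param atoms Atom tibble of a [trajectory()].
#' @export
sel_heads <- function(atoms) {
  atoms$molecule_class == "lipid" & atoms$role %in% c("head_ref", "phosphate")
}

#' @rdname selections
#' @export
sel_tails <- function(atoms) {
  atoms$molecule_class == "lipid" &
    atoms$role %in% c("tail_carbon", "tail_hydrogen")
}

#' Assign lipids to leaflets
#'
#' A lipid belongs to the upper leaflet iff its head-reference atom lies
#' above the midplane (the mean head-reference z over all lipids) in the
#' given frame. A head exactly at the midplane is assigned to the lower
#' leaflet, with a warning: determinism over elegance.
#'
#' @param traj A [trajectory()].
#' @param frame Frame index used for the assignment (default 1).
#' @param check_flips If `TRUE`, re-assign on every frame and warn when any
#'   lipid changes leaflet between frames.
#' @return Tibble with `residue_id` and `leaflet` (`"upper"`/`"lower"`).
#' @export
assign_leaflets <- function(traj, frame = 1L, check_flips = FALSE) {
  atoms <- traj$atoms
  lipids <- unique(atoms$residue_id[atoms$molecule_class == "lipid"])
  heads <- atoms[atoms$role == "head_ref" & atoms$molecule_class == "lipid", ]
  missing <- setdiff(lipids, heads$residue_id)
  if (length(missing)) {
    abort(paste0("lipid residue(s) without a head_ref atom: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  assign_one <- function(f) {
    z <- traj$coords[heads$atom_id, 3, f]
    midplane <- mean(z)
    if (any(z == midplane)) {
      warn("head_ref exactly at the midplane: assigned to the lower leaflet")
    }
    ifelse(z > midplane, "upper", "lower")
  }
  lab <- assign_one(frame)
  if (check_flips && n_frames(traj) > 1L) {
    labs <- vapply(seq_len(n_frames(traj)), assign_one,
                   character(nrow(heads)))
    flips <- apply(labs, 1, function(r) length(unique(r)) > 1L)
    if (any(flips)) {
      warn(sprintf("%d lipid(s) change leaflet between frames", sum(flips)))
    }
  }
  tibble(residue_id = heads$residue_id, leaflet = lab)
}

# Midplane (mean head_ref z) per frame; used to re-centre all z-binned
# quantities so box drift never smears the profiles.
frame_midplanes <- function(traj) {
  heads <- which(traj$atoms$role == "head_ref" &
                   traj$atoms$molecule_class == "lipid")
  if (!length(heads)) return(rep(0, n_frames(traj)))
  vapply(seq_len(n_frames(traj)),
         function(f) mean(traj$coords[heads, 3, f]), numeric(1))
}

#' Mass density profile along the membrane normal
#'
#' Bins atom masses along z (re-centred so the midplane is 0 in every frame),
#' divides by the bin volume `Lx * Ly * bin_width`, and averages over frames.
#' The integral of each profile times the lateral area recovers the mean
#' selected mass per frame exactly (trapezoid on bin centers, to within the
#' half-bin edges).
#'
#' @param traj A [trajectory()].
#' @param selections Named list of predicates (see [sel_heads()]); default
#'   `list(heads = sel_heads, tails = sel_tails)`.
#' @param bin_width Bin width, Angstrom (default 0.5: fine enough to resolve
#'   ~1.4 Angstrom thickness changes).
#' @param recenter Re-centre z on the per-frame midplane (default `TRUE`).
#' @return A tibble of class `density_profile` with columns `z`, `label`,
#'   `density` (amu/Angstrom^3) and attributes `bin_width`, `frame_count`,
#'   `lateral_area`.
#' @export
density_profile <- function(traj,
                            selections = list(heads = sel_heads,
                                              tails = sel_tails),
                            bin_width = 0.5,
                            recenter = TRUE) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (is.null(names(selections)) || any(names(selections) == "")) {
    abort("`selections` must be a named list of predicates")
  }
  nf <- n_frames(traj)
  mid <- if (recenter) frame_midplanes(traj) else rep(0, nf)

  sel_idx <- lapply(selections, function(p) which(p(traj$atoms)))
  for (lab in names(sel_idx)) {
    if (!length(sel_idx[[lab]])) {
      warn(sprintf("selection '%s' matches no atoms; profile is zero", lab))
    }
  }

  all_z <- sweep(traj$coords[, 3, , drop = FALSE][, 1, , drop = TRUE] |>
                   matrix(nrow = n_atoms(traj)), 2, mid)
  zmin <- min(all_z); zmax <- max(all_z)
  e0 <- (floor(zmin / bin_width) - 1L) * bin_width
  n_bins <- ceiling((zmax - e0) / bin_width) + 1L
  centers <- e0 + (seq_len(n_bins) - 0.5) * bin_width

  area <- traj$box[, 1] * traj$box[, 2]
  out <- list()
  for (lab in names(sel_idx)) {
    idx <- sel_idx[[lab]]
    dens <- numeric(n_bins)
    if (length(idx)) {
      m <- traj$atoms$mass[idx]
      for (f in seq_len(nf)) {
        b <- floor((all_z[idx, f] - e0) / bin_width) + 1L
        acc <- numeric(n_bins)
        s <- rowsum(m, b)
        acc[as.integer(rownames(s))] <- s[, 1]
        dens <- dens + acc / (area[f] * bin_width)
      }
    }
    out[[lab]] <- tibble(z = centers, label = lab, density = dens / nf)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("density_profile", class(res))
  attr(res, "bin_width") <- bin_width
  attr(res, "frame_count") <- nf
  attr(res, "lateral_area") <- mean(area)
  res
}

#' Leaflet-resolved lipid-tail density profiles
#'
#' Convenience wrapper producing the two tail profiles (upper and lower
#' leaflet) on a shared grid, as needed by [interdigitation_fraction()].
#'
#' @inheritParams density_profile
#' @return A `density_profile` tibble with labels `"upper"` and `"lower"`.
#' @export
leaflet_tail_profiles <- function(traj, bin_width = 0.5) {
  leaf <- assign_leaflets(traj)
  upper_res <- leaf$residue_id[leaf$leaflet == "upper"]
  density_profile(
    traj,
    selections = list(
      upper = function(a) sel_tails(a) & a$residue_id %in% upper_res,
      lower = function(a) sel_tails(a) & !(a$residue_id %in% upper_res)
    ),
    bin_width = bin_width
  )
}

#' Area per lipid
#'
#' Projected-area convention: per frame, `APL = 2 Lx Ly / N_lipids`. With
#' asymmetric leaflet populations the per-leaflet form `Lx Ly / N_leaflet`
#' is used and both leaflets are reported.
#'
#' @param traj A [trajectory()].
#' @return One-row tibble with `mean`, `sd` (Angstrom^2) and `n_frames`; for
#'   asymmetric leaflets, one row per leaflet.
#' @export
area_per_lipid <- function(traj) {
  leaf <- assign_leaflets(traj)
  n_up <- sum(leaf$leaflet == "upper")
  n_lo <- sum(leaf$leaflet == "lower")
  if (n_up + n_lo == 0L) abort("no lipids in trajectory")
  area <- traj$box[, 1] * traj$box[, 2]
  if (n_up == n_lo) {
    apl <- 2 * area / (n_up + n_lo)
    st <- mean_sd(apl)
    tibble(leaflet = "both", mean = st$mean, sd = st$sd,
           n_frames = n_frames(traj))
  } else {
    warn(sprintf("asymmetric leaflets (%d vs %d): reporting per leaflet",
                 n_up, n_lo))
    dplyr::bind_rows(lapply(
      list(c("upper", n_up), c("lower", n_lo)),
      function(v) {
        st <- mean_sd(area / as.numeric(v[2]))
        tibble(leaflet = v[1], mean = st$mean, sd = st$sd,
               n_frames = n_frames(traj))
      }
    ))
  }
}

#' Bilayer thickness
#'
#' Per frame, the distance along z between the mean positions of the two
#' leaflets' reference atoms (phosphate where present, otherwise the
#' head-reference beads).
#'
#' @param traj A [trajectory()].
#' @param reference_roles Roles accepted as the reference plane, tried in
#'   order.
#' @return One-row tibble with `mean`, `sd` (Angstrom) and `n_frames`.
#' @export
bilayer_thickness <- function(traj,
                              reference_roles = c("phosphate", "head_ref")) {
  atoms <- traj$atoms
  ref_role <- NULL
  for (r in reference_roles) {
    if (any(atoms$role == r & atoms$molecule_class == "lipid")) {
      ref_role <- r
      break
    }
  }
  if (is.null(ref_role)) {
    abort(paste("no reference atoms with role(s):",
                paste(reference_roles, collapse = ", ")))
  }
  leaf <- assign_leaflets(traj)
  refs <- atoms[atoms$role == ref_role & atoms$molecule_class == "lipid", ]
  refs <- dplyr::left_join(refs, leaf, by = "residue_id")
  up <- refs$atom_id[refs$leaflet == "upper"]
  lo <- refs$atom_id[refs$leaflet == "lower"]
  if (!length(up) || !length(lo)) {
    abort("one leaflet has no reference atoms; cannot measure thickness")
  }
  delta <- vapply(seq_len(n_frames(traj)), function(f) {
    mean(traj$coords[up, 3, f]) - mean(traj$coords[lo, 3, f])
  }, numeric(1))
  st <- mean_sd(delta)
  tibble(mean = st$mean, sd = st$sd, n_frames = n_frames(traj))
}

#' Leaflet interdigitation as a fraction of mass overlap
#'
#' `f_ov = integral min(rho_U, rho_L) dz / (0.5 integral (rho_U + rho_L) dz)`
#' on the shared grid (trapezoidal rule); identically 1 for identical
#' profiles, 0 for disjoint supports.
#'
#' @param profile_upper,profile_lower Either two data frames with columns
#'   `z` and `density` on the same grid, or a single `density_profile` with
#'   labels `"upper"`/`"lower"` passed as `profile_upper`.
#' @return `f_ov` in `[0, 1]`.
#' @export
interdigitation_fraction <- function(profile_upper, profile_lower = NULL) {
  if (is.null(profile_lower)) {
    if (!all(c("upper", "lower") %in% profile_upper$label)) {
      abort("single-argument form needs labels 'upper' and 'lower'")
    }
    profile_lower <- profile_upper[profile_upper$label == "lower", ]
    profile_upper <- profile_upper[profile_upper$label == "upper", ]
  }
  if (nrow(profile_upper) != nrow(profile_lower) ||
      max(abs(profile_upper$z - profile_lower$z)) > 1e-9) {
    abort("profiles must share the same z grid")
  }
  z <- profile_upper$z
  u <- profile_upper$density
  l <- profile_lower$density
  total <- 0.5 * trapz_int(z, u + l)
  if (total <= 0) abort("zero total mass in the leaflet profiles")
  f_ov <- trapz_int(z, pmin(u, l)) / total
  min(max(f_ov, 0), 1)
}

#' Interdigitation ratio D_int
#'
#' Ratio of the mass-overlap fraction in the presence vs absence of a
#' modifying agent. The absolute `f_ov` convention cancels to first order in
#' the ratio, which is what carries between analyses.
#'
#' @param treated_f_ov,control_f_ov Overlap fractions.
#' @return One-row tibble `d_int`, `treated_f_ov`, `control_f_ov`.
#' @export
interdigitation_ratio <- function(treated_f_ov, control_f_ov) {
  check_number(treated_f_ov, "treated_f_ov", lower = 0)
  if (!is.numeric(control_f_ov) || length(control_f_ov) != 1L ||
      is.na(control_f_ov) || control_f_ov <= 0) {
    abort("control f_ov must be > 0: the ratio is undefined at zero")
  }
  tibble(d_int = treated_f_ov / control_f_ov,
         treated_f_ov = treated_f_ov, control_f_ov = control_f_ov)
}

#' Deuterium order parameters |SCD| per tail carbon
#'
#' `SCD_k = <(3 cos^2 theta - 1) / 2>` over frames, lipids and the carbon's
#' hydrogens, with theta the angle between the C->H vector and the +z axis;
#' reported per chain (sn-1 / sn-2) as the signed value and its magnitude.
#'
#' @param traj A [trajectory()].
#' @return Tibble of class `scd_profile` with `chain`, `carbon_index`,
#'   `scd`, `abs_scd`, `n_samples`. Carbons lacking hydrogens are omitted
#'   and named in a message.
#' @export
order_parameters <- function(traj) {
  atoms <- traj$atoms
  carbons <- atoms[atoms$role == "tail_carbon", ]
  hydro <- atoms[atoms$role == "tail_hydrogen", ]
  if (!nrow(carbons)) abort("no tail_carbon atoms in trajectory")
  pairs <- dplyr::inner_join(
    carbons[, c("atom_id", "residue_id", "chain", "carbon_index")],
    hydro[, c("atom_id", "residue_id", "chain", "carbon_index")],
    by = c("residue_id", "chain", "carbon_index"),
    suffix = c("_c", "_h"), relationship = "one-to-many"
  )
  key_all <- unique(carbons[, c("chain", "carbon_index")])
  key_have <- unique(pairs[, c("chain", "carbon_index")])
  missing <- dplyr::anti_join(key_all, key_have,
                              by = c("chain", "carbon_index"))
  if (nrow(missing)) {
    inform(paste0("carbons without hydrogens omitted from SCD: ",
                  paste(sprintf("%s C%d", missing$chain,
                                missing$carbon_index), collapse = ", ")))
  }
  grp <- interaction(pairs$chain, pairs$carbon_index, drop = TRUE)
  acc <- numeric(nlevels(grp))
  n_acc <- 0L
  for (f in seq_len(n_frames(traj))) {
    d <- traj$coords[pairs$atom_id_h, , f] - traj$coords[pairs$atom_id_c, , f]
    cosz <- d[, 3] / sqrt(rowSums(d^2))
    val <- (3 * cosz^2 - 1) / 2
    acc <- acc + as.vector(rowsum(val, grp)) / as.vector(table(grp))
    n_acc <- n_acc + 1L
  }
  lev <- levels(grp)
  parts <- do.call(rbind, strsplit(lev, ".", fixed = TRUE))
  res <- tibble(
    chain = parts[, 1],
    carbon_index = as.integer(parts[, 2]),
    scd = acc / n_acc,
    n_samples = as.vector(table(grp)) * n_acc
  )
  res$abs_scd <- abs(res$scd)
  res <- dplyr::arrange(res, .data$chain, .data$carbon_index)
  class(res) <- c("scd_profile", class(res))
  res
}

#' Count geometric hydrogen bonds
#'
#' A donor-hydrogen-acceptor triplet is a hydrogen bond when the
#' donor-acceptor distance is at most `dist_cutoff` and the H-D-A angle at
#' most `angle_cutoff` (minimum-image convention applied in xy). Hydrogens
#' are attached to donors by proximity in the first frame (nearest
#' donor-eligible heavy atom within 1.3 Angstrom).
#'
#' @param traj A [trajectory()].
#' @param donors Predicate selecting donor heavy atoms, or a data frame with
#'   columns `donor` and `hydrogen` (atom ids) fixing the pairing
#'   explicitly.
#' @param acceptors Predicate selecting acceptor atoms, or a vector of atom
#'   ids.
#' @param dist_cutoff Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cutoff H-D-A angle cutoff, degrees.
#' @return One-row tibble with `mean`, `sd`, `n_frames`.
#' @export
count_hydrogen_bonds <- function(traj, donors, acceptors,
                                 dist_cutoff = 3.5, angle_cutoff = 30) {
  atoms <- traj$atoms
  if (is.data.frame(donors)) {
    dh <- tibble(donor = donors$donor, hydrogen = donors$hydrogen)
  } else {
    d_idx <- which(donors(atoms))
    h_idx <- which(atoms$element == "H")
    if (!length(d_idx)) {
      dh <- tibble(donor = integer(), hydrogen = integer())
    } else {
      pair <- lapply(h_idx, function(h) {
        dvec <- traj$coords[d_idx, , 1, drop = FALSE][, , 1, drop = TRUE]
        if (length(d_idx) == 1L) dvec <- matrix(dvec, nrow = 1)
        dist <- sqrt(rowSums(sweep(dvec, 2, traj$coords[h, , 1])^2))
        j <- which.min(dist)
        if (dist[j] <= 1.3) c(d_idx[j], h) else NULL
      })
      pair <- do.call(rbind, pair[!vapply(pair, is.null, logical(1))])
      dh <- if (is.null(pair)) tibble(donor = integer(), hydrogen = integer())
            else tibble(donor = pair[, 1], hydrogen = pair[, 2])
    }
  }
  a_idx <- if (is.function(acceptors)) which(acceptors(atoms))
           else as.integer(acceptors)
  nf <- n_frames(traj)
  if (!nrow(dh) || !length(a_idx)) {
    return(tibble(mean = 0, sd = 0, n_frames = nf))
  }
  cos_cut <- cos(angle_cutoff * pi / 180)
  counts <- vapply(seq_len(nf), function(f) {
    cnt <- 0L
    for (i in seq_len(nrow(dh))) {
      d <- dh$donor[i]; h <- dh$hydrogen[i]
      aa <- setdiff(a_idx, d)
      if (!length(aa)) next
      da <- traj$coords[aa, , f, drop = FALSE][, , 1, drop = TRUE]
      if (length(aa) == 1L) da <- matrix(da, nrow = 1)
      vda <- sweep(da, 2, traj$coords[d, , f])
      vda[, 1] <- min_image(vda[, 1], traj$box[f, 1])
      vda[, 2] <- min_image(vda[, 2], traj$box[f, 2])
      dist <- sqrt(rowSums(vda^2))
      vdh <- traj$coords[h, , f] - traj$coords[d, , f]
      vdh[1] <- min_image(vdh[1], traj$box[f, 1])
      vdh[2] <- min_image(vdh[2], traj$box[f, 2])
      cosang <- (vda %*% vdh) / (dist * sqrt(sum(vdh^2)))
      cnt <- cnt + sum(dist <= dist_cutoff & cosang >= cos_cut)
    }
    as.integer(cnt)
  }, integer(1))
  st <- mean_sd(counts)
  tibble(mean = st$mean, sd = st$sd, n_frames = nf)
}

#' Structural summary of a bilayer trajectory
#'
#' Applies the initial-discard window (default: first 20% of frames, the
#' equilibration share of a typical production run), then gathers area per
#' lipid, thickness, interdigitation fraction and (optionally) hydrogen
#' bonds into one record. All means and standard deviations are over the
#' retained frames.
#'
#' @param traj A [trajectory()].
#' @param discard_fraction Initial fraction of frames discarded.
#' @param bin_width Profile bin width, Angstrom.
#' @param hbond_donors,hbond_acceptors Optional donor/acceptor arguments for
#'   [count_hydrogen_bonds()]; when `NULL` the hydrogen-bond count is `NA`.
#' @return An object of class `structure_summary`.
#' @export
structure_summary <- function(traj, discard_fraction = 0.2, bin_width = 0.5,
                              hbond_donors = NULL, hbond_acceptors = NULL) {
  kept <- discard_initial(traj, discard_fraction)
  apl <- area_per_lipid(kept)
  thick <- bilayer_thickness(kept)
  prof <- leaflet_tail_profiles(kept, bin_width = bin_width)
  f_ov <- interdigitation_fraction(prof)
  hb <- if (!is.null(hbond_donors) && !is.null(hbond_acceptors)) {
    count_hydrogen_bonds(kept, hbond_donors, hbond_acceptors)
  } else {
    tibble(mean = NA_real_, sd = NA_real_, n_frames = n_frames(kept))
  }
  structure(
    list(apl = apl, thickness = thick, f_ov = f_ov, hbond = hb,
         tail_profiles = prof,
         discard_fraction_applied = discard_fraction,
         n_frames_used = n_frames(kept)),
    class = "structure_summary"
  )
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("<structure_summary>\n")
  cat(sprintf("  APL       %.2f +/- %.2f A^2\n",
              x$apl$mean[1], x$apl$sd[1]))
  cat(sprintf("  thickness %.2f +/- %.2f A\n",
              x$thickness$mean, x$thickness$sd))
  cat(sprintf("  f_ov      %.4f\n", x$f_ov))
  if (!is.na(x$hbond$mean)) {
    cat(sprintf("  H-bonds   %.2f +/- %.2f\n", x$hbond$mean, x$hbond$sd))
  }
  cat(sprintf("  frames used %d (discard %.0f%%)\n", x$n_frames_used,
              100 * x$discard_fraction_applied))
  invisible(x)
}

#' Treated-minus-control structural differences
#'
#' The drug-minus-control differences of area per lipid and thickness that
#' a comparative membrane study tabulates.
#'
#' @param treated,control `structure_summary` objects.
#' @param label Row label for the treated condition.
#' @return One-row tibble with `label`, `d_apl`, `d_thickness`, `d_int`.
#' @export
structure_delta <- function(treated, control, label = "treated") {
  stopifnot(inherits(treated, "structure_summary"),
            inherits(control, "structure_summary"))
  tibble(
    label = label,
    d_apl = treated$apl$mean[1] - control$apl$mean[1],
    d_thickness = treated$thickness$mean - control$thickness$mean,
    # the ratio is undefined for a non-interdigitated control
    d_int = if (control$f_ov > 0) {
      interdigitation_ratio(treated$f_ov, control$f_ov)$d_int
    } else NA_real_
  )
}
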