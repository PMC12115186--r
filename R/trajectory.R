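#' Trajectory container
#'
#' A trajectory couples an atom table with time-ordered coordinates and
#' per-frame box dimensions. Coordinates are stored as an
#' `n_atoms x 3 x n_frames` array in Angstrom; boxes as an `n_frames x 3`
#' matrix (orthorhombic Lx, Ly, Lz, Angstrom); times in ps.
#'
#' The atom table is a tibble with columns `atom_id`, `atom_name`, `element`,
#' `mass` (amu), `residue_id`, `residue_name`, `molecule_class` (one of
#' `"lipid"`, `"probe"`, `"drug"`, `"solvent"`), `role` (one of `"head_ref"`,
#' `"phosphate"`, `"tail_carbon"`, `"tail_hydrogen"`, `"other"`), `chain`
#' (`"sn-1"`/`"sn-2"` or `NA`) and `carbon_index` (position along the acyl
#' chain, or `NA`).
#'
#' @param atoms Atom tibble as described above.
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param box Numeric matrix `n_frames x 3` of box lengths in Angstrom.
#' @param times Numeric vector of frame times in ps.
#' @return An object of class `bilayr_traj`.
#' @export
trajectory <- function(atoms, coords, box, times) {
  atoms <- as_tibble(atoms)
  required <- c("atom_id", "atom_name", "element", "mass", "residue_id",
                "residue_name", "molecule_class", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- NA_character_
  if (!"carbon_index" %in% names(atoms)) atoms$carbon_index <- NA_integer_
  if (any(atoms$mass <= 0)) abort("all atom masses must be > 0")
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort("`coords` must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    abort(sprintf("coordinate count (%d) does not match atom-table length (%d)",
                  dim(coords)[1], nrow(atoms)))
  }
  box <- matrix(as.numeric(box), ncol = 3)
  n_frames <- dim(coords)[3]
  if (nrow(box) == 1L) box <- box[rep(1L, n_frames), , drop = FALSE]
  if (nrow(box) != n_frames) abort("`box` must have one row per frame")
  if (any(box <= 0)) abort("box lengths must be > 0")
  if (length(times) != n_frames) abort("`times` must have one entry per frame")
  structure(
    list(atoms = atoms, coords = coords, box = box, times = as.numeric(times)),
    class = "bilayr_traj"
  )
}

#' @export
print.bilayr_traj <- function(x, ...) {
  cat(sprintf("<bilayr_traj> %d atoms, %d frames, %.1f-%.1f ps\n",
              n_atoms(x), n_frames(x), x$times[1], x$times[n_frames(x)]))
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  cls <- table(x$atoms$molecule_class)
  cat("  atoms by class:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_atoms <- function(traj) dim(traj$coords)[1]

#' Convert a trajectory to a long tibble
#'
#' One row per atom per frame, with frame index, time and coordinates joined
#' to the atom table. Convenient for dplyr/ggplot2 work; the compact array
#' form stays the computational representation.
#'
#' @param x A [trajectory()].
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.bilayr_traj <- function(x, ...) {
  nf <- n_frames(x)
  na <- n_atoms(x)
  out <- x$atoms[rep(seq_len(na), nf), ]
  out$frame <- rep(seq_len(nf), each = na)
  out$time <- rep(x$times, each = na)
  out$x <- as.vector(x$coords[, 1, ])
  out$y <- as.vector(x$coords[, 2, ])
  out$z <- as.vector(x$coords[, 3, ])
  as_tibble(out)
}

#' Keep a trailing window of frames
#'
#' Drops the first `discard_fraction` of frames (equilibration window); used
#' by the summary functions so that averages cover only the production part
#' of a run.
#'
#' @param traj A [trajectory()].
#' @param discard_fraction Fraction of initial frames to drop, in `[0, 0.9]`.
#' @return A [trajectory()] restricted to the retained frames.
#' @export
discard_initial <- function(traj, discard_fraction = 0.2) {
  check_number(discard_fraction, "discard_fraction", lower = 0, upper = 0.9)
  nf <- n_frames(traj)
  first <- floor(nf * discard_fraction) + 1L
  if (first > nf) abort("discard window removes every frame")
  keep <- seq.int(first, nf)
  trajectory(traj$atoms, traj$coords[, , keep, drop = FALSE],
             traj$box[keep, , drop = FALSE], traj$times[keep])
}
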