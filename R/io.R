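# File-format boundary: multi-frame GRO (nm in file, Angstrom in memory),
# multi-MODEL PDB, extended XYZ with a Lattice= comment, role-table CSV and
# two-column thermogram CSV. All parsers are fixed-column/line-oriented and
# are held to write -> read round-trip tests.

#' Write a trajectory as multi-frame GRO
#'
#' Coordinates are converted Angstrom -> nm at the boundary and written with
#' the format's three decimals; the orthorhombic box closes each frame.
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_gro <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("synthetic bilayer t= %.3f", traj$times[f]), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- traj$coords[, , f] / 10
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_id %% 100000L,
                       substr(a$residue_name, 1, 5),
                       substr(a$atom_name, 1, 5),
                       a$atom_id %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1] / 10,
                       traj$box[f, 2] / 10, traj$box[f, 3] / 10), con)
  }
  invisible(path)
}

read_gro_frames <- function(lines) {
  i <- 1L
  frames <- list()
  n_total <- length(lines)
  while (i <= n_total && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) abort(sprintf("frame %d: bad atom-count line", length(frames) + 1L))
    if (i + 1L + nat + 1L > n_total) {
      abort(sprintf("frame %d: file truncated", length(frames) + 1L))
    }
    rows <- lines[(i + 2L):(i + 1L + nat)]
    boxline <- strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]
    time <- if (grepl("t=", title)) {
      as.numeric(sub(".*t=\\s*([0-9eE.+-]+).*", "\\1", title))
    } else NA_real_
    frames[[length(frames) + 1L]] <- list(
      time = time,
      residue_id = as.integer(substr(rows, 1, 5)),
      residue_name = trimws(substr(rows, 6, 10)),
      atom_name = trimws(substr(rows, 11, 15)),
      atom_id = as.integer(substr(rows, 16, 20)),
      x = as.numeric(substr(rows, 21, 28)) * 10,
      y = as.numeric(substr(rows, 29, 36)) * 10,
      z = as.numeric(substr(rows, 37, 44)) * 10,
      box = as.numeric(boxline[1:3]) * 10
    )
    i <- i + nat + 3L
  }
  frames
}

read_pdb_frames <- function(lines) {
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cryst)) {
    abort("PDB has no CRYST1 record; box dimensions are required")
  }
  box <- c(as.numeric(substr(cryst[1], 7, 15)),
           as.numeric(substr(cryst[1], 16, 24)),
           as.numeric(substr(cryst[1], 25, 33)))
  model_starts <- grep("^MODEL", lines)
  atom_re <- "^(ATOM  |HETATM)"
  parse_block <- function(block) {
    rows <- block[grepl(atom_re, block)]
    list(
      time = NA_real_,
      residue_id = as.integer(substr(rows, 23, 26)),
      residue_name = trimws(substr(rows, 18, 21)),
      atom_name = trimws(substr(rows, 13, 16)),
      atom_id = as.integer(substr(rows, 7, 11)),
      x = as.numeric(substr(rows, 31, 38)),
      y = as.numeric(substr(rows, 39, 46)),
      z = as.numeric(substr(rows, 47, 54)),
      box = box
    )
  }
  if (!length(model_starts)) return(list(parse_block(lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(model_starts)) {
    abort("unbalanced MODEL/ENDMDL records")
  }
  purrr::map2(model_starts, ends, function(s, e) parse_block(lines[s:e]))
}

read_xyz_frames <- function(lines) {
  i <- 1L
  frames <- list()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort("extended XYZ: bad atom-count line")
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexpr('Lattice="[^"]+"', comment))
    if (!length(m)) abort("extended XYZ: comment line lacks Lattice=\"...\"")
    lat <- as.numeric(strsplit(sub('Lattice="([^"]+)"', "\\1", m),
                               "\\s+")[[1]])
    if (length(lat) != 9L) abort("extended XYZ: Lattice must have 9 numbers")
    tm <- regmatches(comment, regexpr("Time=[0-9eE.+-]+", comment))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    frames[[length(frames) + 1L]] <- list(
      time = if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA_real_,
      residue_id = seq_len(nat),
      residue_name = vapply(rows, `[`, character(1), 1),
      atom_name = vapply(rows, `[`, character(1), 1),
      atom_id = seq_len(nat),
      x = vapply(rows, function(r) as.numeric(r[2]), numeric(1)),
      y = vapply(rows, function(r) as.numeric(r[3]), numeric(1)),
      z = vapply(rows, function(r) as.numeric(r[4]), numeric(1)),
      box = lat[c(1, 5, 9)]
    )
    i <- i + 2L + nat
  }
  frames
}

#' Read a trajectory file
#'
#' Supports multi-frame GRO (fixed columns, nm converted to Angstrom, box on
#' the last line of each frame), multi-MODEL PDB (CRYST1 box required) and
#' extended XYZ (orthorhombic `Lattice="..."` comment). Roles and masses
#' come from `role_table` (see [read_role_table()]); without one, every atom
#' gets role `"other"` and unit mass.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param role_table Optional role mapping from [read_role_table()].
#' @param frame_dt Fallback frame spacing (ps) when the file carries no
#'   times; used with a warning.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                            role_table = NULL, frame_dt = 10) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", xyz = "xyz",
                     abort(sprintf(
                       "unknown trajectory format '%s'; supported: gro, pdb, xyz",
                       ext)))
  }
  lines <- readLines(path)
  frames <- switch(format,
                   gro = read_gro_frames(lines),
                   pdb = read_pdb_frames(lines),
                   xyz = read_xyz_frames(lines))
  if (!length(frames)) abort("no frames found")
  nat <- length(frames[[1]]$x)
  for (f in seq_along(frames)) {
    if (length(frames[[f]]$x) != nat) {
      abort(sprintf("frame %d has %d atoms; frame 1 has %d",
                    f, length(frames[[f]]$x), nat))
    }
  }
  f1 <- frames[[1]]
  atoms <- tibble(
    atom_id = seq_len(nat),
    atom_name = f1$atom_name,
    element = guess_element(f1$atom_name),
    mass = 1.0,
    residue_id = cumsum(c(1L, diff(f1$residue_id) != 0L |
                            f1$residue_name[-1] != f1$residue_name[-nat])),
    residue_name = f1$residue_name,
    molecule_class = "solvent",
    role = "other",
    chain = NA_character_,
    carbon_index = NA_integer_
  )
  if (!is.null(role_table)) atoms <- apply_role_table(atoms, role_table)

  coords <- array(NA_real_, dim = c(nat, 3, length(frames)))
  box <- matrix(NA_real_, nrow = length(frames), ncol = 3)
  times <- numeric(length(frames))
  for (f in seq_along(frames)) {
    coords[, 1, f] <- frames[[f]]$x
    coords[, 2, f] <- frames[[f]]$y
    coords[, 3, f] <- frames[[f]]$z
    box[f, ] <- frames[[f]]$box
    times[f] <- frames[[f]]$time
  }
  if (anyNA(times)) {
    if (length(frames) > 1L) {
      warn(sprintf("no frame times in file; assuming uniform %g ps spacing",
                   frame_dt))
    }
    times <- (seq_along(frames) - 1) * frame_dt
  }
  trajectory(atoms, coords, box, times)
}

guess_element <- function(atom_name) {
  first <- sub("^[0-9]*", "", atom_name)
  one <- toupper(substr(first, 1, 1))
  ifelse(one %in% c("C", "H", "N", "O", "P", "S", "X"), one, "X")
}

#' Read a role table
#'
#' CSV with columns `residue_name`, `atom_name`, `role`, `mass`, `element`
#' and optional `molecule_class`. Roles of the form
#' `tail_carbon(sn-2,5)` / `tail_hydrogen(sn-1,3)` carry the chain label and
#' carbon index; bare roles (`head_ref`, `phosphate`, `other`) have neither.
#'
#' @param path CSV file.
#' @return Tibble keyed by (`residue_name`, `atom_name`) with parsed `role`,
#'   `chain`, `carbon_index`, `mass`, `element`, `molecule_class`.
#' @export
read_role_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (!nrow(tbl)) {
    return(tibble(residue_name = character(), atom_name = character(),
                  role = character(), chain = character(),
                  carbon_index = integer(), mass = numeric(),
                  element = character(), molecule_class = character()))
  }
  need <- c("residue_name", "atom_name", "role", "mass", "element")
  if (!all(need %in% names(tbl))) {
    abort(paste("role table needs columns:", paste(need, collapse = ", ")))
  }
  parsed <- parse_role(tbl$role)
  tbl$role <- parsed$role
  tbl$chain <- parsed$chain
  tbl$carbon_index <- parsed$carbon_index
  if (!"molecule_class" %in% names(tbl)) {
    tbl$molecule_class <- NA_character_
  }
  key <- paste(tbl$residue_name, tbl$atom_name, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(tbl$role[key == k])) > 1L ||
        length(unique(tbl$chain[key == k])) > 1L ||
        length(unique(tbl$carbon_index[key == k])) > 1L
    }, logical(1))
    if (any(conflict)) {
      abort("role table has duplicate (residue_name, atom_name) keys with conflicting roles")
    }
    tbl <- tbl[!dup, ]
  }
  as_tibble(tbl)
}

parse_role <- function(role) {
  m <- regmatches(role, regexec("^(tail_carbon|tail_hydrogen)\\(([^,]+),\\s*([0-9]+)\\)$",
                                role))
  base <- character(length(role))
  chain <- rep(NA_character_, length(role))
  k <- rep(NA_integer_, length(role))
  for (i in seq_along(role)) {
    if (length(m[[i]])) {
      base[i] <- m[[i]][2]
      chain[i] <- m[[i]][3]
      k[i] <- as.integer(m[[i]][4])
    } else {
      base[i] <- role[i]
    }
  }
  ok <- base %in% c("head_ref", "phosphate", "tail_carbon", "tail_hydrogen",
                    "other")
  if (any(!ok)) {
    abort(paste("unknown role(s):", paste(unique(role[!ok]), collapse = ", ")))
  }
  list(role = base, chain = chain, carbon_index = k)
}

#' Apply a role table to an atom table
#'
#' Exact match on (`residue_name`, `atom_name`); unmatched atoms keep role
#' `"other"` and their count is reported. Molecule class defaults to
#' `"lipid"` for residues owning any lipid role, then by residue-name
#' heuristic (NO -> probe, DRG -> drug, water names -> solvent).
#'
#' @param atoms Atom tibble.
#' @param role_table Output of [read_role_table()].
#' @return The annotated atom tibble.
#' @export
apply_role_table <- function(atoms, role_table) {
  hit <- dplyr::left_join(
    atoms[, c("residue_name", "atom_name")], role_table,
    by = c("residue_name", "atom_name")
  )
  matched <- !is.na(hit$role)
  if (any(!matched)) {
    inform(sprintf("%d atom(s) not in role table; defaulted to role=other",
                   sum(!matched)))
  }
  atoms$role <- ifelse(matched, hit$role, "other")
  atoms$chain <- ifelse(matched, hit$chain, NA_character_)
  atoms$carbon_index <- ifelse(matched, hit$carbon_index, NA_integer_)
  atoms$mass[matched] <- hit$mass[matched]
  atoms$element[matched] <- hit$element[matched]
  cls <- hit$molecule_class
  lipid_res <- unique(atoms$residue_id[matched &
                                         hit$role %in% c("head_ref", "phosphate",
                                                         "tail_carbon",
                                                         "tail_hydrogen")])
  atoms$molecule_class <- dplyr::case_when(
    !is.na(cls) ~ cls,
    atoms$residue_id %in% lipid_res ~ "lipid",
    atoms$residue_name %in% c("NO") ~ "probe",
    atoms$residue_name %in% c("DRG") ~ "drug",
    .default = "solvent"
  )
  atoms
}

#' Write the builder's role table for a trajectory
#'
#' Emits the (`residue_name`, `atom_name`) -> role mapping of a synthetic
#' trajectory as CSV, so that written GRO files can be re-read with full
#' annotation.
#'
#' @param traj A [trajectory()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_role_table <- function(traj, path) {
  a <- traj$atoms
  role_str <- ifelse(
    a$role %in% c("tail_carbon", "tail_hydrogen"),
    sprintf("%s(%s,%d)", a$role, a$chain, a$carbon_index),
    a$role
  )
  tbl <- tibble(residue_name = a$residue_name, atom_name = a$atom_name,
                role = role_str, mass = a$mass, element = a$element,
                molecule_class = a$molecule_class)
  tbl <- dplyr::distinct(tbl)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read / write thermogram CSV
#'
#' Two columns, `temperature_C,cp_kcal_per_mol_C`, preceded by a
#' `# direction=heating|cooling` comment line.
#'
#' @param path CSV file.
#' @return A [thermogram()] (`read_thermogram_csv`); `path` invisibly
#'   (`write_thermogram_csv`).
#' @export
read_thermogram_csv <- function(path) {
  lines <- readLines(path)
  direction <- "heating"
  hdr <- grep("^#", lines, value = TRUE)
  dm <- regmatches(hdr, regexpr("direction=(heating|cooling)", hdr))
  if (length(dm)) direction <- sub("direction=", "", dm[1])
  tbl <- readr::read_csv(I(lines[!grepl("^#", lines)]),
                         show_col_types = FALSE, progress = FALSE)
  if (!all(c("temperature_C", "cp_kcal_per_mol_C") %in% names(tbl))) {
    abort("thermogram CSV needs columns temperature_C, cp_kcal_per_mol_C")
  }
  thermogram(tbl$temperature_C, tbl$cp_kcal_per_mol_C, direction = direction)
}

#' @rdname read_thermogram_csv
#' @param trace A [thermogram()] to write.
#' @export
write_thermogram_csv <- function(trace, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# direction=%s", attr(trace, "direction")), con)
  writeLines("temperature_C,cp_kcal_per_mol_C", con)
  writeLines(sprintf("%.6g,%.10g", trace$temperature, trace$cp_excess), con)
  invisible(path)
}

#' Probe trajectory from an atomistic trajectory
#'
#' Extracts the probe particles of a [trajectory()] into the `probe_traj`
#' shape consumed by the transport module, with core boundaries from
#' [classify_regions()] on the discard-window-averaged lipid profile.
#'
#' @param traj A [trajectory()].
#' @param probe_resname Residue name of the probes (default `"NO"`).
#' @param discard_fraction Window applied before the region-defining
#'   profile.
#' @param bin_width Profile bin width, Angstrom.
#' @return A `probe_traj`.
#' @export
probe_trajectory_from <- function(traj, probe_resname = "NO",
                                  discard_fraction = 0.2, bin_width = 0.5) {
  idx <- which(traj$atoms$residue_name == probe_resname |
                 traj$atoms$molecule_class == "probe")
  if (!length(idx)) {
    abort(sprintf("no probe atoms with residue name '%s'", probe_resname))
  }
  prof <- density_profile(discard_initial(traj, discard_fraction),
                          bin_width = bin_width)
  bounds <- classify_regions(prof)
  structure(
    list(times = traj$times,
         coords = traj$coords[idx, , , drop = FALSE],
         box = traj$box,
         region_boundaries = bounds,
         spec = NULL),
    class = "probe_traj"
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (structure before
#' transport; DSC independent) from a configuration list or YAML file, and
#' writes a JSON report plus CSV tables to `out_dir`. A failing stage is
#' recorded as failed and its dependents are skipped; the returned report is
#' deterministic for a fixed config and seed (no timestamps).
#'
#' Configuration fields: `stages` (subset of `"structure"`, `"transport"`,
#' `"dsc"`), `trajectory` (path), `roles` (path), `probe_resname`,
#' `discard_fraction`, `bin_width`, `fit_window_ns` (length-2), `d_m_estimator`,
#' `dsc` (list: `control_heating`, `control_cooling`, `treated_heating`,
#' `treated_cooling`, `ratio_label`), `out_dir`, `seed`.
#'
#' @param config A named list, or path to a YAML file holding one.
#' @return The report, a nested list (class `run_report`), invisibly
#'   written as `report.json` in `out_dir` when `out_dir` is given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% "structure"
  bad <- setdiff(stages, c("structure", "transport", "dsc"))
  if (length(bad)) {
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  discard <- config$discard_fraction %||% 0.2
  check_number(discard, "discard_fraction", lower = 0, upper = 0.9)
  bin_width <- config$bin_width %||% 0.5
  if (any(c("structure", "transport") %in% stages)) {
    if (is.null(config$trajectory)) {
      abort("config needs `trajectory` for the structure/transport stages")
    }
    if (!file.exists(config$trajectory)) {
      abort(sprintf("trajectory file not found: %s", config$trajectory))
    }
  }
  if ("transport" %in% stages && is.null(config$probe_resname)) {
    abort("transport stage needs `probe_resname` in the config")
  }

  report <- list(config = config[order(names(config))],
                 package_version = as.character(utils::packageVersion("bilayr")),
                 stages = list())
  traj <- NULL
  structure_res <- NULL

  if (any(c("structure", "transport") %in% stages)) {
    roles <- if (!is.null(config$roles)) read_role_table(config$roles)
    traj <- read_trajectory(config$trajectory, role_table = roles)
  }

  if ("structure" %in% stages) {
    report$stages$structure <- tryCatch({
      structure_res <- structure_summary(traj, discard_fraction = discard,
                                         bin_width = bin_width)
      list(status = "ok", summary = glance(structure_res))
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
  }

  if ("transport" %in% stages) {
    ok_dep <- !("structure" %in% stages) ||
      identical(report$stages$structure$status, "ok")
    report$stages$transport <- if (!ok_dep) {
      list(status = "skipped", message = "structure stage failed")
    } else tryCatch({
      ptraj <- probe_trajectory_from(traj, config$probe_resname %||% "NO",
                                     discard_fraction = discard,
                                     bin_width = bin_width)
      thick <- if (!is.null(structure_res)) structure_res$thickness$mean
               else diff(ptraj$region_boundaries)
      fw <- if (!is.null(config$fit_window_ns)) {
        as.numeric(config$fit_window_ns) * 1000
      }
      ts <- transport_summary(ptraj, thickness = thick,
                              discard_fraction = discard, fit_window = fw,
                              d_m_estimator = config$d_m_estimator %||% "z")
      list(status = "ok", summary = glance(ts))
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
  }

  if ("dsc" %in% stages) {
    report$stages$dsc <- tryCatch({
      d <- config$dsc
      if (is.null(d)) abort("config needs a `dsc` block for the dsc stage")
      params <- function(p) transition_params(read_thermogram_csv(p))
      ctrl <- list(heating = params(d$control_heating),
                   cooling = params(d$control_cooling))
      trt <- list(heating = params(d$treated_heating),
                  cooling = params(d$treated_cooling))
      list(status = "ok",
           control = as.list(ctrl$heating),
           treated = as.list(trt$heating),
           delta = as.list(delta_report(trt, ctrl,
                                        d$ratio_label %||% "")))
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    if (identical(report$stages$structure$status, "ok")) {
      readr::write_csv(report$stages$structure$summary,
                       file.path(config$out_dir, "structure_summary.csv"),
                       progress = FALSE)
    }
    if (identical(report$stages$transport$status, "ok")) {
      readr::write_csv(report$stages$transport$summary,
                       file.path(config$out_dir, "transport_summary.csv"),
                       progress = FALSE)
    }
  }
  report
}
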