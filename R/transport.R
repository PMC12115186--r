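# Probe transport analysis: hydrophobic-core classification, partition
# coefficient, multiple-time-origin MSD, diffusion-coefficient regression,
# and the solubility-diffusion permeability P_m = D_m * K_p / delta.

#' Classify the hydrophobic core from a density profile
#'
#' The core is the contiguous z interval around the midplane where the
#' lipid-tail density exceeds the headgroup density; its boundaries are the
#' two crossover points, linearly interpolated between bins.
#'
#' @param profile A `density_profile` with labels `"heads"` and `"tails"`.
#' @return Named vector `c(z_low, z_high)`, Angstrom.
#' @export
classify_regions <- function(profile) {
  need <- c("heads", "tails")
  if (!all(need %in% profile$label)) {
    abort("profile must contain 'heads' and 'tails' selections")
  }
  heads <- profile[profile$label == "heads", ]
  tails <- profile[profile$label == "tails", ]
  if (sum(tails$density) <= 0 || sum(heads$density) <= 0) {
    abort("degenerate profile: a selection has zero mass")
  }
  z <- heads$z
  diff_d <- tails$density - heads$density
  i0 <- which.min(abs(z))
  if (diff_d[i0] < 0) {
    abort("no hydrophobic core: head density exceeds tail density at the midplane")
  }
  cross_at <- function(i, j) {
    # linear interpolation of the sign change between bins i and j
    z[i] + (z[j] - z[i]) * diff_d[i] / (diff_d[i] - diff_d[j])
  }
  # expand outward over the contiguous region where tails >= heads; empty
  # bins (both densities zero) do not break the core
  i <- i0
  while (i > 1L && diff_d[i - 1L] >= 0) i <- i - 1L
  j <- i0
  n <- length(z)
  while (j < n && diff_d[j + 1L] >= 0) j <- j + 1L
  if (all(diff_d[i:j] <= 0)) {
    abort("no hydrophobic core: tail density never exceeds head density around the midplane")
  }
  z_low <- if (i == 1L) z[1] else cross_at(i - 1L, i)
  z_high <- if (j == n) z[n] else cross_at(j + 1L, j)
  if (z_low > z_high) abort("degenerate profile: inverted core boundaries")
  c(z_low = z_low, z_high = z_high)
}

#' Set the core boundaries of a probe trajectory
#'
#' @param ptraj A `probe_traj`.
#' @param boundaries Named vector `c(z_low, z_high)`, e.g. from
#'   [classify_regions()].
#' @return The modified `probe_traj`.
#' @export
set_region_boundaries <- function(ptraj, boundaries) {
  if (boundaries[["z_low"]] >= boundaries[["z_high"]]) {
    abort("z_low must be < z_high")
  }
  ptraj$region_boundaries <- c(z_low = boundaries[["z_low"]],
                               z_high = boundaries[["z_high"]])
  ptraj
}

#' Partition coefficient of the probes
#'
#' `K_p` is the ratio of the time-summed number of probe positions inside
#' the hydrophobic core to the number outside, over all retained frames and
#' particles (frame-instantaneous counts, no residence-time smoothing).
#'
#' @param ptraj A `probe_traj` with region boundaries set.
#' @param discard_fraction Initial fraction of frames discarded before
#'   counting.
#' @return `K_p` (dimensionless).
#' @export
partition_coefficient <- function(ptraj, discard_fraction = 0.2) {
  check_number(discard_fraction, "discard_fraction", lower = 0, upper = 0.9)
  nf <- dim(ptraj$coords)[3]
  keep <- seq.int(floor(nf * discard_fraction) + 1L, nf)
  z <- ptraj$coords[, 3, keep, drop = FALSE]
  b <- ptraj$region_boundaries
  inside <- sum(z >= b[["z_low"]] & z <= b[["z_high"]])
  outside <- length(z) - inside
  if (outside == 0L) {
    abort("probe never leaves the core; K_p undefined")
  }
  inside / outside
}

#' Mean squared displacement with multiple time origins
#'
#' For every lag up to half the trajectory length, averages the squared
#' displacement over all particles and all origin pairs separated by that
#' lag; z, xy and 3-D components are reported separately. Positions are
#' unwrapped in xy by minimum-image displacement accumulation; z is treated
#' as bounded and left as stored.
#'
#' @param ptraj A `probe_traj`.
#' @param max_lag_frames Optional cap on the largest lag, frames.
#' @return A tibble of class `msd_curve` with `lag` (ps), `msd_z`,
#'   `msd_xy`, `msd_3d` (Angstrom^2) and `n_origin_pairs`.
#' @export
msd <- function(ptraj, max_lag_frames = NULL) {
  nf <- dim(ptraj$coords)[3]
  if (nf < 3L) abort("need at least 3 frames for an MSD")
  dts <- diff(ptraj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * max(dts[1], 1)) {
    abort("frame times must be uniformly spaced")
  }
  n <- dim(ptraj$coords)[1]
  # unwrap xy: accumulate minimum-image inter-frame displacements
  ux <- ptraj$coords[, 1, , drop = FALSE][, 1, , drop = FALSE]
  dim(ux) <- c(n, nf)
  uy <- ptraj$coords[, 2, , drop = FALSE][, 1, , drop = FALSE]
  dim(uy) <- c(n, nf)
  uz <- ptraj$coords[, 3, , drop = FALSE][, 1, , drop = FALSE]
  dim(uz) <- c(n, nf)
  for (f in 2:nf) {
    ux[, f] <- ux[, f - 1] + min_image(ux[, f] - ux[, f - 1],
                                       ptraj$box[f, 1])
    uy[, f] <- uy[, f - 1] + min_image(uy[, f] - uy[, f - 1],
                                       ptraj$box[f, 2])
  }
  max_lag <- nf %/% 2L
  if (!is.null(max_lag_frames)) max_lag <- min(max_lag, max_lag_frames)
  lags <- 0:max_lag
  msd_z <- msd_xy <- numeric(length(lags))
  n_pairs <- integer(length(lags))
  n_pairs[1] <- n * nf
  for (li in seq_along(lags)[-1]) {
    tau <- lags[li]
    i1 <- seq_len(nf - tau)
    dx <- ux[, i1 + tau, drop = FALSE] - ux[, i1, drop = FALSE]
    dy <- uy[, i1 + tau, drop = FALSE] - uy[, i1, drop = FALSE]
    dz <- uz[, i1 + tau, drop = FALSE] - uz[, i1, drop = FALSE]
    msd_xy[li] <- mean(dx^2 + dy^2)
    msd_z[li] <- mean(dz^2)
    n_pairs[li] <- n * length(i1)
  }
  dt <- dts[1]
  out <- tibble(lag = lags * dt, msd_z = msd_z, msd_xy = msd_xy,
                msd_3d = msd_z + msd_xy, n_origin_pairs = n_pairs)
  class(out) <- c("msd_curve", class(out))
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD versus lag on a window; the slope gives
#' `D = slope / (2 d)` with dimensionality d = 1 (z), 2 (xy) or 3 (3d), and
#' `1 Angstrom^2/ps = 1e-4 cm^2/s`. When `window` is `NULL` the default is
#' the 2-10 ns span when available; otherwise the longest window (anchored
#' scan over start and end lags) with `r^2 >= r2_min`, falling back to the
#' first half of the lags with a degenerate-fit flag if none qualifies.
#'
#' @param curve An `msd_curve`.
#' @param component `"z"`, `"xy"` or `"3d"`.
#' @param window Fit window `(lo, hi)` in ps, or `NULL` for auto-selection.
#' @param r2_min Threshold for auto-window acceptance.
#' @return One-row tibble: `component`, `d` (cm^2/s), `r2`, `window_lo`,
#'   `window_hi` (ps), `n_points`, `degenerate` (TRUE when the slope was
#'   non-positive, reported as 0, or no window met `r2_min`).
#' @export
fit_diffusion <- function(curve, component = c("z", "xy", "3d"),
                          window = NULL, r2_min = 0.99) {
  component <- match.arg(component)
  dim_d <- c(z = 1, xy = 2, `3d` = 3)[[component]]
  ycol <- paste0("msd_", component)
  lag <- curve$lag
  y <- curve[[ycol]]
  degenerate <- FALSE
  auto_restricted <- FALSE

  fit_on <- function(lo, hi) {
    i <- which(lag >= lo & lag <= hi & lag > 0)
    if (length(i) < 2L) return(NULL)
    f <- lm(y[i] ~ lag[i])
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((y[i] - mean(y[i]))^2)
    r2 <- if (ss_tot <= 0) {
      if (ss_res <= 1e-20) 1 else 0
    } else 1 - ss_res / ss_tot
    list(slope = unname(coef(f)[2]), r2 = r2, n = length(i),
         lo = min(lag[i]), hi = max(lag[i]))
  }

  if (is.null(window)) {
    lag_max <- max(lag)
    if (lag_max >= 10000) {
      window <- c(2000, 10000)                 # the 2-10 ns convention
      res <- fit_on(window[1], window[2])
    } else {
      # anchored scan: longest window meeting the r^2 threshold
      pos <- lag[lag > 0]
      starts <- pos[unique(pmax(1, round(seq(1, length(pos) / 2,
                                             length.out = 12))))]
      best <- NULL
      for (s in starts) {
        ends <- pos[pos > s]
        ends <- ends[unique(pmax(1, round(seq(length(ends), 1,
                                              length.out = 24))))]
        for (e in ends) {
          cand <- fit_on(s, e)
          if (is.null(cand) || cand$n < 5L) next
          if (cand$r2 >= r2_min) {
            if (is.null(best) || (cand$hi - cand$lo) > (best$hi - best$lo)) {
              best <- cand
            }
            break                              # longest end first per start
          }
        }
      }
      if (is.null(best)) {
        degenerate <- TRUE
        res <- fit_on(pos[1], pos[min(length(pos),
                                      max(5L, length(pos) %/% 2L))])
      } else {
        res <- best
        # flag when the full lag range did not itself meet the threshold
        auto_restricted <- res$hi < max(pos) || res$lo > pos[1]
      }
    }
  } else {
    res <- fit_on(window[1], window[2])
  }
  if (is.null(res) || res$n < 5L) {
    abort("fewer than 5 MSD points in the fit window")
  }
  d <- res$slope / (2 * dim_d) * CM2S_PER_A2PS
  if (d <= 0) {
    degenerate <- TRUE
    d <- 0
  }
  tibble(component = component, d = d, r2 = res$r2,
         window_lo = res$lo, window_hi = res$hi, n_points = res$n,
         degenerate = degenerate, auto_restricted = auto_restricted)
}

#' Transport summary: partition, diffusion, permeability
#'
#' Gathers `K_p`, the anisotropic diffusion coefficients and the
#' solubility-diffusion permeability `P_m = D_m * K_p / delta` into one
#' record. The membrane diffusion coefficient `D_m` is, by default, the
#' z-component `D_z` (membrane-normal transport governs permeation); the
#' `D_z / D_xy` anisotropy ratio is always reported alongside, and
#' `d_m_estimator = "xy"` or `"3d"` switches the estimator.
#'
#' @param ptraj A `probe_traj` with region boundaries set.
#' @param thickness Membrane thickness delta, Angstrom (e.g. the mean from
#'   [structure_summary()]).
#' @param discard_fraction Initial fraction of frames discarded for `K_p`.
#' @param fit_window MSD fit window in ps, or `NULL` for the default.
#' @param d_m_estimator Which component supplies `D_m`.
#' @return An object of class `transport_summary`.
#' @export
transport_summary <- function(ptraj, thickness,
                              discard_fraction = 0.2,
                              fit_window = NULL,
                              d_m_estimator = c("z", "xy", "3d")) {
  d_m_estimator <- match.arg(d_m_estimator)
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  k_p <- partition_coefficient(ptraj, discard_fraction)
  curve <- msd(ptraj)
  fz <- fit_diffusion(curve, "z", window = fit_window)
  fxy <- fit_diffusion(curve, "xy", window = fit_window)
  f3 <- fit_diffusion(curve, "3d", window = fit_window)
  fits <- dplyr::bind_rows(fz, fxy, f3)
  d_m <- fits$d[match(d_m_estimator, fits$component)]
  delta_cm <- thickness / A_PER_CM
  p_m <- d_m * k_p / delta_cm
  structure(
    list(k_p = k_p, d_z = fz$d, d_xy = fxy$d, d_3d = f3$d,
         anisotropy = if (fxy$d > 0) fz$d / fxy$d else NA_real_,
         d_m = d_m, d_m_estimator = d_m_estimator,
         delta = thickness, p_m = p_m,
         fit_window = c(fz$window_lo, fz$window_hi), fit_r2 = fz$r2,
         fits = fits, msd_curve = curve,
         discard_fraction_applied = discard_fraction),
    class = "transport_summary"
  )
}

#' @export
print.transport_summary <- function(x, ...) {
  cat("<transport_summary>\n")
  cat(sprintf("  K_p        %.3f\n", x$k_p))
  cat(sprintf("  D_z        %.3e cm^2/s\n", x$d_z))
  cat(sprintf("  D_xy       %.3e cm^2/s\n", x$d_xy))
  cat(sprintf("  D_z/D_xy   %.3f\n", x$anisotropy))
  cat(sprintf("  D_m (%s)    %.3e cm^2/s\n", x$d_m_estimator, x$d_m))
  cat(sprintf("  delta      %.2f A\n", x$delta))
  cat(sprintf("  P_m        %.3f cm/s\n", x$p_m))
  invisible(x)
}

#' Solubility-diffusion permeability
#'
#' `P_m = D_m * K_p / delta`, with delta converted Angstrom -> cm. Exposed
#' separately so the unit plumbing can be exercised on published numbers.
#'
#' @param d_m Membrane diffusion coefficient, cm^2/s.
#' @param k_p Partition coefficient.
#' @param thickness Membrane thickness, Angstrom.
#' @return Permeability, cm/s.
#' @export
permeability <- function(d_m, k_p, thickness) {
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  check_number(k_p, "k_p", lower = 0)
  d_m * k_p / (thickness / A_PER_CM)
}
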