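# Two-state van't Hoff excess heat capacity generator for DSC round-trips.
#
# Cp_ex(T) = (dh_vh * dh_cal / (R T_K^2)) * K / (1 + K)^2,
# K = exp[(dh_vh / R) (1/T_m,K - 1/T_K)].
# The noise-free main peak integrates to dh_cal exactly (it is
# dh_cal * d/dT of the fractional conversion K/(1+K)), which anchors the
# enthalpy recovery tests. dh_vh controls cooperativity, hence peak width.

#' Van't Hoff enthalpy producing a requested peak width
#'
#' Solves for the van't Hoff enthalpy whose two-state excess-heat-capacity
#' peak has the requested full width at half maximum, by 1-D root finding on
#' the exact (continuous) peak shape.
#'
#' @param fwhm_c Target full width at half maximum, degrees C.
#' @param t_m Transition temperature, degrees C.
#' @return Van't Hoff enthalpy, kcal/mol.
#' @export
vant_hoff_from_width <- function(fwhm_c, t_m) {
  check_number(fwhm_c, "fwhm_c", lower = 0, strict_lower = TRUE)
  f <- function(dh_vh) two_state_fwhm(dh_vh, t_m) - fwhm_c
  uniroot(f, lower = 1, upper = 1e5, tol = 1e-10)$root
}

# Exact FWHM of the two-state peak, found numerically on the half-height
# crossings of the continuous curve.
two_state_fwhm <- function(dh_vh, t_m) {
  tm_k <- c_to_k(t_m)
  cp <- function(t_c) {
    t_k <- c_to_k(t_c)
    k <- exp((dh_vh / GAS_CONSTANT_KCAL) * (1 / tm_k - 1 / t_k))
    dh_vh / (GAS_CONSTANT_KCAL * t_k^2) * k / (1 + k)^2
  }
  apex <- cp(t_m)
  half <- apex / 2
  span <- max(5 * GAS_CONSTANT_KCAL * tm_k^2 / dh_vh, 1e-3)
  lo <- uniroot(function(t) cp(t) - half,
                lower = max(t_m - 50 * span, -270), # stay above 0 K
                upper = t_m, tol = 1e-12)$root
  hi <- uniroot(function(t) cp(t) - half, lower = t_m,
                upper = t_m + 50 * span, tol = 1e-12)$root
  hi - lo
}

#' Specification of a synthetic DSC scan pair
#'
#' @param t_m Main-transition temperature, degrees C.
#' @param dh_cal Calorimetric enthalpy (peak area), kcal/mol.
#' @param dh_vh Van't Hoff enthalpy, kcal/mol; sets the peak width. Supply
#'   `width_c` instead to have it solved so the peak FWHM equals `width_c`.
#' @param width_c Optional target FWHM, degrees C (overrides `dh_vh`).
#' @param pre_t,pre_dh Optional pre-transition peak position (degrees C) and
#'   enthalpy (kcal/mol); `pre_dh = 0` or `NULL` suppresses it. Its width is
#'   `pre_width_c`.
#' @param pre_width_c FWHM of the pre-transition peak, degrees C.
#' @param hysteresis Temperature offset applied to the cooling-scan main
#'   peak, degrees C (cooling apex sits at `t_m - hysteresis`).
#' @param t_range Scan range `(low, high)`, degrees C; must bracket `t_m`.
#' @param dt_sample Sampling step, degrees C.
#' @param noise_sd Gaussian heat-capacity noise sd, kcal/(mol C).
#' @param baseline_slope,baseline_offset Linear instrumental baseline.
#' @param scan_rate Nominal scan rate, degrees C/min (metadata only).
#' @param seed Integer seed for the noise.
#' @return A list of class `thermogram_spec`.
#' @export
thermogram_spec <- function(t_m = 41.5,
                            dh_cal = 25.0,
                            dh_vh = NULL,
                            width_c = 1.7,
                            pre_t = NULL,
                            pre_dh = NULL,
                            pre_width_c = 1.0,
                            hysteresis = 0.4,
                            t_range = c(30, 55),
                            dt_sample = 0.02,
                            noise_sd = 0,
                            baseline_slope = 0,
                            baseline_offset = 0,
                            scan_rate = 0.2,
                            seed = 20240563) {
  check_number(dh_cal, "dh_cal", lower = 0, strict_lower = TRUE)
  check_number(dt_sample, "dt_sample", lower = 0, strict_lower = TRUE)
  if (length(t_range) != 2L || t_range[1] >= t_range[2]) {
    abort("`t_range` must be (low, high) with low < high")
  }
  if (t_m <= t_range[1] || t_m >= t_range[2]) {
    abort("`t_range` must bracket `t_m`")
  }
  if (is.null(dh_vh)) dh_vh <- vant_hoff_from_width(width_c, t_m)
  check_number(dh_vh, "dh_vh", lower = 0, strict_lower = TRUE)
  structure(
    list(t_m = t_m, dh_cal = dh_cal, dh_vh = dh_vh,
         pre_t = pre_t, pre_dh = pre_dh, pre_width_c = pre_width_c,
         hysteresis = hysteresis, t_range = t_range, dt_sample = dt_sample,
         noise_sd = noise_sd, baseline_slope = baseline_slope,
         baseline_offset = baseline_offset, scan_rate = scan_rate,
         seed = as.integer(seed)),
    class = "thermogram_spec"
  )
}

two_state_peak <- function(t_c, t_m, dh_cal, dh_vh) {
  t_k <- c_to_k(t_c)
  tm_k <- c_to_k(t_m)
  k <- exp((dh_vh / GAS_CONSTANT_KCAL) * (1 / tm_k - 1 / t_k))
  dh_vh * dh_cal / (GAS_CONSTANT_KCAL * t_k^2) * k / (1 + k)^2
}

#' Construct a thermogram tibble
#'
#' @param temperature Temperatures, degrees C (any order; sorted ascending).
#' @param cp_excess Excess heat capacity, kcal/(mol C).
#' @param direction `"heating"` or `"cooling"`.
#' @param scan_rate Scan rate, degrees C/min.
#' @param label Free-text trace label.
#' @return A tibble of class `thermogram` with attributes `direction`,
#'   `scan_rate`, `label`.
#' @export
thermogram <- function(temperature, cp_excess,
                       direction = c("heating", "cooling"),
                       scan_rate = NA_real_, label = "") {
  direction <- match.arg(direction)
  if (length(temperature) != length(cp_excess)) {
    abort("temperature and cp_excess must have equal length")
  }
  ord <- order(temperature)
  temperature <- temperature[ord]
  if (any(diff(temperature) <= 0)) {
    abort("temperature grid must be strictly monotone")
  }
  out <- tibble(temperature = temperature, cp_excess = cp_excess[ord])
  class(out) <- c("thermogram", class(out))
  attr(out, "direction") <- direction
  attr(out, "scan_rate") <- scan_rate
  attr(out, "label") <- label
  out
}

#' Generate a heating/cooling thermogram pair
#'
#' Builds two-state van't Hoff excess-heat-capacity traces on the requested
#' grid: main peak at `t_m` (heating) and `t_m - hysteresis` (cooling),
#' optional pre-transition peak, linear baseline, seeded Gaussian noise. The
#' noise-free, baseline-free main peak integrates to `dh_cal` by
#' construction.
#'
#' @param spec A [thermogram_spec()].
#' @return A list with elements `heating` and `cooling`, each a
#'   [thermogram()]. If `t_range` is too narrow to contain the main peak
#'   (less than ~5 half-widths each side), the traces carry attribute
#'   `truncated = TRUE` and a warning is raised.
#' @export
generate_thermogram <- function(spec) {
  stopifnot(inherits(spec, "thermogram_spec"))
  tt <- seq(spec$t_range[1], spec$t_range[2], by = spec$dt_sample)
  half_w <- two_state_fwhm(spec$dh_vh, spec$t_m) / 2
  truncated <- (spec$t_m - tt[1]) < 10 * half_w ||
    (tt[length(tt)] - spec$t_m) < 10 * half_w
  if (truncated) {
    warn("t_range is narrow: main peak tails extend beyond the scan window")
  }

  build <- function(t_main, direction, noise_seed) {
    cp <- two_state_peak(tt, t_main, spec$dh_cal, spec$dh_vh)
    if (!is.null(spec$pre_dh) && !is.null(spec$pre_t) && spec$pre_dh > 0) {
      pre_vh <- vant_hoff_from_width(spec$pre_width_c, spec$pre_t)
      cp <- cp + two_state_peak(tt, spec$pre_t, spec$pre_dh, pre_vh)
    }
    cp <- cp + spec$baseline_offset + spec$baseline_slope * (tt - tt[1])
    if (spec$noise_sd > 0) {
      cp <- cp + jitter_stream(noise_seed, length(tt), spec$noise_sd)
    }
    tr <- thermogram(tt, cp, direction = direction,
                     scan_rate = spec$scan_rate,
                     label = sprintf("synthetic %s scan", direction))
    attr(tr, "truncated") <- truncated
    tr
  }

  list(
    heating = build(spec$t_m, "heating", spec$seed),
    cooling = build(spec$t_m - spec$hysteresis, "cooling", spec$seed + 1L)
  )
}
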