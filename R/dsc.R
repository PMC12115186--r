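# DSC thermogram parameterization: baseline subtraction, peak detection,
# transition parameters (T_m, width, enthalpy), scan hysteresis, and the
# delta-vs-control tables of a dose-response calorimetry study.

#' Subtract a linear baseline from a thermogram
#'
#' Fits a line through the median heat capacity of the first and last 10% of
#' the temperature range (pre- and post-transition flats) and subtracts it;
#' the residual may be slightly negative off-peak. Edge medians differing by
#' more than 20% of the peak height suggest a non-linear instrumental
#' baseline and raise a warning.
#'
#' @param trace A [thermogram()].
#' @return A baseline-subtracted [thermogram()].
#' @export
subtract_baseline <- function(trace) {
  t <- trace$temperature
  cp <- trace$cp_excess
  span <- t[length(t)] - t[1]
  if (span < 5) abort("temperature range shorter than 5 C; cannot anchor a baseline")
  lo_i <- t <= t[1] + 0.1 * span
  hi_i <- t >= t[length(t)] - 0.1 * span
  m_lo <- median(cp[lo_i])
  m_hi <- median(cp[hi_i])
  t_lo <- median(t[lo_i])
  t_hi <- median(t[hi_i])
  peak_h <- max(cp) - min(cp)
  if (peak_h > 0 && abs(m_hi - m_lo) > 0.2 * peak_h) {
    warn("edge medians differ by >20% of the peak height; baseline may be non-linear")
  }
  base <- m_lo + (m_hi - m_lo) * (t - t_lo) / (t_hi - t_lo)
  out <- thermogram(t, cp - base, direction = attr(trace, "direction"),
                    scan_rate = attr(trace, "scan_rate"),
                    label = attr(trace, "label"))
  attr(out, "baseline") <- c(intercept = m_lo - (m_hi - m_lo) * t_lo / (t_hi - t_lo),
                             slope = (m_hi - m_lo) / (t_hi - t_lo))
  out
}

#' Detect transition peaks
#'
#' Finds local maxima of a baseline-subtracted trace with prominence at
#' least `prominence_frac` of the global maximum. Peak bounds extend to
#' where the heat capacity falls to 1% of the apex or a local minimum is
#' reached. The largest-area peak is labelled `"main"`; any detected peak at
#' lower temperature is a `"pre-transition"`, peaks above are `"post"`.
#'
#' @param trace A baseline-subtracted [thermogram()].
#' @param prominence_frac Prominence floor as a fraction of the global
#'   maximum (default 0.05).
#' @param bound_frac Bound level as a fraction of the apex (default 0.01).
#' @return Tibble with `kind`, `apex_t`, `apex_cp`, `prominence`,
#'   `t_lo`, `t_hi`, `area` (one row per peak, main first, then by area);
#'   zero rows when nothing exceeds the floor.
#' @export
detect_transitions <- function(trace, prominence_frac = 0.05,
                               bound_frac = 0.01) {
  t <- trace$temperature
  cp <- trace$cp_excess
  n <- length(cp)
  if (n < 5L) abort("trace too short for peak detection")
  # running median for the bound-walk decisions only: keeps noise upticks
  # from terminating the descent; apexes and areas stay on the raw trace
  cs <- if (n >= 25L) stats::runmed(cp, 9L) else cp
  floor_h <- prominence_frac * max(cp)
  is_max <- which(cp[2:(n - 1)] > cp[1:(n - 2)] &
                    cp[2:(n - 1)] >= cp[3:n]) + 1L
  peaks <- list()
  for (i in is_max) {
    # prominence: drop to the highest of the two saddle minima that separate
    # this maximum from higher ground (or the trace edge)
    left <- cp[1:i]
    right <- cp[i:n]
    higher_l <- which(left > cp[i])
    min_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    higher_r <- which(right > cp[i])
    min_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    prom <- cp[i] - max(min_l, min_r)
    if (prom < floor_h || cp[i] <= 0) next
    level <- bound_frac * cp[i]
    # walk outward tracking the running minimum; noise upticks smaller than
    # 5% of the apex do not terminate the descent
    walk <- function(dir) {
      j <- i
      run_min <- cs[i]
      j_min <- i
      repeat {
        nxt <- j + dir
        if (nxt < 1L || nxt > n) break
        v <- cs[nxt]
        if (v < run_min) {
          run_min <- v
          j_min <- nxt
        }
        if (run_min <= level) {
          j_min <- nxt
          break
        }
        if (v > run_min + 0.05 * cp[i]) break   # genuine local minimum
        j <- nxt
      }
      j_min
    }
    j <- walk(-1L)
    k <- walk(+1L)
    peaks[[length(peaks) + 1L]] <- tibble(
      apex_i = i, apex_t = t[i], apex_cp = cp[i], prominence = prom,
      t_lo = t[j], t_hi = t[k],
      area = trapz_int(t[j:k], cp[j:k])
    )
  }
  if (!length(peaks)) {
    return(tibble(kind = character(), apex_t = numeric(),
                  apex_cp = numeric(), prominence = numeric(),
                  t_lo = numeric(), t_hi = numeric(), area = numeric()))
  }
  pk <- dplyr::bind_rows(peaks)
  pk <- dplyr::arrange(pk, dplyr::desc(.data$area))
  main_t <- pk$apex_t[1]
  pk$kind <- c("main", ifelse(pk$apex_t[-1] < main_t, "pre-transition",
                              "post"))[seq_len(nrow(pk))]
  dplyr::select(pk, "kind", "apex_t", "apex_cp", "prominence",
                "t_lo", "t_hi", "area", "apex_i")
}

#' Thermotropic parameters of the main transition
#'
#' From a thermogram (baseline is subtracted internally unless
#' `baseline = FALSE`): the transition temperature `t_m` (3-point parabolic
#' interpolation through the apex, so resolution beats the sampling step),
#' the width `delta_t_b` (full width at half maximum of the main peak,
#' linear interpolation at half height), and the enthalpy `delta_h`
#' (trapezoidal integral of the excess heat capacity over the peak bounds).
#'
#' @param trace A [thermogram()].
#' @param baseline Subtract the linear baseline first (default `TRUE`).
#' @param prominence_frac Passed to [detect_transitions()].
#' @return An object of class `transition_params`: a one-row tibble with
#'   `t_m`, `delta_t_b`, `delta_h`, `pre_transition_t` (`NA` when absent),
#'   `t_lo`, `t_hi`, `direction`.
#' @export
transition_params <- function(trace, baseline = TRUE,
                              prominence_frac = 0.05) {
  if (baseline) trace <- subtract_baseline(trace)
  pk <- detect_transitions(trace, prominence_frac = prominence_frac)
  if (!nrow(pk)) abort("no main transition detected")
  main <- pk[pk$kind == "main", ][1, ]
  t <- trace$temperature
  cp <- trace$cp_excess
  i <- main$apex_i

  # parabolic apex interpolation, so t_m resolution beats dt_sample: fit a
  # parabola over the apex neighbourhood (points >= 95% of the apex) and
  # take its vertex; degrades to the classic 3-point formula on sparse grids
  apex_nb <- which(t >= main$t_lo & t <= main$t_hi &
                     cp >= 0.95 * main$apex_cp)
  t_m <- if (length(apex_nb) >= 5L) {
    tc <- t[apex_nb] - t[i]
    fit <- lm(cp[apex_nb] ~ tc + I(tc^2))
    a <- coef(fit)[[3]]; b <- coef(fit)[[2]]
    if (is.finite(a) && a < 0) t[i] - b / (2 * a) else t[i]
  } else if (i > 1L && i < length(t)) {
    y1 <- cp[i - 1]; y2 <- cp[i]; y3 <- cp[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) < 1e-300) t[i]
    else t[i] + 0.5 * (y1 - y3) / denom * (t[i + 1] - t[i])
  } else t[i]

  half <- main$apex_cp / 2
  in_pk <- which(t >= main$t_lo & t <= main$t_hi)
  left <- in_pk[in_pk <= i]
  right <- in_pk[in_pk >= i]
  cross <- function(idx, side) {
    below <- idx[cp[idx] < half]
    if (!length(below)) {
      abort(sprintf("half height not reached on the %s side of the main peak",
                    side))
    }
    j <- if (side == "left") max(below) else min(below)
    j2 <- if (side == "left") j + 1L else j - 1L
    t[j] + (t[j2] - t[j]) * (half - cp[j]) / (cp[j2] - cp[j])
  }
  w_lo <- cross(left, "left")
  w_hi <- cross(right, "right")

  seg <- which(t >= main$t_lo & t <= main$t_hi)
  delta_h <- trapz_int(t[seg], cp[seg])

  pre_t <- if (any(pk$kind == "pre-transition")) {
    pk$apex_t[pk$kind == "pre-transition"][1]
  } else NA_real_

  out <- tibble(t_m = t_m, delta_t_b = w_hi - w_lo, delta_h = delta_h,
                pre_transition_t = pre_t,
                t_lo = main$t_lo, t_hi = main$t_hi,
                direction = attr(trace, "direction") %||% "heating")
  class(out) <- c("transition_params", class(out))
  out
}

#' Scan hysteresis
#'
#' `delta_t_h = t_m(heating) - t_m(cooling)`. A cooling apex above the
#' heating apex yields a negative value (sign preserved).
#'
#' @param heating,cooling `transition_params` of the two scans.
#' @return Hysteresis, degrees C.
#' @export
hysteresis <- function(heating, cooling) {
  heating$t_m - cooling$t_m
}

#' Treated-minus-control thermotropic deltas
#'
#' Builds one row of a dose-response table: `d_t_m`, `dd_t_b` and `dd_h` are
#' heating-scan treated-minus-control differences of `t_m`, `delta_t_b` and
#' `delta_h`; `dd_t_h` is the difference of the scan hystereses.
#'
#' @param treated,control Lists with elements `heating` and `cooling`, each
#'   a [transition_params()].
#' @param ratio_label Lipid:drug ratio label, e.g. `"10:1"`.
#' @return One-row tibble of class `delta_report`.
#' @export
delta_report <- function(treated, control, ratio_label = "") {
  out <- tibble(
    ratio_label = ratio_label,
    d_t_m = treated$heating$t_m - control$heating$t_m,
    dd_t_b = treated$heating$delta_t_b - control$heating$delta_t_b,
    dd_t_h = hysteresis(treated$heating, treated$cooling) -
      hysteresis(control$heating, control$cooling),
    dd_h = treated$heating$delta_h - control$heating$delta_h
  )
  class(out) <- c("delta_report", class(out))
  out
}

# drug fraction implied by an "N:1" lipid:drug ratio label
ratio_fraction <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.numeric(p[2]) / (as.numeric(p[1]) + as.numeric(p[2]))
  }, numeric(1))
}

#' Order delta reports into a dose series
#'
#' Sorts delta reports by increasing drug fraction (e.g. 100:1 before 5:1)
#' and flags a biphasic `d_t_m` series: one where the sign of the successive
#' differences changes exactly once (a single local extremum). With fewer
#' than 3 ratios the flag is suppressed and noted.
#'
#' @param reports A list of [delta_report()] rows or a bound tibble.
#' @return Tibble ordered by drug fraction, with attributes `biphasic`
#'   (logical) and `extremum_between` (the pair of ratio labels bracketing
#'   the extremum, or `NULL`).
#' @export
dose_series <- function(reports) {
  tbl <- if (is.data.frame(reports)) as_tibble(reports)
         else dplyr::bind_rows(reports)
  if (nrow(tbl) < 2L) abort("need at least 2 ratios for a dose series")
  if (anyDuplicated(tbl$ratio_label)) {
    abort("duplicate ratio labels in dose series")
  }
  tbl <- tbl[order(ratio_fraction(tbl$ratio_label)), ]
  biphasic <- FALSE
  extremum <- NULL
  if (nrow(tbl) >= 3L) {
    d <- diff(tbl$d_t_m)
    s <- sign(d)
    s <- s[s != 0]
    changes <- which(diff(s) != 0)
    if (length(unique(sign(diff(tbl$d_t_m))[sign(diff(tbl$d_t_m)) != 0])) > 1 &&
        length(changes) == 1L) {
      biphasic <- TRUE
      flip <- which(diff(sign(diff(tbl$d_t_m))) != 0)[1]
      extremum <- tbl$ratio_label[c(flip + 1L, flip + 2L)]
    }
  } else {
    inform("fewer than 3 ratios: biphasic detection suppressed")
  }
  attr(tbl, "biphasic") <- biphasic
  attr(tbl, "extremum_between") <- extremum
  tbl
}
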