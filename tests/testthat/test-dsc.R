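# Thermogram parameterization: baseline, peak detection, transition
# parameters, hysteresis, delta tables, dose series.

test_that("linear baseline is removed to numerical precision", {
  t <- seq(20, 60, by = 0.05)
  trace <- thermogram(t, 0.3 + 0.02 * t)
  # a pure ramp has no peak, so the non-linear-baseline heuristic fires
  expect_warning(sub <- subtract_baseline(trace), "non-linear")
  resid <- sub$cp_excess
  expect_lt(max(abs(resid)), 1e-9 * max(abs(trace$cp_excess)))
  expect_error(subtract_baseline(thermogram(seq(20, 23, 0.1),
                                            rep(0, 31))),
               "5 C")
})

test_that("baseline subtraction preserves the recovered enthalpy", {
  base <- thermogram_spec(t_m = 41.5, dh_cal = 25, width_c = 1.7,
                          t_range = c(25, 60))
  with_slope <- thermogram_spec(t_m = 41.5, dh_cal = 25, width_c = 1.7,
                                t_range = c(25, 60), baseline_slope = 0.1,
                                baseline_offset = 1.5)
  h0 <- transition_params(generate_thermogram(base)$heating)$delta_h
  h1 <- suppressWarnings(
    transition_params(generate_thermogram(with_slope)$heating)$delta_h
  )
  expect_equal(h1, h0, tolerance = 0.005 * h0)
})

test_that("peak detection separates main and pre-transition", {
  spec <- thermogram_spec(t_m = 41.5, dh_cal = 25, width_c = 1.7,
                          pre_t = 35, pre_dh = 4, t_range = c(25, 60))
  tg <- generate_thermogram(spec)
  pk <- detect_transitions(subtract_baseline(tg$heating))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$kind, c("main", "pre-transition"))
  expect_equal(pk$apex_t[pk$kind == "main"], 41.5, tolerance = 0.03)
  expect_equal(pk$apex_t[pk$kind == "pre-transition"], 35, tolerance = 0.03)

  solo <- generate_thermogram(thermogram_spec(t_m = 41.5, pre_dh = NULL))
  expect_equal(nrow(detect_transitions(subtract_baseline(solo$heating))), 1)

  noise <- thermogram(seq(30, 50, 0.02),
                      bilayr:::jitter_stream(4, 1001, 1e-4))
  expect_equal(nrow(detect_transitions(noise, prominence_frac = 2)), 0)
})

test_that("triangle peak closed form: t_m, width, area", {
  t <- seq(40, 60, by = 0.05)
  cp <- pmax(0, 2 * (1 - abs(t - 50) / 2))  # apex (50, 2), base 48-52
  tp <- transition_params(thermogram(t, cp), baseline = FALSE)
  expect_equal(tp$t_m, 50, tolerance = 0.01)
  expect_equal(tp$delta_t_b, 2.0, tolerance = 0.01)
  expect_equal(tp$delta_h, 4.0, tolerance = 0.05)
})

test_that("generator round trip recovers t_m, width and enthalpy over a grid", {
  for (tm in c(24, 41.5, 76)) {
    for (dh in c(8, 25, 38)) {
      for (w in c(0.8, 1.7, 4)) {
        spec <- thermogram_spec(t_m = tm, dh_cal = dh, width_c = w,
                                t_range = c(tm - 12 * w, tm + 12 * w),
                                dt_sample = 0.02)
        tp <- transition_params(generate_thermogram(spec)$heating)
        expect_equal(tp$t_m, tm, tolerance = 0.02)
        expect_equal(tp$delta_t_b, w, tolerance = 0.02 * w)
        expect_equal(tp$delta_h, dh, tolerance = 0.01 * dh)
      }
    }
  }
})

test_that("main + pre-transition areas are additive when peaks are well separated", {
  joint <- thermogram_spec(t_m = 45, dh_cal = 25, width_c = 1.5,
                           pre_t = 33, pre_dh = 5, pre_width_c = 1.2,
                           t_range = c(20, 65))
  tg <- generate_thermogram(joint)
  pk <- detect_transitions(subtract_baseline(tg$heating))
  expect_equal(sum(pk$area), 30, tolerance = 0.01 * 30)
})

test_that("orientation of the temperature grid does not matter", {
  spec <- thermogram_spec(t_m = 41.5)
  tg <- generate_thermogram(spec)
  fwd <- transition_params(tg$heating)
  rev_trace <- thermogram(rev(tg$heating$temperature),
                          rev(tg$heating$cp_excess))
  bwd <- transition_params(rev_trace)
  expect_equal(bwd$t_m, fwd$t_m)
  expect_equal(bwd$delta_h, fwd$delta_h)
})

test_that("hysteresis: identical scans give 0, sign is preserved", {
  tg <- generate_thermogram(thermogram_spec(hysteresis = 0.4))
  h <- transition_params(tg$heating)
  c_ <- transition_params(tg$cooling)
  expect_equal(hysteresis(h, h), 0)
  expect_equal(hysteresis(h, c_), 0.4, tolerance = 0.02)
  # cooling apex above heating -> negative
  tg2 <- generate_thermogram(thermogram_spec(hysteresis = -0.6))
  expect_equal(hysteresis(transition_params(tg2$heating),
                          transition_params(tg2$cooling)),
               -0.6, tolerance = 0.02)
})

test_that("t_m recovery degrades gracefully under noise", {
  spec0 <- thermogram_spec(t_m = 41.5, dh_cal = 25, width_c = 1.7,
                           t_range = c(30, 55), dt_sample = 0.02)
  apex <- max(generate_thermogram(spec0)$heating$cp_excess)
  tms <- vapply(seq_len(50), function(s) {
    spec <- thermogram_spec(t_m = 41.5, dh_cal = 25, width_c = 1.7,
                            t_range = c(30, 55), dt_sample = 0.02,
                            noise_sd = 0.02 * apex, seed = s)
    transition_params(generate_thermogram(spec)$heating)$t_m
  }, numeric(1))
  expect_lt(sd(tms), 0.1)
  expect_equal(mean(tms), 41.5, tolerance = 0.05)
})

test_that("delta report mirrors the treated-minus-control arithmetic", {
  mk <- function(t_m, width, dh, hyst) {
    tg <- generate_thermogram(thermogram_spec(
      t_m = t_m, dh_cal = dh, width_c = width, hysteresis = hyst,
      t_range = c(25, 60)
    ))
    list(heating = transition_params(tg$heating),
         cooling = transition_params(tg$cooling))
  }
  ctrl <- mk(41.5, 1.7, 25.0, 0.4)
  same <- delta_report(ctrl, ctrl, "10:1")
  expect_equal(same$d_t_m, 0)
  expect_equal(same$dd_t_b, 0)
  expect_equal(same$dd_t_h, 0)
  expect_equal(same$dd_h, 0)

  treated <- mk(41.2, 2.5, 24.3, 0.6)
  dr <- delta_report(treated, ctrl, "10:1")
  expect_equal(dr$d_t_m, -0.3, tolerance = 0.02)
  expect_equal(dr$dd_t_b, 0.8, tolerance = 0.03)
  expect_equal(dr$dd_t_h, 0.2, tolerance = 0.03)
  expect_equal(dr$dd_h, -0.7, tolerance = 0.3)
})

test_that("dose series ordering and biphasic detection", {
  mk_report <- function(ratio, d_t_m) {
    r <- tibble::tibble(ratio_label = ratio, d_t_m = d_t_m, dd_t_b = 0,
                        dd_t_h = 0, dd_h = 0)
    class(r) <- c("delta_report", class(r))
    r
  }
  ratios <- c("100:1", "50:1", "25:1", "10:1", "5:1")
  # published-style biphasic series with the extremum around 25:1-10:1
  vals <- c(-0.1, -0.2, -0.3, -0.3, -0.1)
  shuffle <- sample(seq_along(ratios))      # input order must not matter
  series <- dose_series(purrr::map2(ratios[shuffle], vals[shuffle],
                                    mk_report))
  expect_equal(series$ratio_label, ratios)

  series2 <- dose_series(purrr::map2(ratios, vals, mk_report))
  expect_true(attr(series2, "biphasic"))
  expect_equal(attr(series2, "extremum_between"), c("25:1", "10:1"))

  mono <- dose_series(purrr::map2(ratios, c(-0.1, -0.2, -0.3, -0.4, -0.5),
                                  mk_report))
  expect_false(attr(mono, "biphasic"))

  expect_message(
    two <- dose_series(purrr::map2(c("50:1", "10:1"), c(-0.1, -0.3),
                                   mk_report)),
    "suppressed")
  expect_false(attr(two, "biphasic"))

  expect_error(dose_series(purrr::map2(c("10:1", "10:1"), c(0, 1),
                                       mk_report)),
               "duplicate")
})
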