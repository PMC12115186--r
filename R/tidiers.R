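# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @rdname structure_summary
#' @param x A `structure_summary`.
#' @param ... Unused.
#' @method tidy structure_summary
#' @export
tidy.structure_summary <- function(x, ...) {
  tibble(
    quantity = c("area_per_lipid", "thickness", "f_ov", "hbond_count"),
    mean = c(x$apl$mean[1], x$thickness$mean, x$f_ov, x$hbond$mean),
    sd = c(x$apl$sd[1], x$thickness$sd, NA_real_, x$hbond$sd),
    unit = c("A^2", "A", "1", "count")
  )
}

#' @rdname structure_summary
#' @method glance structure_summary
#' @export
glance.structure_summary <- function(x, ...) {
  tibble(
    apl_mean = x$apl$mean[1], apl_sd = x$apl$sd[1],
    thickness_mean = x$thickness$mean, thickness_sd = x$thickness$sd,
    f_ov = x$f_ov,
    hbond_mean = x$hbond$mean, hbond_sd = x$hbond$sd,
    n_frames_used = x$n_frames_used,
    discard_fraction = x$discard_fraction_applied
  )
}

#' @rdname transport_summary
#' @param x A `transport_summary`.
#' @param ... Unused.
#' @method tidy transport_summary
#' @export
tidy.transport_summary <- function(x, ...) {
  x$fits
}

#' @rdname transport_summary
#' @method glance transport_summary
#' @export
glance.transport_summary <- function(x, ...) {
  tibble(
    k_p = x$k_p, d_z = x$d_z, d_xy = x$d_xy, d_3d = x$d_3d,
    anisotropy = x$anisotropy, d_m = x$d_m,
    d_m_estimator = x$d_m_estimator, delta = x$delta, p_m = x$p_m,
    fit_window_lo = x$fit_window[1], fit_window_hi = x$fit_window[2],
    fit_r2 = x$fit_r2,
    discard_fraction = x$discard_fraction_applied
  )
}

#' @rdname transition_params
#' @param x A `transition_params`.
#' @param ... Unused.
#' @method glance transition_params
#' @export
glance.transition_params <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Plot a density profile
#'
#' @param object A `density_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "mass density (amu/Å³)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MSD curve
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot with the z, xy and 3-D components.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("lag", "msd_z", "msd_xy", "msd_3d")],
    cols = -"lag", names_to = "component", values_to = "msd",
    names_prefix = "msd_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$msd,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = "MSD (Å²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a thermogram
#'
#' @param object A `thermogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermogram
#' @export
autoplot.thermogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature,
                                       y = .data$cp_excess)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = "excess Cp (kcal mol⁻¹ °C⁻¹)",
                  subtitle = attr(object, "direction")) +
    ggplot2::theme_minimal()
}

#' Plot an |SCD| profile
#'
#' @param object An `scd_profile`.
#' @param ... Unused.
#' @return A ggplot, sn-1 solid and sn-2 dashed.
#' @method autoplot scd_profile
#' @export
autoplot.scd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$carbon_index,
                                       y = .data$abs_scd,
                                       linetype = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_linetype_manual(values = c(`sn-1` = "solid",
                                              `sn-2` = "dashed")) +
    ggplot2::labs(x = "carbon index", y = "|SCD|", linetype = NULL) +
    ggplot2::theme_minimal()
}
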