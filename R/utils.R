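# Internal helpers shared across modules.

GAS_CONSTANT_KCAL <- 1.987204259e-3 # kcal / (mol K)
CELSIUS_OFFSET <- 273.15
CM2S_PER_A2PS <- 1e-4               # 1 A^2/ps = 1e-4 cm^2/s
A_PER_CM <- 1e8

c_to_k <- function(t_c) t_c + CELSIUS_OFFSET

#' Mean and standard deviation as a two-element list
#' @noRd
mean_sd <- function(x) {
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
}

#' Trapezoidal integral on possibly irregular grid
#' @noRd
trapz_int <- function(x, y) pracma::trapz(x, y)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

#' Minimum-image wrap of displacement components for one periodic length
#' @noRd
min_image <- function(d, L) d - L * round(d / L)
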