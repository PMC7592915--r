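## Closed-form thermal performance curve (TPC) models and derived quantities.

#' Boltzmann constant in eV per Kelvin
#'
#' @format A length-one numeric, 8.617e-5 eV K^-1.
#' @export
k_boltzmann <- 8.617e-5

#' Default reference temperature (Kelvin)
#'
#' B0 is normalised at 0 degrees Celsius so that it stays below the lowest
#' peak temperature in typical microbial datasets.
#'
#' @format A length-one numeric, 273.15 K.
#' @export
t_ref_default <- 273.15

#' Construct a set of Sharpe-Schoolfield TPC parameters
#'
#' Bundles the four fitted parameters of the high-temperature-deactivation
#' Sharpe-Schoolfield model together with the reference temperature, and
#' validates their joint constraints.
#'
#' @param b0 Trait performance normalised at `t_ref` (trait units, > 0).
#' @param e Activation energy / thermal sensitivity of the rising limb (eV).
#' @param t_pk Temperature at which the curve peaks (K).
#' @param e_d Deactivation energy controlling the fall past the peak (eV);
#'   must exceed `e`.
#' @param t_ref Reference temperature (K). Defaults to [t_ref_default].
#'
#' @return An object of class `"tpc_parameters"`: a named list with fields
#'   `b0`, `e`, `t_pk`, `e_d`, `t_ref`.
#' @examples
#' tpc_parameters(b0 = 1, e = 0.65, t_pk = 298.15, e_d = 3)
#' @export
tpc_parameters <- function(b0, e, t_pk, e_d, t_ref = t_ref_default) {
  stopifnot(is.numeric(b0), is.numeric(e), is.numeric(t_pk),
            is.numeric(e_d), is.numeric(t_ref))
  if (b0 <= 0) stop("b0 must be positive")
  if (e <= 0) stop("e must be positive")
  if (e_d <= e) stop("e_d must exceed e (otherwise the curve has no peak)")
  if (t_pk <= 0) stop("t_pk must be positive (Kelvin)")
  if (t_ref >= t_pk) stop("t_ref must lie below t_pk")
  structure(list(b0 = b0, e = e, t_pk = t_pk, e_d = e_d, t_ref = t_ref),
            class = "tpc_parameters")
}

#' @export
print.tpc_parameters <- function(x, ...) {
  cat("Sharpe-Schoolfield TPC parameters\n")
  cat(sprintf("  B0   = %.6g (at T_ref = %.2f K)\n", x$b0, x$t_ref))
  cat(sprintf("  E    = %.6g eV\n", x$e))
  cat(sprintf("  T_pk = %.6g K\n", x$t_pk))
  cat(sprintf("  E_D  = %.6g eV\n", x$e_d))
  invisible(x)
}

#' Boltzmann-Arrhenius model
#'
#' Exponential rise of a biological rate with temperature,
#' `B0 * exp(-(E/k) * (1/T - 1/T_ref))`. This is the rising limb of the
#' full TPC, without high-temperature deactivation.
#'
#' @param params A [tpc_parameters] object (only `b0`, `e`, `t_ref` used).
#' @param temp Temperature(s) in Kelvin, > 0.
#' @return Trait value(s) at `temp`.
#' @examples
#' p <- tpc_parameters(1, 0.65, 298.15, 3)
#' boltzmann_arrhenius(p, 283.15)
#' @export
boltzmann_arrhenius <- function(params, temp) {
  stopifnot(inherits(params, "tpc_parameters"))
  if (any(temp <= 0)) stop("temperature must be positive (Kelvin)")
  params$b0 * exp(-(params$e / k_boltzmann) * (1 / temp - 1 / params$t_ref))
}

#' Sharpe-Schoolfield model (four-parameter, high-temperature deactivation)
#'
#' The Boltzmann-Arrhenius rise divided by a deactivation term:
#' \deqn{B(T) = \frac{B_0 e^{-\frac{E}{k}(\frac{1}{T}-\frac{1}{T_{ref}})}}
#'   {1 + \frac{E}{E_D - E} e^{\frac{E_D}{k}(\frac{1}{T_{pk}}-\frac{1}{T})}}}
#' This parameterisation peaks exactly at `t_pk`.
#'
#' @inheritParams boltzmann_arrhenius
#' @return Trait value(s) at `temp`.
#' @examples
#' p <- tpc_parameters(1, 0.65, 298.15, 3)
#' sharpe_schoolfield(p, c(288.15, 298.15, 305.15))
#' @export
sharpe_schoolfield <- function(params, temp) {
  stopifnot(inherits(params, "tpc_parameters"))
  if (any(temp <= 0)) stop("temperature must be positive (Kelvin)")
  if (params$e >= params$e_d) stop("invalid parameters: e >= e_d")
  num <- params$b0 *
    exp(-(params$e / k_boltzmann) * (1 / temp - 1 / params$t_ref))
  den <- 1 + (params$e / (params$e_d - params$e)) *
    exp((params$e_d / k_boltzmann) * (1 / params$t_pk - 1 / temp))
  num / den
}

#' Recalculate B(T_ref) from the full model
#'
#' The raw fitted B0 can overestimate the true trait value at the reference
#' temperature because the deactivation denominator is not exactly 1 at
#' T_ref. The recalculated value, `sharpe_schoolfield(params, t_ref)`,
#' replaces the raw B0 in all downstream reporting.
#'
#' @param params A [tpc_parameters] object.
#' @return Trait value at `t_ref`.
#' @export
renormalize_b0 <- function(params) {
  sharpe_schoolfield(params, params$t_ref)
}

#' Quantities derived from a fitted TPC
#'
#' Computes the peak performance `B_pk = B(T_pk)`, the temperature on the
#' rising limb where performance is half of `B_pk`, the operational niche
#' width `W_op = T_pk - T_half_rise`, and the minimum generation time
#' `1 / B_pk` (meaningful when the trait is a population growth rate).
#'
#' @param params A [tpc_parameters] object.
#' @param bracket_width Width (K) of the search window below `t_pk` used to
#'   bracket the half-peak temperature. Default 150 K.
#' @param tol Bisection tolerance on temperature (K). Default 1e-6.
#' @return An object of class `"tpc_derived"`: list with `b_pk`,
#'   `t_half_rise`, `w_op`, `min_generation_time`.
#' @examples
#' p <- tpc_parameters(1, 0.65, 298.15, 3)
#' derive_quantities(p)
#' @export
derive_quantities <- function(params, bracket_width = 150, tol = 1e-6) {
  stopifnot(inherits(params, "tpc_parameters"))
  b_pk <- sharpe_schoolfield(params, params$t_pk)
  t_lo <- max(params$t_pk - bracket_width, tol)
  f <- function(tt) sharpe_schoolfield(params, tt) - 0.5 * b_pk
  if (f(t_lo) >= 0) {
    stop("half-peak root not bracketed: B(T) stays above 0.5*B_pk within ",
         bracket_width, " K below T_pk")
  }
  root <- stats::uniroot(f, lower = t_lo, upper = params$t_pk, tol = tol)
  t_half <- root$root
  structure(list(
    b_pk = b_pk,
    t_half_rise = t_half,
    w_op = params$t_pk - t_half,
    min_generation_time = 1 / b_pk
  ), class = "tpc_derived")
}

#' @export
print.tpc_derived <- function(x, ...) {
  cat(sprintf("B_pk = %.6g; T_half_rise = %.4f K; W_op = %.4f K; 1/B_pk = %.6g\n",
              x$b_pk, x$t_half_rise, x$w_op, x$min_generation_time))
  invisible(x)
}

#' Convert between Celsius and Kelvin
#'
#' @param x Temperature(s).
#' @return Converted temperature(s).
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
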