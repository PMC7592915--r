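## Nonlinear least-squares fitting of the Sharpe-Schoolfield model to
## measured thermal performance curves, goodness-of-fit, quality filters,
## and uncertainty propagation.

#' Construct a thermal performance curve (one strain's measurements)
#'
#' @param curve_id Identifier of this curve (one species may have several).
#' @param species_id Species identifier; must match a tree tip label for the
#'   comparative analyses.
#' @param temperature Measurement temperatures. Kelvin by default; pass
#'   `unit = "C"` for Celsius input.
#' @param value Trait measurements, strictly positive (fitting is on the
#'   log scale), same length as `temperature`.
#' @param trait_name One of `"r_max"`, `"net_photosynthesis"`,
#'   `"respiration"`, `"other"`.
#' @param latitude Decimal degrees in \[-90, 90\], or `NA`.
#' @param unit `"K"` (default) or `"C"`.
#' @return An object of class `"tpc_curve"`.
#' @export
tpc_curve <- function(curve_id, species_id, temperature, value,
                      trait_name = "other", latitude = NA_real_,
                      unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature <- celsius_to_kelvin(temperature)
  if (length(temperature) != length(value))
    stop("temperature and value must have equal length")
  if (length(unique(temperature)) < 2)
    stop("a curve needs at least 2 distinct temperatures")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("trait values must be finite and strictly positive")
  if (any(temperature <= 0)) stop("temperatures must be positive Kelvin")
  trait_name <- match.arg(trait_name,
                          c("r_max", "net_photosynthesis", "respiration",
                            "other"))
  if (!is.na(latitude) && abs(latitude) > 90)
    stop("latitude out of [-90, 90]")
  ord <- order(temperature)
  structure(list(curve_id = as.character(curve_id),
                 species_id = as.character(species_id),
                 trait_name = trait_name,
                 temperature = temperature[ord],
                 value = value[ord],
                 latitude = latitude),
            class = "tpc_curve")
}

#' @export
print.tpc_curve <- function(x, ...) {
  cat(sprintf("TPC curve '%s' (species %s, %s): %d measurements, %.1f-%.1f K\n",
              x$curve_id, x$species_id, x$trait_name, length(x$value),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Fitting options for [fit_sharpe_schoolfield]
#'
#' The optimiser is restarted from a deterministic grid of initial values
#' and the start with the lowest residual sum of squares wins. Activation
#' energy starts cover weak, canonical and steep rises; peak-temperature
#' starts bracket the temperature of the maximum observed value; B0 is
#' seeded from the measurement closest to `t_ref`, extrapolated down the
#' Arrhenius rise.
#'
#' @param e_starts Start values for E (eV).
#' @param t_pk_offsets Offsets (K) around the observed-maximum temperature.
#' @param e_d_starts Start values for E_D (eV).
#' @param e_max Upper optimisation bound on E (eV); deliberately above the
#'   4 eV quality filter so that very steep fits are observable rejections.
#' @param t_pk_margin Allowed distance (K) of T_pk outside the observed
#'   temperature range.
#' @param n_boot Bootstrap replicates for the ln(W_op) standard error.
#' @param min_points Curves with fewer measurements are still fitted but
#'   all quality flags will be false.
#' @return A list of class `"tpc_fit_control"`.
#' @export
tpc_fit_control <- function(e_starts = c(0.3, 0.65, 1.2),
                            t_pk_offsets = c(-3, 0, 3),
                            e_d_starts = c(2, 4),
                            e_max = 10,
                            t_pk_margin = 10,
                            n_boot = 200,
                            min_points = 4) {
  structure(list(e_starts = e_starts, t_pk_offsets = t_pk_offsets,
                 e_d_starts = e_d_starts, e_max = e_max,
                 t_pk_margin = t_pk_margin, n_boot = n_boot,
                 min_points = min_points),
            class = "tpc_fit_control")
}

## log of the Sharpe-Schoolfield curve in the internal parameterisation
## (ln B0, E, T_pk, d) with E_D = E + exp(d), which keeps E < E_D
## automatically during optimisation.
.ss_log_model <- function(lnb0, e, t_pk, d, temp, t_ref) {
  e_d <- e + exp(d)
  lnb0 - (e / k_boltzmann) * (1 / temp - 1 / t_ref) -
    log1p(e / (e_d - e) *
            exp((e_d / k_boltzmann) * (1 / t_pk - 1 / temp)))
}

#' Coefficient of determination on the fitting scale
#'
#' `1 - SSE/SST` where both sums of squares are taken about the observed
#' values (SST about their mean). The TPC pipeline computes it on the log
#' scale, matching the scale on which residuals are minimised.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return R-squared; `NA` with a warning when the observations are
#'   constant (zero total sum of squares).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("constant observations: R-squared undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sst
}

#' Fit the Sharpe-Schoolfield model to one measured curve
#'
#' Minimises squared residuals of ln(value) against the log of the model
#' (multiplicative measurement error), restarting from the deterministic
#' grid in `control`. After fitting, B0 is recalculated as the model value
#' at `t_ref` ([renormalize_b0]), derived quantities are computed, and the
#' quality filters ([apply_quality_filters]) are applied.
#'
#' @param curve A [tpc_curve].
#' @param control A [tpc_fit_control].
#' @param t_ref Reference temperature (K).
#' @return An object of class `"tpc_fit"` with fields `params`
#'   ([tpc_parameters] with the recalculated B0), `b0_raw`, `derived`,
#'   `r_squared`, `n_below_pk`, `n_above_pk`, `qc` (named logical), `vcov`
#'   (covariance of the internal parameters), `converged`, and curve
#'   metadata. When no start converges, `converged` is `FALSE`, parameters
#'   are `NULL` and all quality flags are false.
#' @export
fit_sharpe_schoolfield <- function(curve, control = tpc_fit_control(),
                                   t_ref = t_ref_default) {
  stopifnot(inherits(curve, "tpc_curve"))
  temp <- curve$temperature
  lny <- log(curve$value)
  t_at_max <- temp[which.max(curve$value)]
  t_lo <- min(temp) - control$t_pk_margin
  t_hi <- max(temp) + control$t_pk_margin
  i_near <- which.min(abs(temp - t_ref))

  starts <- expand.grid(e = control$e_starts,
                        dt = control$t_pk_offsets,
                        e_d = control$e_d_starts,
                        KEEP.OUT.ATTRS = FALSE)
  starts <- starts[starts$e_d > starts$e, , drop = FALSE]

  best <- NULL
  best_sse <- Inf
  for (s in seq_len(nrow(starts))) {
    e0 <- starts$e[s]
    tpk0 <- min(max(t_at_max + starts$dt[s], t_lo), t_hi)
    d0 <- log(starts$e_d[s] - e0)
    # Arrhenius extrapolation of the measurement nearest T_ref
    lnb00 <- lny[i_near] -
      (e0 / k_boltzmann) * (1 / t_ref - 1 / temp[i_near])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        lny ~ .ss_log_model(lnb0, e, t_pk, d, temp, t_ref),
        start = list(lnb0 = lnb00, e = e0, t_pk = tpk0, d = d0),
        lower = c(lnb0 = -Inf, e = 1e-6, t_pk = t_lo, d = log(1e-4)),
        upper = c(lnb0 = Inf, e = control$e_max, t_pk = t_hi, d = log(29)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.finite(sse) && sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }

  meta <- list(curve_id = curve$curve_id, species_id = curve$species_id,
               trait_name = curve$trait_name, latitude = curve$latitude,
               n_points = length(temp))
  if (is.null(best)) {
    return(structure(c(meta, list(
      converged = FALSE, params = NULL, b0_raw = NA_real_, derived = NULL,
      r_squared = NA_real_, n_below_pk = NA_integer_,
      n_above_pk = NA_integer_,
      qc = c(b0 = FALSE, e = FALSE, w_op = FALSE, t_pk = FALSE,
             b_pk = FALSE, e_d = FALSE),
      vcov = NULL, sigma = NA_real_)), class = "tpc_fit"))
  }

  cf <- stats::coef(best)
  e_hat <- unname(cf["e"])
  e_d_hat <- e_hat + exp(unname(cf["d"]))
  b0_raw <- exp(unname(cf["lnb0"]))
  t_pk_hat <- unname(cf["t_pk"])
  params <- tpc_parameters(b0 = b0_raw, e = e_hat, t_pk = t_pk_hat,
                           e_d = e_d_hat, t_ref = t_ref)
  b0_recalc <- renormalize_b0(params)
  params$b0 <- b0_recalc
  derived <- tryCatch(derive_quantities(params), error = function(e) NULL)
  r2 <- r_squared(lny, stats::fitted(best))
  # measurements exactly at the fitted peak count as "below" (conservative
  # for the rise-side filter rules)
  n_below <- sum(temp <= t_pk_hat)
  n_above <- sum(temp > t_pk_hat)
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  fit_obj <- structure(c(meta, list(
    converged = TRUE, params = params, b0_raw = b0_raw, derived = derived,
    r_squared = r2, n_below_pk = n_below, n_above_pk = n_above,
    qc = NULL, vcov = vc, sigma = stats::sigma(best))), class = "tpc_fit")
  fit_obj$qc <- apply_quality_filters(fit_obj,
                                      min_points = control$min_points)
  fit_obj
}

#' @export
print.tpc_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("TPC fit '%s': FAILED (no start converged)\n", x$curve_id))
    return(invisible(x))
  }
  cat(sprintf("TPC fit '%s' (species %s): R2 = %.3f\n",
              x$curve_id, x$species_id, x$r_squared))
  cat(sprintf("  E = %.3f eV, T_pk = %.2f K, E_D = %.3f eV, B0 = %.4g\n",
              x$params$e, x$params$t_pk, x$params$e_d, x$params$b0))
  cat(sprintf("  points below/above peak: %d/%d; accepted: %s\n",
              x$n_below_pk, x$n_above_pk,
              paste(names(x$qc)[x$qc], collapse = ", ")))
  invisible(x)
}

#' Per-parameter quality filters
#'
#' A fit with R-squared below 0.5 (or undefined) is rejected wholesale.
#' Otherwise each reported quantity is accepted or rejected from the
#' numbers of measurements below and above the fitted peak:
#' \itemize{
#'   \item B0 and E need at least 4 points below T_pk;
#'   \item E is additionally rejected above 4 eV;
#'   \item W_op needs at least 4 points below and 2 above T_pk;
#'   \item T_pk and B_pk need at least 2 points on each side;
#'   \item E_D needs at least 4 points above T_pk.
#' }
#'
#' @param fit A `"tpc_fit"`.
#' @param e_cap Upper acceptance cap on E (eV), default 4.
#' @param min_points Curves with fewer total measurements get all flags
#'   false.
#' @return Named logical vector with elements `b0, e, w_op, t_pk, b_pk,
#'   e_d`.
#' @export
apply_quality_filters <- function(fit, e_cap = 4, min_points = 4) {
  stopifnot(inherits(fit, "tpc_fit"))
  reject_all <- c(b0 = FALSE, e = FALSE, w_op = FALSE, t_pk = FALSE,
                  b_pk = FALSE, e_d = FALSE)
  if (!fit$converged) return(reject_all)
  if (is.na(fit$r_squared) || fit$r_squared < 0.5) return(reject_all)
  if (fit$n_points < min_points) return(reject_all)
  nb <- fit$n_below_pk
  na_ <- fit$n_above_pk
  e_ok <- nb >= 4 && fit$params$e <= e_cap
  c(b0 = nb >= 4,
    e = e_ok,
    w_op = nb >= 4 && na_ >= 2,
    t_pk = nb >= 2 && na_ >= 2,
    b_pk = nb >= 2 && na_ >= 2,
    e_d = na_ >= 4)
}

#' Standard errors of the transformed TPC quantities
#'
#' Delta-method standard errors for ln(B0), ln(E), ln(B_pk), ln(E_D) and
#' T_pk from the inverse-Hessian covariance of the fit, and a seeded
#' nonparametric residual bootstrap (on the log scale) for ln(W_op), whose
#' dependence on the parameters has no convenient closed form.
#'
#' @param fit A converged `"tpc_fit"`.
#' @param curve The [tpc_curve] that produced it.
#' @param n_boot Bootstrap replicates (default from the fit control, 200).
#' @param seed Integer seed for the bootstrap.
#' @return Named numeric vector of standard errors
#'   (`ln_b0, ln_e, t_pk, ln_e_d, ln_b_pk, ln_w_op`); entries are `NA` when
#'   the covariance is unavailable (singular Hessian) rather than invented.
#' @export
estimate_uncertainty <- function(fit, curve, n_boot = 200, seed = 1L) {
  stopifnot(inherits(fit, "tpc_fit"), inherits(curve, "tpc_curve"))
  if (!fit$converged) stop("cannot propagate uncertainty for a failed fit")
  out <- c(ln_b0 = NA_real_, ln_e = NA_real_, t_pk = NA_real_,
           ln_e_d = NA_real_, ln_b_pk = NA_real_, ln_w_op = NA_real_)
  p <- fit$params
  if (!is.null(fit$vcov) && all(is.finite(fit$vcov))) {
    vc <- fit$vcov  # order: lnb0, e, t_pk, d
    e <- p$e
    e_d <- p$e_d
    expd <- e_d - e
    out["ln_b0"] <- sqrt(vc["lnb0", "lnb0"])
    out["ln_e"] <- sqrt(vc["e", "e"]) / e
    out["t_pk"] <- sqrt(vc["t_pk", "t_pk"])
    # ln E_D with E_D = E + exp(d): gradient (0, 1/E_D, 0, exp(d)/E_D)
    g_ed <- c(0, 1 / e_d, 0, expd / e_d)
    out["ln_e_d"] <- sqrt(drop(t(g_ed) %*% vc %*% g_ed))
    # ln B_pk = ln B0_raw - (E/k)(1/T_pk - 1/T_ref) - ln(E_D/(E_D - E))
    g_bpk <- c(1,
               -(1 / k_boltzmann) * (1 / p$t_pk - 1 / p$t_ref) - 1 / e_d,
               (e / k_boltzmann) / p$t_pk^2,
               e / e_d)
    out["ln_b_pk"] <- sqrt(drop(t(g_bpk) %*% vc %*% g_bpk))
  }
  # residual bootstrap for ln(W_op)
  if (!is.null(fit$derived) && n_boot > 0) {
    lny <- log(curve$value)
    pred <- .ss_log_model(log(fit$b0_raw), p$e, p$t_pk, log(p$e_d - p$e),
                          curve$temperature, p$t_ref)
    resid <- lny - pred
    ctrl <- tpc_fit_control(e_starts = p$e, t_pk_offsets = 0,
                            e_d_starts = p$e_d)
    set.seed(as.integer(seed))
    lw <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      yb <- exp(pred + sample(resid, length(resid), replace = TRUE))
      cb <- tpc_curve(curve$curve_id, curve$species_id,
                      curve$temperature, yb, curve$trait_name,
                      curve$latitude)
      fb <- suppressWarnings(fit_sharpe_schoolfield(cb, ctrl, p$t_ref))
      if (fb$converged && !is.null(fb$derived))
        lw[b] <- log(fb$derived$w_op)
    }
    if (sum(!is.na(lw)) >= 2) out["ln_w_op"] <- stats::sd(lw, na.rm = TRUE)
  }
  out
}

#' Gaussian-scale trait table rows from an accepted fit
#'
#' Emits the log-transformed parameters (and T_pk untransformed) whose
#' quality flags are accepted, each with its variance when standard errors
#' are supplied. The log transforms bring the right-skewed parameter
#' distributions close to Gaussian, as the comparative analyses assume.
#'
#' @param fit A converged `"tpc_fit"`.
#' @param se Optional named SE vector from [estimate_uncertainty].
#' @return A data.frame with columns `species_id, curve_id, trait_name,
#'   variable, value, variance` (zero rows if nothing is accepted).
#' @export
transform_parameters <- function(fit, se = NULL) {
  stopifnot(inherits(fit, "tpc_fit"))
  empty <- data.frame(species_id = character(), curve_id = character(),
                      trait_name = character(), variable = character(),
                      value = numeric(), variance = numeric(),
                      stringsAsFactors = FALSE)
  if (!fit$converged) return(empty)
  p <- fit$params
  d <- fit$derived
  vals <- c(ln_b0 = if (p$b0 > 0) log(p$b0) else NA_real_,
            ln_e = log(p$e),
            ln_w_op = if (!is.null(d) && d$w_op > 0) log(d$w_op)
                      else NA_real_,
            t_pk = p$t_pk,
            ln_b_pk = if (!is.null(d) && d$b_pk > 0) log(d$b_pk)
                      else NA_real_,
            ln_e_d = log(p$e_d))
  flag_of <- c(ln_b0 = "b0", ln_e = "e", ln_w_op = "w_op", t_pk = "t_pk",
               ln_b_pk = "b_pk", ln_e_d = "e_d")
  keep <- names(vals)[fit$qc[flag_of] & !is.na(vals)]
  if (!length(keep)) return(empty)
  variance <- rep(NA_real_, length(keep))
  if (!is.null(se)) {
    idx <- match(keep, names(se))
    variance <- ifelse(is.na(idx), NA_real_, se[idx]^2)
  }
  data.frame(species_id = fit$species_id, curve_id = fit$curve_id,
             trait_name = fit$trait_name, variable = keep,
             value = unname(vals[keep]), variance = unname(variance),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the best fit per species
#'
#' The comparative analyses use one value per species: the fit with the
#' highest R-squared; ties are broken by the larger number of measurements,
#' then by lexicographic curve id.
#'
#' @param fits A list of `"tpc_fit"` objects.
#' @return Named list (by species id) of the selected fits; failed fits are
#'   dropped.
#' @export
best_fit_per_species <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) return(list())
  sp <- vapply(fits, `[[`, character(1), "species_id")
  out <- list()
  for (s in sort(unique(sp))) {
    cand <- fits[sp == s]
    r2 <- vapply(cand, `[[`, numeric(1), "r_squared")
    np <- vapply(cand, `[[`, numeric(1), "n_points")
    id <- vapply(cand, `[[`, character(1), "curve_id")
    ord <- order(-r2, -np, id)
    out[[s]] <- cand[[ord[1]]]
  }
  out
}
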