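#' Mono-exponential pharmacokinetic parameters
#'
#' First-order elimination: `C(t) = C0 * exp(-ke * t)` with
#' `ke = ln(2) / t_half`. Brain ketamine clears with a half-life of roughly
#' 13 minutes in mice, the time scale against which the day-long NMDAR
#' blockade is paradoxical.
#'
#' @param C0 Initial concentration (uM, > 0).
#' @param t_half Elimination half-life (min, > 0).
#' @return An object of class `pk_params` with `C0`, `t_half`, `ke` (1/min).
#' @export
pk_params <- function(C0, t_half) {
  check_number(C0, "C0", lower = 0, allow_equal_lower = FALSE)
  check_number(t_half, "t_half", lower = 0, allow_equal_lower = FALSE)
  structure(list(C0 = C0, t_half = t_half, ke = log(2) / t_half),
            class = "pk_params")
}

#' Concentration at time t under first-order elimination
#'
#' @param params A [pk_params()].
#' @param t Time in minutes (vectorized, >= 0).
#' @return Concentration in uM: `C0 * 2^(-t / t_half)`.
#' @export
conc_at <- function(params, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop_invalid("`t` must be non-negative")
  params$C0 * exp(-params$ke * t)
}

#' Fit a mono-exponential decay to a concentration profile
#'
#' Log-linear least squares of `ln C` on `t`; the half-life is
#' `ln(2) / |slope|`. Noiseless mono-exponential inputs are recovered
#' exactly. Non-positive concentrations cannot enter the log fit: they are
#' dropped with a warning when they are at most 20% of the points, otherwise
#' the fit errors.
#'
#' @param profile A [pk_profile()] (or any list with `times` and
#'   `concentrations`).
#' @return A [pk_params()] with additional fields `se` (standard errors of
#'   `ke` and `t_half`, delta method) and `fit` (the underlying `lm`).
#' @export
fit_monoexp <- function(profile) {
  t <- profile$times; y <- profile$concentrations
  pos <- y > 0
  if (sum(!pos) > 0) {
    if (mean(!pos) > 0.2)
      stop_invalid("more than 20% of concentrations are non-positive",
                   class = "habtrap_log_domain_error")
    warning(sprintf("dropping %d non-positive concentration(s) from log fit",
                    sum(!pos)))
    t <- t[pos]; y <- y[pos]
  }
  if (length(y) < 3L)
    stop_invalid("need at least 3 positive concentrations")
  fit <- stats::lm(log(y) ~ t)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= -1e-12)
    stop_invalid("non-decaying profile; half-life undefined",
                 class = "habtrap_degenerate_fit")
  ke <- -slope
  t_half <- log(2) / ke
  se_slope <- tryCatch(suppressWarnings(summary(fit)$coefficients[2L, 2L]),
                       error = function(e) NA_real_)
  out <- pk_params(C0 = exp(unname(stats::coef(fit)[1L])), t_half = t_half)
  out$se <- c(ke = se_slope, t_half = log(2) / ke^2 * se_slope)
  out$fit <- fit
  out
}

#' Piecewise-linear concentration forcing function from a tabulated profile
#'
#' The measured brain concentration curve is not mono-exponential from its
#' peak; for driving the kinetic simulator the profile is used as a
#' tabulated forcing function (linear interpolation, constant extrapolation
#' at the ends) rather than forced through a parametric fit.
#'
#' @param profile A [pk_profile()] with times in minutes.
#' @return A function of time in seconds returning concentration in uM.
#' @export
conc_fun_from_profile <- function(profile) {
  f <- stats::approxfun(profile$times * 60, profile$concentrations, rule = 2)
  function(t_s) f(t_s)
}
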