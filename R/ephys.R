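# patch-clamp photocurrent analysis rules

#' Peak photocurrent within the light window
#'
#' Signed extremum (maximum absolute current) of the raw trace inside the
#' illumination window; no smoothing is applied (pre-filter upstream if
#' needed). Inward currents are negative by convention.
#'
#' @param trace a `photocurrent_trace` (see [current_from_occupancy()]) or a
#'   data frame with `time_s`, `current_pA`.
#' @param light_window optional c(on, off) override (s).
#' @return peak current (pA, signed).
#' @export
extract_peak <- function(trace, light_window = attr(trace, "light_window")) {
  if (is.null(light_window)) abort_pc("light window is not set")
  sel <- trace$time_s >= light_window[1] & trace$time_s <= light_window[2]
  if (!any(sel)) abort_pc("no samples inside the light window")
  i <- which.max(abs(trace$current_pA[sel]))
  trace$current_pA[sel][i]
}

#' Stationary photocurrent (last 50 ms of illumination)
#'
#' Mean current over the final 50 ms of the light window — the standard rule
#' for quantifying the residual current of a strongly desensitizing channel.
#'
#' @inheritParams extract_peak
#' @param window_s averaging window before light-off (s), default 0.05.
#' @return stationary current (pA, signed).
#' @export
extract_stationary <- function(trace, light_window = attr(trace, "light_window"),
                               window_s = 0.05) {
  if (is.null(light_window)) abort_pc("light window is not set")
  if (diff(light_window) < window_s - 1e-12) {
    abort_pc("light window shorter than the ", window_s * 1e3,
             " ms stationary averaging rule")
  }
  sel <- trace$time_s >= light_window[2] - window_s & trace$time_s <= light_window[2]
  mean(trace$current_pA[sel])
}

#' Desensitization extent
#'
#' 1 - |stationary / peak|, the fraction of the peak current lost during
#' continuous illumination (0 = none, 1 = complete).
#'
#' @param peak,stationary currents (pA); same sign, or stationary 0.
#' @return fraction in \[0, 1\].
#' @export
desensitization_extent <- function(peak, stationary) {
  if (peak == 0) abort_pc("zero peak current")
  if (stationary != 0 && sign(stationary) != sign(peak)) {
    abort_pc("peak and stationary currents must share a sign")
  }
  max(0, min(1, 1 - abs(stationary / peak)))
}

# multi-exponential model via variable projection over log10 taus
exp_resid <- function(theta, t, y, offset = TRUE) {
  E <- exp(-outer(t, 1 / 10^theta))       # n x k
  X <- if (offset) cbind(1, E) else E
  co <- qr.coef(qr(X), y)
  co[is.na(co)] <- 0
  list(resid = y - X %*% co, coef = co)
}

#' Mono- or bi-exponential fit of a kinetic segment
#'
#' Least-squares fit of `offset + sum(a_i exp(-t/tau_i))` to a
#' monotone-trending segment (crop before calling). Time constants are
#' optimized in log space with exact linear amplitudes (variable projection);
#' taus are returned ascending and the apparent time constant is the
#' amplitude-weighted mean `sum(|a_i| tau_i) / sum(|a_i|)`.
#'
#' @param times,values the segment to fit (times in s).
#' @param model_order 1 or 2 exponentials.
#' @param offset fit an additive offset (default TRUE).
#' @return object of class `exp_fit`: amplitudes, `taus` (s), offset,
#'   `apparent_tau`, `residual_rms`, `aic`, `converged`, `degenerate`.
#' @export
fit_exponentials <- function(times, values, model_order = 1, offset = TRUE) {
  if (!model_order %in% c(1, 2)) abort_pc("model_order must be 1 or 2")
  if (length(times) < 5 * model_order) {
    abort_pc("need at least ", 5 * model_order, " points for model order ", model_order)
  }
  t <- as.numeric(times) - times[1]
  y <- as.numeric(values)
  span <- max(t[t > 0])
  tau0 <- if (model_order == 1) span / 3 else c(span / 20, span / 2)
  fit <- minpack.lm::nls.lm(
    par = log10(tau0),
    fn = function(th) exp_resid(th, t, y, offset)$resid,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15, ptol = 1e-15))
  taus <- 10^fit$par
  o <- order(taus)
  res <- exp_resid(log10(taus), t, y, offset)
  co <- as.numeric(res$coef)
  off <- if (offset) co[1] else 0
  amps <- (if (offset) co[-1] else co)[o]
  taus <- taus[o]
  rng <- diff(range(y))
  degenerate <- rng == 0 || sum(abs(amps)) < 1e-6 * max(rng, abs(off), 1e-300)
  apparent <- if (sum(abs(amps)) > 0) sum(abs(amps) * taus) / sum(abs(amps)) else NA_real_
  rss <- sum(res$resid^2)
  n <- length(y); k <- length(amps) * 2 + as.integer(offset)
  structure(list(amplitudes = amps, taus = taus, offset = off,
                 model_order = model_order, apparent_tau = apparent,
                 residual_rms = sqrt(rss / n),
                 aic = n * log(max(rss, 1e-300) / n) + 2 * k,
                 converged = fit$info %in% 1:4 && !degenerate,
                 degenerate = degenerate),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> order", x$model_order, "; taus (s):",
      paste(signif(x$taus, 4), collapse = ", "),
      "; apparent tau:", signif(x$apparent_tau, 4), "\n")
  invisible(x)
}

#' @rdname fit_exponentials
#' @param x an `exp_fit`.
#' @param ... unused.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c(paste0("tau", seq_along(x$taus)),
                          paste0("amplitude", seq_along(x$amplitudes)),
                          "offset", "apparent_tau"),
                 estimate = c(x$taus, x$amplitudes, x$offset, x$apparent_tau))
}

#' @rdname fit_exponentials
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(model_order = x$model_order, residual_rms = x$residual_rms,
                 aic = x$aic, converged = x$converged, degenerate = x$degenerate)
}

#' Reversal potential from a current-voltage series
#'
#' If consecutive voltages bracket a sign change, the crossing is found by
#' linear interpolation within the first such pair (scanning from negative
#' voltages). Otherwise the line through the two voltage-adjacent points of
#' smallest absolute current is extrapolated to zero; when the smallest-|I|
#' points are not adjacent, the adjacent pair containing the global minimum
#' |I| is used.
#'
#' @param iv data frame with strictly increasing `voltage_mV` and `current_pA`
#'   (one condition), at least 2 rows.
#' @return reversal potential (mV).
#' @export
reversal_potential <- function(iv) {
  v <- iv$voltage_mV; i <- iv$current_pA
  if (length(v) < 2) abort_pc("need at least two IV points")
  if (!is_strictly_increasing(v)) abort_pc("voltages must be strictly increasing")
  s <- sign(i)
  cross <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  cross0 <- which(s[-length(s)] == 0)
  if (length(cross0)) return(v[cross0[1]])
  if (length(cross)) {
    j <- cross[1]
    if (i[j] == 0 && i[j + 1] == 0) abort_pc("both currents zero in the crossing pair")
    return(v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j]))
  }
  # extrapolation branch: two smallest-|I| points, required voltage-adjacent
  o <- order(abs(i))
  j1 <- o[1]; j2 <- o[2]
  if (abs(j1 - j2) != 1L) {
    jmin <- o[1]  # adjacent pair containing the global minimum |I|
    cand <- c(jmin - 1L, jmin + 1L)
    cand <- cand[cand >= 1 & cand <= length(v)]
    j2 <- cand[which.min(abs(i[cand]))]
    j1 <- jmin
  }
  lo <- min(j1, j2); hi <- max(j1, j2)
  if (i[hi] == i[lo]) abort_pc("degenerate extrapolation pair (equal currents)")
  v[lo] - i[lo] * (v[hi] - v[lo]) / (i[hi] - i[lo])
}

#' Nernst equilibrium potential
#'
#' E = (RT / zF) ln(c_out / c_in), in mV.
#'
#' @param c_out,c_in concentrations (mM, > 0).
#' @param z ion charge (non-zero integer).
#' @param temperature_C temperature (degrees C), default 24 (HEK recordings).
#' @return potential (mV).
#' @export
nernst_potential <- function(c_out, c_in, z, temperature_C = 24) {
  if (z == 0) abort_pc("z must be non-zero")
  if (c_out <= 0 || c_in <= 0) abort_pc("concentrations must be positive")
  rt_over_f(temperature_C) / z * log(c_out / c_in)
}

#' Bi-ionic permeability ratio from a reversal-potential shift
#'
#' P_test / P_ref = exp(z F dE / (RT)) with dE = E_rev(test) - E_rev(ref),
#' under full substitution of the reference ion by the test ion. The sign
#' convention is chosen so that for an anion (z = -1) a negative shift —
#' i.e. the test anion enters more readily — gives a ratio above one
#' (dE = -25.61 mV at 24 degrees C gives e = 2.718).
#'
#' @param delta_e_rev_mV reversal-potential shift (mV).
#' @param z charge of the substituted ion.
#' @param temperature_C temperature (degrees C).
#' @return permeability ratio (dimensionless).
#' @export
permeability_ratio <- function(delta_e_rev_mV, z, temperature_C = 24) {
  exp(z * delta_e_rev_mV / rt_over_f(temperature_C))
}

#' Fit the double-pulse recovery curve
#'
#' Fits R(dt) = 1 - exp(-dt / tau_rec) to peak-ratio vs dark-interval data,
#' the mono-exponential repopulation law of the dark state.
#'
#' @param recovery data frame with `interval_s`, `peak_ratio` (>= 4 rows).
#' @return an `exp_fit`-style object with `tau_rec` (s).
#' @export
recovery_fit <- function(recovery) {
  dt <- recovery$interval_s; r <- recovery$peak_ratio
  if (length(dt) < 4) abort_pc("need at least 4 recovery intervals")
  if (diff(range(r)) < 1e-3) {
    return(structure(list(tau_rec = NA_real_, residual_rms = 0,
                          converged = FALSE, degenerate = TRUE),
                     class = c("recovery_fit", "exp_fit")))
  }
  fit <- minpack.lm::nls.lm(
    par = log10(stats::median(dt)),
    fn = function(th) r - (1 - exp(-dt / 10^th)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  tau <- 10^fit$par
  structure(list(tau_rec = tau,
                 residual_rms = sqrt(sum(fit$fvec^2) / length(dt)),
                 converged = fit$info %in% 1:4, degenerate = FALSE),
            class = c("recovery_fit", "exp_fit"))
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit> tau_rec:", signif(x$tau_rec, 4), "s\n")
  invisible(x)
}

#' @rdname recovery_fit
#' @param x a `recovery_fit`.
#' @param ... unused.
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(term = "tau_rec", estimate = x$tau_rec)
}

#' @rdname recovery_fit
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms, converged = x$converged,
                 degenerate = x$degenerate)
}
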