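# seeded generators for every input the pipeline consumes; each is a pure
# function of (parameters, seed) and attaches its ground truth as attributes

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

#' Generate a synthetic photocurrent trace
#'
#' Simulates a packaged fixture under a light protocol, converts the
#' conducting occupancy to current ohmically, and adds i.i.d. Gaussian noise.
#' The reversal potential defaults to the Nernst potential for chloride at
#' the fixture's recording conditions (150 mM out / 120 mM in, 24 degrees C).
#'
#' @param fixture fixture name, see [fixture_scheme()].
#' @param protocol a [light_protocol()].
#' @param times evaluation grid (s).
#' @param voltage_mV holding potential.
#' @param e_rev_mV reversal potential; `NULL` = chloride Nernst value.
#' @param conductance_scale pA/mV.
#' @param noise_sd_pA Gaussian noise SD (pA); 0 reproduces the simulator.
#' @param seed RNG seed (NULL = use current RNG state).
#' @param sigma photoexcitation coefficient.
#' @return `photocurrent_trace` tibble; ground truth in `trace_meta()$metadata`.
#' @export
gen_photocurrent <- function(fixture = "mermaid1_ephys", protocol, times,
                             voltage_mV = -60, e_rev_mV = NULL,
                             conductance_scale = 20, noise_sd_pA = 0,
                             seed = NULL, sigma = 1) {
  if (is.null(e_rev_mV)) {
    e_rev_mV <- nernst_potential(fixture_value("mermaid1_ephys", "cl_out"),
                                 fixture_value("mermaid1_ephys", "cl_in"),
                                 z = -1,
                                 temperature_C = fixture_value("mermaid1_ephys",
                                                               "temperature"))
  }
  scheme <- fixture_scheme(fixture, sigma = sigma)
  traj <- propagate(scheme, protocol, times)
  seg <- protocol$segments
  lw <- if (nrow(seg)) c(min(seg$t_start), max(seg$t_end)) else NULL
  if (!is.null(lw)) {
    lw[1] <- max(lw[1], min(times)); lw[2] <- min(lw[2], max(times))
  }
  trace <- current_from_occupancy(traj, scheme, voltage_mV = voltage_mV,
                                  e_rev_mV = e_rev_mV,
                                  conductance_scale = conductance_scale,
                                  light_window = lw)
  noisy <- trace$current_pA +
    with_seed(seed, stats::rnorm(nrow(trace), 0, noise_sd_pA))
  new_photocurrent_trace(
    tibble::tibble(time_s = trace$time_s, current_pA = noisy),
    voltage_mV = voltage_mV, e_rev_mV = e_rev_mV,
    conductance_scale = conductance_scale, light_window = lw,
    metadata = list(fixture = fixture, noise_sd_pA = noise_sd_pA, seed = seed,
                    ground_truth = list(
                      tau_open = scheme$thermal_rates$rate[1]^-1,
                      tau_close = scheme$thermal_rates$rate[2]^-1,
                      tau_recover = scheme$thermal_rates$rate[3]^-1,
                      clean_current_pA = trace$current_pA)))
}

# Gaussian band in wavelength
gauss_band <- function(wl, center, sd, amp = 1) amp * exp(-(wl - center)^2 / (2 * sd^2))

#' Model EADS of the packaged spectroscopy fixture
#'
#' Difference spectra (vs. the dark state) of the K, L and M intermediates,
#' built from Gaussian bands: every intermediate carries the negative
#' dark-state bleach at 502 nm; K adds a red-shifted photoproduct band, L a
#' slightly blue-shifted and broadened dark-like band, and M the
#' fine-structured UV triple band at 346/364/384 nm.
#'
#' @param wavelengths_nm wavelength grid.
#' @return matrix wavelengths x 3 (K, L, M).
#' @export
fixture_eads <- function(wavelengths_nm) {
  wl <- wavelengths_nm
  bleach <- -gauss_band(wl, 502, 28, 1.0)
  k_spec <- bleach + gauss_band(wl, 535, 30, 0.85)
  l_spec <- bleach + gauss_band(wl, 490, 36, 0.80)
  m_spec <- bleach +
    gauss_band(wl, 346, 7, 0.55) +
    gauss_band(wl, 364, 8, 0.75) +
    gauss_band(wl, 384, 9, 0.60)
  cbind(K = k_spec, L = l_spec, M = m_spec)
}

#' Generate a synthetic transient-absorption matrix
#'
#' Builds delta-A = EADS x sequential concentration profiles from the
#' spectroscopy fixture lifetimes (173 ns, 6 ms, 1.2 s) on the requested
#' grid and adds Gaussian noise. At long times the matrix returns to zero
#' (full dark-state recovery).
#'
#' @param times time grid (s), default the standard 101-point isolog grid.
#' @param wavelengths_nm wavelength axis (nm).
#' @param noise_sd Gaussian noise SD (delta-A units).
#' @param seed RNG seed.
#' @param lifetimes chain lifetimes (s); default from the fixture registry.
#' @param excluded_ranges optional scatter-mask intervals (nm).
#' @return [time_resolved_spectra()]; ground truth in `$metadata`.
#' @export
gen_transient_absorption <- function(times = make_isolog_grid(10e-9, 100, 10),
                                     wavelengths_nm = seq(300, 650, by = 2),
                                     noise_sd = 0, seed = NULL,
                                     lifetimes = NULL,
                                     excluded_ranges = NULL) {
  if (is.null(lifetimes)) {
    lifetimes <- c(fixture_value("mermaid1_spectro", "tau_K"),
                   fixture_value("mermaid1_spectro", "tau_L"),
                   fixture_value("mermaid1_spectro", "tau_M"))
  }
  eads <- fixture_eads(wavelengths_nm)[, seq_along(lifetimes), drop = FALSE]
  conc <- bateman_concentrations(lifetimes, times)
  M <- eads %*% conc
  M <- M + with_seed(seed, matrix(stats::rnorm(length(M), 0, noise_sd),
                                  nrow(M), ncol(M)))
  time_resolved_spectra(wavelengths_nm, times, M, axis_kind = "wavelength",
                        excluded_ranges = excluded_ranges,
                        metadata = list(lifetimes = lifetimes, eads = eads,
                                        noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic pH-titration series
#'
#' @param pK transition midpoint; default the fixture value (9.8).
#' @param hill Hill slope (default 1).
#' @param ph_grid sampling grid; default 7.8-10.4 in 0.2 steps.
#' @param plateaus c(acid-side, base-side) amplitudes.
#' @param noise_sd Gaussian noise SD (amplitude units).
#' @param seed RNG seed.
#' @return tibble `pH`, `amplitude`; ground truth as attribute `ground_truth`.
#' @export
gen_titration <- function(pK = fixture_value("mermaid1_spectro", "pK"),
                          hill = 1,
                          ph_grid = seq(fixture_value("mermaid1_spectro", "titration_min"),
                                        fixture_value("mermaid1_spectro", "titration_max"),
                                        by = 0.2),
                          plateaus = c(0, 1), noise_sd = 0, seed = NULL) {
  amp <- boltzmann_curve(ph_grid, plateaus[1], plateaus[2], pK, hill)
  amp <- amp + with_seed(seed, stats::rnorm(length(amp), 0, noise_sd))
  out <- tibble::tibble(pH = ph_grid, amplitude = amp)
  attr(out, "ground_truth") <- list(pK = pK, hill = hill, plateaus = plateaus,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic action spectrum
#'
#' Weibull-shaped response peaking at the fixture's maximum-response
#' wavelength (502 nm), max-normalized.
#'
#' @param wavelengths_nm grid; default 390-680 nm in 10 nm steps.
#' @param lambda_max_nm peak wavelength; default from the fixture registry.
#' @param lambda0,k Weibull location (nm) and shape; the scale beta is solved
#'   from `lambda_max_nm`.
#' @param noise_sd Gaussian noise SD (normalized units).
#' @param seed RNG seed.
#' @return tibble `wavelength_nm`, `response` with attribute `ground_truth`.
#' @export
gen_action_spectrum <- function(wavelengths_nm = seq(390, 680, by = 10),
                                lambda_max_nm = fixture_value("mermaid1_spectro",
                                                              "action_lambda_max"),
                                lambda0 = 350, k = 2.5,
                                noise_sd = 0, seed = NULL) {
  beta <- (lambda_max_nm - lambda0) / ((k - 1) / k)^(1 / k)
  resp <- weibull_shape(wavelengths_nm, lambda0, beta, k)
  resp <- resp / max(resp)
  resp <- resp + with_seed(seed, stats::rnorm(length(resp), 0, noise_sd))
  resp <- resp / max(resp)
  out <- tibble::tibble(wavelength_nm = wavelengths_nm, response = resp)
  attr(out, "ground_truth") <- list(lambda_max_nm = lambda_max_nm,
                                    lambda0 = lambda0, beta = beta, k = k,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a linear current-voltage series
#'
#' @param e_rev_mV reversal potential.
#' @param slope_pA_per_mV chord conductance.
#' @param voltages_mV default -80..+40 mV in 20 mV steps.
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed RNG seed.
#' @return tibble `voltage_mV`, `current_pA` with attribute `ground_truth`.
#' @export
gen_iv <- function(e_rev_mV, slope_pA_per_mV = 10,
                   voltages_mV = seq(-80, 40, by = 20),
                   noise_sd = 0, seed = NULL) {
  i <- slope_pA_per_mV * (voltages_mV - e_rev_mV)
  i <- i + with_seed(seed, stats::rnorm(length(i), 0, noise_sd))
  out <- tibble::tibble(voltage_mV = voltages_mV, current_pA = i)
  attr(out, "ground_truth") <- list(e_rev_mV = e_rev_mV,
                                    slope_pA_per_mV = slope_pA_per_mV,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a double-pulse recovery series
#'
#' @param tau_rec_s recovery time constant.
#' @param intervals_s dark intervals (s).
#' @param noise_sd Gaussian noise SD on the ratios.
#' @param seed RNG seed.
#' @return tibble `interval_s`, `peak_ratio` with attribute `ground_truth`.
#' @export
gen_recovery <- function(tau_rec_s = fixture_value("mermaid1_ephys", "tau_recover"),
                         intervals_s = c(0.2, 0.5, 1, 2, 5, 10),
                         noise_sd = 0, seed = NULL) {
  r <- 1 - exp(-intervals_s / tau_rec_s)
  r <- r + with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
  out <- tibble::tibble(interval_s = intervals_s, peak_ratio = pmin(r, 1))
  attr(out, "ground_truth") <- list(tau_rec_s = tau_rec_s, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Generate a rhodopsin-like steady-state absorption spectrum
#'
#' Dark state: protein band at 280 nm plus a chromophore Gaussian at the dark
#' peak. M-like state: the fine-structured UV triple band. Used for
#' normalization, smoothing, difference and sub-maxima tests.
#'
#' @param state `"dark"` or `"m_state"`.
#' @param wavelengths_nm grid (nm).
#' @param noise_sd Gaussian noise SD (AU).
#' @param seed RNG seed.
#' @return tibble `wavelength_nm`, `absorbance` with attribute `ground_truth`.
#' @export
gen_steady_spectrum <- function(state = c("dark", "m_state"),
                                wavelengths_nm = seq(250, 700, by = 1),
                                noise_sd = 0, seed = NULL) {
  state <- match.arg(state)
  wl <- wavelengths_nm
  protein <- gauss_band(wl, 280, 18, 2.0)
  chromo <- if (state == "dark") {
    gauss_band(wl, fixture_value("mermaid1_spectro", "dark_peak"), 28, 1.0)
  } else {
    gauss_band(wl, 346, 5.5, 0.55) + gauss_band(wl, 364, 6, 0.75) +
      gauss_band(wl, 384, 6.5, 0.60)
  }
  a <- protein + chromo
  a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sd))
  out <- tibble::tibble(wavelength_nm = wl, absorbance = a)
  attr(out, "ground_truth") <- list(state = state, noise_sd = noise_sd, seed = seed)
  out
}
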