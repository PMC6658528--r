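# packaged parameter fixtures for the MerMAID anion channelrhodopsins

#' Three-state reduction of the photocycle
#'
#' C --(sigma * I)--> O --(k_close)--> D --(k_recover)--> C. Useful for
#' closed-form analysis: under saturating light the stationary open fraction
#' tends to k_recover / (k_recover + k_close).
#'
#' @param k_close O->D rate (1/s).
#' @param k_recover D->C rate (1/s).
#' @param sigma cross-section-like coefficient of the C->O photo transition.
#' @return a [kinetic_scheme()].
#' @export
three_state_scheme <- function(k_close, k_recover, sigma = 1) {
  kinetic_scheme(
    states = c("C", "O", "Dst"),
    conducting = "O",
    ground = "C",
    photo_rates = tibble::tibble(from = "C", to = "O", coefficient = sigma),
    thermal_rates = tibble::tibble(from = c("O", "Dst"), to = c("Dst", "C"),
                                   rate = c(k_close, k_recover)))
}

#' Four-state photocycle D -> K -> L -> M -> D
#'
#' The canonical single-photocycle model: photon absorption converts the dark
#' state D to the early K intermediate, which relaxes thermally through the
#' conducting L state into the blue-shifted, non-conducting M state; M decays
#' back to D on the seconds scale and is not photoactive.
#'
#' @param tau_K,tau_L,tau_M lifetimes (s) of K (K->L), L (L->M) and M (M->D).
#' @param sigma photoexcitation coefficient of D.
#' @return a [kinetic_scheme()].
#' @export
four_state_scheme <- function(tau_K, tau_L, tau_M, sigma = 1) {
  kinetic_scheme(
    states = c("D", "K", "L", "M"),
    conducting = "L",
    ground = "D",
    photo_rates = tibble::tibble(from = "D", to = "K", coefficient = sigma),
    thermal_rates = tibble::tibble(from = c("K", "L", "M"),
                                   to = c("L", "M", "D"),
                                   rate = 1 / c(tau_K, tau_L, tau_M)))
}

#' Calibrate the effective opening lifetime from the conductance-peak time
#'
#' For a delta flash into the pre-open state the open occupancy is
#' f(t) = k1/(k1 - k2) (exp(-k2 t) - exp(-k1 t)), peaking at
#' t_peak = ln(k1/k2)/(k1 - k2). Given the closing rate k2 and the observed
#' peak time this solves for the opening rate k1 by root finding.
#'
#' @param t_peak_s observed time of maximal conductance after the flash (s).
#' @param tau_close_s closing lifetime 1/k2 (s).
#' @return opening lifetime 1/k1 (s).
#' @examples
#' calibrate_opening_tau(350e-6, 2.7e-3) # about 103 microseconds
#' @export
calibrate_opening_tau <- function(t_peak_s, tau_close_s) {
  k2 <- 1 / tau_close_s
  f <- function(k1) log(k1 / k2) / (k1 - k2) - t_peak_s
  # peak time decreases with k1; bracket above k2
  sol <- stats::uniroot(f, lower = k2 * (1 + 1e-9), upper = 1e9,
                        tol = 1e-15)
  1 / sol$root
}

#' Packaged fixture parameter registry
#'
#' Every numeric that parameterizes the packaged MerMAID fixtures, with units
#' and a provenance note (measurement the value represents, or the derivation
#' rule used). Two MerMAID1 fixtures are kept deliberately distinct: the
#' electrophysiology fixture carries the apparent electrical constants
#' (350 us conductance peak, 2.7 ms closing, 1.21 s recovery) while the
#' spectroscopy fixture carries the spectroscopic lifetimes
#' (173 ns, 6 ms, 1.2 s); the two are not reconciled by construction.
#'
#' @return tibble with columns `fixture`, `parameter`, `value`, `units`,
#'   `provenance`.
#' @export
fixture_registry <- function() {
  tibble::tribble(
    ~fixture, ~parameter, ~value, ~units, ~provenance,
    "mermaid1_ephys", "t_peak", 350e-6, "s",
      "measured time of maximal conductance after ns-flash excitation",
    "mermaid1_ephys", "tau_close", 2.7e-3, "s",
      "apparent closing time constant (dominant fast component)",
    "mermaid1_ephys", "tau_open", calibrate_opening_tau(350e-6, 2.7e-3), "s",
      "derived: root of ln(k1/k2)/(k1-k2) = t_peak given tau_close",
    "mermaid1_ephys", "tau_recover", 1.21, "s",
      "peak-current recovery time constant from double-pulse experiments",
    "mermaid1_ephys", "cl_out", 150, "mM",
      "standard extracellular chloride of the recording buffer",
    "mermaid1_ephys", "cl_in", 120, "mM",
      "intracellular chloride of the recording buffer",
    "mermaid1_ephys", "temperature", 24, "degC",
      "recording temperature of the HEK-cell experiments",
    "mermaid1_spectro", "tau_K", 173e-9, "s",
      "K-intermediate decay lifetime from transient absorption",
    "mermaid1_spectro", "tau_L", 6e-3, "s",
      "L->M conversion lifetime from transient absorption",
    "mermaid1_spectro", "tau_M", 1.2, "s",
      "M decay / dark-state recovery on the seconds scale",
    "mermaid1_spectro", "dark_peak", 502, "nm",
      "dark-state absorption maximum",
    "mermaid1_spectro", "m_submax_1", 346, "nm",
      "first sub-maximum of the fine-structured M spectrum",
    "mermaid1_spectro", "m_submax_2", 364, "nm",
      "second sub-maximum of the fine-structured M spectrum",
    "mermaid1_spectro", "m_submax_3", 384, "nm",
      "third sub-maximum of the fine-structured M spectrum",
    "mermaid1_spectro", "pK", 9.8, "pH",
      "alkaline transition pK of the dark state",
    "mermaid1_spectro", "titration_min", 7.8, "pH",
      "lower bound of the titration series",
    "mermaid1_spectro", "titration_max", 10.4, "pH",
      "upper bound of the titration series",
    "mermaid1_spectro", "action_lambda_max", 502, "nm",
      "action-spectrum maximum, matching the dark-state absorption peak",
    "mermaid6_ephys", "tau_close", 2.7e-3, "s",
      "closing constant assumed as for MerMAID1 (not separately fixed)",
    "mermaid6_ephys", "tau_open", calibrate_opening_tau(350e-6, 2.7e-3), "s",
      "derived as for mermaid1_ephys",
    "mermaid6_ephys", "tau_recover", 6, "s",
      "slowest recovery constant of the family",
  )
}

fixture_value <- function(fixture, parameter) {
  reg <- fixture_registry()
  v <- reg$value[reg$fixture == fixture & reg$parameter == parameter]
  if (length(v) != 1L) abort_pc("unknown fixture parameter: ", fixture, "/", parameter)
  v
}

#' Build the kinetic scheme of a packaged fixture
#'
#' @param name one of `"mermaid1_ephys"`, `"mermaid1_spectro"`, `"mermaid6_ephys"`.
#' @param sigma photoexcitation coefficient (arbitrary intensity units).
#' @return a [kinetic_scheme()].
#' @export
fixture_scheme <- function(name = c("mermaid1_ephys", "mermaid1_spectro",
                                    "mermaid6_ephys"), sigma = 1) {
  name <- match.arg(name)
  if (name == "mermaid1_spectro") {
    four_state_scheme(tau_K = fixture_value(name, "tau_K"),
                      tau_L = fixture_value(name, "tau_L"),
                      tau_M = fixture_value(name, "tau_M"), sigma = sigma)
  } else {
    four_state_scheme(tau_K = fixture_value(name, "tau_open"),
                      tau_L = fixture_value(name, "tau_close"),
                      tau_M = fixture_value(name, "tau_recover"), sigma = sigma)
  }
}
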