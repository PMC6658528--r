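#' Define a photocycle kinetic scheme
#'
#' A kinetic scheme is a continuous-time Markov model of the photocycle:
#' a set of named states, a logical mask marking which states conduct,
#' light-driven transitions whose rate is `coefficient * intensity`
#' (cross-section-like, per second per intensity unit) and first-order
#' thermal transitions (per second). The canonical model for desensitizing
#' anion channelrhodopsins is the four-state cycle
#' dark --(light)--> K --> L (conducting) --> M (desensitized) --> dark,
#' where M is not photoactive and recovers thermally.
#'
#' @param states character vector of state labels (ordered).
#' @param conducting character vector of conducting state labels.
#' @param ground single label of the dark (ground) state.
#' @param photo_rates data frame with columns `from`, `to`, `coefficient`
#'   (rate per unit light intensity, 1/(s * intensity unit)).
#' @param thermal_rates data frame with columns `from`, `to`, `rate` (1/s).
#' @return an object of class `kinetic_scheme`.
#' @examples
#' three_state_scheme(k_close = 1 / 2.7e-3, k_recover = 1 / 1.21)
#' @export
kinetic_scheme <- function(states, conducting, ground, photo_rates, thermal_rates) {
  states <- as.character(states)
  if (anyDuplicated(states)) abort_pc("duplicate state labels")
  if (length(ground) != 1L || !ground %in% states) {
    abort_pc("exactly one ground state, present in `states`, is required")
  }
  if (!all(conducting %in% states)) abort_pc("unknown conducting state")
  check_rates <- function(df, rate_col) {
    df <- as.data.frame(df)
    if (nrow(df) == 0L) return(df)
    if (!all(df$from %in% states) || !all(df$to %in% states)) {
      abort_pc("rate table names unknown states: ",
               paste(setdiff(unique(c(df$from, df$to)), states), collapse = ", "))
    }
    if (any(df$from == df$to)) abort_pc("self-transitions are not allowed")
    if (any(df[[rate_col]] < 0)) abort_pc("negative rates are not allowed")
    df
  }
  photo_rates <- check_rates(photo_rates, "coefficient")
  thermal_rates <- check_rates(thermal_rates, "rate")
  structure(
    list(states = states,
         conducting = states %in% conducting,
         ground = ground,
         photo_rates = tibble::as_tibble(photo_rates),
         thermal_rates = tibble::as_tibble(thermal_rates)),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> states:",
      paste0(x$states, ifelse(x$conducting, "*", "")), "\n")
  cat("  ground:", x$ground, " (* = conducting)\n")
  cat("  photo transitions:", nrow(x$photo_rates),
      "; thermal transitions:", nrow(x$thermal_rates), "\n")
  invisible(x)
}

#' Generator matrix of a scheme at fixed light intensity
#'
#' Columns are source states; every column sums to zero so that total
#' population is conserved by the master equation dx/dt = Q x.
#'
#' @param scheme a [kinetic_scheme()].
#' @param intensity light intensity (arbitrary units, >= 0).
#' @return square numeric matrix with dimnames = states.
#' @export
generator_matrix <- function(scheme, intensity = 0) {
  if (intensity < 0) abort_pc("negative intensity")
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  add <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  tr <- scheme$thermal_rates
  if (nrow(tr)) for (i in seq_len(nrow(tr))) add(tr$from[i], tr$to[i], tr$rate[i])
  pr <- scheme$photo_rates
  if (intensity > 0 && nrow(pr)) {
    for (i in seq_len(nrow(pr))) add(pr$from[i], pr$to[i], pr$coefficient[i] * intensity)
  }
  Q
}

#' First post-excitation state of the ground state
#'
#' Used as the destination of a delta-flash initial condition.
#' @param scheme a [kinetic_scheme()].
#' @return state label.
#' @export
flash_target <- function(scheme) {
  pr <- scheme$photo_rates
  hit <- pr$to[pr$from == scheme$ground & pr$coefficient > 0]
  if (length(hit) != 1L) abort_pc("ground state must have exactly one photo transition")
  hit
}

#' Piecewise-constant light protocol
#'
#' Encodes the illumination protocols used in channel characterisation:
#' continuous light steps (e.g. a 500 ms pulse), nanosecond-flash single
#' turnover (as a `delta_flash` that instantaneously promotes a fraction of
#' the ground state) and double-pulse recovery sequences.
#'
#' @param segments data frame with columns `t_start`, `t_end` (s) and
#'   `intensity` (>= 0, arbitrary units); non-overlapping and ordered.
#'   May be empty (darkness).
#' @param delta_flash optional list `list(time =, excited_fraction =)` with
#'   excited_fraction in \[0, 1\].
#' @return object of class `light_protocol`.
#' @export
light_protocol <- function(segments = NULL, delta_flash = NULL) {
  if (is.null(segments)) {
    segments <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                               intensity = numeric())
  }
  segments <- tibble::as_tibble(segments)
  if (nrow(segments)) {
    if (any(segments$t_end <= segments$t_start)) abort_pc("segment t_end must exceed t_start")
    if (any(segments$intensity < 0)) abort_pc("negative intensity")
    o <- order(segments$t_start)
    segments <- segments[o, ]
    if (nrow(segments) > 1L &&
        any(segments$t_start[-1L] < segments$t_end[-nrow(segments)] - 1e-15)) {
      abort_pc("light segments overlap")
    }
  }
  if (!is.null(delta_flash)) {
    f <- delta_flash$excited_fraction
    if (is.null(f) || f < 0 || f > 1) abort_pc("excited_fraction must lie in [0, 1]")
    if (is.null(delta_flash$time)) abort_pc("delta_flash needs a time")
  }
  structure(list(segments = segments, delta_flash = delta_flash),
            class = "light_protocol")
}

#' Single continuous light step
#' @param duration_s length of the step (s).
#' @param intensity light intensity (arbitrary units).
#' @param t_start onset time (s).
#' @return a [light_protocol()].
#' @export
pulse_protocol <- function(duration_s, intensity, t_start = 0) {
  light_protocol(tibble::tibble(t_start = t_start,
                                t_end = t_start + duration_s,
                                intensity = intensity))
}

#' Nanosecond-flash single-turnover protocol
#' @param time flash time (s).
#' @param excited_fraction fraction of ground-state population promoted.
#' @return a [light_protocol()].
#' @export
flash_protocol <- function(time = 0, excited_fraction = 1) {
  light_protocol(delta_flash = list(time = time, excited_fraction = excited_fraction))
}

#' Discretize a time-varying intensity into a piecewise-constant protocol
#'
#' Ramps or other smooth intensity programs must be discretized before
#' propagation; this helper samples `intensity_fun` at fixed 0.1 ms steps
#' (midpoint rule) so that exact matrix-exponential propagation applies.
#'
#' @param intensity_fun function of time (s) returning intensity.
#' @param t_start,t_end window to discretize (s).
#' @param dt step width (s), default 1e-4 (0.1 ms).
#' @return a [light_protocol()].
#' @export
discretize_protocol <- function(intensity_fun, t_start, t_end, dt = 1e-4) {
  edges <- seq(t_start, t_end, by = dt)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  light_protocol(tibble::tibble(t_start = edges[-length(edges)],
                                t_end = edges[-1],
                                intensity = pmax(0, intensity_fun(mid))))
}
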