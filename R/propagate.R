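# master-equation propagation: exact piecewise matrix-exponential solution

# x(t) = expm(Q t) x0 evaluated at several dt, via eigendecomposition with an
# expm fallback when the eigenvector matrix is ill-conditioned
propagate_constant <- function(Q, x0, dts) {
  n <- length(x0)
  out <- matrix(0, n, length(dts))
  eg <- eigen(Q)
  V <- eg$vectors
  ok <- is.finite(rcond(V)) && rcond(V) > 1e-10
  if (ok) {
    c0 <- solve(V, x0 + 0i)
    for (j in seq_along(dts)) {
      out[, j] <- Re(V %*% (exp(eg$values * dts[j]) * c0))
    }
  } else {
    for (j in seq_along(dts)) {
      out[, j] <- as.numeric(Matrix::expm(Q * dts[j]) %*% x0)
    }
  }
  out
}

# intensity as a step function over [t0, t_max]: breakpoints + levels
intensity_pieces <- function(protocol, t0, t_max) {
  seg <- protocol$segments
  brk <- sort(unique(c(t0, t_max, seg$t_start, seg$t_end)))
  brk <- brk[brk >= t0 - 1e-300 & brk <= t_max]
  if (brk[1] > t0) brk <- c(t0, brk)
  if (brk[length(brk)] < t_max) brk <- c(brk, t_max)
  lev <- vapply(seq_len(length(brk) - 1L), function(i) {
    mid <- (brk[i] + brk[i + 1L]) / 2
    hit <- which(seg$t_start <= mid & mid < seg$t_end)
    if (length(hit)) seg$intensity[hit[1]] else 0
  }, numeric(1))
  list(breaks = brk, levels = lev)
}

#' Propagate a kinetic scheme under a light protocol
#'
#' Solves the linear master equation dx/dt = Q(I(t)) x exactly on each
#' constant-intensity piece (matrix exponential via eigendecomposition),
#' starting from all population in the ground state. If the protocol carries
#' a `delta_flash`, the flash instantaneously moves `excited_fraction` of the
#' ground-state population into the first post-excitation state at the flash
#' time. Occupancies are probability fractions and sum to one at all times.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [light_protocol()].
#' @param times strictly increasing evaluation grid (s).
#' @return tibble of class `occupancy_trajectory` with column `time_s` and one
#'   occupancy column per state.
#' @examples
#' sc <- three_state_scheme(k_close = 370, k_recover = 0.83)
#' propagate(sc, pulse_protocol(0.5, intensity = 1e4), seq(0, 1, 1e-3))
#' @export
propagate <- function(scheme, protocol, times) {
  if (!is_strictly_increasing(times)) abort_pc("time grid must be strictly increasing")
  n <- length(scheme$states)
  x <- numeric(n)
  names(x) <- scheme$states
  x[scheme$ground] <- 1

  t0 <- min(times[1], 0)
  flash <- protocol$delta_flash
  if (!is.null(flash)) t0 <- min(t0, flash$time)
  pieces <- intensity_pieces(protocol, t0, times[length(times)])
  brk <- pieces$breaks
  lev <- pieces$levels
  if (!is.null(flash)) {
    # split pieces at the flash time
    i <- findInterval(flash$time, brk, rightmost.closed = TRUE)
    if (!flash$time %in% brk) {
      brk <- sort(c(brk, flash$time))
      lev <- append(lev, lev[i], after = i)
    }
  }

  occ <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, scheme$states))
  t_cur <- brk[1]
  for (p in seq_along(lev)) {
    a <- brk[p]; b <- brk[p + 1L]
    if (!is.null(flash) && abs(a - flash$time) < 1e-300) {
      tgt <- flash_target(scheme)
      moved <- x[scheme$ground] * flash$excited_fraction
      x[scheme$ground] <- x[scheme$ground] - moved
      x[tgt] <- x[tgt] + moved
    }
    Q <- generator_matrix(scheme, lev[p])
    inside <- which(times > a + 1e-300 & times <= b)
    dts <- c(times[inside] - a, b - a)
    sol <- propagate_constant(Q, x, dts)
    if (length(inside)) occ[inside, ] <- t(sol[, seq_along(inside), drop = FALSE])
    x <- sol[, length(dts)]
    # guard tiny negative round-off, renormalise
    x <- pmax(x, 0); x <- x / sum(x)
  }
  exact <- which(times <= brk[1] + 1e-300)
  if (length(exact)) {
    x_init <- numeric(n); names(x_init) <- scheme$states; x_init[scheme$ground] <- 1
    for (i in exact) occ[i, ] <- x_init
  }
  out <- tibble::tibble(time_s = as.numeric(times))
  for (s in scheme$states) out[[s]] <- occ[, s]
  class(out) <- c("occupancy_trajectory", class(out))
  attr(out, "scheme") <- scheme
  out
}

#' Total conducting-state occupancy of a trajectory
#' @param traj result of [propagate()].
#' @param scheme the scheme used (defaults to the one stored in `traj`).
#' @return numeric vector along the trajectory grid.
#' @export
conducting_occupancy <- function(traj, scheme = attr(traj, "scheme")) {
  cols <- scheme$states[scheme$conducting]
  rowSums(as.matrix(traj[, cols, drop = FALSE]))
}

#' Stationary occupancy under constant light
#'
#' Returns the probability vector in the null space of the generator at the
#' given intensity. At zero intensity with an absorbing dark state this is the
#' ground-state point mass.
#'
#' @inheritParams generator_matrix
#' @return named occupancy vector (non-negative, sums to 1).
#' @export
steady_state <- function(scheme, intensity) {
  Q <- generator_matrix(scheme, intensity)
  sv <- svd(Q)
  v <- sv$v[, ncol(Q)]
  if (max(abs(Q %*% v)) > 1e-8 * max(1, max(abs(Q)))) {
    abort_pc("no stationary distribution found")
  }
  v <- v / sum(v)
  if (any(v < -1e-9)) abort_pc("generator is reducible away from the ground state")
  v <- pmax(v, 0); v <- v / sum(v)
  names(v) <- scheme$states
  v
}

#' Convert occupancy to an ohmic photocurrent trace
#'
#' I(t) = conductance_scale * f_conducting(t) * (V - E_rev), with the inward
#' current negative. `conductance_scale` lumps channel number and unitary
#' conductance (pA/mV).
#'
#' @param traj an occupancy trajectory from [propagate()].
#' @param scheme the generating [kinetic_scheme()].
#' @param voltage_mV holding potential (mV).
#' @param e_rev_mV reversal potential (mV).
#' @param conductance_scale pA/mV, >= 0.
#' @param light_window optional c(on, off) seconds; stored as metadata.
#' @return tibble of class `photocurrent_trace` with columns `time_s`,
#'   `current_pA`; voltage, reversal potential, scale and light window are
#'   attached as attributes (see [trace_meta()]).
#' @export
current_from_occupancy <- function(traj, scheme = attr(traj, "scheme"),
                                   voltage_mV, e_rev_mV, conductance_scale,
                                   light_window = NULL) {
  if (conductance_scale < 0) abort_pc("conductance_scale must be >= 0")
  f <- conducting_occupancy(traj, scheme)
  out <- tibble::tibble(time_s = traj$time_s,
                        current_pA = conductance_scale * f * (voltage_mV - e_rev_mV))
  new_photocurrent_trace(out, voltage_mV = voltage_mV, e_rev_mV = e_rev_mV,
                         conductance_scale = conductance_scale,
                         light_window = light_window)
}

new_photocurrent_trace <- function(df, voltage_mV = NA_real_, e_rev_mV = NA_real_,
                                   conductance_scale = NA_real_,
                                   light_window = NULL, metadata = list()) {
  if (!is_strictly_increasing(df$time_s)) abort_pc("trace times must be strictly increasing")
  if (!is.null(light_window)) {
    if (light_window[1] < df$time_s[1] - 1e-12 ||
        light_window[2] > df$time_s[nrow(df)] + 1e-12) {
      abort_pc("light window must lie inside the trace time range")
    }
  }
  structure(tibble::as_tibble(df),
            class = c("photocurrent_trace", class(tibble::tibble())),
            voltage_mV = voltage_mV, e_rev_mV = e_rev_mV,
            conductance_scale = conductance_scale,
            light_window = light_window, metadata = metadata)
}

#' Metadata of a photocurrent trace
#' @param trace a `photocurrent_trace`.
#' @return named list (voltage_mV, e_rev_mV, conductance_scale, light_window, metadata).
#' @export
trace_meta <- function(trace) {
  list(voltage_mV = attr(trace, "voltage_mV"),
       e_rev_mV = attr(trace, "e_rev_mV"),
       conductance_scale = attr(trace, "conductance_scale"),
       light_window = attr(trace, "light_window"),
       metadata = attr(trace, "metadata"))
}

#' Double-pulse recovery simulation
#'
#' Simulates pulse - dark interval - pulse for each interval and returns the
#' ratio of the second to the first peak of conducting occupancy. With a
#' desensitizing photocycle the ratio grows towards one as the dark interval
#' lets the ground state repopulate (recovery time constant 1/k(M->D)).
#'
#' @param scheme a [kinetic_scheme()].
#' @param pulse_duration_s,intensity the (identical) light pulses.
#' @param intervals_s positive dark intervals between the pulses (s).
#' @param dt_s simulation step used inside the pulses (s).
#' @return tibble with columns `interval_s`, `peak_ratio`.
#' @export
double_pulse_recovery <- function(scheme, pulse_duration_s, intensity,
                                  intervals_s, dt_s = 2e-5) {
  if (length(intervals_s) == 0L) abort_pc("empty interval list")
  if (any(intervals_s <= 0)) abort_pc("intervals must be positive")
  pulse_grid <- seq(0, pulse_duration_s, by = dt_s)
  ratios <- vapply(intervals_s, function(gap) {
    prot <- light_protocol(tibble::tibble(
      t_start = c(0, pulse_duration_s + gap),
      t_end = c(pulse_duration_s, 2 * pulse_duration_s + gap),
      intensity = intensity))
    grid <- sort(unique(c(pulse_grid, pulse_duration_s + gap + pulse_grid)))
    traj <- propagate(scheme, prot, grid)
    f <- conducting_occupancy(traj, scheme)
    first <- max(f[grid <= pulse_duration_s + 1e-15])
    second <- max(f[grid >= pulse_duration_s + gap - 1e-15])
    second / first
  }, numeric(1))
  tibble::tibble(interval_s = as.numeric(intervals_s), peak_ratio = ratios)
}
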