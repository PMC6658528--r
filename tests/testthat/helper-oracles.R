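# independent oracles used across the suite

# stiff ODE integration of the master equation under a piecewise-constant
# protocol -- independent of the matrix-exponential path in propagate()
ode_propagate <- function(scheme, protocol, times) {
  intensity_at <- function(t) {
    seg <- protocol$segments
    hit <- which(seg$t_start <= t & t < seg$t_end)
    if (length(hit)) seg$intensity[hit[1]] else 0
  }
  x0 <- numeric(length(scheme$states))
  names(x0) <- scheme$states
  x0[scheme$ground] <- 1
  flash <- protocol$delta_flash
  if (!is.null(flash)) {
    tgt <- flash_target(scheme)
    moved <- x0[scheme$ground] * flash$excited_fraction
    x0[scheme$ground] <- x0[scheme$ground] - moved
    x0[tgt] <- x0[tgt] + moved
  }
  rhs <- function(t, x, parms) {
    list(as.numeric(generator_matrix(scheme, intensity_at(t)) %*% x))
  }
  t_all <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(x0, t_all, rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  sol[match(times, t_all), -1, drop = FALSE]
}

# numeric ODE solution of the unidirectional chain (Bateman oracle)
ode_bateman <- function(lifetimes, times) {
  k <- 1 / lifetimes
  n <- length(k)
  rhs <- function(t, x, parms) {
    dx <- -k * x
    if (n > 1) dx[-1] <- dx[-1] + k[-n] * x[-n]
    list(dx)
  }
  x0 <- c(1, rep(0, n - 1))
  t_all <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(x0, t_all, rhs, parms = NULL, rtol = 1e-11, atol = 1e-14)
  t(sol[match(times, t_all), -1, drop = FALSE])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
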