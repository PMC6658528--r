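# global lifetime analysis of time-resolved difference spectra

#' Isologarithmic time grid
#'
#' Geometric sequence from `t_start` to `t_end` with a fixed number of points
#' per decade, including both endpoints — the standard sampling of flash
#' photolysis covering ns to s. For decade-aligned endpoints the point count
#' is `round(log10(t_end/t_start)) * points_per_decade + 1` (e.g. 10 ns to
#' 100 s at 10 points per decade gives 101 points).
#'
#' @param t_start,t_end positive window bounds (s), t_start < t_end.
#' @param points_per_decade integer >= 1.
#' @return numeric vector of times (s).
#' @export
make_isolog_grid <- function(t_start, t_end, points_per_decade) {
  if (t_start <= 0 || t_end <= t_start) abort_pc("need 0 < t_start < t_end")
  if (points_per_decade < 1) abort_pc("points_per_decade must be >= 1")
  n_dec <- log10(t_end / t_start)
  n <- round(n_dec * points_per_decade) + 1L
  g <- 10^seq(log10(t_start), log10(t_end), length.out = n)
  g[1] <- t_start; g[n] <- t_end
  g
}

#' Container for a time-resolved spectral matrix
#'
#' Holds a wavelength (nm) or wavenumber (1/cm) by time difference-absorbance
#' matrix, with optional excluded axis ranges (e.g. laser-scatter masks that
#' are dropped before decomposition).
#'
#' @param axis_values strictly increasing axis (nm or 1/cm).
#' @param times strictly increasing times (s).
#' @param delta_A matrix, rows = axis, cols = times.
#' @param axis_kind `"wavelength"` or `"wavenumber"`.
#' @param excluded_ranges optional list of c(lo, hi) axis intervals.
#' @param metadata named list.
#' @return object of class `time_resolved_spectra`.
#' @export
time_resolved_spectra <- function(axis_values, times, delta_A,
                                  axis_kind = c("wavelength", "wavenumber"),
                                  excluded_ranges = NULL, metadata = list()) {
  axis_kind <- match.arg(axis_kind)
  delta_A <- as.matrix(delta_A)
  if (!is_strictly_increasing(axis_values)) abort_pc("axis must be strictly increasing")
  if (!is_strictly_increasing(times)) abort_pc("times must be strictly increasing")
  if (nrow(delta_A) != length(axis_values) || ncol(delta_A) != length(times)) {
    abort_pc("delta_A dimensions do not match axes")
  }
  if (!is.null(excluded_ranges)) {
    for (r in excluded_ranges) {
      if (r[1] > r[2] || r[2] < min(axis_values) || r[1] > max(axis_values)) {
        abort_pc("excluded range outside the axis span")
      }
    }
  }
  structure(list(axis_values = as.numeric(axis_values),
                 times = as.numeric(times),
                 delta_A = delta_A, axis_kind = axis_kind,
                 excluded_ranges = excluded_ranges, metadata = metadata),
            class = "time_resolved_spectra")
}

#' @export
print.time_resolved_spectra <- function(x, ...) {
  cat("<time_resolved_spectra> ", length(x$axis_values), " ", x$axis_kind,
      " points x ", length(x$times), " times (",
      format(min(x$times)), " - ", format(max(x$times)), " s)\n", sep = "")
  if (!is.null(x$excluded_ranges)) {
    cat("  excluded ranges:",
        paste(vapply(x$excluded_ranges, function(r) paste(r, collapse = "-"),
                     character(1)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a spectral matrix
#' @param x a [time_resolved_spectra()].
#' @param ... unused.
#' @return tibble with columns `axis`, `time_s`, `delta_A`.
#' @export
tidy.time_resolved_spectra <- function(x, ...) {
  tibble::tibble(axis = rep(x$axis_values, times = length(x$times)),
                 time_s = rep(x$times, each = length(x$axis_values)),
                 delta_A = as.vector(x$delta_A))
}

# rows kept after applying the exclusion mask
axis_keep <- function(data) {
  keep <- rep(TRUE, length(data$axis_values))
  for (r in data$excluded_ranges %||% list()) {
    keep <- keep & !(data$axis_values >= r[1] & data$axis_values <= r[2])
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bateman coefficient matrix B for the unidirectional chain with rates k:
# c_j(t) = sum_l B[j, l] exp(-k_l t). Degenerate rates are jittered.
bateman_coefficients <- function(rates) {
  k <- jitter_degenerate(rates)
  n <- length(k)
  B <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pref <- prod(k[seq_len(j - 1)])
    for (l in seq_len(j)) {
      denom <- prod(k[setdiff(seq_len(j), l)] - k[l])
      B[j, l] <- if (j == 1L) 1 else pref / denom
    }
  }
  B
}

# rates differing by < 1e-9 relative get a 1e-6 relative jitter (later member)
jitter_degenerate <- function(rates) {
  k <- as.numeric(rates)
  for (i in seq_along(k)[-1]) {
    while (any(abs(k[seq_len(i - 1)] - k[i]) < 1e-9 * max(k[i], k[seq_len(i - 1)]))) {
      k[i] <- k[i] * (1 + 1e-6)
    }
  }
  k
}

#' Sequential-chain concentration profiles (Bateman solution)
#'
#' Closed-form populations of the unidirectional chain A1 -> A2 -> ... -> An
#' (terminal decay to an unobserved ground state) with c1(0) = 1.
#'
#' @param lifetimes positive lifetimes (s) of the chain members, in chain order.
#' @param times evaluation times (s, >= 0).
#' @return matrix n_components x n_times.
#' @export
bateman_concentrations <- function(lifetimes, times) {
  if (any(lifetimes <= 0)) abort_pc("lifetimes must be positive")
  k <- 1 / as.numeric(lifetimes)
  B <- bateman_coefficients(k)
  k <- jitter_degenerate(k)
  E <- exp(-outer(k, times))     # n x n_times
  B %*% E
}

#' Truncated singular value decomposition of a spectral matrix
#'
#' Drops masked axis rows, decomposes, and keeps the leading `n` components.
#' With `n = "auto"` the rank is the smallest n whose cumulative squared
#' singular values reach 99.9% of the total AND whose first discarded
#' temporal vector has lag-1 autocorrelation below 0.5 (i.e. looks like
#' noise rather than kinetics).
#'
#' @param data a [time_resolved_spectra()].
#' @param n integer rank or `"auto"`.
#' @return list with `u` (axis x n), `d` (singular values, length n),
#'   `v` (time x n), `rank_estimate`, `axis_values` (rows kept) and
#'   `singular_values_all`.
#' @export
svd_truncate <- function(data, n = "auto") {
  keep <- axis_keep(data)
  M <- data$delta_A[keep, , drop = FALSE]
  if (!all(is.finite(M))) abort_pc("non-finite values in the spectral matrix")
  sv <- svd(M)
  r <- sum(sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1])
  if (identical(n, "auto")) {
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    n_est <- r
    for (i in seq_len(r)) {
      ok_energy <- cum[i] >= 0.999
      ok_noise <- if (i < length(sv$d)) {
        v_next <- sv$v[, i + 1L]
        lag1_autocor(v_next) < 0.5
      } else TRUE
      if (ok_energy && ok_noise) { n_est <- i; break }
    }
    n <- n_est
  }
  if (n > min(dim(M))) abort_pc("requested rank ", n, " exceeds matrix rank ", min(dim(M)))
  list(u = sv$u[, seq_len(n), drop = FALSE],
       d = sv$d[seq_len(n)],
       v = sv$v[, seq_len(n), drop = FALSE],
       rank_estimate = n,
       axis_values = data$axis_values[keep],
       singular_values_all = sv$d)
}

lag1_autocor <- function(x) {
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(0)
  sum(x[-1] * x[-length(x)]) / denom
}

#' Convert between decay- and evolution-associated spectra
#'
#' DADS and EADS are two amplitude representations of the same global
#' multiexponential fit: the data are EADS x sequential concentrations =
#' DADS x exponentials, so DADS = EADS B where B is the Bateman coefficient
#' matrix of the sequential chain. The round trip is exact.
#'
#' @param spectra matrix, axis x n_components.
#' @param lifetimes chain lifetimes (s), chain order.
#' @param direction `"dads_to_eads"` or `"eads_to_dads"`.
#' @return transformed matrix, axis x n_components.
#' @export
eads_dads_transform <- function(spectra, lifetimes,
                                direction = c("dads_to_eads", "eads_to_dads")) {
  direction <- match.arg(direction)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(lifetimes)) {
    abort_pc("component count does not match lifetime count")
  }
  B <- bateman_coefficients(1 / as.numeric(lifetimes))
  if (direction == "eads_to_dads") spectra %*% B else spectra %*% solve(B)
}

# variable projection residual: amplitudes solved exactly by QR at fixed taus
varpro_amplitudes <- function(M, C) {
  # M: axis x time, C: n x time; returns list(A = axis x n, resid = matrix)
  qrC <- qr(t(C))
  At <- qr.coef(qrC, t(M))
  At[is.na(At)] <- 0
  A <- t(At)
  list(A = A, resid = M - A %*% C)
}

#' Global sequential-model lifetime analysis
#'
#' Fits the sequential compartment model A1 -> A2 -> ... -> An to a
#' time-resolved spectral matrix by variable projection: the nonlinear
#' parameters (log10 lifetimes) are optimized with Levenberg-Marquardt
#' least squares while the amplitude spectra are solved exactly by linear
#' least squares (QR) at every iterate. Returns evolution-associated (EADS)
#' and decay-associated (DADS) difference spectra, with lifetimes sorted
#' ascending.
#'
#' @param data a [time_resolved_spectra()].
#' @param n_components number of sequential compartments (>= 1).
#' @param tau_init initial lifetimes (s), length `n_components`.
#' @param maxit maximum optimizer iterations.
#' @return object of class `sequential_fit`: list with `lifetimes` (s,
#'   ascending), `eads`, `dads` (axis x n matrices), `axis_values`,
#'   `residual_rms`, `n_svd_components`, `converged`.
#' @export
global_fit_sequential <- function(data, n_components, tau_init, maxit = 200) {
  if (n_components < 1) abort_pc("n_components must be >= 1")
  if (length(tau_init) != n_components) abort_pc("tau_init length must equal n_components")
  if (any(tau_init <= 0)) abort_pc("tau_init must be positive")
  keep <- axis_keep(data)
  M <- data$delta_A[keep, , drop = FALSE]
  times <- data$times
  sv_rank <- svd_truncate(data, "auto")$rank_estimate
  if (n_components > sv_rank) {
    warning("n_components (", n_components, ") exceeds the SVD rank estimate (",
            sv_rank, ")", call. = FALSE)
  }

  resid_fun <- function(theta) {
    C <- bateman_concentrations(10^theta, times)
    as.vector(varpro_amplitudes(M, C)$resid)
  }
  theta0 <- log10(sort(as.numeric(tau_init)))
  rss0 <- sum(resid_fun(theta0)^2)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxit, ftol = 1e-15, ptol = 1e-15))
  converged <- fit$info %in% 1:4
  theta <- sort(fit$par)
  taus <- 10^theta
  C <- bateman_concentrations(taus, times)
  amp <- varpro_amplitudes(M, C)
  rss <- sum(amp$resid^2)
  if (rss > rss0 * (1 + 1e-12)) {  # never worse than the start
    theta <- theta0; taus <- 10^theta
    C <- bateman_concentrations(taus, times)
    amp <- varpro_amplitudes(M, C)
    rss <- sum(amp$resid^2)
    converged <- FALSE
  }
  eads <- amp$A
  colnames(eads) <- paste0("EADS", seq_len(n_components))
  dads <- eads_dads_transform(eads, taus, "eads_to_dads")
  colnames(dads) <- paste0("DADS", seq_len(n_components))
  structure(list(lifetimes = taus, eads = eads, dads = dads,
                 axis_values = data$axis_values[keep],
                 axis_kind = data$axis_kind,
                 times = times,
                 residual_rms = sqrt(rss / length(M)),
                 n_svd_components = sv_rank,
                 converged = converged),
            class = "sequential_fit")
}

#' @export
print.sequential_fit <- function(x, ...) {
  cat("<sequential_fit>", length(x$lifetimes), "components; lifetimes (s):",
      paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  cat("  residual RMS:", format(x$residual_rms, digits = 4),
      "; converged:", x$converged, "\n")
  invisible(x)
}

#' @rdname global_fit_sequential
#' @param x a `sequential_fit`.
#' @param ... unused.
#' @export
tidy.sequential_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$lifetimes),
                 lifetime_s = x$lifetimes,
                 rate_per_s = 1 / x$lifetimes)
}

#' @rdname global_fit_sequential
#' @export
glance.sequential_fit <- function(x, ...) {
  tibble::tibble(n_components = length(x$lifetimes),
                 residual_rms = x$residual_rms,
                 n_svd_components = x$n_svd_components,
                 converged = x$converged)
}

#' Reconstruct the data matrix from a sequential fit
#' @param fit a `sequential_fit`.
#' @param from `"eads"` or `"dads"` representation.
#' @return matrix axis x time.
#' @export
reconstruct_spectra <- function(fit, from = c("eads", "dads")) {
  from <- match.arg(from)
  k <- 1 / fit$lifetimes
  if (from == "eads") {
    fit$eads %*% bateman_concentrations(fit$lifetimes, fit$times)
  } else {
    kj <- jitter_degenerate(k)
    fit$dads %*% exp(-outer(kj, fit$times))
  }
}

#' SVD-plus-rotation kinetic decomposition of FTIR difference spectra
#'
#' Truncates the data to rank `n`, fits the temporal vectors globally with a
#' shared sum of `n` exponentials (optionally plus a constant plateau for
#' continuous-illumination series), and rotates the spectral left vectors by
#' the fitted amplitude matrix into physical component spectra. Assuming a
#' sequential reaction scheme, the exponential (DADS-like) amplitudes are
#' rotated into evolution-associated component spectra, so the slow component
#' decays mono-exponentially.
#'
#' @param data a [time_resolved_spectra()].
#' @param n number of kinetic components (default 2: fast L-like, slow M-like).
#' @param tau_init optional initial lifetimes (s); defaults to log-spaced over
#'   the time span.
#' @param constant add a constant basis function (continuous illumination).
#' @return list with `component_spectra` (axis x n, sequential/evolution
#'   representation), `time_constants` (s, ascending), `amplitudes`
#'   (rotation matrix applied to the SVD basis), `axis_values`, `fit`
#'   (the underlying `sequential_fit`-style details).
#' @export
ftir_kinetic_decomposition <- function(data, n = 2, tau_init = NULL,
                                       constant = FALSE) {
  if (n < 1) abort_pc("n must be >= 1")
  sv <- svd_truncate(data, n)
  times <- data$times
  # temporal matrix to fit: n x n_times, weighted by singular values
  Tm <- diag(sv$d, n, n) %*% t(sv$v)
  if (is.null(tau_init)) {
    tau_init <- 10^seq(log10(times[2] - times[1] + times[1]),
                       log10(max(times)), length.out = n)
  }
  basis <- function(taus) {
    kj <- jitter_degenerate(1 / taus)
    E <- exp(-outer(kj, times))
    if (constant) rbind(E, rep(1, length(times))) else E
  }
  resid_fun <- function(theta) {
    as.vector(varpro_amplitudes(Tm, basis(10^theta))$resid)
  }
  fit <- minpack.lm::nls.lm(par = log10(sort(tau_init)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  taus <- sort(10^fit$par)
  E <- basis(taus)
  amp <- varpro_amplitudes(Tm, E)$A      # n x (n [+1])
  # DADS-like spectra in data space, then rotate into the sequential picture
  dads_full <- sv$u %*% amp              # axis x (n [+1])
  dads <- dads_full[, seq_len(n), drop = FALSE]
  eads <- eads_dads_transform(dads, taus, "dads_to_eads")
  colnames(eads) <- paste0("component", seq_len(n))
  list(component_spectra = eads,
       time_constants = taus,
       amplitudes = amp,
       dads = dads,
       plateau = if (constant) dads_full[, n + 1L] else NULL,
       axis_values = sv$axis_values,
       converged = fit$info %in% 1:4)
}
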