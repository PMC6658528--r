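# isolog grids, Bateman chains, SVD truncation and global lifetime analysis

test_that("isologarithmic grids have the canonical point counts", {
  g <- make_isolog_grid(10e-9, 100, 10)
  expect_length(g, 101)
  expect_equal(g[1], 10e-9)
  expect_equal(g[101], 100)
  expect_equal(make_isolog_grid(1, 10, 1), c(1, 10))
  expect_equal(make_isolog_grid(1, 100, 2), 10^seq(0, 2, by = 0.5), tolerance = 1e-12)
  # geometric: constant ratio
  expect_lt(diff(range(diff(log(g)))), 1e-12)
  expect_error(make_isolog_grid(0, 1, 10), "t_start")
})

test_that("Bateman profiles match closed forms and an ODE oracle", {
  t <- seq(0, 5, by = 0.01)
  # single component
  c1 <- bateman_concentrations(2, t)
  expect_equal(as.numeric(c1), exp(-t / 2), tolerance = 1e-12)
  # two components, rates 2 and 1: c2 = 2(exp(-t) - exp(-2t)), c2(ln 2) = 0.5
  c2 <- bateman_concentrations(c(1 / 2, 1), log(2))
  expect_equal(c2[2, 1], 0.5, tolerance = 1e-12)
  skip_if_not_installed("deSolve")
  lt <- c(0.05, 0.7, 3)
  got <- bateman_concentrations(lt, t)
  ref <- ode_bateman(lt, t)
  expect_lt(max(abs(got - ref)), 1e-8)
})

test_that("Bateman chains stay within the probability simplex", {
  t <- make_isolog_grid(1e-8, 100, 8)
  for (lt in list(c(173e-9, 6e-3, 1.2), c(1e-4, 0.2), c(0.3, 2, 40))) {
    C <- bateman_concentrations(lt, t)
    expect_true(all(C > -1e-12))
    expect_true(all(colSums(C) <= 1 + 1e-9))
  }
  # degenerate lifetimes use the documented jitter rule; cancellation error
  # stays far below fit tolerances
  for (lt in list(c(1, 1), c(0.1, 0.1000000001, 5))) {
    C <- bateman_concentrations(lt, t)
    expect_true(all(C > -1e-5))
    expect_true(all(colSums(C) <= 1 + 1e-5))
  }
  expect_error(bateman_concentrations(c(1, -1), t), "positive")
})

test_that("SVD truncation estimates rank and obeys Eckart-Young", {
  wl <- seq(300, 650, by = 5)
  t <- make_isolog_grid(1e-6, 10, 8)
  # rank-1: one spectrum x one exponential
  d1 <- time_resolved_spectra(wl, t, outer(exp(-(wl - 500)^2 / 900), exp(-t / 0.01)))
  expect_equal(svd_truncate(d1)$rank_estimate, 1)
  # two components with high-SNR noise (the 99.9 percent energy rule needs
  # the noise floor well below 0.1 percent of total energy)
  d2 <- gen_transient_absorption(times = t, wavelengths_nm = wl,
                                 lifetimes = c(1e-4, 0.5), noise_sd = 0.002,
                                 seed = 11)
  expect_equal(svd_truncate(d2)$rank_estimate, 2)
  sv <- svd_truncate(d2, 2)
  M <- d2$delta_A
  approx2 <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_equal(norm(M - approx2, "F"),
               sqrt(sum(sv$singular_values_all[-(1:2)]^2)), tolerance = 1e-9)
  expect_error(svd_truncate(d1, 500), "rank")
})

test_that("masked axis ranges are dropped before decomposition", {
  wl <- seq(300, 650, by = 5)
  t <- make_isolog_grid(1e-6, 10, 6)
  d <- gen_transient_absorption(times = t, wavelengths_nm = wl,
                                lifetimes = c(1e-3, 0.3),
                                excluded_ranges = list(c(495, 520)))
  sv <- svd_truncate(d, 2)
  expect_false(any(sv$axis_values >= 495 & sv$axis_values <= 520))
  fit <- global_fit_sequential(d, 2, c(5e-3, 0.1))
  expect_equal(nrow(fit$eads), length(sv$axis_values))
  expect_rel(fit$lifetimes, c(1e-3, 0.3), 1e-3)
})

test_that("global sequential fit recovers fixture lifetimes and EADS exactly", {
  d <- gen_transient_absorption()  # noiseless, 101-point grid
  truth <- d$metadata$lifetimes
  for (scale in c(3, 1 / 3)) {
    fit <- global_fit_sequential(d, 3, tau_init = truth * scale)
    expect_true(fit$converged)
    expect_rel(fit$lifetimes, truth, 1e-3)
    expect_lt(sqrt(mean((fit$eads - d$metadata$eads)^2)), 1e-6)
    expect_lt(fit$residual_rms, 1e-8)
  }
  # basin check: mixed perturbation
  fit_mixed <- global_fit_sequential(d, 3, tau_init = truth * c(3, 1 / 3, 3))
  expect_rel(fit_mixed$lifetimes, truth, 5e-3)
})

test_that("EADS of the last component equals the long-time model spectrum", {
  d <- gen_transient_absorption(times = make_isolog_grid(1e-8, 50, 10))
  fit <- global_fit_sequential(d, 3, d$metadata$lifetimes)
  # at t = 5 * max lifetime only the last compartment survives;
  # reconstructed dA(t)/c_last(t) equals the last EADS
  t_late <- 5 * max(fit$lifetimes)
  conc <- bateman_concentrations(fit$lifetimes, t_late)
  recon <- fit$eads %*% conc
  expect_equal(as.numeric(recon), as.numeric(fit$eads[, 3] * conc[3, 1]),
               tolerance = 1e-10)
})

test_that("one-component fit reduces to a shared single-exponential fit", {
  wl <- seq(400, 600, by = 5)
  t <- make_isolog_grid(1e-4, 10, 10)
  spec <- exp(-(wl - 500)^2 / 1800)
  d <- time_resolved_spectra(wl, t, outer(spec, exp(-t / 0.07)))
  fit <- global_fit_sequential(d, 1, 0.01)
  expect_rel(fit$lifetimes, 0.07, 1e-6)
  expect_equal(as.numeric(fit$eads[, 1]), spec, tolerance = 1e-8)
  expect_equal(as.numeric(fit$dads), as.numeric(fit$eads))  # identity transform
})

test_that("EADS/DADS transforms are exact inverses and match reconstruction", {
  wl <- seq(350, 620, by = 3)
  eads <- cbind(exp(-(wl - 480)^2 / 800), -exp(-(wl - 520)^2 / 1200))
  taus <- c(2e-3, 0.4)
  dads <- eads_dads_transform(eads, taus, "eads_to_dads")
  back <- eads_dads_transform(dads, taus, "dads_to_eads")
  expect_lt(max(abs(back - eads)), 1e-12)
  # two-component relation DADS1 = EADS1 - k1/(k1 - k2) EADS2
  k <- 1 / taus
  expect_equal(dads[, 1], eads[, 1] - k[1] / (k[1] - k[2]) * eads[, 2],
               tolerance = 1e-12)
  # both representations reconstruct the same matrix
  t <- make_isolog_grid(1e-5, 5, 8)
  C <- bateman_concentrations(taus, t)
  E <- exp(-outer(k, t))
  expect_lt(max(abs(eads %*% C - dads %*% E)), 1e-12)
})

test_that("lifetime recovery tolerates 1 percent noise across seeds", {
  t <- make_isolog_grid(1e-8, 100, 6)
  wl <- seq(300, 650, by = 5)
  truth <- c(173e-9, 6e-3, 1.2)
  errs <- vapply(1:20, function(s) {
    d <- gen_transient_absorption(times = t, wavelengths_nm = wl,
                                  noise_sd = 0.01, seed = s)
    fit <- global_fit_sequential(d, 3, truth * 2)
    max(abs(fit$lifetimes / truth - 1))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("FTIR kinetic decomposition recovers spectra and time constants", {
  wn <- seq(1000, 1800, by = 4)
  spec_L <- exp(-(wn - 1550)^2 / 500) - 0.6 * exp(-(wn - 1650)^2 / 400)
  spec_M <- 0.8 * exp(-(wn - 1180)^2 / 800) - 0.5 * exp(-(wn - 1520)^2 / 600)
  taus <- c(6e-3, 1.2)
  t <- make_isolog_grid(1e-4, 50, 12)
  M <- cbind(spec_L, spec_M) %*% bateman_concentrations(taus, t)
  d <- time_resolved_spectra(wn, t, M, axis_kind = "wavenumber")
  dec <- ftir_kinetic_decomposition(d, n = 2)
  expect_rel(dec$time_constants, taus, 0.01)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(dec$component_spectra[, 1], spec_L), 0.999)
  expect_gt(cosine(dec$component_spectra[, 2], spec_M), 0.999)
  # agreement with the variable-projection global fit
  fit <- global_fit_sequential(d, 2, taus * 3)
  expect_rel(dec$time_constants, fit$lifetimes, 0.01)
  # rank-1 input with n = 2: second component amplitude vanishes
  d1 <- time_resolved_spectra(wn, t, outer(spec_L, exp(-t / 6e-3)),
                              axis_kind = "wavenumber")
  dec1 <- ftir_kinetic_decomposition(d1, n = 2)
  slow_amp <- max(abs(dec1$dads[, 2]))
  expect_lt(slow_amp, 1e-6 * max(abs(dec1$dads[, 1])))
})

test_that("non-convergence is flagged, never silent", {
  wl <- seq(400, 600, by = 10)
  t <- make_isolog_grid(1e-4, 1, 6)
  d <- time_resolved_spectra(wl, t, outer(exp(-(wl - 500)^2 / 900), exp(-t / 0.01)))
  expect_warning(fit <- global_fit_sequential(d, 3, c(1e-3, 1e-2, 1e-1)),
                 "SVD rank")
  expect_true(is.logical(fit$converged))
})
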