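# photocurrent analysis rules: peak, stationary, kinetics, reversal, recovery

make_trace <- function(t, i, lw = range(t)) {
  photocycler:::new_photocurrent_trace(tibble::tibble(time_s = t, current_pA = i),
                                       light_window = lw)
}

test_that("peak extraction returns the signed extremum in the light window", {
  t <- seq(0, 0.6, by = 1e-3)
  tr <- gen_photocurrent(protocol = pulse_protocol(0.5, 2000), times = t,
                         voltage_mV = -60, conductance_scale = 40)
  pk <- extract_peak(tr)
  expect_lt(pk, 0)  # inward at -60 mV
  expect_equal(pk, min(tr$current_pA[t <= 0.5]))
  expect_equal(extract_peak(make_trace(t, rep(0, length(t)))), 0)
  expect_error(extract_peak(make_trace(t, t * 0, lw = NULL)), "light window")
})

test_that("single-turnover current peaks about 350 us after the flash", {
  t <- seq(0, 0.02, by = 1e-6)
  tr <- gen_photocurrent(protocol = flash_protocol(0, 1), times = t,
                         voltage_mV = -60, conductance_scale = 40)
  t_pk <- t[which.max(abs(tr$current_pA))]
  expect_equal(t_pk * 1e6, 350, tolerance = 0.005)
})

test_that("stationary rule averages the last 50 ms of illumination", {
  t <- seq(0, 0.5, by = 1e-4)
  expect_equal(extract_stationary(make_trace(t, rep(-7, length(t)))), -7)
  # linear current a + b t averages to a + b (t_off - 0.025)
  a <- 2; b <- -3
  expect_equal(extract_stationary(make_trace(t, a + b * t)),
               a + b * (0.5 - 0.025), tolerance = 1e-6)
  expect_error(extract_stationary(make_trace(seq(0, 0.02, 1e-4), rep(1, 201))),
               "50 ms")
})

test_that("desensitization extent behaves as a fraction of lost current", {
  expect_equal(desensitization_extent(-1000, -10), 0.99)
  expect_equal(desensitization_extent(-1000, -1000), 0)
  expect_error(desensitization_extent(0, 1), "zero peak")
  expect_error(desensitization_extent(-10, 5), "sign")
  # fixture at saturating light desensitizes near-completely
  t <- sort(unique(c(seq(0, 0.05, 1e-5), seq(0.05, 0.5, 1e-3))))
  tr <- gen_photocurrent(protocol = pulse_protocol(0.5, 1e5), times = t,
                         voltage_mV = -60, conductance_scale = 40)
  d <- desensitization_extent(extract_peak(tr), extract_stationary(tr))
  expect_gte(d, 0.99)
  expect_lte(d, 1)
})

test_that("exponential fits recover known time constants and apparent tau", {
  t <- seq(0, 0.02, by = 2e-5)
  fit1 <- fit_exponentials(t, exp(-t / 2.7e-3), model_order = 1)
  expect_rel(fit1$taus, 2.7e-3, 1e-6)
  y2 <- 0.9 * exp(-t / 2.7e-3) + 0.1 * exp(-t / 20e-3)
  fit2 <- fit_exponentials(t, y2, model_order = 2)
  expect_equal(fit2$apparent_tau, (0.9 * 2.7e-3 + 0.1 * 20e-3), tolerance = 1e-4)
  expect_true(all(diff(fit2$taus) > 0))
  expect_gte(fit2$apparent_tau, fit2$taus[1])
  expect_lte(fit2$apparent_tau, fit2$taus[2])
  # constant input is flagged degenerate
  fit0 <- fit_exponentials(t, rep(4, length(t)), model_order = 1)
  expect_true(fit0$degenerate)
  expect_error(fit_exponentials(t[1:3], exp(-t[1:3]), 1), "at least")
  expect_s3_class(tidy(fit2), "tbl_df")
  expect_true(all(c("aic", "residual_rms") %in% names(glance(fit2))))
})

test_that("reversal potentials follow the crossing/extrapolation rule", {
  v <- seq(-80, 40, by = 20)
  expect_equal(reversal_potential(tibble::tibble(voltage_mV = v,
                                                 current_pA = 2 * (v + 10))), -10)
  expect_equal(reversal_potential(tibble::tibble(voltage_mV = c(-20, 0),
                                                 current_pA = c(-1, 3))), -15)
  # no crossing: extrapolate the two smallest-|I| (adjacent) points
  expect_equal(reversal_potential(tibble::tibble(voltage_mV = c(0, 20, 40),
                                                 current_pA = c(12, 20, 28))), -30)
  # exact zero sample
  expect_equal(reversal_potential(tibble::tibble(voltage_mV = c(-20, 0, 20),
                                                 current_pA = c(-5, 0, 5))), 0)
  expect_error(reversal_potential(tibble::tibble(voltage_mV = 0, current_pA = 1)),
               "two")
})

test_that("reversal potential equals the analytic crossing on monotone IVs", {
  set.seed(42)
  for (rep in 1:25) {
    e_rev <- stats::runif(1, -75, 35)
    slope <- stats::runif(1, 0.5, 30)
    curve <- function(v) slope * (v - e_rev) * (1 + 0.004 * (v - e_rev))
    v <- seq(-80, 40, by = 20)
    iv <- tibble::tibble(voltage_mV = v, current_pA = curve(v))
    if (!any(diff(sign(iv$current_pA)) != 0)) next
    got <- reversal_potential(iv)
    # analytic zero of the piecewise-linear interpolant through the pair
    j <- max(which(sign(iv$current_pA[-length(v)]) * sign(iv$current_pA[-1]) < 0)[1], 1)
    expected <- v[j] - iv$current_pA[j] * 20 / (iv$current_pA[j + 1] - iv$current_pA[j])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("Nernst potentials match the electrochemical formula", {
  expect_equal(nernst_potential(120, 120, -1, 24), 0)
  expect_equal(nernst_potential(150, 120, -1, 24), -5.71, tolerance = 1e-3)
  # extracellular depletion 150 -> 10 mM at fixed internal 120 mM
  shift <- nernst_potential(10, 120, -1, 24) - nernst_potential(150, 120, -1, 24)
  expect_equal(shift, 69.4, tolerance = 1e-3)
  # antisymmetry and linearity in absolute temperature
  expect_equal(nernst_potential(30, 90, 1, 24), -nernst_potential(90, 30, 1, 24))
  r <- nernst_potential(50, 10, 1, 100) / nernst_potential(50, 10, 1, 0)
  expect_equal(r, 373.15 / 273.15, tolerance = 1e-12)
  expect_error(nernst_potential(10, 10, 0), "z")
})

test_that("bi-ionic permeability ratios are oriented for anion selectivity", {
  expect_equal(permeability_ratio(0, -1), 1)
  expect_equal(permeability_ratio(-10, -1, 24), 1.478, tolerance = 1e-3)
  expect_equal(permeability_ratio(-rt_over_f(24), -1, 24), exp(1))
  # more permeant anion (negative shift) must give ratio > 1
  expect_gt(permeability_ratio(-5, -1, 24), 1)
})

test_that("recovery fits find tau_rec and flag degenerate series", {
  rec <- gen_recovery(tau_rec_s = 1.21, intervals_s = c(0.2, 0.5, 1, 2, 5, 10))
  fit <- recovery_fit(rec)
  expect_rel(fit$tau_rec, 1.21, 1e-6)
  flat <- tibble::tibble(interval_s = 1:5, peak_ratio = rep(1, 5))
  expect_true(recovery_fit(flat)$degenerate)
  expect_error(recovery_fit(rec[1:3, ]), "4")
  # MerMAID6-like slow recovery
  rec6 <- gen_recovery(tau_rec_s = 6, intervals_s = c(0.5, 1, 2, 5, 10, 20))
  expect_rel(recovery_fit(rec6)$tau_rec, 6, 1e-6)
})

test_that("noisy round trips recover generator ground truth within tolerance", {
  # reversal potentials: 2 percent full-scale current noise; the natural
  # tolerance for a potential is 5 percent of the 20 mV step resolution
  err_iv <- vapply(1:20, function(s) {
    iv <- gen_iv(e_rev_mV = -12, slope_pA_per_mV = 15, noise_sd = 0.02 * 15 * 50,
                 seed = s)
    abs(reversal_potential(iv) - (-12))
  }, numeric(1))
  expect_lt(stats::median(err_iv), 1)
  err_rec <- vapply(1:20, function(s) {
    rec <- gen_recovery(tau_rec_s = 1.21, noise_sd = 0.02, seed = s)
    abs(recovery_fit(rec)$tau_rec / 1.21 - 1)
  }, numeric(1))
  expect_lt(stats::median(err_rec), 0.05)
})

test_that("Weibull action fit returns the analytic peak wavelength", {
  # closed form: lambda0 400, beta 120, k 2 peaks at 484.85 nm
  expect_equal(weibull_lambda_max(400, 120, 2), 400 + 120 * sqrt(0.5),
               tolerance = 1e-12)
  wl <- seq(390, 680, by = 10)
  resp <- photocycler:::weibull_shape(wl, 400, 120, 2)
  fit <- weibull_action_fit(tibble::tibble(wavelength_nm = wl,
                                           response = resp / max(resp)))
  expect_equal(fit$lambda_max_nm, 484.85, tolerance = 1e-3)
  # analytic peak equals the numeric argmax of the fitted curve
  grid <- seq(390, 680, by = 0.01)
  curve <- photocycler:::weibull_shape(grid, fit$lambda0, fit$beta, fit$k)
  expect_equal(grid[which.max(curve)], fit$lambda_max_nm, tolerance = 0.02)
  # fixture spectrum peaks at 502 nm
  fx <- weibull_action_fit(gen_action_spectrum())
  expect_equal(fx$lambda_max_nm, 502, tolerance = 0.5)
  expect_error(weibull_action_fit(tibble::tibble(wavelength_nm = wl[1:4],
                                                 response = resp[1:4])), "6")
})

test_that("Henderson LJP reproduces the printed neuronal correction", {
  internal <- solution_composition(tibble::tibble(
    species = c("K-gluconate", "MgCl2", "Na2-ATP", "Na-GTP",
                "Na2-phosphocreatine", "ascorbate", "EGTA", "HEPES"),
    mM = c(135, 4, 4, 0.4, 10, 3, 0.2, 10)), pH = 7.2)
  acsf <- solution_composition(tibble::tibble(
    species = c("NaCl", "KCl", "CaCl2", "MgCl2", "Na-HEPES", "glucose", "NaH2PO4"),
    mM = c(135, 2.5, 2, 1, 10, 12.5, 1.25)), pH = 7.4)
  ljp <- henderson_ljp(internal, acsf)
  expect_equal(ljp, -14.5, tolerance = 1 / 14.5)  # +- 1 mV band
  # identical solutions -> 0; antisymmetry under swap
  expect_equal(henderson_ljp(acsf, acsf), 0)
  expect_equal(henderson_ljp(internal, acsf), -henderson_ljp(acsf, internal),
               tolerance = 1e-12)
})

test_that("solution dissociation resolves ions and flags unknown species", {
  s <- solution_composition(tibble::tibble(species = c("NaCl", "CaCl2"),
                                           mM = c(100, 2)), pH = 7.4)
  cl <- s$ions$mM[s$ions$ion == "Cl"]
  expect_equal(cl, 104)  # 100 + 2 x 2
  expect_error(solution_composition(tibble::tibble(species = "unobtainium",
                                                   mM = 1), pH = 7),
               "unobtainium")
})
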