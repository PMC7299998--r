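# Fitting: sigmoidal extraction, global and constrained fits, scaling,
# dose summaries, chi-squared.

test_that("fit_sigmoidal recovers noiseless parameters to machine-level precision", {
  tr <- sigmoid_trace(F0 = 0, A = 1, r_max = 5e-4, tau_half = 1e4, t_end = 3e4)
  f <- fit_sigmoidal(tr)
  expect_true(f$converged)
  expect_lt(abs(f$params$F0), 1e-6)
  expect_equal(f$params$A, 1, tolerance = 1e-6)
  expect_equal(f$params$r_max, 5e-4, tolerance = 1e-6)
  expect_equal(f$params$tau_half, 1e4, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-8)
})

test_that("fit_sigmoidal tau_half matches the kinetic model's half-amplitude crossing", {
  rc <- ref_rc()
  m0 <- 3e-6
  th <- model_halftime(rc, m0)
  t <- seq(0, 4 * th, length.out = 200)
  tr <- aggregation_trace("A01", t, fibril_mass_fraction(t, rc, m0),
                          substrate_conc = m0)
  f <- fit_sigmoidal(tr)
  expect_true(f$converged)
  expect_lt(abs(f$params$tau_half - th) / th, 0.05)
})

test_that("fit_sigmoidal is accurate under noise (seeded simulation)", {
  errs <- vapply(1:12, function(s) {
    tr <- sigmoid_trace(noise_sd = 0.02, seed = s, t_end = 3e4)
    f <- fit_sigmoidal(tr)
    abs(f$params$tau_half - 1e4) / 1e4
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("fit_global recovers generator truth and validates its design", {
  # scaled-down recovery run (acceptance covers the full design): 4
  # concentrations, 2 replicates
  pl <- generate_tht_plate(ref_rc(), m0_list = c(1.5, 3, 5, 9) * 1e-6,
                           noise_sd = 0.02, n_reps = 2, seed = 3)
  gl <- fit_global(plate_to_means(pl))
  expect_true(gl$converged)
  expect_lt(abs(gl$sqrt_knkp / 6.4 - 1), 0.10)
  expect_lt(abs(gl$sqrt_kpk2 / 2.74e5 - 1), 0.10)
  expect_true(all(is.finite(gl$standard_errors)))
  expect_gte(gl$chi2, 0)
  # single concentration is rank-deficient
  one <- generate_tht_plate(ref_rc(), m0_list = 3e-6, noise_sd = 0,
                            n_reps = 1, seed = 1, n_time = 60)
  expect_error(fit_global(plate_to_means(one)), class = "aggkin_invalid_input")
})

test_that("noiseless single-parameter-set data is recovered near-exactly", {
  pl <- generate_tht_plate(ref_rc(), m0_list = c(2, 3, 6) * 1e-6,
                           noise_sd = 0, n_reps = 1, seed = 1, n_time = 300)
  gl <- fit_global(plate_to_means(pl))
  expect_lt(abs(gl$sqrt_knkp / 6.4 - 1), 0.02)
  expect_lt(abs(gl$sqrt_kpk2 / 2.74e5 - 1), 0.005)
  expect_lt(gl$ssr, 1e-4)
})

test_that("mechanism fit: null inhibitor gives unit factors; joint reduction ranks kn last", {
  # no inhibitor effect: all dose factors within 5% of 1
  pl0 <- generate_tht_plate(ref_rc(), m0_list = 3e-6,
                            inhib = inhibitor_model("none"),
                            ratios = c(0, 0.5, 1), noise_sd = 0.01,
                            n_reps = 3, seed = 8, n_time = 100)
  mech0 <- fit_constrained_mechanism(plate_to_means(pl0))
  for (h in names(mech0$fits))
    expect_true(all(abs(mech0$fits[[h]]$dose_factors - 1) < 0.05))
  # joint k2 + k+ reduction: both k2_free and kplus_free beat kn_free
  pl2 <- generate_tht_plate(ref_rc(), m0_list = 3e-6,
                            inhib = inhibitor_model("combo"),
                            ratios = c(0, 0.3, 0.7, 1), noise_sd = 0.02,
                            n_reps = 4, seed = 8, n_time = 100)
  mech2 <- fit_constrained_mechanism(plate_to_means(pl2))
  expect_lt(mech2$chi2[["k2_free"]], mech2$chi2[["kn_free"]])
  expect_lt(mech2$chi2[["kplus_free"]], mech2$chi2[["kn_free"]])
  expect_identical(mech2$ranking[3], "kn_free")
  # missing zero-dose reference
  bad <- plate_to_means(pl2)
  bad <- bad[vapply(bad, function(tr) tr$molar_ratio > 0, logical(1))]
  expect_error(fit_constrained_mechanism(bad), class = "aggkin_invalid_input")
})

test_that("combined-free dose fits: anchor at 1, k2-only signature, amplitude invariance", {
  pl <- generate_tht_plate(ref_rc(), m0_list = 3e-6,
                           inhib = inhibitor_model("k2"),
                           ratios = c(0, 0.3, 0.7, 1), noise_sd = 0.02,
                           n_reps = 4, seed = 4, n_time = 100)
  means <- plate_to_means(pl)
  cf <- fit_combined_free(means)
  expect_equal(cf$rel_sqrt_knkp[cf$dose == 0], 1)
  expect_equal(cf$rel_sqrt_kpk2[cf$dose == 0], 1)
  # secondary constant tracks the generator's k2 factors (sqrt scaling on
  # kappa -> sqrt(f) on sqrt(k+*k2)); primary stays within 15% of 1
  expect_true(all(diff(cf$rel_sqrt_kpk2) < 0))
  expect_equal(cf$rel_sqrt_kpk2[cf$dose == 1], sqrt(0.12), tolerance = 0.15)
  expect_true(all(abs(cf$rel_sqrt_knkp - 1) < 0.15))
  # relative values invariant to rescaling all trace amplitudes
  scaled <- lapply(means, function(tr) { tr$signals <- tr$signals * 3.1; tr })
  cf2 <- fit_combined_free(scaled)
  expect_equal(cf2$rel_sqrt_kpk2, cf$rel_sqrt_kpk2, tolerance = 0.02)
})

test_that("half-time scaling: exact power law and model-implied gamma", {
  m0 <- c(1.5, 2, 3, 5, 9) * 1e-6
  exact <- data.frame(m0 = m0, tau_half = 7e-4 * m0^(-1.5))
  sc <- fit_halftime_scaling(exact)
  expect_equal(sc$gamma, -1.5, tolerance = 1e-6)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_halftime_scaling(exact[1:2, ]), class = "aggkin_invalid_input")
  expect_error(fit_halftime_scaling(data.frame(m0 = m0, tau_half = -1)),
               class = "aggkin_invalid_input")
})

test_that("inhibitor dependence summaries recover exact inputs", {
  dose <- c(0, 0.5, 1, 2, 3) * 1e-6
  tab <- data.frame(dose = dose,
                    tau_half = 5000 + 2e9 * dose,        # exact linear
                    r_max = 4e-4 * exp(-8e5 * dose) + 1e-5)  # exact exponential
  s <- summarize_inhibitor_dependence(tab)
  expect_equal(s$tau_linear$slope, 2e9, tolerance = 1e-6)
  expect_equal(s$tau_linear$intercept, 5000, tolerance = 1e-6)
  expect_equal(s$rmax_exponential$b, 8e5, tolerance = 1e-4)
  expect_equal(s$rmax_exponential$a, 4e-4, tolerance = 1e-4)
  expect_error(summarize_inhibitor_dependence(tab[1:2, ]),
               class = "aggkin_invalid_input")
})

test_that("chi_squared definition and nested-fit monotonicity", {
  # perfect fit
  expect_equal(as.numeric(chi_squared(list(1:10 / 10), list(1:10 / 10), 2)), 0)
  # residuals all r with sigma 1: r^2 * N / (N - p)
  m <- rep(0, 50); d <- rep(0.3, 50)
  expect_equal(as.numeric(chi_squared(m, d, 4, sigma = 1)),
               0.3^2 * 50 / (50 - 4))
  expect_error(chi_squared(m, d, 50), class = "aggkin_invalid_input")
  expect_error(chi_squared(list(m), list(d[1:10]), 2), class = "aggkin_invalid_input")
  # nested hypotheses: raw SSR of the less-constrained fit is never larger
  pl <- generate_tht_plate(ref_rc(), m0_list = 3e-6,
                           inhib = inhibitor_model("k2"),
                           ratios = c(0, 0.5, 1), noise_sd = 0.02,
                           n_reps = 2, seed = 6, n_time = 80)
  means <- plate_to_means(pl)
  mech <- fit_constrained_mechanism(means)
  cf <- fit_combined_free(means)
  # the per-dose 2-parameter fit nests every 1-parameter hypothesis
  expect_lte(sum(cf$ssr), min(vapply(mech$fits, `[[`, numeric(1), "ssr")) + 1e-9)
})

test_that("fits are deterministic given data and seed", {
  pl <- generate_tht_plate(ref_rc(), m0_list = c(2, 3, 6) * 1e-6,
                           noise_sd = 0.02, n_reps = 1, seed = 2, n_time = 60)
  means <- plate_to_means(pl)
  g1 <- fit_global(means); g2 <- fit_global(means)
  expect_identical(g1$sqrt_knkp, g2$sqrt_knkp)
  expect_identical(g1$sqrt_kpk2, g2$sqrt_kpk2)
})
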