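# Plate ingestion, normalization, replicate averaging, endpoints.

test_that("load_plate joins wells and metadata and validates them", {
  pl <- generate_tht_plate(ref_rc(), m0_list = 3e-6,
                           inhib = inhibitor_model("k2"),
                           ratios = c(0, 0.1, 0.3, 0.5, 0.7, 1),
                           noise_sd = 0.01, n_reps = 4, seed = 5, n_time = 60)
  traces <- load_plate(pl$data, pl$metadata)
  expect_length(traces, 24)          # 6 ratios x 4 replicates
  tr <- traces[[1]]
  expect_s3_class(tr, "agg_trace")
  expect_equal(tr$substrate_conc, 3e-6)        # uM -> M conversion
  expect_equal(tr$molar_ratio, tr$inhibitor_conc / tr$substrate_conc,
               tolerance = 1e-12)
  # metadata missing one well: error names the well
  meta_bad <- pl$metadata[-3, ]
  expect_error(load_plate(pl$data, meta_bad), pl$metadata$well[3],
               class = "aggkin_load_error")
  # non-monotone time
  dat_bad <- pl$data
  dat_bad$time_s[5] <- dat_bad$time_s[7]
  expect_error(load_plate(dat_bad, pl$metadata), class = "aggkin_load_error")
})

test_that("written plates round-trip bit-identically and long dialect matches wide", {
  pl <- generate_tht_plate(ref_rc(), m0_list = c(2e-6, 4e-6), noise_sd = 0.02,
                           n_reps = 2, seed = 9, n_time = 40)
  d <- withr::local_tempdir()
  paths <- write_plate(pl, d)
  traces <- load_plate(paths[["plate"]], paths[["metadata"]])
  for (w in names(traces)) {
    expect_identical(traces[[w]]$signals, pl$data[[w]])
    expect_identical(traces[[w]]$times, pl$data$time_s)
  }
  # long dialect
  long <- do.call(rbind, lapply(setdiff(names(pl$data), "time_s"), function(w)
    data.frame(time_s = pl$data$time_s, well = w, signal = pl$data[[w]])))
  traces_long <- load_plate(long, pl$metadata)
  expect_identical(traces_long[[1]]$signals, traces[[1]]$signals)
})

test_that("baseline_and_normalize recovers sigmoid anchors and is affine-invariant", {
  # r_max * tau_half = 10 so the baseline tail (A/(1+e^10)) is negligible
  tr <- sigmoid_trace(F0 = 3, A = 7, r_max = 1e-3, t_end = 4e4)
  nt <- baseline_and_normalize(tr)
  expect_true(nt$aggregating)
  expect_equal(nt$baseline_used, 3, tolerance = 1e-3)
  expect_equal(nt$plateau_used, 10, tolerance = 1e-3)
  expect_equal(mean(head(nt$signals, 5)), 0, tolerance = 0.05)
  expect_equal(mean(tail(nt$signals, 10)), 1, tolerance = 0.05)
  # affine invariance
  tr2 <- tr; tr2$signals <- 13.7 * tr$signals + 42
  nt2 <- baseline_and_normalize(tr2)
  expect_equal(nt2$signals, nt$signals, tolerance = 1e-10)
  # fitted-plateau variant recovers F0 + A
  ntf <- baseline_and_normalize(tr, plateau = "fitted")
  expect_equal(ntf$plateau_used, 10, tolerance = 1e-4)
  # noisy plateau lands within 2% of 1
  trn <- sigmoid_trace(F0 = 0, A = 1, noise_sd = 0.02, seed = 7, t_end = 4e4)
  ntn <- baseline_and_normalize(trn)
  expect_equal(mean(tail(ntn$signals, 10)), 1, tolerance = 0.02)
  # flat trace flagged, not normalized
  flat <- sigmoid_trace(F0 = 5, A = 1e-4, t_end = 4e4)
  nf <- baseline_and_normalize(flat)
  expect_false(nf$aggregating)
  expect_error(baseline_and_normalize(tr, baseline_window = 150,
                                      plateau_window = 100),
               class = "aggkin_invalid_input")
})

test_that("average_replicates: SD semantics, symmetry, 1/sqrt(n) error decay", {
  t1 <- sigmoid_trace(); t2 <- sigmoid_trace(well = "A02")
  m <- average_replicates(list(t1, t2))
  expect_identical(max(m$sd), 0)       # identical replicates
  expect_equal(m$n, 2)
  # two traces at 0 and 1 -> mean 0.5, SD sqrt(0.5)
  a <- sigmoid_trace(); b <- sigmoid_trace(well = "A02")
  a$signals[] <- 0; b$signals[] <- 1
  m2 <- average_replicates(list(a, b))
  expect_equal(unique(m2$signals), 0.5)
  expect_equal(unique(m2$sd), sqrt(0.5))
  # permutation invariance
  x <- sigmoid_trace(noise_sd = 0.05, seed = 1)
  y <- sigmoid_trace(noise_sd = 0.05, seed = 2, well = "A02")
  z <- sigmoid_trace(noise_sd = 0.05, seed = 3, well = "A03")
  expect_equal(average_replicates(list(x, y, z))$signals,
               average_replicates(list(z, x, y))$signals)
  # rms error of the mean decays like 1/sqrt(n)
  mk <- function(n, s0) lapply(seq_len(n), function(i)
    sigmoid_trace(noise_sd = 0.05, seed = s0 + i, well = paste0("W", i)))
  truth <- sigmoid_trace()$signals
  rms <- function(n, s0) sqrt(mean((average_replicates(mk(n, s0))$signals - truth)^2))
  r4 <- mean(vapply(1:5, function(k) rms(4, 100 * k), numeric(1)))
  r16 <- mean(vapply(1:5, function(k) rms(16, 1000 * k), numeric(1)))
  expect_equal(r16 / r4, 0.5, tolerance = 0.2)
  # mismatched grids rejected with a helpful message
  short <- sigmoid_trace(n = 150, well = "A04")
  expect_error(average_replicates(list(t1, short)), "interpolate",
               class = "aggkin_load_error")
})

test_that("final_intensity averages the endpoint window", {
  tr <- sigmoid_trace()
  tr$signals[] <- 2.5
  expect_equal(final_intensity(tr), 2.5)
  ramp <- sigmoid_trace(n = 100)
  ramp$signals <- seq(0, 1, length.out = 100)
  expect_equal(final_intensity(ramp, window = 1), 1)
  expect_error(final_intensity(ramp, window = 101), class = "aggkin_invalid_input")
})
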