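# Shared fixtures, all generated in code.

# reference combined rate constants used throughout (uninhibited / inhibited)
ref_rc <- function() rate_constants_from_combined(6.4, 2.74e5)
ref_rc_inhibited <- function() rate_constants_from_combined(10.8, 0.4e5)

# a noiseless sigmoidal trace as an agg_trace
sigmoid_trace <- function(F0 = 0, A = 1, r_max = 5e-4, tau_half = 1e4,
                          n = 200, t_end = 3e4, noise_sd = 0, seed = 1,
                          well = "A01", m0 = 3e-6, ratio = NA_real_,
                          group = "g1") {
  t <- seq(0, t_end, length.out = n)
  p <- sigmoidal_params(F0, A, r_max, tau_half)
  y <- sigmoidal_signal(t, p)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  aggregation_trace(well, t, y, assay = "ThT", substrate = "Abeta42",
                    substrate_conc = m0, molar_ratio = ratio,
                    replicate_group = group)
}

# normalized mean curves per condition from a synthetic plate
plate_to_means <- function(plate, plateau = "endpoint") {
  norm <- lapply(load_plate(plate$data, plate$metadata),
                 baseline_and_normalize, plateau = plateau)
  key <- vapply(norm, `[[`, "", "replicate_group")
  lapply(split(norm, key), average_replicates)
}
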