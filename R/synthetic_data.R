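# Synthetic plate-data generation with known ground truth, for exercising
# the full pipeline without external data.
#
# ThT plates follow the unseeded nucleation-elongation kinetics with
# configurable inhibitor action on the microscopic rates; turbidity plates
# emulate thermal (non-fibrillar) aggregation with plateau suppression at
# sub-stoichiometric chaperone ratios.

#' Inhibitor action model for synthetic ThT plates
#'
#' Describes which microscopic rate constant(s) an inhibitor suppresses and
#' by how much at each dose (molar ratio). Factors are multiplicative on the
#' targeted rate, in (0, 1], and equal 1 at dose 0.
#'
#' @param target `"kn"`, `"k_plus"`, `"k2"`, `"combo"`, or `"none"`.
#' @param dose_factor_map data.frame with columns `dose` and `factor`
#'   (for `"combo"`: columns `dose`, `kn`, `k_plus`, `k2`). Must contain
#'   dose 0 with factor 1. The default map mirrors a strong secondary
#'   nucleation suppressor over molar ratios 0 to 1.
#' @return object of class `inhibitor_model`.
#' @export
inhibitor_model <- function(target = c("k2", "kn", "k_plus", "combo", "none"),
                            dose_factor_map = NULL) {
  target <- match.arg(target)
  if (is.null(dose_factor_map)) {
    dose_factor_map <- if (target == "combo")
      data.frame(dose = c(0, 0.1, 0.3, 0.5, 0.7, 1),
                 kn = 1, k_plus = c(1, 0.9, 0.75, 0.6, 0.5, 0.4),
                 k2 = c(1, 0.7, 0.45, 0.3, 0.2, 0.12))
    else
      data.frame(dose = c(0, 0.1, 0.3, 0.5, 0.7, 1),
                 factor = c(1, 0.7, 0.45, 0.3, 0.2, 0.12))
  }
  cols <- if (target == "combo") c("kn", "k_plus", "k2") else "factor"
  if (!all(c("dose", cols) %in% names(dose_factor_map)))
    abort_invalid("`dose_factor_map` lacks required columns")
  if (!any(dose_factor_map$dose == 0))
    abort_invalid("`dose_factor_map` must include dose 0")
  fac0 <- unlist(dose_factor_map[dose_factor_map$dose == 0, cols])
  if (any(abs(fac0 - 1) > 1e-12)) abort_invalid("factors must equal 1 at dose 0")
  if (any(unlist(dose_factor_map[cols]) <= 0))
    abort_invalid("factors must be positive")
  structure(list(target = target, map = dose_factor_map[order(dose_factor_map$dose), ]),
            class = "inhibitor_model")
}

# Per-rate multiplicative factors c(kn, k_plus, k2) at a dose (linear
# interpolation between tabulated doses).
dose_factors <- function(inhib, dose) {
  if (is.null(inhib) || inhib$target == "none")
    return(c(kn = 1, k_plus = 1, k2 = 1))
  m <- inhib$map
  look <- function(col) {
    if (dose <= min(m$dose)) return(m[[col]][which.min(m$dose)])
    if (dose >= max(m$dose)) return(m[[col]][which.max(m$dose)])
    stats::approx(m$dose, m[[col]], xout = dose)$y
  }
  if (inhib$target == "combo")
    c(kn = look("kn"), k_plus = look("k_plus"), k2 = look("k2"))
  else {
    f <- look("factor")
    out <- c(kn = 1, k_plus = 1, k2 = 1)
    out[inhib$target] <- f
    out
  }
}

# Apply dose factors to rate constants.
scale_rates <- function(rc, fac) {
  rate_constants(kn = rc$kn * fac[["kn"]], k_plus = rc$k_plus * fac[["k_plus"]],
                 k2 = rc$k2 * fac[["k2"]], nc = rc$nc, n2 = rc$n2)
}

well_ids <- function(n) {
  if (n > 384) abort_invalid("more than 384 wells requested")
  i <- seq_len(n) - 1L
  sprintf("%s%02d", LETTERS[i %/% 24 + 1L], i %% 24 + 1L)
}

#' Generate a synthetic ThT fibrillization plate
#'
#' Simulates unseeded ThT traces F(t) = F0 + A * M(t)/M(inf) + noise for
#' every combination of monomer concentration, inhibitor molar ratio and
#' replicate. The shared time grid spans `span_halftimes` half-times of the
#' slowest well. Kinetic curves use the oracle-corrected closed form where
#' the secondary pathway dominates (kappa/lambda > 10) and the moment-ODE
#' integrator otherwise, so noiseless wells reproduce
#' [fibril_mass_fraction()] exactly in the closed-form regime.
#'
#' @param rc uninhibited [rate_constants()].
#' @param m0_list monomer concentrations, molar. Default: the standard
#'   eight-concentration series 1.5-9 uM.
#' @param inhib an [inhibitor_model()] or NULL (no inhibitor).
#' @param ratios inhibitor:substrate molar ratios (default 0).
#' @param noise_sd Gaussian noise SD as a fraction of the amplitude
#'   (default 0.02).
#' @param n_reps replicates per condition (default 4).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param n_time points on the time grid (default 400, roughly 2-minute
#'   reader cycles over a typical 12-16 h run).
#' @param span_halftimes grid span in units of the slowest half time
#'   (default 4).
#' @param F0,A baseline and amplitude in arbitrary fluorescence units.
#' @param substrate substrate label in the metadata.
#' @return object of class `synthetic_plate`: `data` (wide plate
#'   data.frame), `metadata` (data.frame), `truth` (all generator
#'   parameters, per-condition half times, seed, warnings).
#' @export
generate_tht_plate <- function(rc, m0_list = c(1.5, 2, 2.5, 3, 4, 5, 7, 9) * 1e-6,
                               inhib = NULL, ratios = 0, noise_sd = 0.02,
                               n_reps = 4, seed = 1, n_time = 400,
                               span_halftimes = 4, F0 = 10, A = 100,
                               substrate = "Abeta42") {
  if (noise_sd < 0) abort_invalid("`noise_sd` must be >= 0")
  if (length(m0_list) < 1 || length(ratios) < 1)
    abort_invalid("need at least one monomer concentration and one ratio")
  cond <- expand.grid(m0 = m0_list, ratio = ratios, KEEP.OUT.ATTRS = FALSE)
  cond <- cond[order(cond$m0, cond$ratio), , drop = FALSE]
  cond$lam <- NA_real_; cond$kap <- NA_real_; cond$tau <- NA_real_
  for (i in seq_len(nrow(cond))) {
    fac <- dose_factors(inhib, cond$ratio[i])
    rci <- scale_rates(rc, fac)
    cond$lam[i] <- compute_lambda(rci, cond$m0[i])
    cond$kap[i] <- compute_kappa(rci, cond$m0[i])
    cond$tau[i] <- model_halftime(rci, cond$m0[i])
  }
  warnings <- character()
  if (any(!is.finite(cond$tau)))
    abort_invalid("a condition never aggregates (infinite half time)")
  t_end <- span_halftimes * max(cond$tau)
  t_grid <- seq(0, t_end, length.out = n_time)
  slow <- cond$tau * span_halftimes > t_end + 1e-9
  if (any(slow))
    warnings <- c(warnings, sprintf("condition m0=%g ratio=%g: half time %.3g s exceeds grid",
                                    cond$m0[slow], cond$ratio[slow], cond$tau[slow]))
  n_wells <- nrow(cond) * n_reps
  ids <- well_ids(n_wells)
  dat <- data.frame(time_s = t_grid)
  meta <- NULL
  w <- 0L
  signals <- with_seed(seed, {
    cols <- list()
    for (i in seq_len(nrow(cond))) {
      u <- kinetic_curve(t_grid, cond$lam[i], cond$kap[i], rc$nc, rc$n2,
                         method = "auto", exact = TRUE)
      for (rep in seq_len(n_reps)) {
        w <- w + 1L
        noise <- if (noise_sd > 0) stats::rnorm(n_time, 0, noise_sd * A) else 0
        cols[[ids[w]]] <- F0 + A * u + noise
        meta <- rbind(meta, data.frame(
          well = ids[w], assay = "ThT", substrate = substrate,
          substrate_conc_uM = cond$m0[i] * 1e6,
          inhibitor = if (cond$ratio[i] > 0 || length(ratios) > 1) "chaperone" else "",
          inhibitor_conc_uM = cond$ratio[i] * cond$m0[i] * 1e6,
          molar_ratio = cond$ratio[i],
          replicate_group = sprintf("m%g_r%g", cond$m0[i] * 1e6, cond$ratio[i])))
      }
    }
    cols
  })
  dat <- cbind(dat, as.data.frame(signals, check.names = FALSE))
  truth <- list(
    kind = "tht", seed = seed, rate_constants = unclass(rc),
    combined = as.list(combined_rate_constants(rc)),
    m0_list = m0_list, ratios = ratios,
    inhibitor = if (is.null(inhib)) NULL else unclass(inhib),
    dose_rate_factors = lapply(stats::setNames(ratios, ratios),
                               function(r) as.list(dose_factors(inhib, r))),
    noise_sd = noise_sd, n_reps = n_reps, F0 = F0, A = A,
    t_end = t_end, n_time = n_time, span_halftimes = span_halftimes,
    conditions = cond[, c("m0", "ratio", "lam", "kap", "tau")],
    warnings = warnings)
  structure(list(data = dat, metadata = meta, truth = truth),
            class = "synthetic_plate")
}

#' Turbidity trace model for synthetic holdase-assay plates
#'
#' Monotone saturating (logistic-rise) light-scattering traces whose final
#' plateau is suppressed by the chaperone according to a residual-fraction
#' map (fraction of the substrate-alone plateau remaining at each molar
#' ratio).
#'
#' @param plateau substrate-alone plateau intensity (signal units).
#' @param rise_rate logistic rate, s^-1 (default 1/300).
#' @param t_mid logistic midpoint, seconds (default 2400).
#' @param residual_map data.frame with columns `ratio` and `fraction`
#'   (fraction 1 at ratio 0). Default mirrors near-complete suppression at
#'   a 1:1 molar ratio.
#' @return object of class `turbidity_model`.
#' @export
turbidity_model <- function(plateau = 100, rise_rate = 1 / 300, t_mid = 2400,
                            residual_map = data.frame(
                              ratio = c(0, 0.1, 0.3, 0.5, 1),
                              fraction = c(1, 0.75, 0.45, 0.22, 0.05))) {
  stopifnot_scalar_positive(plateau, "plateau")
  stopifnot_scalar_positive(rise_rate, "rise_rate")
  if (!all(c("ratio", "fraction") %in% names(residual_map)))
    abort_invalid("`residual_map` needs columns ratio and fraction")
  if (!any(residual_map$ratio == 0) ||
      abs(residual_map$fraction[residual_map$ratio == 0] - 1) > 1e-12)
    abort_invalid("`residual_map` must have fraction 1 at ratio 0")
  if (any(residual_map$fraction <= 0 | residual_map$fraction > 1))
    abort_invalid("residual fractions must be in (0, 1]")
  structure(list(plateau = plateau, rise_rate = rise_rate, t_mid = t_mid,
                 residual_map = residual_map[order(residual_map$ratio), ]),
            class = "turbidity_model")
}

residual_fraction <- function(tm, ratio) {
  m <- tm$residual_map
  if (ratio <= min(m$ratio)) return(m$fraction[which.min(m$ratio)])
  if (ratio >= max(m$ratio)) return(m$fraction[which.max(m$ratio)])
  stats::approx(m$ratio, m$fraction, xout = ratio)$y
}

#' Generate a synthetic turbidity (holdase assay) plate
#'
#' Emulates thermal aggregation of a destabilized substrate followed by
#' light scattering: `n_blocks` independent experiment blocks, each with
#' `n_reps` replicate wells per molar ratio, multiplicative block gain
#' effects and additive Gaussian noise. Traces start at 0 and saturate at
#' plateau * residual_fraction(ratio) * block_gain.
#'
#' @param tm a [turbidity_model()].
#' @param ratios chaperone:substrate molar ratios; must include 0 (control).
#' @param n_blocks experiment blocks (default 3).
#' @param n_reps replicates per ratio within a block (default 3).
#' @param noise_sd additive noise SD as a fraction of the plateau
#'   (default 0.02).
#' @param block_gain half-width of the uniform multiplicative block gain
#'   (default 0.1, i.e. gains in [0.9, 1.1]).
#' @param seed integer seed.
#' @param t_grid time grid in seconds (default 2 h at 60 s cycles).
#' @param substrate substrate label (default "CS").
#' @param substrate_conc_uM substrate concentration in the metadata
#'   (default 0.6, i.e. 600 nM).
#' @return object of class `synthetic_plate` (see [generate_tht_plate()]).
#' @export
generate_turbidity_plate <- function(tm, ratios = c(0, 0.1, 0.3, 0.5, 1),
                                     n_blocks = 3, n_reps = 3, noise_sd = 0.02,
                                     block_gain = 0.1, seed = 1,
                                     t_grid = seq(0, 7200, by = 60),
                                     substrate = "CS", substrate_conc_uM = 0.6) {
  if (!any(ratios == 0)) abort_invalid("`ratios` must include the control ratio 0")
  if (noise_sd < 0 || block_gain < 0) abort_invalid("noise and gain must be >= 0")
  L <- function(t) 1 / (1 + exp(tm$rise_rate * (tm$t_mid - t)))
  L0 <- L(0)
  shape <- (L(t_grid) - L0) / (1 - L0)
  n_wells <- n_blocks * length(ratios) * n_reps
  ids <- well_ids(n_wells)
  meta <- NULL; w <- 0L
  out <- with_seed(seed, {
    gains <- 1 + stats::runif(n_blocks, -block_gain, block_gain)
    cols <- list()
    for (b in seq_len(n_blocks)) {
      for (r in ratios) {
        amp <- tm$plateau * residual_fraction(tm, r) * gains[b]
        for (rep in seq_len(n_reps)) {
          w <- w + 1L
          noise <- if (noise_sd > 0)
            stats::rnorm(length(t_grid), 0, noise_sd * tm$plateau) else 0
          cols[[ids[w]]] <- amp * shape + noise
          meta <- rbind(meta, data.frame(
            well = ids[w], assay = "turbidity", substrate = substrate,
            substrate_conc_uM = substrate_conc_uM,
            inhibitor = if (r > 0) "chaperone" else "",
            inhibitor_conc_uM = r * substrate_conc_uM, molar_ratio = r,
            replicate_group = sprintf("block%d", b)))
        }
      }
    }
    list(cols = cols, gains = gains)
  })
  dat <- cbind(data.frame(time_s = t_grid),
               as.data.frame(out$cols, check.names = FALSE))
  truth <- list(kind = "turbidity", seed = seed, model = unclass(tm),
                ratios = ratios,
                residual_fractions = stats::setNames(
                  vapply(ratios, function(r) residual_fraction(tm, r), numeric(1)),
                  ratios),
                block_gains = out$gains, n_blocks = n_blocks, n_reps = n_reps,
                noise_sd = noise_sd, block_gain = block_gain)
  structure(list(data = dat, metadata = meta, truth = truth),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %s: %d wells x %d time points (seed %d)\n",
              x$truth$kind, ncol(x$data) - 1L, nrow(x$data), x$truth$seed))
  invisible(x)
}

#' Write a synthetic plate to CSV files plus a JSON truth record
#'
#' Emits `<prefix>_plate.csv` and `<prefix>_metadata.csv` in the dialects
#' [load_plate()] reads, and `<prefix>_truth.json`.
#'
#' @param plate a `synthetic_plate`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default the plate kind).
#' @return named character vector of the three paths, invisibly.
#' @export
write_plate <- function(plate, dir, prefix = plate$truth$kind) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(plate = file.path(dir, paste0(prefix, "_plate.csv")),
             metadata = file.path(dir, paste0(prefix, "_metadata.csv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  # %.17g preserves doubles exactly, so written plates round-trip
  # bit-identically through load_plate()
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.17g", col) else col)
    df
  }
  utils::write.csv(fmt(plate$data), paths[["plate"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(plate$metadata), paths[["metadata"]], row.names = FALSE)
  jsonlite::write_json(plate$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
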