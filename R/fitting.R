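# Model fitting: sigmoidal per-trace fits, multi-concentration global fits of
# the combined rate constants, constrained single-rate-constant mechanism
# fits, half-time scaling, and inhibitor-dependence summaries.
#
# All nonlinear fits work on log-transformed positive parameters with a
# Latin-hypercube multi-start (fixed seed, default 1730), so results are
# deterministic given (data, seed).

default_fit_seed <- 1730

# Latin hypercube on [lower, upper]^d, midpoint-jittered, fixed seed.
lhs_sample <- function(n, lower, upper, seed = default_fit_seed) {
  d <- length(lower)
  with_seed(seed, {
    sapply(seq_len(d), function(j) {
      strata <- (sample.int(n) - 1 + stats::runif(n)) / n
      lower[j] + strata * (upper[j] - lower[j])
    })
  })
}

# Convert traces to a plain list of curves for least squares; kinetic fits
# exclude wells flagged non-aggregating.
traces_to_curves <- function(traces, kinetic = TRUE) {
  if (inherits(traces, "agg_trace")) traces <- list(traces)
  if (!length(traces)) abort_invalid("no traces supplied")
  out <- lapply(traces, function(tr) {
    if (kinetic && !is.null(tr$aggregating) && !tr$aggregating) return(NULL)
    y <- tr$signals
    if (kinetic) {
      # defensive renormalization: kinetic fits assume curves on the 0..1
      # scale; rescale anything that clearly is not (e.g. gain-shifted
      # input), leaving already-normalized traces untouched
      n <- length(y)
      b <- mean(y[seq_len(min(5, n))])
      p <- mean(y[seq.int(max(1L, n - 9L), n)])
      if ((abs(b) > 0.1 || abs(p - 1) > 0.1) && p - b > 0) y <- (y - b) / (p - b)
    }
    list(t = tr$times, y = y, m0 = tr$substrate_conc,
         ratio = tr$molar_ratio, dose = tr$inhibitor_conc, well = tr$well_id)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) abort_invalid("no aggregating traces left to fit")
  out
}

# Sum of squared residuals of the kinetic model over curves, given a function
# mapping a curve to its (lam, kap).
kinetic_ssr <- function(curves, lk_fun, nc, n2, method = "auto") {
  ssr <- 0
  for (cv in curves) {
    lk <- lk_fun(cv)
    u <- kinetic_curve(cv$t, lk[1], lk[2], nc, n2, method = method)
    ssr <- ssr + sum((cv$y - u)^2)
  }
  ssr
}

# Nelder-Mead with one restart; returns list(par, value, converged).
nm_polish <- function(par, fn, maxit = 800) {
  o1 <- stats::optim(par, fn, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12))
  o2 <- stats::optim(o1$par, fn, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12))
  list(par = o2$par, value = o2$value, converged = o2$convergence == 0)
}

# Multi-start driver: LHS starts, coarse screen, polish the best `n_polish`.
multistart_fit <- function(fn, lower, upper, n_start = 10, n_polish = 3,
                           seed = default_fit_seed, extra_starts = NULL) {
  starts <- lhs_sample(n_start, lower, upper, seed = seed)
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  vals <- apply(starts, 1, fn)
  ord <- order(vals)[seq_len(min(n_polish, nrow(starts)))]
  best <- NULL
  for (i in ord) {
    o <- nm_polish(starts[i, ], fn)
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}

#' Fit the sigmoidal model to a trace
#'
#' Least-squares fit of F(t) = F0 + A/(1 + exp(r_max (tau_half - t))) with
#' deterministic data-driven initialization: F0 and A from the baseline and
#' plateau windows, tau_half from the first half-amplitude crossing, r_max
#' from 4 * (max numerical slope) / A. Falls back to a deterministic
#' multi-start and a Nelder-Mead pre-optimization when Gauss-Newton fails.
#'
#' @param trace a (preferably normalized) aggregation trace.
#' @param check_flag refuse traces flagged non-aggregating (default TRUE).
#' @return object of class `sigmoidal_fit`: `params`
#'   ([sigmoidal_params()]), `param_errors`, `residual_rms`, `converged`,
#'   and `diagnostics`.
#' @export
fit_sigmoidal <- function(trace, check_flag = TRUE) {
  if (check_flag && !is.null(trace$aggregating) && !trace$aggregating)
    abort_invalid(sprintf("well %s is flagged non-aggregating", trace$well_id))
  t <- trace$times; y <- trace$signals
  n <- length(t)
  F0_0 <- mean(y[seq_len(min(5, n))])
  plat <- mean(y[seq.int(max(1L, n - 9L), n)])
  A_0 <- max(plat - F0_0, 1e-12 + 0.1 * stats::sd(y))
  half <- F0_0 + A_0 / 2
  idx <- which(y >= half)[1]
  tau_0 <- if (is.na(idx) || idx <= 1L) t[which.max(y)] else {
    t[idx - 1L] + (half - y[idx - 1L]) / (y[idx] - y[idx - 1L]) * (t[idx] - t[idx - 1L])
  }
  if (!is.finite(tau_0) || tau_0 <= 0) tau_0 <- stats::median(t)
  slope <- max(diff(y) / diff(t))
  r_0 <- max(4 * slope / A_0, 1e-3 / max(t))
  dat <- data.frame(t = t, y = y)
  try_nls <- function(st) {
    tryCatch(
      stats::nls(y ~ F0 + A / (1 + exp(r_max * (tau_half - t))), data = dat,
                 start = st, algorithm = "port",
                 lower = c(F0 = -Inf, A = 1e-12, r_max = 1e-12, tau_half = 1e-9),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
  }
  starts <- list(list(F0 = F0_0, A = A_0, r_max = r_0, tau_half = tau_0))
  for (fr in c(0.3, 3)) for (ft in c(0.7, 1.3))
    starts <- c(starts, list(list(F0 = F0_0, A = A_0, r_max = r_0 * fr,
                                  tau_half = tau_0 * ft)))
  fit <- NULL
  for (st in starts) { fit <- try_nls(st); if (!is.null(fit)) break }
  if (is.null(fit)) {
    ssr <- function(p) sum((y - (p[1] + exp(p[2]) /
      (1 + exp(exp(p[3]) * (exp(p[4]) - t)))))^2)
    o <- nm_polish(c(F0_0, log(A_0), log(r_0), log(tau_0)), ssr, maxit = 2000)
    fit <- try_nls(list(F0 = o$par[1], A = exp(o$par[2]), r_max = exp(o$par[3]),
                        tau_half = exp(o$par[4])))
  }
  if (is.null(fit)) {
    return(structure(list(
      params = sigmoidal_params(F0_0, A_0, r_0, tau_0),
      param_errors = c(F0 = NA, A = NA, r_max = NA, tau_half = NA),
      residual_rms = NA_real_, converged = FALSE,
      diagnostics = "nls failed from all deterministic starts"),
      class = "sigmoidal_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  res <- stats::resid(fit)
  structure(list(
    params = sigmoidal_params(cf[["F0"]], cf[["A"]], cf[["r_max"]], cf[["tau_half"]]),
    param_errors = c(F0 = se[["F0"]], A = se[["A"]], r_max = se[["r_max"]],
                     tau_half = se[["tau_half"]]),
    residual_rms = sqrt(mean(res^2)),
    converged = TRUE, diagnostics = "ok"), class = "sigmoidal_fit")
}

#' @export
print.sigmoidal_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<sigmoidal_fit> F0 = %.4g, A = %.4g, r_max = %.4g s^-1, tau_half = %.5g s (%s)\n",
              p$F0, p$A, p$r_max, p$tau_half,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Global fit of combined rate constants across monomer concentrations
#'
#' Fits the unseeded kinetic model to normalized traces at several monomer
#' concentrations, with sqrt(kn*k+) and sqrt(k+*k2) constrained to the same
#' value across all concentrations (the only quantities unseeded kinetics
#' identify). The closed form is used where the secondary pathway dominates
#' (kappa/lambda > 10), the moment-ODE integrator otherwise.
#'
#' @param traces normalized traces (each carrying `substrate_conc`) at >= 3
#'   distinct monomer concentrations; replicates may be pre-averaged.
#' @param nc,n2 reaction orders (default 2).
#' @param n_start Latin-hypercube multi-start size (default 10).
#' @param seed multi-start seed (default 1730).
#' @param lower,upper log10 search box for c(sqrt_knkp, sqrt_kpk2).
#' @return object of class `global_fit`: `sqrt_knkp`, `sqrt_kpk2`,
#'   `standard_errors`, `chi2`, `ssr`, `n_curves`, `per_curve_residuals`,
#'   `converged`.
#' @export
fit_global <- function(traces, nc = 2, n2 = 2, n_start = 10,
                       seed = default_fit_seed,
                       lower = c(-2, 2), upper = c(3, 8)) {
  curves <- traces_to_curves(traces)
  m0s <- vapply(curves, `[[`, numeric(1), "m0")
  if (anyNA(m0s)) abort_invalid("every trace needs a substrate concentration")
  if (length(unique(signif(m0s, 8))) < 3L)
    abort_invalid("rank-deficient design: need >= 3 distinct monomer concentrations")
  obj <- function(th) {
    v <- 10^th
    kinetic_ssr(curves, function(cv)
      lk_from_combined(v[1], v[2], cv$m0, nc, n2), nc, n2)
  }
  best <- multistart_fit(obj, lower, upper, n_start = n_start, seed = seed)
  v <- 10^best$par
  model <- lapply(curves, function(cv) {
    lk <- lk_from_combined(v[1], v[2], cv$m0, nc, n2)
    kinetic_curve(cv$t, lk[1], lk[2], nc, n2)
  })
  datl <- lapply(curves, `[[`, "y")
  chi2 <- chi_squared(model, datl, n_params = 2)
  per_curve <- data.frame(
    well = vapply(curves, `[[`, "", "well"),
    m0 = m0s,
    rms = mapply(function(m, d) sqrt(mean((d - m)^2)), model, datl))
  se <- tryCatch(combined_fit_se(curves, v, nc, n2), error = function(e)
    c(sqrt_knkp = NA_real_, sqrt_kpk2 = NA_real_))
  structure(list(sqrt_knkp = unname(v[1]), sqrt_kpk2 = unname(v[2]),
                 standard_errors = se, chi2 = chi2, ssr = best$value,
                 n_curves = length(curves), per_curve_residuals = per_curve,
                 nc = nc, n2 = n2, converged = best$converged),
            class = "global_fit")
}

# Asymptotic standard errors from the numerical Jacobian at the optimum.
combined_fit_se <- function(curves, v, nc, n2) {
  resid_vec <- function(vv) {
    unlist(lapply(curves, function(cv) {
      lk <- lk_from_combined(vv[1], vv[2], cv$m0, nc, n2)
      cv$y - kinetic_curve(cv$t, lk[1], lk[2], nc, n2)
    }))
  }
  r0 <- resid_vec(v)
  J <- sapply(1:2, function(j) {
    h <- v[j] * 1e-4
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    (resid_vec(vp) - resid_vec(vm)) / (2 * h)
  })
  dof <- length(r0) - 2L
  s2 <- sum(r0^2) / dof
  cv <- s2 * solve(crossprod(J))
  c(sqrt_knkp = sqrt(cv[1, 1]), sqrt_kpk2 = sqrt(cv[2, 2]))
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> %d curves: sqrt(kn*k+) = %.4g +/- %.2g M^-1 s^-1, sqrt(k+*k2) = %.4g +/- %.2g, chi2 = %.4g\n",
              x$n_curves, x$sqrt_knkp, x$standard_errors[["sqrt_knkp"]],
              x$sqrt_kpk2, x$standard_errors[["sqrt_kpk2"]], x$chi2))
  invisible(x)
}

# Fit (lambda, kappa) to curves at a single monomer concentration.
fit_single_lk <- function(curves, nc = 2, n2 = 2, seed = default_fit_seed,
                          lower = c(-8, -6), upper = c(-2, -1), n_start = 10) {
  obj <- function(th) {
    lk <- 10^th
    kinetic_ssr(curves, function(cv) lk, nc, n2)
  }
  best <- multistart_fit(obj, lower, upper, n_start = n_start, seed = seed)
  list(lam = unname(10^best$par[1]), kap = unname(10^best$par[2]),
       ssr = best$value, converged = best$converged)
}

# Hypothesis-independent noise estimate from pooled second differences of
# the observed curves (the smooth kinetic trend cancels on a dense grid).
# Used so mechanism hypotheses are ranked against a common sigma.
estimate_noise_sd <- function(curves) {
  pooled <- unlist(lapply(curves, function(cv) diff(cv$y, differences = 2)))
  s <- stats::sd(pooled) / sqrt(6)
  if (!is.finite(s) || s <= 0) 1 else s
}

# Dose levels of an inhibitor series: molar_ratio preferred, else
# inhibitor concentration.
curve_dose <- function(cv) {
  if (!is.na(cv$ratio)) cv$ratio else if (!is.na(cv$dose)) cv$dose else 0
}

#' Constrained single-rate-constant mechanism fits
#'
#' For an inhibitor dose series at fixed monomer concentration, fits each of
#' the three hypotheses in which only one microscopic rate constant responds
#' to the inhibitor: `kn_free` (lambda scales as sqrt(factor)), `k2_free`
#' (kappa scales as sqrt(factor)), `kplus_free` (both scale, since k+ enters
#' both pathways). One multiplicative factor per nonzero dose is fitted
#' (factor = 1 at dose zero); hypotheses are ranked by reduced chi-squared,
#' lowest = supported mechanism.
#'
#' @param traces normalized traces at one monomer concentration with a dose
#'   variable (molar ratio or inhibitor concentration), including dose 0.
#' @param baseline zero-dose kinetics: a [rate_constants()] object, a
#'   `global_fit`, or NULL to fit lambda/kappa from the zero-dose traces.
#' @inheritParams fit_global
#' @return object of class `mechanism_selection`: per-hypothesis results
#'   (`hypothesis`, `dose_factors`, `chi2`, `ssr`) and a `ranking`.
#' @export
fit_constrained_mechanism <- function(traces, baseline = NULL, nc = 2, n2 = 2,
                                      seed = default_fit_seed) {
  curves <- traces_to_curves(traces)
  m0s <- vapply(curves, `[[`, numeric(1), "m0")
  if (length(unique(signif(m0s, 8))) != 1L)
    abort_invalid("mechanism fits need a single monomer concentration")
  m0 <- m0s[1]
  doses <- vapply(curves, curve_dose, numeric(1))
  lev <- sort(unique(doses))
  if (!any(lev == 0)) abort_invalid("missing zero-inhibitor reference traces")
  if (is.null(baseline)) {
    bl <- fit_single_lk(curves[doses == 0], nc, n2, seed = seed)
    lam0 <- bl$lam; kap0 <- bl$kap; n_base <- 2L
  } else if (inherits(baseline, "rate_constants")) {
    lam0 <- compute_lambda(baseline, m0); kap0 <- compute_kappa(baseline, m0)
    n_base <- 0L
  } else if (inherits(baseline, "global_fit")) {
    lk <- lk_from_combined(baseline$sqrt_knkp, baseline$sqrt_kpk2, m0, nc, n2)
    lam0 <- lk[[1]]; kap0 <- lk[[2]]; n_base <- 0L
  } else abort_invalid("`baseline` must be NULL, rate_constants, or global_fit")
  sigma_common <- estimate_noise_sd(curves)
  hyp_lk <- function(hyp, f) {
    s <- sqrt(f)
    switch(hyp,
           kn_free = c(lam0 * s, kap0),
           k2_free = c(lam0, kap0 * s),
           kplus_free = c(lam0 * s, kap0 * s))
  }
  fits <- lapply(c("kn_free", "k2_free", "kplus_free"), function(hyp) {
    factors <- stats::setNames(rep(1, length(lev)), as.character(lev))
    for (d in lev[lev > 0]) {
      cvd <- curves[doses == d]
      o <- stats::optimize(function(lf) {
        lk <- hyp_lk(hyp, exp(lf))
        kinetic_ssr(cvd, function(cv) lk, nc, n2)
      }, interval = c(log(1e-4), log(100)), tol = 1e-10)
      factors[as.character(d)] <- exp(o$minimum)
    }
    model <- lapply(curves, function(cv) {
      lk <- hyp_lk(hyp, factors[as.character(curve_dose(cv))])
      kinetic_curve(cv$t, lk[1], lk[2], nc, n2)
    })
    datl <- lapply(curves, `[[`, "y")
    np <- sum(lev > 0) + n_base
    list(hypothesis = hyp, dose_factors = factors,
         chi2 = chi_squared(model, datl, n_params = np, sigma = sigma_common),
         ssr = sum(unlist(mapply(function(m, d) (d - m)^2, model, datl,
                                 SIMPLIFY = FALSE))))
  })
  names(fits) <- vapply(fits, `[[`, "", "hypothesis")
  chi2s <- vapply(fits, `[[`, numeric(1), "chi2")
  structure(list(fits = fits, chi2 = chi2s,
                 ranking = names(sort(chi2s)),
                 baseline = c(lam = lam0, kap = kap0), m0 = m0),
            class = "mechanism_selection")
}

#' @export
print.mechanism_selection <- function(x, ...) {
  cat("<mechanism_selection> reduced chi2 by hypothesis (lower = supported):\n")
  for (h in x$ranking) cat(sprintf("  %-11s %.4g\n", h, x$chi2[[h]]))
  invisible(x)
}

#' Per-dose fits with both combined rate constants free
#'
#' Fits sqrt(kn*k+) and sqrt(k+*k2) independently at every inhibitor dose of
#' a fixed-monomer series and normalizes them to the zero-dose values
#' (relative combined rate constants, = 1 at dose 0).
#'
#' @inheritParams fit_constrained_mechanism
#' @return data.frame with columns `dose`, `sqrt_knkp`, `sqrt_kpk2`,
#'   `rel_sqrt_knkp`, `rel_sqrt_kpk2`, `ssr`, `n_curves`.
#' @export
fit_combined_free <- function(traces, nc = 2, n2 = 2, seed = default_fit_seed) {
  curves <- traces_to_curves(traces)
  m0s <- vapply(curves, `[[`, numeric(1), "m0")
  if (length(unique(signif(m0s, 8))) != 1L)
    abort_invalid("combined-free dose fits need a single monomer concentration")
  m0 <- m0s[1]
  doses <- vapply(curves, curve_dose, numeric(1))
  lev <- sort(unique(doses))
  if (!any(lev == 0)) abort_invalid("missing zero-inhibitor reference traces")
  rows <- lapply(lev, function(d) {
    f <- fit_single_lk(curves[doses == d], nc, n2, seed = seed)
    data.frame(dose = d,
               sqrt_knkp = f$lam / (sqrt(2) * m0^(nc / 2)),
               sqrt_kpk2 = f$kap / (sqrt(2) * m0^((n2 + 1) / 2)),
               ssr = f$ssr, n_curves = sum(doses == d))
  })
  out <- do.call(rbind, rows)
  out$rel_sqrt_knkp <- out$sqrt_knkp / out$sqrt_knkp[out$dose == 0]
  out$rel_sqrt_kpk2 <- out$sqrt_kpk2 / out$sqrt_kpk2[out$dose == 0]
  out
}

#' Half-time scaling exponent (gamma)
#'
#' Ordinary least squares of log(tau_half) on log(m0); the slope is the
#' gamma exponent diagnostic of the dominant aggregation pathway
#' (about -(n2+1)/2 when secondary nucleation dominates, about -nc/2 for
#' purely primary nucleation).
#'
#' @param halftimes data.frame with columns `m0` (molar) and `tau_half`
#'   (seconds), >= 3 concentrations, all positive.
#' @return object of class `scaling_fit`: `gamma`, `intercept`,
#'   `r_squared`, `halftimes`.
#' @export
fit_halftime_scaling <- function(halftimes) {
  if (!all(c("m0", "tau_half") %in% names(halftimes)))
    abort_invalid("`halftimes` needs columns m0 and tau_half")
  h <- halftimes[stats::complete.cases(halftimes[, c("m0", "tau_half")]), ]
  if (length(unique(h$m0)) < 3L)
    abort_invalid("need >= 3 distinct concentrations for the scaling fit")
  if (any(h$m0 <= 0) || any(h$tau_half <= 0))
    abort_invalid("m0 and tau_half must be positive")
  fit <- stats::lm(log(tau_half) ~ log(m0), data = h)
  structure(list(gamma = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 halftimes = h), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> gamma = %.3f (R^2 = %.4f, %d concentrations)\n",
              x$gamma, x$r_squared, nrow(x$halftimes)))
  invisible(x)
}

#' Inhibitor dependence of tau_half and r_max
#'
#' Summarizes sigmoidal-fit parameters across an inhibitor dose series:
#' tau_half is fitted linearly against inhibitor concentration; r_max with a
#' mono-exponential decay r_max(B) = a * exp(-b * B) + c.
#'
#' @param summary_table data.frame with columns `dose` (inhibitor
#'   concentration, any consistent unit), `tau_half` (s), `r_max` (s^-1);
#'   >= 3 distinct doses.
#' @return list with `tau_linear` (slope, intercept, r_squared) and
#'   `rmax_exponential` (a, b, c, r_squared, converged).
#' @export
summarize_inhibitor_dependence <- function(summary_table) {
  need <- c("dose", "tau_half", "r_max")
  if (!all(need %in% names(summary_table)))
    abort_invalid("`summary_table` needs columns dose, tau_half, r_max")
  st <- summary_table[order(summary_table$dose), ]
  if (length(unique(st$dose)) < 3L)
    abort_invalid("degenerate dose design: need >= 3 distinct doses")
  lf <- stats::lm(tau_half ~ dose, data = st)
  tau_lin <- list(slope = unname(stats::coef(lf)[2]),
                  intercept = unname(stats::coef(lf)[1]),
                  r_squared = suppressWarnings(summary(lf)$r.squared))
  r <- st$r_max; B <- st$dose
  c0 <- max(min(r) - 0.05 * diff(range(r)), 0)
  a0 <- max(r) - c0
  pos <- which(r - c0 > 0)
  b0 <- if (length(pos) >= 2) {
    i1 <- pos[1]; i2 <- pos[length(pos)]
    db <- B[i2] - B[i1]
    if (db > 0) max(log((r[i1] - c0) / (r[i2] - c0)) / db, 1e-12) else 1 / max(B)
  } else 1 / max(B[B > 0])
  env <- data.frame(B = B, r = r)
  fit <- tryCatch(
    stats::nls(r ~ a * exp(-b * B) + c, data = env,
               start = list(a = a0, b = b0, c = c0), algorithm = "port",
               lower = c(a = 1e-15, b = 1e-15, c = 0),
               control = stats::nls.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # deterministic fallback: profile over b on a log grid, linear in (a, c)
    bs <- 10^seq(log10(b0) - 3, log10(b0) + 3, length.out = 61)
    prof <- sapply(bs, function(b) {
      X <- cbind(exp(-b * B), 1)
      cf <- tryCatch(stats::lm.fit(X, r)$coefficients, error = function(e) c(NA, NA))
      if (anyNA(cf)) Inf else sum((r - X %*% cf)^2)
    })
    b_best <- bs[which.min(prof)]
    X <- cbind(exp(-b_best * B), 1)
    cf <- stats::lm.fit(X, r)$coefficients
    pred <- as.numeric(X %*% cf)
    rmax_exp <- list(a = cf[1], b = b_best, c = cf[2],
                     r_squared = 1 - sum((r - pred)^2) / sum((r - mean(r))^2),
                     converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    pred <- stats::predict(fit)
    rmax_exp <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                     r_squared = 1 - sum((r - pred)^2) / sum((r - mean(r))^2),
                     converged = TRUE)
  }
  list(tau_linear = tau_lin, rmax_exponential = rmax_exp)
}

#' Reduced, noise-scaled chi-squared of model curves against data
#'
#' chi2 = SSR / (sigma^2 * (N - p)). When `sigma` is not supplied it is
#' estimated from the pre-transition residuals (points where the model is
#' below 10 percent of its maximum), which are dominated by measurement
#' noise under every fit hypothesis; if too few such points exist (or they
#' are noiseless) sigma falls back to 1, making chi2 the plain reduced SSR.
#'
#' @param model list of numeric vectors (or one vector): fitted curves.
#' @param data matching list of observed curves.
#' @param n_params number of fitted parameters.
#' @param sigma optional known noise SD.
#' @return chi-squared value with attributes `sigma` and `ssr`.
#' @export
chi_squared <- function(model, data, n_params, sigma = NULL) {
  if (is.numeric(model)) model <- list(model)
  if (is.numeric(data)) data <- list(data)
  if (length(model) != length(data))
    abort_invalid("model and data have different numbers of curves")
  for (i in seq_along(model))
    if (length(model[[i]]) != length(data[[i]]))
      abort_invalid(sprintf("curve %d: model and data lengths differ", i))
  N <- sum(lengths(data))
  if (N <= n_params) abort_invalid("fewer data points than parameters")
  res <- mapply(function(m, d) d - m, model, data, SIMPLIFY = FALSE)
  ssr <- sum(unlist(res)^2)
  if (is.null(sigma)) {
    pre <- unlist(mapply(function(m, r) r[m < 0.1 * max(m)], model, res,
                         SIMPLIFY = FALSE))
    sigma <- if (length(pre) >= 8) stats::sd(pre) else 1
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  out <- ssr / (sigma^2 * (N - n_params))
  attr(out, "sigma") <- sigma
  attr(out, "ssr") <- ssr
  out
}
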