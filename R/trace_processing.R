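# Plate-reader trace ingestion, baseline correction, normalization,
# replicate averaging and endpoint extraction.

#' Construct an aggregation trace
#'
#' One well's time series plus assay metadata. Times are seconds, substrate
#' and inhibitor concentrations molar; `molar_ratio` is inhibitor:substrate.
#'
#' @param well_id well label, e.g. "A01".
#' @param times strictly increasing times in seconds (length >= 10).
#' @param signals signal values (arbitrary units), same length as `times`.
#' @param assay `"ThT"` or `"turbidity"`.
#' @param substrate substrate identity (text).
#' @param substrate_conc substrate concentration, molar.
#' @param inhibitor_conc inhibitor concentration, molar (NA if none).
#' @param molar_ratio inhibitor:substrate molar ratio; computed from the
#'   concentrations when both are present.
#' @param replicate_group replicate grouping label.
#' @param inhibitor inhibitor identity (text, optional).
#' @return object of class `agg_trace`.
#' @export
aggregation_trace <- function(well_id, times, signals, assay = c("ThT", "turbidity"),
                              substrate = "", substrate_conc = NA_real_,
                              inhibitor_conc = NA_real_, molar_ratio = NA_real_,
                              replicate_group = "", inhibitor = "") {
  assay <- match.arg(assay)
  if (length(times) != length(signals))
    abort_invalid(sprintf("well %s: times and signals differ in length", well_id))
  if (length(times) < 10L)
    abort_invalid(sprintf("well %s: need at least 10 time points", well_id))
  if (any(diff(times) <= 0))
    abort_invalid(sprintf("well %s: times must be strictly increasing", well_id))
  if (is.na(molar_ratio) && !is.na(inhibitor_conc) && !is.na(substrate_conc) &&
      substrate_conc > 0)
    molar_ratio <- inhibitor_conc / substrate_conc
  structure(list(well_id = as.character(well_id), times = as.numeric(times),
                 signals = as.numeric(signals), assay = assay,
                 substrate = substrate, substrate_conc = substrate_conc,
                 inhibitor = inhibitor, inhibitor_conc = inhibitor_conc,
                 molar_ratio = molar_ratio, replicate_group = replicate_group),
            class = "agg_trace")
}

#' @export
print.agg_trace <- function(x, ...) {
  cat(sprintf("<agg_trace> well %s (%s), %d points over %.3g h\n", x$well_id,
              x$assay, length(x$times), diff(range(x$times)) / 3600))
  cat(sprintf("  substrate %s %.3g uM, molar ratio %s, group %s\n", x$substrate,
              x$substrate_conc * 1e6,
              ifelse(is.na(x$molar_ratio), "-", format(x$molar_ratio)),
              x$replicate_group))
  invisible(x)
}

#' Load a plate CSV and its metadata table into aggregation traces
#'
#' Two CSV dialects are accepted. Wide: a `time_s` column plus one signal
#' column per well. Long: columns `time_s`, `well`, `signal`. The metadata
#' CSV has columns `well`, `assay`, `substrate`, `substrate_conc_uM`,
#' `inhibitor`, `inhibitor_conc_uM`, `molar_ratio`, `replicate_group`.
#' Concentrations are converted from micromolar to molar on ingestion.
#'
#' @param data_table path to the plate CSV (or a data.frame).
#' @param meta_table path to the metadata CSV (or a data.frame).
#' @return list of [aggregation_trace()] objects, one per well, with class
#'   `agg_plate`.
#' @export
load_plate <- function(data_table, meta_table) {
  dat <- if (is.data.frame(data_table)) data_table else
    utils::read.csv(data_table, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- if (is.data.frame(meta_table)) meta_table else
    utils::read.csv(meta_table, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(dat)) abort_load("plate table lacks a `time_s` column")
  need <- c("well", "assay", "substrate", "substrate_conc_uM", "inhibitor_conc_uM",
            "molar_ratio", "replicate_group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort_load(paste("metadata table lacks columns:", paste(miss, collapse = ", ")))
  if (all(c("well", "signal") %in% names(dat))) {      # long dialect
    wells <- unique(dat$well)
    series <- lapply(wells, function(w) {
      d <- dat[dat$well == w, , drop = FALSE]
      d <- d[order(d$time_s), , drop = FALSE]
      list(times = d$time_s, signals = d$signal)
    })
    names(series) <- wells
  } else {                                             # wide dialect
    wells <- setdiff(names(dat), "time_s")
    series <- lapply(wells, function(w) list(times = dat$time_s, signals = dat[[w]]))
    names(series) <- wells
  }
  if (anyDuplicated(meta$well))
    abort_load(paste("duplicated metadata rows for well(s):",
                     paste(unique(meta$well[duplicated(meta$well)]), collapse = ", ")))
  missing_meta <- setdiff(wells, meta$well)
  if (length(missing_meta))
    abort_load(paste("no metadata row for well(s):", paste(missing_meta, collapse = ", ")))
  traces <- lapply(wells, function(w) {
    m <- meta[meta$well == w, , drop = FALSE]
    s <- series[[w]]
    if (anyNA(s$signals))
      abort_load(sprintf("well %s: missing signal values", w))
    if (any(diff(s$times) <= 0))
      abort_load(sprintf("well %s: time column is not strictly increasing", w))
    sub_uM <- suppressWarnings(as.numeric(m$substrate_conc_uM))
    inh_uM <- suppressWarnings(as.numeric(m$inhibitor_conc_uM))
    if (!is.na(m$substrate_conc_uM) && m$substrate_conc_uM != "" && is.na(sub_uM))
      abort_load(sprintf("well %s: cannot parse substrate_conc_uM", w))
    aggregation_trace(
      well_id = w, times = s$times, signals = s$signals,
      assay = m$assay, substrate = m$substrate,
      substrate_conc = uM_to_M(sub_uM),
      inhibitor = if ("inhibitor" %in% names(m)) m$inhibitor else "",
      inhibitor_conc = uM_to_M(inh_uM),
      molar_ratio = suppressWarnings(as.numeric(m$molar_ratio)),
      replicate_group = m$replicate_group)
  })
  names(traces) <- wells
  structure(traces, class = c("agg_plate", "list"))
}

#' Baseline-correct and normalize a trace
#'
#' Subtracts a baseline (mean of up to `baseline_window` pre-transition
#' points, i.e. points before the signal first exceeds 10 percent of its
#' amplitude) and scales so the plateau is 1. With `plateau = "endpoint"`
#' (default) the plateau is the mean of the last `plateau_window` points;
#' with `plateau = "fitted"` both anchors come from a sigmoidal fit
#' (preferable when the trace is truncated before a clean plateau). Wells
#' whose plateau/baseline signal ratio is below `min_fold` are flagged
#' non-aggregating and left unnormalized (raw baseline-corrected signals
#' are kept so endpoint analyses still work).
#'
#' @param trace an [aggregation_trace()].
#' @param baseline_window number of initial points for the baseline (default 5).
#' @param plateau_window number of final points for the plateau (default 10).
#' @param plateau `"endpoint"` or `"fitted"`. In fitted mode both anchors
#'   (baseline F0 and plateau F0 + A) come from the sigmoidal fit, with the
#'   window means as fallback when the fit fails.
#' @param min_fold aggregating-well threshold on plateau/baseline (default 1.2).
#' @return the trace with normalized `signals`, fields `baseline_used`,
#'   `plateau_used`, logical `aggregating`, and class `norm_trace` prepended.
#' @export
baseline_and_normalize <- function(trace, baseline_window = 5, plateau_window = 10,
                                   plateau = c("endpoint", "fitted"),
                                   min_fold = 1.2) {
  plateau <- match.arg(plateau)
  n <- length(trace$signals)
  if (baseline_window + plateau_window > n)
    abort_invalid(sprintf("well %s: windows (%d + %d) exceed trace length %d",
                          trace$well_id, baseline_window, plateau_window, n))
  y <- trace$signals
  plat <- mean(y[seq.int(n - plateau_window + 1L, n)])
  # baseline from pre-transition points only: on a shared plate grid a fast
  # well can enter its transition within the first few cycles, so a blind
  # first-window mean would eat into the lag phase. Pre-transition = before
  # the first crossing of 10% amplitude.
  ylo <- min(y[seq_len(max(3L, baseline_window))])
  pre <- which(cummax(y > ylo + 0.1 * (plat - ylo)) == 0L)
  base <- if (length(pre)) mean(y[utils::head(pre, baseline_window)]) else y[1L]
  if (plateau == "fitted") {
    # both anchors from the sigmoidal fit; best when traces are truncated
    # before a clean plateau, but biased for strongly asymmetric curves
    fit <- tryCatch(fit_sigmoidal(trace, check_flag = FALSE), error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      base <- fit$params$F0
      plat <- fit$params$F0 + fit$params$A
    }
  }
  aggregating <- if (base > 0) (plat / base) >= min_fold else (plat - base) > 0
  out <- trace
  out$baseline_used <- base
  out$plateau_used <- plat
  out$aggregating <- aggregating
  if (aggregating) {
    out$signals <- (y - base) / (plat - base)
  } else {
    out$signals <- y - base               # kept raw for endpoint analyses
  }
  class(out) <- c("norm_trace", class(trace))
  out
}

#' Average replicate traces pointwise
#'
#' @param traces list of normalized traces sharing an identical time grid
#'   and replicate group.
#' @param require_same_group require a common `replicate_group` (default TRUE).
#' @return a trace-like object (class `mean_trace`) with fields `times`,
#'   `signals` (pointwise mean), `sd` (pointwise SD), `n`, and the shared
#'   metadata of the first trace.
#' @export
average_replicates <- function(traces, require_same_group = TRUE) {
  if (!length(traces)) abort_invalid("no traces to average")
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || any(tr$times != t0))
      abort_load(sprintf(
        "well %s: time grid differs from the first replicate; interpolate to a common grid first",
        tr$well_id))
  }
  if (require_same_group) {
    grp <- unique(vapply(traces, `[[`, "", "replicate_group"))
    if (length(grp) > 1L)
      abort_invalid(paste("traces span several replicate groups:",
                          paste(grp, collapse = ", ")))
  }
  sig <- vapply(traces, `[[`, numeric(length(t0)), "signals")
  out <- traces[[1]]
  out$well_id <- paste0("mean(", paste(vapply(traces, `[[`, "", "well_id"),
                                       collapse = ","), ")")
  out$signals <- rowMeans(sig)
  out$sd <- apply(sig, 1, stats::sd)
  out$n <- length(traces)
  class(out) <- unique(c("mean_trace", class(traces[[1]])))
  out
}

#' Endpoint (final) intensity of a trace
#'
#' Mean of the last `window` signal values; for turbidity dose-response the
#' input should be baseline-corrected.
#'
#' @param trace an aggregation trace (raw or normalized).
#' @param window number of final points to average (default 10).
#' @return scalar signal value.
#' @export
final_intensity <- function(trace, window = 10) {
  n <- length(trace$signals)
  if (window > n) abort_invalid("`window` exceeds trace length")
  mean(trace$signals[seq.int(n - window + 1L, n)])
}

# helper: subset a plate by predicate on trace fields
plate_filter <- function(traces, pred) {
  keep <- vapply(traces, pred, logical(1))
  structure(traces[keep], class = c("agg_plate", "list"))
}
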