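# Dose-response analysis of non-fibrillar (turbidity) aggregation
# suppression by chaperones, citrate-synthase / rhodanese style assays.

#' Turbidity dose-response table
#'
#' Computes normalized final aggregation intensities per chaperone:substrate
#' molar ratio. Per experiment block (`replicate_group`): each well's final
#' intensity is taken from the baseline-corrected trace, within-block
#' replicates at the same ratio are averaged, and the block is normalized to
#' its own substrate-alone (ratio 0) mean. Across blocks the per-ratio mean
#' and SD are reported (the "mean +/- SD of n experiments performed in
#' replicates" convention).
#'
#' @param traces turbidity traces (an `agg_plate` or list of traces).
#' @param control_ratio molar ratio identifying the substrate-alone control
#'   wells (default 0).
#' @param window number of final points for [final_intensity()] (default 10).
#' @param baseline_window number of initial points for baseline correction.
#' @return data.frame of class `dose_response` with columns `ratio`, `mean`,
#'   `sd`, `n` (number of experiment blocks), sorted by ratio; the control
#'   row has mean 1 by construction.
#' @export
dose_response <- function(traces, control_ratio = 0, window = 10,
                          baseline_window = 5) {
  if (inherits(traces, "agg_trace")) traces <- list(traces)
  if (!length(traces)) abort_invalid("no traces supplied")
  info <- data.frame(
    block = vapply(traces, `[[`, "", "replicate_group"),
    ratio = vapply(traces, function(tr) tr$molar_ratio, numeric(1)),
    fin = vapply(traces, function(tr) {
      base <- mean(tr$signals[seq_len(min(baseline_window, length(tr$signals)))])
      final_intensity(tr, window = min(window, length(tr$signals))) - base
    }, numeric(1)))
  if (anyNA(info$ratio)) abort_invalid("every trace needs a molar_ratio")
  blocks <- unique(info$block)
  per_block <- lapply(blocks, function(b) {
    d <- info[info$block == b, ]
    ctrl <- d$fin[d$ratio == control_ratio]
    if (!length(ctrl))
      abort_invalid(sprintf("experiment block '%s' has no control wells (ratio %g)",
                            b, control_ratio))
    agg <- stats::aggregate(fin ~ ratio, data = d, FUN = mean)
    agg$norm <- agg$fin / mean(ctrl)
    agg$block <- b
    agg
  })
  all_rows <- do.call(rbind, per_block)
  out <- do.call(rbind, lapply(sort(unique(all_rows$ratio)), function(r) {
    v <- all_rows$norm[all_rows$ratio == r]
    data.frame(ratio = r, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
  }))
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Compare two chaperone dose-response tables
#'
#' Per-ratio difference of means (A - B) with SD propagated in quadrature;
#' ratios where the mean +/- SD intervals of A and B do not overlap are
#' flagged.
#'
#' @param tableA,tableB `dose_response` tables on the same ratio grid.
#' @return data.frame with columns `ratio`, `diff`, `sd`, `flag`.
#' @export
compare_chaperones <- function(tableA, tableB) {
  if (!setequal(tableA$ratio, tableB$ratio))
    abort_invalid("dose-response tables have disjoint ratio grids")
  a <- tableA[order(tableA$ratio), ]
  b <- tableB[order(tableB$ratio), ]
  lo_a <- a$mean - a$sd; hi_a <- a$mean + a$sd
  lo_b <- b$mean - b$sd; hi_b <- b$mean + b$sd
  data.frame(ratio = a$ratio, diff = a$mean - b$mean,
             sd = sqrt(a$sd^2 + b$sd^2),
             flag = (lo_a > hi_b) | (lo_b > hi_a))
}

#' Rescale the molar-ratio axis of a dose-response table
#'
#' Applies a concentration-calibration factor (e.g. a BCA/A280 ratio when
#' chaperone concentrations were re-measured by a colorimetric assay) to the
#' molar ratios; intensities are unchanged.
#'
#' @param table a `dose_response` table.
#' @param factor positive calibration factor.
#' @return the table with `ratio` multiplied by `factor`.
#' @export
rescale_concentrations <- function(table, factor) {
  if (!is_scalar_number(factor) || factor <= 0)
    abort_invalid("`factor` must be a single positive number")
  table$ratio <- table$ratio * factor
  table
}
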