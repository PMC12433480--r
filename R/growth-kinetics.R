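#' Normalize a confluence series to its baseline
#'
#' Divides (default) every confluence value of one well by the value at the
#' first timepoint, so the series starts at exactly 1 and is expressed as
#' fold change over baseline. Division keeps all downstream AUC summaries
#' invariant to the absolute confluence scale of a well; subtraction
#' (baseline set to 0) is available for comparison.
#'
#' @param values numeric vector of confluence measurements (%), ordered by
#'   time; the first element is the baseline.
#' @param mode `"divide"` (fold change, default) or `"subtract"`.
#' @return numeric vector of the same length; first element exactly 1
#'   (`"divide"`) or 0 (`"subtract"`).
#' @examples
#' normalize_to_baseline(c(10, 20, 40))
#' @export
normalize_to_baseline <- function(values, mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  vs_check(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
           "viroscore_bad_series", "confluence values must be finite numbers")
  b <- values[[1]]
  if (mode == "divide") {
    vs_check(b > 0, "viroscore_zero_baseline",
             "baseline confluence is %g; division by a non-positive baseline is undefined", b)
    values / b
  } else {
    values - b
  }
}

#' Trapezoidal area under a curve on the observed grid
#'
#' @param times strictly increasing numeric vector (hours).
#' @param values numeric vector, same length as `times`.
#' @return the trapezoidal integral (units of `values` x hours).
#' @examples
#' trapezoid_auc(c(0, 2, 4), c(1, 2, 4)) # 9
#' @export
trapezoid_auc <- function(times, values) {
  vs_check(length(times) >= 2, "viroscore_too_few_points",
           "AUC needs at least 2 timepoints, got %d", length(times))
  vs_check(length(times) == length(values), "viroscore_length_mismatch",
           "times and values differ in length (%d vs %d)", length(times), length(values))
  vs_check(all(diff(times) > 0), "viroscore_nonmonotone_times",
           "times must be strictly increasing")
  pracma::trapz(times, values)
}

#' Normalize a treated AUC to the untreated condition
#'
#' Ratio of the treated to the untreated mean AUC; 1 means no growth
#' inhibition, values below 1 indicate virus-induced growth suppression.
#'
#' @param auc_treated mean AUC of the treated condition (fold-change x h).
#' @param auc_untreated mean AUC of the matched untreated condition.
#' @return unitless ratio.
#' @export
normalize_to_untreated <- function(auc_treated, auc_untreated) {
  vs_check(is.finite(auc_untreated) && auc_untreated > 0, "viroscore_zero_untreated",
           "untreated AUC is %g; normalization needs a positive untreated AUC", auc_untreated)
  auc_treated / auc_untreated
}

#' Death index: dead-cell density normalized to confluence
#'
#' Pointwise ratio of dead cells per mm^2 to confluence, plus the
#' trapezoidal AUC of that index. Timepoints at which confluence is not
#' positive cannot be normalized and are dropped with a warning.
#'
#' @param times strictly increasing numeric vector (hours).
#' @param dead_per_mm2 non-negative dead-cell densities.
#' @param confluence confluence (%) on the same grid.
#' @return list with `times`, `index` (the pointwise ratio) and `auc`.
#' @export
death_index <- function(times, dead_per_mm2, confluence) {
  vs_check(length(times) == length(dead_per_mm2) && length(times) == length(confluence),
           "viroscore_length_mismatch", "times, dead_per_mm2 and confluence must align")
  vs_check(all(dead_per_mm2 >= 0), "viroscore_bad_series",
           "dead-cell densities must be non-negative")
  keep <- confluence > 0
  if (!all(keep)) {
    warning(sprintf("death_index: dropped %d timepoint(s) with confluence <= 0",
                    sum(!keep)))
  }
  vs_check(sum(keep) >= 2, "viroscore_all_dropped",
           "fewer than 2 timepoints with positive confluence; death index undefined")
  idx <- dead_per_mm2[keep] / confluence[keep]
  list(times = times[keep], index = idx, auc = trapezoid_auc(times[keep], idx))
}

#' Summarize well time series into per-repeat AUC statistics
#'
#' The core growth-kinetics reduction: each well's confluence series is
#' baseline-normalized, integrated by trapezoid over its own observed grid,
#' technical replicate wells are averaged per (cell line, biological repeat,
#' MOI), and each treated mean AUC is normalized to that repeat's untreated
#' mean AUC.
#'
#' @param wells long-format data frame with columns `cell_line`, `moi`,
#'   `bio_repeat`, `replicate`, `time_h`, `confluence_pct` (the schema
#'   emitted by [simulate_confluence()] and read by [read_timeseries_csv()]).
#' @param baseline_mode passed to [normalize_to_baseline()].
#' @return data frame with one row per (cell_line, bio_repeat, moi):
#'   `auc_mean` (fold-change x h, mean of technical wells), `auc_norm`
#'   (treated/untreated ratio; exactly 1 for the untreated condition), and
#'   `n_wells`.
#' @export
summarize_auc <- function(wells, baseline_mode = c("divide", "subtract")) {
  baseline_mode <- match.arg(baseline_mode)
  need <- c("cell_line", "moi", "bio_repeat", "replicate", "time_h", "confluence_pct")
  miss <- setdiff(need, names(wells))
  vs_check(length(miss) == 0, "viroscore_schema",
           "missing column(s): %s", paste(miss, collapse = ", "))

  key <- interaction(wells$cell_line, wells$moi, wells$bio_repeat, wells$replicate,
                     drop = TRUE)
  per_well <- lapply(split(wells, key), function(w) {
    w <- w[order(w$time_h), , drop = FALSE]
    norm <- normalize_to_baseline(w$confluence_pct, baseline_mode)
    data.frame(cell_line = w$cell_line[[1]], moi = w$moi[[1]],
               bio_repeat = w$bio_repeat[[1]], replicate = w$replicate[[1]],
               auc = trapezoid_auc(w$time_h, norm))
  })
  per_well <- do.call(rbind, per_well)

  agg <- aggregate(auc ~ cell_line + bio_repeat + moi, data = per_well, FUN = mean)
  names(agg)[names(agg) == "auc"] <- "auc_mean"
  nrep <- aggregate(auc ~ cell_line + bio_repeat + moi, data = per_well, FUN = length)
  agg$n_wells <- nrep$auc

  out <- lapply(split(agg, interaction(agg$cell_line, agg$bio_repeat, drop = TRUE)),
    function(g) {
      ut <- g$auc_mean[g$moi == 0]
      vs_check(length(ut) == 1, "viroscore_no_untreated",
               "cell line %s, repeat %s: expected exactly one untreated (moi = 0) condition",
               g$cell_line[[1]], g$bio_repeat[[1]])
      g$auc_norm <- vapply(g$auc_mean, normalize_to_untreated, numeric(1),
                           auc_untreated = ut)
      g
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_line, out$bio_repeat, out$moi), ]
}
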