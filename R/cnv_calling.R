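# CNV calling from segments: the +/-0.35 log2 threshold, the
# minimum-consecutive-window rule, the window-size detection limit and the
# variance-based quality gate for failed amplification profiles.

#' Calling configuration
#'
#' @param log2_threshold A segment is called when `|mean_log2|` strictly
#'   exceeds this (default 0.35, i.e. CN above `2 * 2^0.35 ~ 2.55` or below
#'   `2 * 2^-0.35 ~ 1.57`).
#' @param min_windows Minimum windows a called segment must span (default 3
#'   neighboring windows, giving a 3 Mb detection limit at 1 Mb windows).
#' @param quality_cutoff Pairwise read-count variance above which a sample
#'   is flagged as a failed profile (default 0.1; a heuristic at roughly
#'   50x the Poisson floor `2/a` at ~4000-count depth, configurable).
#' @return A `calling_config` list.
#' @export
calling_config <- function(log2_threshold = 0.35, min_windows = 3L,
                           quality_cutoff = 0.1) {
  stop_if_not(log2_threshold > 0, "log2_threshold must be > 0")
  stop_if_not(min_windows >= 1, "min_windows must be >= 1")
  structure(list(log2_threshold = log2_threshold,
                 min_windows = as.integer(min_windows),
                 quality_cutoff = quality_cutoff),
            class = "calling_config")
}

#' Call copy-number variants from a segment set
#'
#' A segment becomes a call iff `|mean_log2| > log2_threshold` (strictly;
#' boundary segments at exactly the threshold are not called) and it spans
#' at least `min_windows` windows. Gains have `mean_log2 > 0`. Adjacent
#' same-direction calls separated by a sub-threshold gap are deliberately
#' not merged: diploid gaps between events are meaningful.
#'
#' @param segments A `segment_set` from [cbs_segment()].
#' @param config A [calling_config()].
#' @return A `cnv_calls` data frame in genome order with columns `chrom`,
#'   `start`, `end`, `direction` ("gain"/"loss"), `mean_log2`,
#'   `cn_estimate` (`2 * 2^mean_log2`), `n_windows`.
#' @export
call_cnvs <- function(segments, config = calling_config()) {
  stop_if_not(inherits(segments, "segment_set") || is.data.frame(segments),
              "segments must be a segment_set")
  keep <- abs(segments$mean_log2) > config$log2_threshold &
    segments$n_windows >= config$min_windows
  calls <- segments[keep, c("chrom", "start", "end", "mean_log2", "n_windows"),
                    drop = FALSE]
  calls <- as.data.frame(calls)
  calls$direction <- ifelse(calls$mean_log2 > 0, "gain", "loss")
  calls$cn_estimate <- 2 * 2^calls$mean_log2
  calls <- calls[, c("chrom", "start", "end", "direction", "mean_log2",
                     "cn_estimate", "n_windows")]
  rownames(calls) <- NULL
  structure(calls, class = c("cnv_calls", "data.frame"))
}

#' Smallest callable CNV for a window size and minimum-window rule
#'
#' @param window_size Window size in bp.
#' @param min_windows Consecutive windows required for a call (default 3).
#' @return `min_windows * window_size` in bp (3 Mb for 1 Mb windows and the
#'   3-window rule; 1.5 Mb for 500 kb windows).
#' @export
detection_limit <- function(window_size, min_windows = 3L) {
  stop_if_not(window_size > 0 && min_windows > 0,
              "window_size and min_windows must be positive")
  min_windows * window_size
}

#' Quality gate on the per-sample read-count variance
#'
#' Failed amplification profiles show per-window read counts so irregular
#' that CNVs would be called across the entire genome; they are detected by
#' the [pairwise_variance()] statistic strictly exceeding
#' `quality_cutoff` (a value exactly at the cutoff passes).
#'
#' @param track A `count_track` (raw counts).
#' @param config A [calling_config()].
#' @return `"usable"` or `"failed"`, with the statistic attached as
#'   attribute `variance`.
#' @export
quality_gate <- function(track, config = calling_config()) {
  v <- pairwise_variance(track)
  status <- if (v > config$quality_cutoff) "failed" else "usable"
  message(sprintf("quality_gate[%s]: variance %.4g (cutoff %.4g) -> %s",
                  if (!is.null(track$spec)) track$spec$sample_id else "?",
                  v, config$quality_cutoff, status))
  structure(status, variance = v)
}
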