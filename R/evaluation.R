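# Evaluation: TP/FP/FN scoring of call sets against a reference karyotype,
# one-way ANOVA of variance statistics across WGA-method groups, and cohort
# summaries.

#' Call-matching configuration
#'
#' @param min_reciprocal_overlap Minimum overlap as a fraction of BOTH the
#'   call and the reference event length (default 0.5, the common
#'   CNV-benchmarking convention).
#' @param breakpoint_tolerance Slack in bp applied to each call endpoint
#'   before computing overlap (default 1e6, i.e. one 1 Mb window).
#' @return A `match_config` list.
#' @export
match_config <- function(min_reciprocal_overlap = 0.5, breakpoint_tolerance = 1e6) {
  stop_if_not(min_reciprocal_overlap > 0 && min_reciprocal_overlap <= 1,
              "min_reciprocal_overlap must lie in (0, 1]")
  stop_if_not(breakpoint_tolerance >= 0, "breakpoint_tolerance must be >= 0")
  structure(list(min_reciprocal_overlap = min_reciprocal_overlap,
                 breakpoint_tolerance = breakpoint_tolerance),
            class = "match_config")
}

#' Match CNV calls against a reference karyotype
#'
#' Greedy one-to-one matching in genome order: a call matches a reference
#' event iff both lie on the same chromosome, agree in direction (gain vs
#' loss relative to the baseline), and their overlap — computed after
#' relaxing the call's endpoints by `breakpoint_tolerance` — is at least
#' `min_reciprocal_overlap` of both the call length and the event length.
#' Each reference event matches at most one call: a single call spanning
#' two events yields one TP and one FN. Unmatched calls are false
#' positives; unmatched reference events are false negatives.
#'
#' @param calls A `cnv_calls` data frame (columns `chrom`, `start`, `end`,
#'   `direction`).
#' @param reference A [karyotype()] (its events must be non-overlapping).
#' @param config A [match_config()].
#' @return An `evaluation_result`: list with data frames `tp` (matched
#'   call/event pairs), `fp`, `fn` and counts `tp_count`, `fp_count`,
#'   `fn_count`.
#' @export
match_calls <- function(calls, reference, config = match_config()) {
  stop_if_not(inherits(reference, "karyotype"), "reference must be a karyotype")
  ev <- reference$events
  ev$direction <- ifelse(ev$copy_number > reference$baseline, "gain", "loss")
  ev$matched <- FALSE
  calls <- as.data.frame(calls)
  chrom_rank <- match(calls$chrom, reference$layout$chrom)
  calls <- calls[order(chrom_rank, calls$start), , drop = FALSE]
  tol <- config$breakpoint_tolerance
  mro <- config$min_reciprocal_overlap

  tp <- list(); fp_rows <- integer(0)
  for (k in seq_len(nrow(calls))) {
    cand <- which(!ev$matched &
                    ev$chrom == calls$chrom[k] &
                    ev$direction == calls$direction[k])
    hit <- NA_integer_
    for (e in cand) {
      ov <- min(calls$end[k] + tol, ev$end[e]) - max(calls$start[k] - tol, ev$start[e])
      len_call <- calls$end[k] - calls$start[k]
      len_ev <- ev$end[e] - ev$start[e]
      if (ov >= mro * len_call && ov >= mro * len_ev) { hit <- e; break }
    }
    if (is.na(hit)) {
      fp_rows <- c(fp_rows, k)
    } else {
      ev$matched[hit] <- TRUE
      tp[[length(tp) + 1L]] <- data.frame(
        chrom = calls$chrom[k],
        call_start = calls$start[k], call_end = calls$end[k],
        ref_start = ev$start[hit], ref_end = ev$end[hit],
        direction = calls$direction[k],
        stringsAsFactors = FALSE)
    }
  }
  tp <- if (length(tp)) do.call(rbind, tp) else
    data.frame(chrom = character(0), call_start = numeric(0), call_end = numeric(0),
               ref_start = numeric(0), ref_end = numeric(0), direction = character(0))
  fp <- calls[fp_rows, , drop = FALSE]
  fn <- ev[!ev$matched, setdiff(names(ev), "matched"), drop = FALSE]
  rownames(tp) <- rownames(fp) <- rownames(fn) <- NULL
  structure(list(tp = tp, fp = fp, fn = fn,
                 tp_count = nrow(tp), fp_count = nrow(fp), fn_count = nrow(fn)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: %d TP, %d FP, %d FN (sensitivity %.3f)\n",
              x$tp_count, x$fp_count, x$fn_count,
              if (x$tp_count + x$fn_count > 0) x$tp_count / (x$tp_count + x$fn_count) else NA))
  invisible(x)
}

#' Classical one-way fixed-effects ANOVA
#'
#' Computed from sums of squares: `F = (SSB / (k-1)) / (SSW / (n-k))`, with
#' the p-value from the F distribution on `(k-1, n-k)` degrees of freedom.
#' When the within-group variance is zero and all group means agree, `F`
#' is defined as 0.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return An `anova_result`: list with `f_stat`, `df_between`, `df_within`,
#'   `p_value`, `group_means`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
#' @export
one_way_anova <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(vapply(groups, length, 1L) >= 2), "each group needs >= 2 values")
  k <- length(groups)
  n <- sum(vapply(groups, length, 1L))
  stop_if_not(n > k, "total n must exceed the number of groups")
  means <- vapply(groups, mean, 1.0)
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, length, 1L) * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  df_b <- k - 1L
  df_w <- n - k
  if (ssw <= 0) {
    f <- if (ssb <= 0) 0 else Inf
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f_stat = f, df_between = df_b, df_within = as.integer(df_w),
                 p_value = p, group_means = means),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Summarize a cohort of pipeline results
#'
#' Builds the per-sample table (status, variance statistic, TP/FP/FN against
#' the reference) and per-method aggregates (mean variance, aggregate
#' sensitivity `TP / (TP + FN)`, total FP), plus a one-way ANOVA of the
#' variance statistic across methods. Failed profiles are listed but
#' excluded from matching, aggregates and the ANOVA.
#'
#' @param results List of `sample_result` objects from [run_pipeline()].
#' @param reference A [karyotype()] to score usable samples against.
#' @param config A [match_config()].
#' @return A `cohort_report`: list with data frames `samples` and `methods`,
#'   and `anova` (an [one_way_anova()] result across methods, `NULL` when
#'   fewer than two methods have >= 2 usable samples).
#' @export
cohort_report <- function(results, reference, config = match_config()) {
  stop_if_not(length(results) >= 1, "no samples")
  rows <- lapply(results, function(res) {
    ev <- if (res$status == "usable") match_calls(res$calls, reference, config) else NULL
    data.frame(sample_id = res$spec$sample_id,
               method = res$spec$method_label,
               n_cells = res$spec$n_cells,
               replicate = res$spec$replicate,
               window_size = res$window_size,
               status = res$status,
               variance = res$variance,
               n_calls = if (res$status == "usable") nrow(res$calls) else 0L,
               tp = if (is.null(ev)) NA_integer_ else ev$tp_count,
               fp = if (is.null(ev)) NA_integer_ else ev$fp_count,
               fn = if (is.null(ev)) NA_integer_ else ev$fn_count,
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  if (!any(samples$status == "usable")) stop("no usable samples", call. = FALSE)
  ok <- samples[samples$status == "usable", , drop = FALSE]
  methods <- do.call(rbind, lapply(split(ok, ok$method), function(g) {
    data.frame(method = g$method[1],
               n_usable = nrow(g),
               n_failed = sum(samples$method == g$method[1]) - nrow(g),
               mean_variance = mean(g$variance),
               tp = sum(g$tp), fp = sum(g$fp), fn = sum(g$fn),
               sensitivity = if (sum(g$tp) + sum(g$fn) > 0)
                 sum(g$tp) / (sum(g$tp) + sum(g$fn)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(methods) <- NULL
  groups <- split(ok$variance, ok$method)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  anova <- if (length(groups) >= 2) one_way_anova(groups) else NULL
  structure(list(samples = samples, methods = methods, anova = anova),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d samples (%d failed), %d methods\n",
              nrow(x$samples), sum(x$samples$status == "failed"), nrow(x$methods)))
  print.data.frame(x$methods)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}
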