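# Circular binary segmentation (CBS) of the per-window log2 ratio track.
#
# Per chromosome, the algorithm searches all circular arcs of the value
# sequence for the arc maximizing the pooled-variance two-sample
# t-statistic between the arc and its complement, assesses the split with a
# seeded permutation test, splits when significant and recurses into the
# children. Adjacent segments that are not significantly different are
# merged afterwards.

#' Segmentation configuration
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Permutations per split test (default 1000; >= 100).
#' @param min_seg_windows Minimum windows in an arc and in its complement
#'   (default 2).
#' @param seed Integer seed for the permutation streams.
#' @param merge_alpha Significance level below which adjacent segments are
#'   kept separate during post-hoc merging (default 0.05).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(alpha = 0.01, n_perm = 1000L, min_seg_windows = 2L,
                                seed = 1L, merge_alpha = 0.05) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  stop_if_not(n_perm >= 100, "n_perm must be >= 100")
  stop_if_not(min_seg_windows >= 1, "min_seg_windows must be >= 1")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_seg_windows = as.integer(min_seg_windows),
                 seed = as.integer(seed), merge_alpha = merge_alpha),
            class = "segmentation_config")
}

#' Maximal-t arc of a value sequence
#'
#' Scans every circular arc `(i, j)` (0-based half-open window indices; the
#' complement of an interior arc wraps around) whose length and complement
#' both span at least `min_seg_windows` windows, and returns the arc
#' maximizing the absolute pooled-variance two-sample t-statistic between
#' the values inside and outside the arc. Maxima are ordered by `|t|`, then
#' by signed `t` (the elevated side of a tied boundary split wins), then by
#' smallest `i`, then smallest `j`. When the pooled variance is zero the
#' statistic is 0 for equal means and `+/-1e12` otherwise.
#'
#' @param values Numeric sequence (a chromosome's log2 ratios, genome
#'   order, no missing values).
#' @param min_seg_windows Minimum arc/complement width (default 2).
#' @return List with `i`, `j` (0-based half-open) and `t`.
#' @examples
#' max_t_arc(c(rep(0, 20), rep(1, 10), rep(0, 20)))  # arc (20, 30)
#' @export
max_t_arc <- function(values, min_seg_windows = 2L) {
  values <- as.numeric(values)
  stop_if_not(all(is.finite(values)), "values must be finite")
  stop_if_not(length(values) >= 2 * min_seg_windows,
              "sequence too short for min_seg_windows")
  r <- .cpp_max_t_arc(values, as.integer(min_seg_windows))
  list(i = as.integer(r[1]), j = as.integer(r[2]), t = r[3])
}

#' Permutation significance of a candidate split
#'
#' Estimates `p = (1 + #{permutations whose max |t| >= observed}) /
#' (1 + n_perm)` by seeded random shuffles of the values, each re-scanned
#' for its own maximal arc. The add-one estimator avoids p = 0.
#'
#' @param values Numeric sequence, as in [max_t_arc()].
#' @param arc Result of [max_t_arc()] on `values` (recomputed when `NULL`).
#' @param config A [segmentation_config()].
#' @param seed Seed for the permutation stream (defaults to `config$seed`).
#' @param early_stop Stop permuting once enough exceedances guarantee
#'   `p >= alpha`; the exact add-one estimator is returned when `FALSE`
#'   (default). [cbs_segment()] enables it internally for speed.
#' @return p-value in (0, 1].
#' @export
split_significance <- function(values, arc = NULL, config = segmentation_config(),
                               seed = config$seed, early_stop = FALSE) {
  values <- as.numeric(values)
  if (is.null(arc)) arc <- max_t_arc(values, config$min_seg_windows)
  .cpp_perm_pvalue(values, arc$t, config$min_seg_windows, config$n_perm,
                   as.integer(seed), config$alpha, isTRUE(early_stop))
}

# Recursive splitting over vals[(lo+1):hi] (0-based half-open [lo, hi)).
# Children derive their own seeds from (seed, depth, child index, cut), so
# the recursion is deterministic regardless of evaluation order.
seg_recurse <- function(vals, lo, hi, config, seed, depth = 0L) {
  n <- hi - lo
  if (n < 2 * config$min_seg_windows) return(list(c(lo, hi)))
  v <- vals[(lo + 1):hi]
  arc <- max_t_arc(v, config$min_seg_windows)
  if (abs(arc$t) == 0) return(list(c(lo, hi)))
  p <- split_significance(v, arc, config, seed = seed, early_stop = TRUE)
  if (p >= config$alpha) return(list(c(lo, hi)))
  cuts <- unique(c(0L, arc$i, arc$j, n))
  out <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    child_seed <- derive_seed(seed, depth + 1L, k, cuts[k])
    out <- c(out, seg_recurse(vals, lo + cuts[k], lo + cuts[k + 1], config,
                              child_seed, depth + 1L))
  }
  out
}

# Pooled two-sample t-test p-value (merging criterion). df <= 0 (e.g. two
# single-window segments) cannot be tested and merges (p = 1).
pooled_t_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  if (df <= 0) return(1)
  m1 <- mean(x); m2 <- mean(y)
  sp2 <- (sum((x - m1)^2) + sum((y - m2)^2)) / df
  if (sp2 <= 0) return(if (abs(m1 - m2) <= 1e-12) 1 else 0)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tt), df)
}

merge_adjacent <- function(v, segs, merge_alpha) {
  repeat {
    if (length(segs) < 2) return(segs)
    merged <- FALSE
    for (k in seq_len(length(segs) - 1L)) {
      a <- segs[[k]]; b <- segs[[k + 1]]
      p <- pooled_t_pvalue(v[(a[1] + 1):a[2]], v[(b[1] + 1):b[2]])
      if (p >= merge_alpha) {
        segs[[k]] <- c(a[1], b[2])
        segs[[k + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) return(segs)
  }
}

#' Segment a copy-number track by circular binary segmentation
#'
#' Masked windows (blacklisted or short terminal windows) are removed
#' before segmentation; segment bp coordinates are re-expanded afterwards,
#' a segment spanning from the start of its first usable window to the end
#' of its last. Each chromosome is segmented independently: recursive
#' max-|t| arc search with permutation significance, followed by merging of
#' adjacent segments whose pooled two-sample t-test p-value is at least
#' `merge_alpha`.
#'
#' @param track A `cn_track` from [estimate_cn()].
#' @param config A [segmentation_config()].
#' @return A `segment_set` data frame with columns `chrom`, `start_idx`,
#'   `end_idx` (chromosome-local half-open indices into the usable-window
#'   sequence), `start`, `end` (bp), `n_windows`, `mean_log2`; the
#'   configuration is attached as attribute `config`.
#' @export
cbs_segment <- function(track, config = segmentation_config()) {
  stop_if_not(inherits(track, "cn_track"), "track must be a cn_track")
  stop_if_not(any(track$usable), "track has no usable windows")
  grid <- track$grid
  layout <- attr(grid, "layout")
  rows <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]
    idx <- which(grid$chrom == ch & track$usable & !is.na(track$log2ratio))
    if (!length(idx)) {
      warning("chromosome ", ch, " has no usable windows; skipped")
      next
    }
    v <- track$log2ratio[idx]
    n <- length(v)
    if (n < 2 * config$min_seg_windows) {
      segs <- list(c(0L, n))
    } else {
      segs <- seg_recurse(v, 0L, n, config, derive_seed(config$seed, ch, 0L, 0L))
      segs <- merge_adjacent(v, segs, config$merge_alpha)
    }
    for (s in segs) {
      lo <- s[1]; hi <- s[2]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_idx = lo, end_idx = hi,
        start = grid$start[idx[lo + 1]], end = grid$end[idx[hi]],
        n_windows = hi - lo,
        mean_log2 = mean(v[(lo + 1):hi]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, config = config, class = c("segment_set", "data.frame"))
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments on %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(x, ...)
  invisible(x)
}
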