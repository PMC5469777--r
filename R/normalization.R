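# Normalization: GC/mappability correction, median normalization, copy
# number estimation and the per-sample read-count variance statistic.
#
# All medians here use the lower-median convention (for an even number of
# values, the smaller central order statistic), so every operation is fully
# deterministic and the window attaining the median maps to ratio exactly 1.

# One-dimensional stratified-median scaling factor, smoothed along the
# covariate: bin medians (over usable windows) divided by the global median
# give per-bin factors; factors are then linearly interpolated between the
# bins' median covariate values, so a smooth trend is removed without
# leaving a within-bin residual. Bins with fewer than min_n usable windows
# are dropped from the node set (their windows fall back on interpolation
# from the populated neighbors); if no bin is populated every bin becomes a
# node.
stratum_median_factor <- function(x, covariate, usable, bin_width, min_n) {
  b <- pmin(floor(covariate / bin_width), floor(1 / bin_width) - 1)
  global_med <- median_low(x[usable])
  meds <- tapply(x[usable], b[usable], median_low)
  nodes_x <- tapply(covariate[usable], b[usable], median_low)
  counts <- tapply(x[usable], b[usable], length)
  pop <- counts >= min_n
  if (!any(pop)) pop <- rep(TRUE, length(pop))
  fx <- as.numeric(nodes_x)[pop]
  fy <- as.numeric(meds)[pop] / global_med
  if (length(fx) == 1) return(rep(fy, length(x)))
  o <- order(fx)
  fx <- fx[o]; fy <- fy[o]
  f <- stats::approx(fx, fy, xout = covariate, rule = 2, ties = "ordered")$y
  # linear extrapolation beyond the outermost nodes, continuing the end slopes
  m <- length(fx)
  lo <- covariate < fx[1]
  f[lo] <- fy[1] + (covariate[lo] - fx[1]) * (fy[2] - fy[1]) / (fx[2] - fx[1])
  hi <- covariate > fx[m]
  f[hi] <- fy[m] + (covariate[hi] - fx[m]) * (fy[m] - fy[m - 1]) / (fx[m] - fx[m - 1])
  f
}

#' Correct per-window counts for GC-content and mappability bias
#'
#' Two sequential stratified-median corrections: windows are grouped into
#' GC bins of width `gc_bin_width`, each bin's factor is its median count
#' divided by the global median over usable windows, and the factors are
#' linearly interpolated between the bins' median GC values so the removed
#' trend is smooth; the same procedure is then applied along mappability
#' with `map_bin_width` bins. Bins with fewer than
#' `min_windows_per_stratum` usable windows do not form interpolation
#' nodes and inherit from their populated neighbors. Blacklisted and short
#' terminal windows are excluded from factor estimation; their counts pass
#' through unchanged and remain masked downstream.
#'
#' @param track A `count_track`.
#' @param gc_bin_width,map_bin_width Stratum widths (defaults 0.05 and 0.1).
#' @param min_windows_per_stratum Minimum usable windows for a stratum to
#'   serve as an interpolation node (default 20).
#' @return A `count_track` with real-valued corrected counts.
#' @export
correct_gc_mappability <- function(track, gc_bin_width = 0.05, map_bin_width = 0.1,
                                   min_windows_per_stratum = 20) {
  stop_if_not(inherits(track, "count_track"), "track must be a count_track")
  grid <- track$grid
  usable <- usable_windows(grid)
  stop_if_not(any(usable), "all windows are masked")
  x <- track$counts
  stop_if_not(median_low(x[usable]) > 0, "zero global median count; track unusable")

  f_gc <- stratum_median_factor(x, grid$gc, usable, gc_bin_width,
                                min_windows_per_stratum)
  x1 <- x / pmax(f_gc, 1e-9)
  f_map <- stratum_median_factor(x1, grid$mappability, usable, map_bin_width,
                                 min_windows_per_stratum)
  corrected <- x1 / pmax(f_map, 1e-9)
  corrected[!usable] <- x[!usable]  # masked windows pass through untouched
  out <- track
  out$counts <- corrected
  out$total_reads <- sum(corrected)
  out
}

#' Median-normalize a count track
#'
#' Divides each window's (corrected) count by `a`, the median count across
#' all usable windows. Since chromosomal aberrations are assumed rare, `a`
#' estimates the expected diploid count, and the ratios measure deviation
#' from diploidy.
#'
#' @param track A `count_track` (typically after [correct_gc_mappability()]).
#' @return A `normalized_track`: list with `grid`, per-window `ratios`
#'   (`NA` where masked), the normalizer `a`, `n_usable` and the logical
#'   `usable` mask.
#' @export
median_normalize <- function(track) {
  stop_if_not(inherits(track, "count_track"), "track must be a count_track")
  usable <- usable_windows(track$grid)
  stop_if_not(any(usable), "no usable windows")
  a <- median_low(track$counts[usable])
  if (!is.finite(a) || a <= 0)
    stop("median count is zero: degenerate track, sample unusable", call. = FALSE)
  ratios <- track$counts / a
  ratios[!usable] <- NA_real_
  structure(list(grid = track$grid, ratios = ratios, a = a,
                 n_usable = sum(usable), usable = usable, spec = track$spec),
            class = "normalized_track")
}

#' Copy-number estimates from a normalized track
#'
#' `CN = 2 * ratio` and `log2ratio = log2(CN / 2) = log2(ratio)`. A ratio of
#' zero maps to the configurable log2 floor instead of `-Inf`.
#'
#' @param norm A `normalized_track`.
#' @param log2_floor Floor for the log2 ratio of zero-count windows
#'   (default -4).
#' @return A `cn_track`: list with `grid`, `cn`, `log2ratio`, `usable`.
#' @export
estimate_cn <- function(norm, log2_floor = -4) {
  stop_if_not(inherits(norm, "normalized_track"), "norm must be a normalized_track")
  cn <- 2 * norm$ratios
  l2 <- log2(norm$ratios)
  l2[!is.na(l2) & l2 < log2_floor] <- log2_floor
  structure(list(grid = norm$grid, cn = cn, log2ratio = l2,
                 usable = norm$usable, spec = norm$spec),
            class = "cn_track")
}

#' @export
print.cn_track <- function(x, ...) {
  cat(sprintf("cn_track: %d windows (%d usable), median CN %.3f\n",
              length(x$cn), sum(x$usable),
              stats::median(x$cn[x$usable], na.rm = TRUE)))
  invisible(x)
}

#' Average read-count variance between consecutive windows
#'
#' The per-sample quality statistic
#' \deqn{\sum_{i=1}^{N-1} ((x_i/a) - (x_{i+1}/a))^2 / N}
#' where \eqn{x_i} is the read count in window \eqn{i}, \eqn{a} the median
#' count across all usable windows and \eqn{N} the number of usable windows.
#' Scaling by `a` normalizes for the total number of reads sequenced, so
#' the statistic is invariant under joint rescaling of all counts. Pairs
#' are formed between consecutive usable windows; masked windows are
#' skipped (the pair is formed across them) and pairs never straddle a
#' chromosome boundary.
#'
#' @param track A `count_track`.
#' @param across_chromosomes If `TRUE`, also pair the last window of a
#'   chromosome with the first of the next (default `FALSE`).
#' @return A single non-negative number.
#' @examples
#' g <- build_window_grid(genome_layout("1", 3e6), 1e6)
#' t <- count_track(g, c(100, 200, 100), sample_spec("demo"))
#' pairwise_variance(t)  # ((1-2)^2 + (2-1)^2) / 3 = 2/3
#' @export
pairwise_variance <- function(track, across_chromosomes = FALSE) {
  stop_if_not(inherits(track, "count_track"), "track must be a count_track")
  usable <- usable_windows(track$grid)
  n <- sum(usable)
  stop_if_not(n >= 2, "need at least 2 usable windows")
  a <- median_low(track$counts[usable])
  stop_if_not(is.finite(a) && a > 0, "median count must be positive")
  r <- track$counts[usable] / a
  if (across_chromosomes) {
    ss <- sum(diff(r)^2)
  } else {
    chrom <- track$grid$chrom[usable]
    ss <- sum(unlist(lapply(split(r, factor(chrom, levels = unique(chrom))),
                            function(v) diff(v)^2)))
  }
  ss / n
}
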