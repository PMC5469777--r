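# Genome layout, window grids, annotation and the built-in reference
# karyotype fixture.
#
# Coordinates are 0-based half-open (BED convention) throughout. A genome
# layout fixes the chromosome order, which in turn defines the genome-wide
# window ordering used by every downstream track.

#' Construct a genome layout
#'
#' @param chrom Character vector of unique chromosome names, in the order
#'   that defines genome-wide window ordering.
#' @param length Positive integer vector of chromosome lengths in bp.
#' @return A `genome_layout` data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("1", "2"), c(5e6, 3e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  stop_if_not(base::length(chrom) == base::length(length) && base::length(chrom) > 0,
              "chrom and length must be non-empty vectors of equal length")
  stop_if_not(!anyDuplicated(chrom), "chromosome names must be unique")
  stop_if_not(all(is.finite(length) & length > 0), "chromosome lengths must be > 0")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Tile a genome layout into equal-size windows
#'
#' Divides every chromosome into consecutive windows of `window_size` bp.
#' The terminal window of a chromosome is truncated at the chromosome end
#' and may therefore be shorter; windows tile each chromosome without gaps
#' or overlaps, and the total window count is
#' `sum(ceiling(length / window_size))`.
#'
#' Windows carry default annotation (`gc = 0.4`, `mappability = 1`,
#' `blacklisted = FALSE`) until [annotate_windows()] is applied.
#'
#' @param layout A [genome_layout()].
#' @param window_size Window size in bp (> 0); typically 1e6 or 5e5.
#' @return A `window_grid` data frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `blacklisted`, plus attributes `window_size` and
#'   `layout`.
#' @examples
#' grid <- build_window_grid(genome_layout("1", 2.5e6), 1e6)
#' nrow(grid)  # 3 windows, last one truncated to [2e6, 2.5e6)
#' @export
build_window_grid <- function(layout, window_size) {
  stop_if_not(inherits(layout, "genome_layout"), "layout must be a genome_layout")
  stop_if_not(is.numeric(window_size) && length(window_size) == 1 && window_size > 0,
              "window_size must be a single positive number")
  pieces <- lapply(seq_len(nrow(layout)), function(k) {
    len <- layout$length[k]
    starts <- seq(0, by = window_size, length.out = ceiling(len / window_size))
    data.frame(chrom = layout$chrom[k],
               start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  win$gc <- 0.4
  win$mappability <- 1.0
  win$blacklisted <- FALSE
  rownames(win) <- NULL
  structure(win, window_size = window_size, layout = layout,
            class = c("window_grid", "data.frame"))
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %s bp over %d chromosomes\n",
              nrow(x), format(attr(x, "window_size"), big.mark = ","),
              nrow(attr(x, "layout"))))
  cat(sprintf("  blacklisted: %d; usable: %d\n",
              sum(x$blacklisted), sum(usable_windows(x))))
  invisible(x)
}

#' Number of windows in a grid
#' @param grid A `window_grid`.
#' @return Integer window count.
#' @export
n_windows <- function(grid) nrow(grid)

#' Usable-window mask
#'
#' A window is usable when it is not blacklisted and at least half a window
#' long (terminal truncated windows shorter than `window_size / 2` carry
#' counts that are not comparable to full windows and are excluded from
#' medians, the variance statistic and segmentation).
#'
#' @param grid A `window_grid`.
#' @return Logical vector of length `n_windows(grid)`.
#' @export
usable_windows <- function(grid) {
  !grid$blacklisted & (grid$end - grid$start) >= attr(grid, "window_size") / 2
}

# Merge possibly-overlapping intervals (two-column matrix start/end) into a
# disjoint union, per chromosome caller's responsibility.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- me <- numeric(0)
  for (k in seq_along(start)) {
    if (length(ms) && start[k] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[k])
    } else {
      ms <- c(ms, start[k]); me <- c(me, end[k])
    }
  }
  cbind(ms, me)
}

#' Annotate a window grid with GC, mappability and a blacklist
#'
#' Attaches per-window GC and mappability fractions and flags windows
#' overlapping blacklist regions. Blacklist intervals are merged into a
#' disjoint union first; a window is blacklisted when the union covers at
#' least `blacklist_overlap_fraction` of the window's length.
#'
#' @param grid A `window_grid`.
#' @param gc Optional numeric vector of GC fractions, length `n_windows(grid)`.
#' @param mappability Optional numeric vector of mappability fractions, same
#'   length.
#' @param blacklist Optional data frame with columns `chrom`, `start`, `end`
#'   (BED semantics) of regions to exclude.
#' @param blacklist_overlap_fraction Minimum covered fraction of a window for
#'   it to be flagged (default 0.5: a majority-covered window is unreliable).
#' @return The annotated `window_grid`.
#' @export
annotate_windows <- function(grid, gc = NULL, mappability = NULL, blacklist = NULL,
                             blacklist_overlap_fraction = 0.5) {
  stop_if_not(inherits(grid, "window_grid"), "grid must be a window_grid")
  n <- nrow(grid)
  if (!is.null(gc)) {
    stop_if_not(length(gc) == n, sprintf("gc track length %d != %d windows", length(gc), n))
    stop_if_not(all(gc >= 0 & gc <= 1), "gc fractions must lie in [0, 1]")
    grid$gc <- as.numeric(gc)
  }
  if (!is.null(mappability)) {
    stop_if_not(length(mappability) == n,
                sprintf("mappability track length %d != %d windows", length(mappability), n))
    stop_if_not(all(mappability >= 0 & mappability <= 1),
                "mappability fractions must lie in [0, 1]")
    grid$mappability <- as.numeric(mappability)
  }
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    stop_if_not(all(blacklist$start < blacklist$end),
                "malformed blacklist interval (start >= end)")
    overlap <- numeric(n)
    for (ch in unique(blacklist$chrom)) {
      sel <- blacklist$chrom == ch
      iv <- merge_intervals(blacklist$start[sel], blacklist$end[sel])
      wsel <- which(grid$chrom == ch)
      if (!length(wsel)) next
      for (k in seq_len(nrow(iv))) {
        ov <- pmax(0, pmin(grid$end[wsel], iv[k, 2]) - pmax(grid$start[wsel], iv[k, 1]))
        overlap[wsel] <- overlap[wsel] + ov
      }
    }
    frac <- overlap / (grid$end - grid$start)
    grid$blacklisted <- frac >= blacklist_overlap_fraction
  }
  grid
}

#' Construct a reference karyotype
#'
#' A karyotype is a diploid baseline plus a set of non-overlapping copy-number
#' events (`copy_number != baseline`).
#'
#' @param layout A [genome_layout()].
#' @param events Data frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (non-negative integers; never equal to `baseline`).
#' @param baseline Baseline copy number (default 2).
#' @return A `karyotype` object.
#' @export
karyotype <- function(layout, events, baseline = 2) {
  stop_if_not(inherits(layout, "genome_layout"), "layout must be a genome_layout")
  events <- as.data.frame(events)
  stop_if_not(all(c("chrom", "start", "end", "copy_number") %in% names(events)),
              "events needs columns chrom, start, end, copy_number")
  stop_if_not(all(events$start < events$end), "event start must be < end")
  stop_if_not(all(events$copy_number >= 0), "copy_number must be non-negative")
  stop_if_not(all(events$copy_number != baseline),
              "events must differ from the baseline copy number")
  stop_if_not(all(events$chrom %in% layout$chrom),
              "event chromosome not present in layout")
  len <- stats::setNames(layout$length, layout$chrom)
  stop_if_not(all(events$end <= len[events$chrom]),
              "event extends beyond its chromosome")
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping events on chromosome ", ch, call. = FALSE)
  }
  # genome order
  events <- events[order(match(events$chrom, layout$chrom), events$start), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(layout = layout, events = events, baseline = baseline),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("karyotype: baseline CN %d, %d events on %d chromosomes\n",
              x$baseline, nrow(x$events), nrow(x$layout)))
  print(x$events)
  invisible(x)
}

#' Built-in reference karyotype of a Loucy-like cell line
#'
#' A synthetic genome layout with round coordinates carrying the reference
#' aneuploidies and CNVs (all >= 3 Mb) of the Loucy lymphoblastoid cell line:
#' on chromosome 5 two deletions of 6 Mb and 36.5 Mb separated by a 2.5 Mb
#' diploid gap plus a 30 Mb deletion; a 60 Mb deletion on chromosome 6; a
#' 3 Mb deletion near the start of chromosome 12; a 26 Mb duplication (CN 3)
#' on chromosome 13; deletions of 16 Mb and 3 Mb on chromosome 16; and loss
#' of the entire X chromosome. Chromosomes "2" and "7" are copy-neutral.
#' Cytoband-accurate placement is irrelevant to the read-depth computation,
#' so events sit at round coordinates.
#'
#' @param scale Positive shrink factor; all coordinates are divided by it
#'   (e.g. `scale = 10` yields a 10x smaller genome for fast tests).
#' @return A [karyotype()] object.
#' @examples
#' k <- loucy_fixture()
#' subset(k$events, chrom == "13")$end - subset(k$events, chrom == "13")$start
#' @export
loucy_fixture <- function(scale = 1) {
  stop_if_not(is.numeric(scale) && length(scale) == 1 && scale > 0,
              "scale must be a single positive number")
  layout <- genome_layout(
    chrom  = c("2",    "5",    "6",    "7",    "12",   "13",   "16",  "X"),
    length = c(240e6,  180e6,  170e6,  160e6,  130e6,  115e6,  90e6,  155e6) / scale)
  ev <- data.frame(
    chrom       = c("5",    "5",     "5",    "6",    "12",  "13",   "16",  "16",  "X"),
    start       = c(85e6,   93.5e6,  145e6,  105e6,  2e6,   85e6,   0,     84e6,  0) / scale,
    end         = c(91e6,   130e6,   175e6,  165e6,  5e6,   111e6,  16e6,  87e6,  155e6) / scale,
    copy_number = c(1L,     1L,      1L,     1L,     1L,    3L,     1L,    1L,    1L),
    stringsAsFactors = FALSE)
  karyotype(layout, ev, baseline = 2)
}

#' Length-weighted copy number of each window under a karyotype
#'
#' @param kar A [karyotype()].
#' @param grid A `window_grid` built on the same layout.
#' @return Numeric vector: for each window, the average copy number over its
#'   bases (fractional where an event boundary falls inside a window).
#' @export
window_cn <- function(kar, grid) {
  stop_if_not(inherits(kar, "karyotype") && inherits(grid, "window_grid"),
              "window_cn needs a karyotype and a window_grid")
  stop_if_not(identical(attr(grid, "layout")$chrom, kar$layout$chrom),
              "grid and karyotype layouts differ")
  cn <- rep(as.numeric(kar$baseline), nrow(grid))
  ev <- kar$events
  for (k in seq_len(nrow(ev))) {
    wsel <- which(grid$chrom == ev$chrom[k])
    if (!length(wsel)) next
    ov <- pmax(0, pmin(grid$end[wsel], ev$end[k]) - pmax(grid$start[wsel], ev$start[k]))
    frac <- ov / (grid$end[wsel] - grid$start[wsel])
    cn[wsel] <- cn[wsel] + frac * (ev$copy_number[k] - kar$baseline)
  }
  cn
}
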