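# Pipeline composition: quality gate -> GC/mappability correction -> median
# normalization -> CN estimation -> CBS -> threshold calling, plus the
# end-to-end demo cohort and the line-profile plot.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. The same window size must be used
#' for every sample within a comparison.
#'
#' @param window_size Window size in bp (default 1e6).
#' @param segmentation A [segmentation_config()].
#' @param calling A [calling_config()].
#' @param matching A [match_config()]; its default breakpoint tolerance is
#'   set to one window.
#' @param seed Master seed; the segmentation seed is derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_size = 1e6,
                            segmentation = NULL,
                            calling = calling_config(),
                            matching = NULL,
                            seed = 1L) {
  stop_if_not(window_size > 0, "window_size must be > 0")
  if (is.null(segmentation))
    segmentation <- segmentation_config(seed = derive_seed(seed, 101L))
  if (is.null(matching))
    matching <- match_config(breakpoint_tolerance = window_size)
  structure(list(window_size = window_size, segmentation = segmentation,
                 calling = calling, matching = matching, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full per-sample pipeline
#'
#' Applies, in order: the variance quality gate, GC/mappability correction,
#' median normalization, copy-number estimation, circular binary
#' segmentation and threshold calling. Failed profiles carry no calls.
#'
#' @param counts A `count_track` binned at `config$window_size`.
#' @param config A [pipeline_config()].
#' @return A `sample_result`: list with `spec`, `window_size`, `status`
#'   ("usable"/"failed"), `variance`, and for usable samples `norm`, `cn`,
#'   `segments`, `calls`.
#' @export
run_pipeline <- function(counts, config = pipeline_config()) {
  stop_if_not(inherits(counts, "count_track"), "counts must be a count_track")
  stop_if_not(isTRUE(all.equal(attr(counts$grid, "window_size"), config$window_size)),
              "count track window size differs from config$window_size")
  gate <- suppressMessages(quality_gate(counts, config$calling))
  variance <- attr(gate, "variance")
  empty_calls <- structure(
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               direction = character(0), mean_log2 = numeric(0),
               cn_estimate = numeric(0), n_windows = integer(0)),
    class = c("cnv_calls", "data.frame"))
  res <- list(spec = counts$spec, window_size = config$window_size,
              status = as.character(gate), variance = variance,
              config = config, calls = empty_calls)
  if (identical(as.character(gate), "failed")) {
    class(res) <- "sample_result"
    return(res)
  }
  corrected <- correct_gc_mappability(counts)
  norm <- median_normalize(corrected)
  cn <- estimate_cn(norm)
  segments <- cbs_segment(cn, config$segmentation)
  res$norm <- norm
  res$cn <- cn
  res$segments <- segments
  res$calls <- call_cnvs(segments, config$calling)
  class(res) <- "sample_result"
  res
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("sample_result '%s' (%s bp windows): %s, variance %.4g, %d calls\n",
              x$spec$sample_id, format(x$window_size, big.mark = ","),
              x$status, x$variance, nrow(x$calls)))
  invisible(x)
}

#' Simulate and analyze a full study cohort
#'
#' Simulates the study design (four WGA methods x \{1, 3, 5\} input cells x
#' triplicates, plus one bias-free "bulk" sample), runs the pipeline at each
#' window size, evaluates every usable sample against the reference
#' karyotype and writes the per-sample and per-method reports, the
#' method-level ANOVA and the bulk line profiles to `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param scale Shrink factor of the genome fixture (see [loucy_fixture()]).
#' @param window_sizes Window sizes in bp (default `c(1e6, 5e5)`).
#' @param design Cohort design (see [default_cohort_design()]).
#' @param depth,read_length Sequencing parameters (defaults 0.3x, 75 bp).
#' @param seed Master seed for the whole demo.
#' @param n_perm,alpha Segmentation parameters (defaults 1000, 0.01).
#' @param plot_format File extension for the bulk line profiles ("png" or
#'   "pdf"; `NULL` disables plotting).
#' @return Invisibly, a list of [cohort_report()] objects, one per window
#'   size, named by window size.
#' @export
run_demo <- function(out_dir, scale = 1, window_sizes = c(1e6, 5e5),
                     design = default_cohort_design(), depth = 0.3,
                     read_length = 75, seed = 1L, n_perm = 1000L,
                     alpha = 0.01, plot_format = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kar <- loucy_fixture(scale)
  reports <- list()
  for (ws in window_sizes) {
    tag <- sprintf("%gkb", ws / 1e3)
    grid <- build_window_grid(kar$layout, ws)
    tracks <- simulate_cohort(kar, grid, design, depth = depth,
                              read_length = read_length,
                              seed = derive_seed(seed, ws))
    bulk_spec <- sample_spec("bulk", 1L, 1L, depth = depth, read_length = read_length)
    tracks[["bulk_c1_r1"]] <- simulate_counts(
      kar, grid, bulk_spec, bias_model(sigma = 0, seed = derive_seed(seed, ws, 0L)),
      seed = derive_seed(seed, ws, 0L))
    cfg <- pipeline_config(window_size = ws,
                           segmentation = segmentation_config(
                             alpha = alpha, n_perm = n_perm,
                             seed = derive_seed(seed, ws, 999L)),
                           seed = seed)
    results <- lapply(tracks, function(tr) {
      tryCatch(run_pipeline(tr, cfg),
               error = function(e) {
                 message("sample ", tr$spec$sample_id, " aborted: ", conditionMessage(e))
                 NULL
               })
    })
    results <- Filter(Negate(is.null), results)
    rep_ws <- cohort_report(results, kar,
                            match_config(breakpoint_tolerance = ws))
    utils::write.table(rep_ws$samples,
                       file.path(out_dir, sprintf("samples_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep_ws$methods,
                       file.path(out_dir, sprintf("methods_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep_ws$anova)) {
      a <- rep_ws$anova
      utils::write.table(
        data.frame(f_stat = a$f_stat, df_between = a$df_between,
                   df_within = a$df_within, p_value = a$p_value),
        file.path(out_dir, sprintf("anova_%s.tsv", tag)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    bulk <- results[["bulk_c1_r1"]]
    if (!is.null(plot_format) && !is.null(bulk) && bulk$status == "usable") {
      pl <- render_line_profile(bulk$cn, bulk$segments, bulk$calls)
      save_line_profile(pl, file.path(out_dir, sprintf("bulk_profile_%s.%s",
                                                       tag, plot_format)))
    }
    reports[[as.character(ws)]] <- rep_ws
  }
  invisible(reports)
}

#' Genome-wide copy-number line profile
#'
#' Windows are ordered along the x-axis by genomic position; the y-axis
#' shows the median-normalized log2(CN/2). Each dot is a window, horizontal
#' lines are segments, chromosomes alternate a white/grey background, and
#' segments beyond the calling threshold are colored blue (gain) or red
#' (loss).
#'
#' @param cn A `cn_track`.
#' @param segments Optional `segment_set` drawn as horizontal lines.
#' @param calls Unused except for compatibility; coloring derives from the
#'   threshold.
#' @param log2_threshold Calling threshold used for coloring (default 0.35).
#' @return A ggplot object.
#' @export
render_line_profile <- function(cn, segments = NULL, calls = NULL,
                                log2_threshold = 0.35) {
  stop_if_not(inherits(cn, "cn_track"), "cn must be a cn_track")
  stop_if_not(length(cn$log2ratio) > 0, "empty track")
  grid <- cn$grid
  layout <- attr(grid, "layout")
  offset <- stats::setNames(cumsum(c(0, layout$length[-nrow(layout)])), layout$chrom)
  pts <- data.frame(x = (offset[grid$chrom] + (grid$start + grid$end) / 2) / 1e6,
                    y = cn$log2ratio)
  pts <- pts[cn$usable & !is.na(pts$y), , drop = FALSE]
  bands <- data.frame(chrom = layout$chrom,
                      xmin = offset[layout$chrom] / 1e6,
                      xmax = (offset[layout$chrom] + layout$length) / 1e6,
                      fill = rep(c("a", "b"), length.out = nrow(layout)))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = xmin, xmax = xmax,
                                    ymin = -Inf, ymax = Inf, fill = fill),
                       show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(a = "white", b = "grey92")) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = x, y = y),
                        size = 0.4, colour = "grey30") +
    ggplot2::labs(x = "genomic position (Mb)", y = expression(log[2](CN / 2))) +
    ggplot2::theme_classic()
  if (!is.null(segments)) {
    seg <- as.data.frame(segments)
    seg$x0 <- (offset[seg$chrom] + seg$start) / 1e6
    seg$x1 <- (offset[seg$chrom] + seg$end) / 1e6
    seg$state <- ifelse(seg$mean_log2 > log2_threshold, "gain",
                        ifelse(seg$mean_log2 < -log2_threshold, "loss", "neutral"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = x0, xend = x1,
                   y = mean_log2, yend = mean_log2,
                   colour = state),
      linewidth = 1.1) +
      ggplot2::scale_colour_manual(
        values = c(gain = "#2166ac", loss = "#b2182b", neutral = "#1b7837"),
        guide = "none")
  }
  p
}

#' Save a line profile to disk
#'
#' @param plot A ggplot object from [render_line_profile()].
#' @param path Output path; the device is chosen from the extension
#'   (".png" or ".pdf").
#' @param width,height Size in inches.
#' @export
save_line_profile <- function(plot, path, width = 10, height = 3) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  invisible(path)
}
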