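mk_calls <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]], direction = r[[4]],
               mean_log2 = if (r[[4]] == "gain") 0.6 else -1,
               cn_estimate = if (r[[4]] == "gain") 3 else 1, n_windows = 5L,
               stringsAsFactors = FALSE)
  }))
  structure(d, class = c("cnv_calls", "data.frame"))
}

ref2 <- function() {
  karyotype(genome_layout(c("1", "2"), c(1e8, 1e8)),
            data.frame(chrom = c("1", "2"), start = c(10e6, 50e6),
                       end = c(20e6, 60e6), copy_number = c(1L, 3L)))
}

test_that("exact, disjoint and partial calls classify as TP/FP/FN", {
  ref <- ref2()
  # identical call -> TP; the other event unmatched -> FN
  ev <- match_calls(mk_calls(list("1", 10e6, 20e6, "loss")), ref,
                    match_config(breakpoint_tolerance = 0))
  expect_equal(c(ev$tp_count, ev$fp_count, ev$fn_count), c(1L, 0L, 1L))
  # zero overlap -> FP + 2 FN
  ev0 <- match_calls(mk_calls(list("1", 70e6, 80e6, "loss")), ref,
                     match_config(breakpoint_tolerance = 0))
  expect_equal(c(ev0$tp_count, ev0$fp_count, ev0$fn_count), c(0L, 1L, 2L))
  # direction must agree
  evd <- match_calls(mk_calls(list("1", 10e6, 20e6, "gain")), ref,
                     match_config(breakpoint_tolerance = 0))
  expect_equal(evd$fp_count, 1L)
})

test_that("reciprocal overlap at 50% of both lengths decides matching", {
  ref <- ref2()
  # 10 Mb call overlapping 6 Mb of the 10 Mb event -> TP
  ev <- match_calls(mk_calls(list("1", 14e6, 24e6, "loss")), ref,
                    match_config(breakpoint_tolerance = 0))
  expect_equal(ev$tp_count, 1L)
  # 4 Mb overlap -> below 50% of both -> FP + FN
  ev4 <- match_calls(mk_calls(list("1", 16e6, 26e6, "loss")), ref,
                     match_config(breakpoint_tolerance = 0))
  expect_equal(c(ev4$tp_count, ev4$fp_count), c(0L, 1L))
  # breakpoint tolerance of one window rescues near-miss boundaries
  ev_tol <- match_calls(mk_calls(list("1", 15.5e6, 25.5e6, "loss")), ref,
                        match_config(breakpoint_tolerance = 1e6))
  expect_equal(ev_tol$tp_count, 1L)
})

test_that("matching is one-to-one: a spanning call absorbs only one event", {
  ref <- karyotype(genome_layout("1", 1e8),
                   data.frame(chrom = "1", start = c(10e6, 30e6),
                              end = c(20e6, 40e6), copy_number = c(1L, 1L)))
  ev <- match_calls(mk_calls(list("1", 10e6, 40e6, "loss")), ref,
                    match_config(min_reciprocal_overlap = 0.3,
                                 breakpoint_tolerance = 0))
  expect_equal(c(ev$tp_count, ev$fp_count, ev$fn_count), c(1L, 0L, 1L))
})

test_that("one-way ANOVA matches the hand-computed and lm fixtures", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$f_stat, 3)
  expect_equal(c(res$df_between, res$df_within), c(2L, 6L))
  expect_equal(res$group_means, c(2, 3, 4))

  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$f_stat, 0)

  # independent cross-check against anova(lm())
  set.seed(88)
  groups <- list(rnorm(7, 0), rnorm(9, 0.5), rnorm(6, 1), rnorm(8, 0.2))
  res2 <- one_way_anova(groups)
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(seq_along(groups), lengths(groups))))
  a <- anova(stats::lm(y ~ g, data = d))
  expect_equal(res2$f_stat, a[["F value"]][1])
  expect_equal(res2$p_value, a[["Pr(>F)"]][1])
  # F is invariant under group relabeling
  res3 <- one_way_anova(groups[c(3, 1, 4, 2)])
  expect_equal(res3$f_stat, res2$f_stat)
})

test_that("cohort reports tabulate samples, methods and exclude failures", {
  k <- loucy_fixture(scale = 4)
  g <- build_window_grid(k$layout, 5e5)  # 620 windows
  design <- data.frame(method_label = c("good", "bad"), sigma = c(0.05, 0.08),
                       n_cells = 1L, replicates = 3L)
  tracks <- simulate_cohort(k, g, design, seed = 10)
  tracks[["fail_c1_r1"]] <- simulate_failed_profile(g, sample_spec("fail"), seed = 10)
  cfg <- pipeline_config(window_size = 5e5,
                         segmentation = segmentation_config(n_perm = 200, seed = 10))
  results <- lapply(tracks, run_pipeline, config = cfg)
  report <- cohort_report(results, k, match_config(breakpoint_tolerance = 5e5))
  expect_equal(nrow(report$samples), 7L)
  expect_equal(sum(report$samples$status == "failed"), 1L)
  expect_equal(report$samples$n_calls[report$samples$status == "failed"], 0L)
  # failed samples never enter the method aggregates or the ANOVA
  expect_false("fail" %in% report$methods$method)
  expect_equal(report$anova$df_within, 4L)  # 6 usable samples, 2 groups
  expect_s3_class(report$anova, "anova_result")
})

test_that("sensitivity degrades and false positives do not improve with bias", {
  k <- loucy_fixture(scale = 10)
  g <- build_window_grid(k$layout, 1e5)  # 1240 windows, events >= 3 windows
  cfg <- pipeline_config(window_size = 1e5,
                         segmentation = segmentation_config(n_perm = 200, seed = 1))
  stats_at <- function(sigma, seeds) {
    out <- vapply(seeds, function(s) {
      tr <- simulate_counts(k, g, sample_spec("s"),
                            bias_model(sigma = sigma, seed = s), seed = s)
      res <- run_pipeline(tr, cfg)
      ev <- match_calls(res$calls, k, match_config(breakpoint_tolerance = 1e5))
      c(sens = ev$tp_count / (ev$tp_count + ev$fn_count), fp = ev$fp_count)
    }, c(sens = 1.0, fp = 1.0))
    rowMeans(out)
  }
  seeds <- 1:20
  low <- stats_at(0.05, seeds)
  high <- stats_at(0.5, seeds)
  expect_gte(low["sens"], high["sens"])
  expect_lte(low["fp"], high["fp"])
  expect_gt(low["sens"], 0.9)  # low-noise profiles recover nearly everything
})
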