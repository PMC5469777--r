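test_that("the pipeline composes cleanly on noiseless and failed input", {
  g <- tiny_grid(c(A = 2e7, B = 1e7), 1e6)
  k <- diploid_karyotype(attr(g, "layout"))
  tr <- simulate_counts(k, g, sample_spec("bulk"), bias_model(sigma = 0, seed = 2),
                        seed = 2)
  res <- run_pipeline(tr, pipeline_config(seed = 2))
  expect_equal(res$status, "usable")
  expect_equal(nrow(res$calls), 0L)

  gbig <- tiny_grid(c(A = 1.2e9), 1e6)
  bad <- simulate_failed_profile(gbig, sample_spec("f"), seed = 2)
  resf <- run_pipeline(bad, pipeline_config(seed = 2))
  expect_equal(resf$status, "failed")
  expect_equal(nrow(resf$calls), 0L)
})

test_that("the fixture genome yields the expected direction of calls", {
  k <- loucy_fixture(scale = 5)
  g <- build_window_grid(k$layout, 2e5)  # same window geometry as 1 Mb at scale 1
  tr <- simulate_counts(k, g, sample_spec("s"), bias_model(sigma = 0.05, seed = 12),
                        seed = 12)
  res <- run_pipeline(tr, pipeline_config(window_size = 2e5,
                                          segmentation = segmentation_config(
                                            n_perm = 500, seed = 12)))
  calls <- res$calls
  expect_true(any(calls$chrom == "13" & calls$direction == "gain"))
  for (ch in c("5", "6", "16", "X"))
    expect_true(any(calls$chrom == ch & calls$direction == "loss"))
})

test_that("serialized artifacts round-trip", {
  dir <- withr::local_tempdir()
  layout <- genome_layout(c("1", "X"), c(8e6, 5e6))
  lf <- file.path(dir, "layout.tsv")
  write_genome_layout(layout, lf)
  expect_equal(read_genome_layout(lf), layout)

  kar <- karyotype(layout, data.frame(chrom = "X", start = 0, end = 5e6,
                                      copy_number = 1L))
  kf <- file.path(dir, "kar.tsv")
  write_karyotype(kar, kf)
  expect_equal(read_karyotype(kf, layout)$events, kar$events)

  g <- build_window_grid(layout, 1e6)
  tr <- simulate_counts(kar, g, sample_spec("m", 3, 2), bias_model(seed = 4),
                        seed = 4)
  cf <- file.path(dir, "counts.tsv")
  write_count_track(tr, cf)
  tr2 <- read_count_track(cf, g)
  expect_equal(tr2$counts, tr$counts)
  expect_equal(tr2$spec$sample_id, "m_c3_r2")
  expect_equal(tr2$spec$n_cells, 3L)

  cn <- estimate_cn(median_normalize(tr))
  segs <- cbs_segment(cn, segmentation_config(seed = 4))
  sf <- file.path(dir, "segs.tsv")
  write_segments(segs, sf, sample_id = "m_c3_r2")
  s2 <- read_segments(sf)
  expect_equal(s2$mean_log2, segs$mean_log2, tolerance = 1e-12)
  expect_equal(s2$start, segs$start)

  calls <- call_cnvs(segs)
  tf <- file.path(dir, "calls.tsv")
  write_calls_tsv(calls, tf)
  c2 <- read_calls_tsv(tf)
  expect_equal(c2$chrom, calls$chrom)
  expect_equal(c2$mean_log2, calls$mean_log2, tolerance = 1e-12)

  bf <- file.path(dir, "calls.bed")
  write_calls_bed(calls, bf)
  bed <- read.delim(bf, header = FALSE)
  expect_equal(nrow(bed), nrow(calls))
  expect_equal(bed$V5, round(1000 * abs(calls$mean_log2)))

  nf <- file.path(dir, "cn.tsv")
  write_cn_track(cn, nf)
  n2 <- read_cn_track(nf)
  expect_equal(n2$log2ratio, cn$log2ratio, tolerance = 1e-12)

  blf <- file.path(dir, "blacklist.bed")
  writeLines("1\t0\t1000000", blf)
  bl <- read_blacklist(blf)
  expect_equal(bl, data.frame(chrom = "1", start = 0, end = 1e6))
})

test_that("line profiles carry the window dots and colored segment lines", {
  k <- loucy_fixture(scale = 10)
  g <- build_window_grid(k$layout, 1e6)
  tr <- exact_count_track(g, window_cn(k, g))
  cn <- estimate_cn(median_normalize(tr))
  segs <- cbs_segment(cn, segmentation_config(seed = 1))
  p <- render_line_profile(cn, segs)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  # layer 2 = window dots: one per usable finite window
  expect_equal(nrow(built$data[[2]]), sum(cn$usable & is.finite(cn$log2ratio)))
  # rendering is deterministic in its data series
  built2 <- ggplot2::ggplot_build(render_line_profile(cn, segs))
  expect_identical(built$data[[2]]$y, built2$data[[2]]$y)
  expect_error(render_line_profile(estimate_cn(structure(
    list(grid = g[0, ], ratios = numeric(0), a = 1, n_usable = 0L,
         usable = logical(0), spec = NULL), class = "normalized_track"))),
    "empty")
})

test_that("run_demo writes reports, anova and profiles for a reduced cohort", {
  dir <- withr::local_tempdir()
  design <- data.frame(method_label = c("m1", "m2"), sigma = c(0.05, 0.1),
                       n_cells = 1L, replicates = 2L)
  reports <- run_demo(dir, scale = 8, window_sizes = 125e3, design = design,
                      seed = 3, n_perm = 200, plot_format = "pdf")
  expect_named(reports, "125000")
  rep1 <- reports[[1]]
  expect_equal(nrow(rep1$samples), 5L)  # 4 WGA samples + bulk
  expect_true(file.exists(file.path(dir, "samples_125kb.tsv")))
  expect_true(file.exists(file.path(dir, "methods_125kb.tsv")))
  expect_true(file.exists(file.path(dir, "anova_125kb.tsv")))
  expect_true(file.exists(file.path(dir, "bulk_profile_125kb.pdf")))
  # bulk recovers every reference event at this window size
  bulk <- rep1$samples[rep1$samples$method == "bulk", ]
  expect_equal(bulk$fn, 0L)
  expect_equal(bulk$fp, 0L)
  # full determinism of the report
  dir2 <- withr::local_tempdir()
  reports2 <- run_demo(dir2, scale = 8, window_sizes = 125e3, design = design,
                       seed = 3, n_perm = 200, plot_format = NULL)
  expect_identical(reports[[1]]$samples, reports2[[1]]$samples)
})

test_that("the command-line wrapper runs its subcommands on fixture files", {
  skip_if_not(nzchar(Sys.which(file.path(R.home("bin"), "Rscript"))))
  cli <- system.file("cli", "sccnv.R", package = "shallowCNV")
  skip_if(cli == "")
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")

  layout <- loucy_fixture(scale = 10)$layout
  lf <- file.path(dir, "layout.tsv"); write_genome_layout(layout, lf)
  kf <- file.path(dir, "kar.tsv"); write_karyotype(loucy_fixture(scale = 10), kf)
  counts <- file.path(dir, "counts.tsv")

  run <- function(...) system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE)
  run("simulate", "--layout", lf, "--karyotype", kf, "--window-size", "1e6",
      "--sigma", "0.05", "--seed", "5", "--out", counts)
  expect_true(file.exists(counts))

  cnf <- file.path(dir, "cn.tsv")
  run("normalize", "--layout", lf, "--window-size", "1e6",
      "--counts", counts, "--out", cnf)
  expect_true(file.exists(cnf))

  segf <- file.path(dir, "segs.tsv")
  run("segment", "--layout", lf, "--window-size", "1e6", "--counts", counts,
      "--n-perm", "200", "--seed", "5", "--out", segf)
  expect_true(file.exists(segf))

  callf <- file.path(dir, "calls.tsv")
  run("call", "--segments", segf, "--out", callf)
  expect_true(file.exists(callf))

  evalf <- file.path(dir, "eval.tsv")
  run("evaluate", "--calls", callf, "--layout", lf, "--reference", kf,
      "--tolerance", "1e6", "--out", evalf)
  expect_true(file.exists(evalf))
  ev <- read.delim(evalf)
  expect_true(ev$tp >= 1)
})
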