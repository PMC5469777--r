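test_that("GC correction is a no-op on homogeneous grids and masks pass through", {
  g <- tiny_grid(c(A = 3e7), 1e6)
  tr <- count_track(g, rpois(30, 1000), sample_spec("s"))
  corrected <- correct_gc_mappability(tr)
  expect_equal(corrected$counts, tr$counts)

  # blacklisted windows keep raw values and stay masked
  gb <- annotate_windows(g, blacklist = data.frame(chrom = "A", start = 0, end = 2e6))
  trb <- count_track(gb, tr$counts, sample_spec("s"))
  corr_b <- correct_gc_mappability(trb)
  expect_equal(corr_b$counts[1:2], tr$counts[1:2])
  expect_equal(usable_windows(gb)[1:2], c(FALSE, FALSE))
})

test_that("stratified median correction equalizes stratum medians", {
  # two GC strata, 25 windows each (odd medians avoid any convention issues)
  g <- tiny_grid(c(A = 5e7), 1e6)
  gc <- rep(c(0.3, 0.6), each = 25)
  g <- annotate_windows(g, gc = gc)
  counts <- c(96:120, 188:212)  # stratum medians 108 and 200
  tr <- count_track(g, counts, sample_spec("s"))
  corr <- correct_gc_mappability(tr, min_windows_per_stratum = 20)
  med <- tapply(corr$counts, gc, function(x) sort(x)[13])
  global_med <- sort(counts)[25]
  expect_equal(as.numeric(med), rep(global_med, 2), tolerance = 1e-12)
})

test_that("GC correction removes an injected quadratic GC effect", {
  g <- tiny_grid(c(A = 2.5e9), 1e6)  # 2500 windows
  set.seed(31)
  gc <- pmin(pmax(rnorm(nrow(g), 0.45, 0.08), 0.2), 0.7)
  g <- annotate_windows(g, gc = gc)
  k <- diploid_karyotype(attr(g, "layout"))
  tr <- simulate_counts(k, g, sample_spec("s"),
                        bias_model(sigma = 0, gc_quad = c(1.0, 0), seed = 31),
                        seed = 31)
  expect_gt(abs(cor(tr$counts, gc)), 0.5)  # effect present before correction
  corr <- correct_gc_mappability(tr)
  expect_lt(abs(cor(corr$counts, gc)), 0.05)
})

test_that("median normalization divides by the median and propagates masks", {
  g <- tiny_grid(c(A = 4e6), 1e6)
  tr <- count_track(g, c(100, 200, 100, 100), sample_spec("s"))
  norm <- median_normalize(tr)
  expect_equal(norm$a, 100)
  expect_equal(norm$ratios, c(1, 2, 1, 1))
  expect_equal(norm$n_usable, 4L)

  trc <- count_track(g, rep(77, 4), sample_spec("s"))
  expect_equal(median_normalize(trc)$ratios, rep(1, 4))

  g3 <- tiny_grid(c(A = 3e6), 1e6)
  expect_error(median_normalize(count_track(g3, c(0, 0, 0), sample_spec("s"))),
               "zero")
})

test_that("the median of usable normalized ratios is exactly 1", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    g <- tiny_grid(c(A = n * 1e6), 1e6)
    tr <- count_track(g, rpois(n, 500) + 1, sample_spec("s"))
    norm <- median_normalize(tr)
    expect_identical(median_low(norm$ratios[norm$usable]), 1)
  }
})

test_that("CN estimates follow CN = 2 * ratio with a log2 floor at zero", {
  g <- tiny_grid(c(A = 5e6), 1e6)
  tr <- count_track(g, c(100, 150, 100, 100, 0), sample_spec("s"))
  cn <- estimate_cn(median_normalize(tr))
  expect_equal(cn$cn, c(2, 3, 2, 2, 0))
  expect_equal(cn$log2ratio[1], 0)
  expect_equal(cn$log2ratio[2], log2(1.5))
  expect_equal(cn$log2ratio[5], -4)
  # the calling threshold's CN bounds: ratio 2^0.35 maps to CN 2*2^0.35
  expect_equal(2 * 2^0.35, 2.5491213, tolerance = 1e-6)
})

test_that("pairwise variance matches the hand-computed formula", {
  g <- tiny_grid(c(A = 3e6), 1e6)
  expect_equal(pairwise_variance(count_track(g, c(100, 100, 100), sample_spec("s"))), 0)
  v <- pairwise_variance(count_track(g, c(100, 200, 100), sample_spec("s")))
  expect_equal(v, 2 / 3)
  # joint rescaling invariance (a recomputes to 200)
  v2 <- pairwise_variance(count_track(g, c(200, 400, 200), sample_spec("s")))
  expect_identical(v, v2)
  expect_error(pairwise_variance(count_track(tiny_grid(c(A = 1e6), 1e6), 5,
                                             sample_spec("s"))),
               "2 usable")
})

test_that("pairwise variance skips masked windows and chromosome boundaries", {
  g <- tiny_grid(c(A = 3e6, B = 2e6), 1e6)
  # A: 100,200,100 ; B: 400,100 -- the A->B jump must not contribute
  x <- c(100, 200, 100, 400, 100)
  v <- pairwise_variance(count_track(g, x, sample_spec("s")))
  # a = 100; pairs: (1,2),(2,1) on A and (4,1) on B -> (1+1+9)/5
  expect_equal(v, 11 / 5)
  # masking the middle window of A pairs its neighbors directly
  gm <- annotate_windows(g, blacklist = data.frame(chrom = "A", start = 1e6, end = 2e6))
  vm <- pairwise_variance(count_track(gm, x, sample_spec("s")))
  # usable: 100,100 | 400,100; a = 100; pairs (1,1),(4,1) -> (0+9)/4
  expect_equal(vm, 9 / 4)
})

test_that("a pure-Poisson diploid track has variance near 2/a", {
  g <- tiny_grid(c(A = 5e9), 1e6)  # 5000 windows
  k <- diploid_karyotype(attr(g, "layout"))
  tr <- simulate_counts(k, g, sample_spec("s"), bias_model(sigma = 0, seed = 13),
                        seed = 13)
  a <- median_low(tr$counts)
  v <- pairwise_variance(tr)
  expect_lt(abs(v - 2 / a) / (2 / a), 0.1)
})

test_that("the variance statistic survives read thinning", {
  # with bias dominating Poisson noise, halving the depth leaves the
  # statistic unchanged up to sampling error
  g <- tiny_grid(c(A = 4e9), 1e6)
  k <- diploid_karyotype(attr(g, "layout"))
  tr <- simulate_counts(k, g, sample_spec("s"), bias_model(sigma = 0.3, seed = 17),
                        seed = 17)
  v_full <- pairwise_variance(tr)
  set.seed(99)
  thinned <- count_track(g, rbinom(length(tr$counts), tr$counts, 0.5),
                         sample_spec("s"))
  v_half <- pairwise_variance(thinned)
  expect_lt(abs(v_half - v_full) / v_full, 0.1)
})
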