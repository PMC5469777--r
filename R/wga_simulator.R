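# Synthetic read-count simulator for WGA shallow-sequencing profiles.
#
# The statistical model is the one the downstream analysis assumes:
# per-window Poisson sampling around an expected count that is proportional
# to sequencing depth, window length and copy number, distorted by a
# multiplicative log-normal amplification bias (the "representation bias"
# of whole-genome amplification) and an optional quadratic GC response.
# Bias shrinks geometrically with the number of input cells, reflecting
# averaging of independent amplification trajectories.

#' Amplification bias model
#'
#' @param sigma Standard deviation (natural-log scale) of the per-window
#'   log-normal amplification bias for a single cell; 0 disables bias.
#' @param gc_quad Numeric length-2 vector `(c1, c2)`: coefficients of the
#'   quadratic GC response `g(gc) = 1 + c1*(gc - 0.4) + c2*(gc - 0.4)^2`,
#'   mean-normalized over the grid. Defaults to `c(0, 0)` so GC correction
#'   is exercised explicitly, never implicitly.
#' @param cell_attenuation Factor in (0, 1] by which `sigma` shrinks per
#'   additional input cell (effective sigma for n cells is
#'   `sigma * cell_attenuation^(n - 1)`). Default 0.85: multi-cell samples
#'   show slightly lower read-count variance than single cells.
#' @param seed Integer seed used when no explicit seed is passed to the
#'   simulation functions.
#' @return A `bias_model` list.
#' @export
bias_model <- function(sigma = 0.1, gc_quad = c(0, 0), cell_attenuation = 0.85,
                       seed = 1L) {
  stop_if_not(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
              "sigma must be a single non-negative number")
  stop_if_not(length(gc_quad) == 2, "gc_quad must have two coefficients")
  stop_if_not(cell_attenuation > 0 && cell_attenuation <= 1,
              "cell_attenuation must lie in (0, 1]")
  structure(list(sigma = sigma, gc_quad = as.numeric(gc_quad),
                 cell_attenuation = cell_attenuation, seed = as.integer(seed)),
            class = "bias_model")
}

#' Sample specification
#'
#' Metadata describing one sequenced sample: amplification method label,
#' number of input cells, replicate index, mean fold-coverage and read
#' length.
#'
#' @param method_label Character label of the WGA method (or "bulk").
#' @param n_cells Number of input cells (>= 1; the study design uses 1, 3, 5).
#' @param replicate Replicate index (>= 1).
#' @param depth Mean fold-coverage (default 0.3, i.e. ~0.3x shallow WGS).
#' @param read_length Read length in bp (default 75, single-end).
#' @return A `sample_spec` list with a derived `sample_id`.
#' @export
sample_spec <- function(method_label, n_cells = 1L, replicate = 1L,
                        depth = 0.3, read_length = 75) {
  stop_if_not(n_cells >= 1, "n_cells must be >= 1")
  stop_if_not(depth > 0, "depth must be > 0")
  stop_if_not(read_length > 0, "read_length must be > 0")
  structure(list(method_label = as.character(method_label),
                 n_cells = as.integer(n_cells),
                 replicate = as.integer(replicate),
                 depth = depth, read_length = read_length,
                 sample_id = sprintf("%s_c%d_r%d", method_label, n_cells, replicate)),
            class = "sample_spec")
}

# Mean-normalized quadratic GC response over the grid.
gc_response <- function(gc, gc_quad) {
  g <- 1 + gc_quad[1] * (gc - 0.4) + gc_quad[2] * (gc - 0.4)^2
  g <- pmax(g, 1e-6)
  g / mean(g)
}

#' Simulate per-window amplification bias factors
#'
#' Draws one positive multiplicative factor per window:
#' `factor = exp(z)`, `z ~ Normal(0, (sigma * cell_attenuation^(n_cells-1))^2)`,
#' independently per window.
#'
#' @param grid A `window_grid`.
#' @param model A [bias_model()].
#' @param n_cells Number of input cells (attenuates sigma).
#' @param seed Integer seed (defaults to `model$seed`).
#' @return Numeric vector of positive factors, length `n_windows(grid)`.
#' @export
simulate_bias <- function(grid, model, n_cells = 1L, seed = model$seed) {
  stop_if_not(inherits(model, "bias_model"), "model must be a bias_model")
  sd_eff <- model$sigma * model$cell_attenuation^(n_cells - 1)
  set.seed(seed)
  exp(stats::rnorm(nrow(grid), mean = 0, sd = sd_eff))
}

#' Expected read count per window (no bias, no sampling noise)
#'
#' The deterministic part of the count model:
#' `lambda_w = depth * width_w / read_length * CN_w / 2`,
#' where `CN_w` is the length-weighted copy number of window `w` under the
#' karyotype. At 0.3x depth, 75 bp reads and a full 1 Mb diploid window this
#' is 4000 reads.
#'
#' @param kar A [karyotype()].
#' @param grid A `window_grid` on the same layout.
#' @param spec A [sample_spec()].
#' @return Numeric vector of expected counts.
#' @export
expected_counts <- function(kar, grid, spec) {
  width <- grid$end - grid$start
  spec$depth * width / spec$read_length * window_cn(kar, grid) / 2
}

#' Simulate a per-window count track for one sample
#'
#' Counts are drawn `Poisson(lambda_w)` with
#' `lambda_w = expected_counts * bias_w * g(gc_w)`. Blacklisted windows
#' still receive counts; exclusion happens downstream in normalization.
#'
#' @param kar A [karyotype()].
#' @param grid A `window_grid` on the same layout.
#' @param spec A [sample_spec()].
#' @param model A [bias_model()].
#' @param seed Integer seed (defaults to `model$seed`); bias and Poisson
#'   draws use sub-seeds derived from it.
#' @return A `count_track`: list with `grid`, integer `counts`, `spec`,
#'   `total_reads`.
#' @export
simulate_counts <- function(kar, grid, spec, model = bias_model(),
                            seed = model$seed) {
  stop_if_not(inherits(spec, "sample_spec"), "spec must be a sample_spec")
  stop_if_not(identical(attr(grid, "layout")$chrom, kar$layout$chrom),
              "grid and karyotype layouts differ")
  bias <- simulate_bias(grid, model, spec$n_cells, seed = derive_seed(seed, 1L))
  g <- gc_response(grid$gc, model$gc_quad)
  lambda <- expected_counts(kar, grid, spec) * bias * g
  set.seed(derive_seed(seed, 2L))
  counts <- stats::rpois(nrow(grid), lambda)
  count_track(grid, counts, spec)
}

#' Construct a count track
#'
#' @param grid A `window_grid`.
#' @param counts Non-negative integer vector, one value per window.
#' @param spec A [sample_spec()].
#' @return A `count_track` object.
#' @export
count_track <- function(grid, counts, spec) {
  stop_if_not(length(counts) == nrow(grid), "counts length must equal window count")
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  structure(list(grid = grid, counts = as.numeric(counts), spec = spec,
                 total_reads = sum(counts)),
            class = "count_track")
}

#' @export
print.count_track <- function(x, ...) {
  cat(sprintf("count_track '%s': %d windows, %s reads\n",
              x$spec$sample_id, length(x$counts),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Default cohort design of the study
#'
#' Four WGA methods x {1, 3, 5} input cells x 3 replicates = 36 samples.
#' Per-method sigmas are free parameters of the simulator (the study reports
#' no significant variance difference between methods but slightly better
#' calling accuracy for DOPlify and Picoseq, reflected here as slightly
#' lower bias).
#'
#' @return Data frame with columns `method_label`, `sigma`, `n_cells`,
#'   `replicates`.
#' @export
default_cohort_design <- function() {
  methods <- c("Ampli1", "REPLI-g", "DOPlify", "Picoseq")
  sigmas  <- c(0.10,     0.11,      0.07,      0.08)
  data.frame(method_label = rep(methods, each = 3),
             sigma = rep(sigmas, each = 3),
             n_cells = rep(c(1L, 3L, 5L), times = 4),
             replicates = 3L,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort of count tracks
#'
#' One `count_track` per (method, cell count, replicate) combination, each
#' with a deterministic sub-seed derived from the master seed and the
#' sample's identity, so cohorts are reproducible sample-by-sample.
#'
#' @param kar A [karyotype()].
#' @param grid A `window_grid` on the same layout.
#' @param design Data frame with columns `method_label`, `sigma`, `n_cells`,
#'   `replicates` (one row per method x cell-count cell); see
#'   [default_cohort_design()].
#' @param depth Mean fold-coverage for every sample (default 0.3).
#' @param read_length Read length in bp (default 75).
#' @param seed Master integer seed.
#' @param gc_quad,cell_attenuation Passed to [bias_model()].
#' @return List of `count_track` objects, named by `sample_id`.
#' @export
simulate_cohort <- function(kar, grid, design = default_cohort_design(),
                            depth = 0.3, read_length = 75, seed = 1L,
                            gc_quad = c(0, 0), cell_attenuation = 0.85) {
  design <- as.data.frame(design)
  stop_if_not(nrow(design) > 0, "empty cohort design")
  stop_if_not(all(design$replicates >= 1), "replicates must be >= 1")
  tracks <- list()
  for (k in seq_len(nrow(design))) {
    for (rep_i in seq_len(design$replicates[k])) {
      spec <- sample_spec(design$method_label[k], design$n_cells[k], rep_i,
                          depth = depth, read_length = read_length)
      sub <- derive_seed(seed, design$method_label[k], design$n_cells[k], rep_i)
      model <- bias_model(sigma = design$sigma[k], gc_quad = gc_quad,
                          cell_attenuation = cell_attenuation, seed = sub)
      tracks[[spec$sample_id]] <- simulate_counts(kar, grid, spec, model, seed = sub)
    }
  }
  tracks
}

#' Simulate a failed amplification profile
#'
#' Generates a diploid track with very large amplification bias
#' (`sigma = 1.5` by default), emulating amplification failures whose
#' per-window read counts are so irregular that CNVs would be called across
#' the entire genome; the downstream quality gate flags such tracks.
#'
#' @param grid A `window_grid`.
#' @param spec A [sample_spec()].
#' @param seed Integer seed.
#' @param sigma Bias magnitude (default 1.5).
#' @return A `count_track`.
#' @export
simulate_failed_profile <- function(grid, spec, seed = 1L, sigma = 1.5) {
  diploid <- karyotype(attr(grid, "layout"),
                       data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), copy_number = integer(0)))
  model <- bias_model(sigma = sigma, cell_attenuation = 1, seed = seed)
  simulate_counts(diploid, grid, spec, model, seed = seed)
}
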