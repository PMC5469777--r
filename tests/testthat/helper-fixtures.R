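# Shared fixtures and the independent exhaustive oracle for the CBS arc
# statistic.

# A small two-chromosome layout/grid for unit tests.
tiny_grid <- function(lengths = c(A = 5e6, B = 3e6), window_size = 1e6) {
  build_window_grid(genome_layout(names(lengths), unname(lengths)), window_size)
}

# A diploid karyotype on an arbitrary layout.
diploid_karyotype <- function(layout) {
  karyotype(layout, data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), copy_number = integer(0)))
}

# Exhaustive double-loop scan over all admissible circular arcs, written
# independently of the package's compiled scan. Same statistic conventions:
# pooled-variance two-sample t; t = 0 for zero variance with equal means,
# +/-1e12 surrogate otherwise; maxima ordered by |t|, then signed t, then
# smallest i, then smallest j.
oracle_max_t_arc <- function(x, min_seg = 2L) {
  n <- length(x)
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  best <- NULL
  for (i in 0:(n - min_seg)) {
    jmax <- min(n, n - min_seg + i)
    for (j in seq(i + min_seg, jmax)) {
      n1 <- j - i; n2 <- n - n1
      s1 <- S[j + 1] - S[i + 1]; q1 <- Q[j + 1] - Q[i + 1]
      s2 <- S[n + 1] - s1;       q2 <- Q[n + 1] - q1
      m1 <- s1 / n1; m2 <- s2 / n2
      ss1 <- max(q1 - s1 * s1 / n1, 0)
      ss2 <- max(q2 - s2 * s2 / n2, 0)
      sp2 <- if (n - 2 > 0) (ss1 + ss2) / (n - 2) else 0
      t <- if (sp2 <= 0) {
        if (abs(m1 - m2) <= 1e-12) 0 else if (m1 > m2) 1e12 else -1e12
      } else {
        (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      }
      if (is.null(best) || abs(t) > abs(best$t) ||
          (abs(t) == abs(best$t) && t > best$t)) {
        best <- list(i = i, j = j, t = t)
      }
    }
  }
  best
}

# Counts with a given per-window expected value and an exact CN profile,
# bypassing the simulator (deterministic, no Poisson noise).
exact_count_track <- function(grid, cn_per_window, base = 4000,
                              label = "exact") {
  count_track(grid, round(base * cn_per_window / 2), sample_spec(label))
}
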