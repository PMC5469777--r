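# Plain-text readers/writers for the pipeline's artifacts: genome layout
# and karyotype TSVs, blacklist and call BEDs, per-window annotation, count
# tracks with a JSON sidecar, SEG-like segment tables and call tables.

#' Read/write a genome layout TSV
#'
#' Two tab-separated columns with header: `chrom`, `length`.
#'
#' @param path File path.
#' @return [read_genome_layout()] returns a [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("chrom", "length") %in% names(d)),
              "layout TSV needs columns chrom, length")
  genome_layout(d$chrom, d$length)
}

#' @rdname read_genome_layout
#' @param layout A [genome_layout()].
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a reference karyotype
#'
#' BED-like four-column TSV with header: `chrom`, `start`, `end`,
#' `copy_number`.
#'
#' @param path File path.
#' @param layout The [genome_layout()] the events live on.
#' @param baseline Baseline copy number (default 2).
#' @return [read_karyotype()] returns a [karyotype()].
#' @export
read_karyotype <- function(path, layout, baseline = 2) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  stop_if_not(all(c("chrom", "start", "end", "copy_number") %in% names(d)),
              "karyotype TSV needs columns chrom, start, end, copy_number")
  karyotype(layout, d, baseline = baseline)
}

#' @rdname read_karyotype
#' @param kar A [karyotype()].
#' @export
write_karyotype <- function(kar, path) {
  utils::write.table(kar$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a blacklist BED file
#'
#' Three headerless tab-separated columns: chrom, start, end (0-based
#' half-open).
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_blacklist <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "numeric"))[, 1:3]
  names(d) <- c("chrom", "start", "end")
  d
}

#' Read a per-window annotation track
#'
#' Four-column TSV with header (`chrom`, `start`, `end`, `value`) whose
#' windows must match the grid exactly, in order.
#'
#' @param path File path.
#' @param grid The `window_grid` the track annotates.
#' @return Numeric vector of values, length `n_windows(grid)`.
#' @export
read_annotation_track <- function(path, grid) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  stop_if_not(nrow(d) == nrow(grid), "annotation track does not match grid size")
  stop_if_not(all(d$chrom == grid$chrom & d$start == grid$start & d$end == grid$end),
              "annotation track windows do not match the grid")
  d$value
}

#' Write/read a count track
#'
#' Five-column TSV with header (`chrom`, `start`, `end`, `count`,
#' `sample_id`) plus a JSON sidecar `<path>.json` holding the sample
#' specification. The reader validates the windows against the grid.
#'
#' @param track A `count_track`.
#' @param path File path for the TSV (sidecar written next to it).
#' @return [read_count_track()] returns a `count_track`.
#' @export
write_count_track <- function(track, path) {
  d <- data.frame(chrom = track$grid$chrom, start = track$grid$start,
                  end = track$grid$end, count = track$counts,
                  sample_id = track$spec$sample_id, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(track$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_count_track
#' @param grid The `window_grid` the counts were binned on.
#' @export
read_count_track <- function(path, grid) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  stop_if_not(nrow(d) == nrow(grid), "count track does not match grid size")
  stop_if_not(all(d$chrom == grid$chrom & d$start == grid$start & d$end == grid$end),
              "count track windows do not match the grid")
  sidecar <- paste0(path, ".json")
  spec <- if (file.exists(sidecar)) {
    s <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sample_spec(s$method_label, s$n_cells, s$replicate, s$depth, s$read_length)
  } else {
    sample_spec(d$sample_id[1])
  }
  count_track(grid, d$count, spec)
}

#' Write/read a segment table
#'
#' SEG-like TSV with header: `sample_id`, `chrom`, `start`, `end`,
#' `n_windows`, `mean_log2`.
#'
#' @param segments A `segment_set`.
#' @param path File path.
#' @param sample_id Sample identifier recorded in the first column.
#' @return [read_segments()] returns the table as a data frame.
#' @export
write_segments <- function(segments, path, sample_id = "sample") {
  d <- data.frame(sample_id = sample_id,
                  segments[, c("chrom", "start", "end", "n_windows", "mean_log2")],
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write segments as a BED file
#'
#' Headerless BED with name `log2=<mean_log2>`.
#'
#' @param segments A `segment_set`.
#' @param path File path.
#' @export
write_segments_bed <- function(segments, path) {
  d <- data.frame(segments$chrom, format(segments$start, scientific = FALSE, trim = TRUE),
                  format(segments$end, scientific = FALSE, trim = TRUE),
                  sprintf("log2=%.4f", segments$mean_log2))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read CNV calls
#'
#' `write_calls_bed()` emits headerless BED with `name` gain/loss and
#' `score = round(1000 * |mean_log2|)`; `write_calls_tsv()` emits the full
#' table (with `cn_estimate` and `n_windows`) with a header, which
#' `read_calls_tsv()` reads back.
#'
#' @param calls A `cnv_calls` data frame.
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  d <- data.frame(calls$chrom,
                  format(calls$start, scientific = FALSE, trim = TRUE),
                  format(calls$end, scientific = FALSE, trim = TRUE),
                  calls$direction,
                  round(1000 * abs(calls$mean_log2)))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  structure(d, class = c("cnv_calls", "data.frame"))
}

#' Write/read a copy-number track
#'
#' TSV with header: `chrom`, `start`, `end`, `ratio`, `cn`, `log2ratio`,
#' `usable`.
#'
#' @param cn A `cn_track`.
#' @param path File path.
#' @export
write_cn_track <- function(cn, path) {
  d <- data.frame(chrom = cn$grid$chrom, start = cn$grid$start, end = cn$grid$end,
                  ratio = cn$cn / 2, cn = cn$cn, log2ratio = cn$log2ratio,
                  usable = cn$usable, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_track
#' @export
read_cn_track <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
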