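#' Read count matrix container
#'
#' Windows x samples integer read counts on a fixed window grid. Built by
#' [read_count_matrix()], [simulate_counts()] or internally; `counts` is a
#' numeric matrix with one row per window of `window_table(layout)` and one
#' column per sample.
#'
#' @param layout a [genome_layout()].
#' @param counts numeric matrix, windows x samples, non-negative.
#' @param sample_ids character vector of column names.
#' @return object of class `read_count_matrix` with fields `layout`,
#'   `windows`, `counts`, `sample_ids`.
#' @export
new_read_count_matrix <- function(layout, counts, sample_ids = colnames(counts)) {
  win <- window_table(layout)
  if (nrow(counts) != nrow(win))
    .stopf("counts has %d rows but layout has %d windows", nrow(counts), nrow(win))
  if (any(counts < 0, na.rm = TRUE)) .stopf("read counts must be non-negative")
  colnames(counts) <- sample_ids
  structure(list(layout = layout, windows = win,
                 counts = counts, sample_ids = sample_ids),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat(sprintf("read_count_matrix: %d windows x %d samples (WL = %.0f bp)\n",
              nrow(x$counts), length(x$sample_ids), x$layout$window_length))
  invisible(x)
}

#' Read a window read-count matrix from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `start`, `end`
#' followed by one column per sample; windows must be sorted and
#' non-overlapping within each chromosome. The window length is inferred as
#' the modal `end - start + 1`; a trailing shorter window is flagged as
#' partial. Chromosome lengths are inferred from the last window end.
#'
#' @param path TSV file path.
#' @return a [new_read_count_matrix()] object.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, c("chrom", "start", "end"), "count matrix")
  sample_ids <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(sample_ids) == 0) .stopf("count matrix: no sample columns found")
  counts <- as.matrix(df[, sample_ids, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0))
    .stopf("count matrix: counts must be non-negative numbers")
  # per-chromosome ordering / overlap checks
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, c("start", "end")]
    if (is.unsorted(sub$start, strictly = TRUE))
      .stopf("count matrix: windows on %s are unsorted or duplicated", ch)
    if (any(sub$start[-1] <= sub$end[-nrow(sub)]))
      .stopf("count matrix: overlapping windows on %s", ch)
  }
  wl <- .modal(df$end - df$start + 1)
  lens <- vapply(split(df$end, df$chrom), max, numeric(1))
  lens <- lens[unique(df$chrom)]  # preserve file order
  layout <- genome_layout(lens, window_length = wl)
  win <- window_table(layout)
  if (nrow(win) != nrow(df) || any(win$start != df$start) || any(win$end != df$end))
    .stopf("count matrix: windows do not tile chromosomes contiguously at WL=%d", wl)
  new_read_count_matrix(layout, counts, sample_ids)
}

#' Write a read-count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; numeric counts are written as-is.
#'
#' @param rcm a `read_count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(rcm, path) {
  df <- cbind(rcm$windows[, c("chrom", "start", "end")],
              as.data.frame(rcm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
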