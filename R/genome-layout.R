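#' Genome layout: chromosomes tiled into fixed windows
#'
#' A `genome_layout` fixes the coordinate system of the whole pipeline:
#' chromosomes of known length tiled into non-overlapping windows of
#' `window_length` bp. Coordinates are 1-based inclusive everywhere, so
#' window i on a chromosome is `[(i-1)*WL + 1, i*WL]` and an interval's
#' length is `end - start + 1`. A trailing window shorter than `WL` is kept
#' in the layout but flagged `partial`; partial windows are excluded from
#' CNV calling.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_length window size in bp (default 1000, the size at which
#'   a window holds on the order of 100 reads at ~10x coverage with 100 bp
#'   reads).
#' @return an object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c(chr1 = 5e6, chr2 = 2e6))
#' head(window_table(gl))
#' @export
genome_layout <- function(chrom_lengths, window_length = 1000) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    .stopf("genome_layout: chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) .stopf("genome_layout: chromosome lengths must be > 0")
  if (length(window_length) != 1 || window_length <= 0)
    .stopf("genome_layout: window_length must be a single positive number")
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = setNames(as.numeric(chrom_lengths),
                                          names(chrom_lengths)),
                 window_length = as.numeric(window_length)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.0f bp total, WL = %.0f bp\n",
              length(x$chrom_names), sum(x$chrom_lengths), x$window_length))
  invisible(x)
}

#' Window tiling of a genome layout
#'
#' @param layout a [genome_layout()].
#' @return data.frame with columns `chrom`, `start`, `end`, `partial`
#'   (logical: window shorter than `window_length`), in genome order.
#' @export
window_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  wl <- layout$window_length
  pieces <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    n <- ceiling(len / wl)
    start <- (seq_len(n) - 1) * wl + 1
    end <- pmin(seq_len(n) * wl, len)
    data.frame(chrom = ch, start = start, end = end,
               partial = (end - start + 1) < wl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# GRanges view of arbitrary interval tables (1-based inclusive in and out)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}
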