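#' Read per-sample CNV calls from a BED-like TSV
#'
#' One row per CNV: columns `chrom`, `start`, `end`, `sample`, `cn`
#' (1-based inclusive coordinates, integer copy-number genotype 0-8,
#' never 2). Rows with `cn = 2` are dropped with a warning: CN2 is the
#' reference genotype, not a CNV. An optional `dataset` column overrides
#' the `dataset_id` argument.
#'
#' @param path TSV file with header.
#' @param dataset_id dataset label attached to every call (batch unit; the
#'   pipeline analyses datasets separately).
#' @return data.frame of calls with columns `chrom`, `start`, `end`,
#'   `sample`, `cn`, `dataset`, in input order.
#' @export
read_cnv_calls <- function(path, dataset_id = "dataset1") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("chrom", "start", "end", "sample", "cn"), "CNV calls")
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sample = character(), cn = integer(),
                      dataset = character(), stringsAsFactors = FALSE))
  }
  cn_num <- suppressWarnings(as.numeric(df$cn))
  bad_cn <- which(is.na(cn_num) | cn_num != round(cn_num))
  if (length(bad_cn) > 0)
    .stopf("CNV calls: non-integer cn at data line %d (value '%s')",
           bad_cn[1], df$cn[bad_cn[1]])
  bad_coord <- which(df$start > df$end)
  if (length(bad_coord) > 0)
    .stopf("CNV calls: start > end at data line %d", bad_coord[1])
  if (any(cn_num < 0 | cn_num > 8))
    .stopf("CNV calls: cn must be in 0..8")
  is_cn2 <- cn_num == 2
  if (any(is_cn2))
    .warnf("dropped %d row(s) with cn=2: CN2 is the reference genotype, not a CNV",
           sum(is_cn2))
  out <- df[!is_cn2, , drop = FALSE]
  calls <- data.frame(chrom = as.character(out$chrom),
                      start = as.numeric(out$start),
                      end = as.numeric(out$end),
                      sample = as.character(out$sample),
                      cn = as.integer(cn_num[!is_cn2]),
                      dataset = if ("dataset" %in% names(out))
                        as.character(out$dataset) else dataset_id,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Write CNV calls to the same TSV layout read by [read_cnv_calls()]
#' @param calls data.frame of calls.
#' @param path output file.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(calls[, c("chrom", "start", "end", "sample", "cn", "dataset")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like annotation track (QTL, gap, repeat, segmental duplication)
#'
#' Tab-separated with header `chrom`, `start`, `end` and optionally `name`;
#' coordinates 1-based inclusive.
#'
#' @param path TSV file.
#' @param kind feature kind label (e.g. "QTL", "gap", "repeat", "segdup").
#' @return data.frame with `chrom`, `start`, `end`, `name`, `kind`.
#' @export
read_track <- function(path, kind) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("chrom", "start", "end"), sprintf("%s track", kind))
  if (!"name" %in% names(df))
    df$name <- sprintf("%s_%d", kind, seq_len(nrow(df)))
  data.frame(chrom = as.character(df$chrom), start = as.numeric(df$start),
             end = as.numeric(df$end), name = as.character(df$name),
             kind = kind, stringsAsFactors = FALSE)
}
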