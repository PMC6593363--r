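#' Write a CNVR summary table to CSV
#'
#' One row per CNVR ordered by (chrom, start, end): id, coordinates,
#' length, category, `n_samples` (samples with a non-CN2, non-CN_
#' genotype), per-genotype counts `n_CN0` .. `n_CN8`, and `n_CN_`
#' (undetermined after CN2 correction; counted in its own column, never in
#' `n_samples`).
#'
#' @param cnvr_set a `cnvr_set`.
#' @param genotypes corrected genotype matrix from [cn2_correction()] (or
#'   [assign_genotypes()]); rownames must cover the CNVR ids.
#' @param path output CSV (written atomically via a temp file).
#' @return the path, invisibly.
#' @export
write_cnvr_table <- function(cnvr_set, genotypes, path) {
  tab <- cnvr_table(cnvr_set, genotypes)
  tmp <- paste0(path, ".tmp")
  write.csv(tab, tmp, row.names = FALSE, quote = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Build the CNVR summary table (the in-memory form of [write_cnvr_table()])
#' @inheritParams write_cnvr_table
#' @return data.frame.
#' @export
cnvr_table <- function(cnvr_set, genotypes) {
  cnvrs <- cnvr_set$cnvrs
  cnvrs <- cnvrs[order(cnvrs$chrom, cnvrs$start, cnvrs$end), , drop = FALSE]
  cnt <- t(vapply(cnvrs$cnvr_id, function(id) {
    g <- genotypes[id, ]
    c(vapply(0:8, function(k) sum(g == k, na.rm = TRUE), integer(1)),
      sum(is.na(g)))
  }, integer(10)))
  colnames(cnt) <- c(paste0("n_CN", 0:8), "n_CN_")
  n_carrier <- rowSums(cnt[, paste0("n_CN", c(0, 1, 3:8)), drop = FALSE])
  out <- cbind(cnvrs[, c("cnvr_id", "chrom", "start", "end", "length", "category")],
               n_samples = as.integer(n_carrier),
               as.data.frame(cnt, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Read back a CSV written by [write_cnvr_table()]
#' @param path CSV file.
#' @return data.frame with the same columns.
#' @export
read_cnvr_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, c("cnvr_id", "chrom", "start", "end", "length",
                       "category", "n_samples"), "CNVR table")
  df
}
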