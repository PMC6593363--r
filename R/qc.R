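#' Tukey-fence outlier flags (1.5 x IQR rule)
#'
#' A value is flagged iff it lies below `Q1 - multiplier * IQR` or above
#' `Q3 + multiplier * IQR`, with quartiles computed by linear interpolation
#' (quantile type 7). Constant input has IQR 0 and flags nothing.
#'
#' @param values numeric vector (>= 4 values recommended).
#' @param multiplier fence multiplier (default 1.5).
#' @return logical vector (NA values are never flagged).
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))
#' @export
iqr_outliers <- function(values, multiplier = 1.5) {
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flags <- values < q[1] - multiplier * iqr | values > q[2] + multiplier * iqr
  flags[is.na(flags)] <- FALSE
  flags
}

#' PCA outlier detection on normalized window counts
#'
#' Projects samples onto the first two principal components of the
#' column-centered normalized count matrix and flags samples whose
#' Euclidean distance from the coordinate-wise median in (PC1, PC2)
#' exceeds `k_mad` times the median absolute deviation of those distances.
#' This replaces by-eye outlier identification with a deterministic rule.
#'
#' @param norm a normalized `read_count_matrix` (or raw; normalization is
#'   recommended first), >= 3 samples.
#' @param k_mad robust distance threshold (default 6).
#' @return named logical vector of flags; attributes `"scores"` (PC1/PC2
#'   coordinates) and `"distance"`.
#' @export
pca_outliers <- function(norm, k_mad = 6) {
  x <- t(norm$counts)  # samples x windows
  if (nrow(x) < 3) .stopf("pca_outliers: need at least 3 samples")
  ncomp <- min(2, nrow(x) - 1)
  if (ncomp < 2) .warnf("pca_outliers: fewer samples than components; using %d", ncomp)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  ctr <- apply(scores, 2, median)
  d <- sqrt(rowSums(sweep(scores, 2, ctr)^2))
  thr <- k_mad * mad(d)
  # k_mad = Inf disables the rule (thr Inf, or NaN when the MAD is 0 too)
  flags <- is.finite(thr) & d > thr
  names(flags) <- norm$sample_ids
  attr(flags, "scores") <- scores
  attr(flags, "distance") <- d
  flags
}

#' Per-sample QC report
#'
#' Computes, dataset-wise (QC must never mix batches), per-sample CNV-call
#' summaries and outlier flags: total calls, deletion proportion (fraction
#' of calls with copy number < 2, a call-count fraction), Tukey-fence
#' flags on both, PCA outlier flags on normalized counts (when a count
#' matrix is supplied), and an optional high-coverage fence on the
#' metadata coverage field (off by default). A sample passes iff no flag
#' is set.
#'
#' @param calls CNV call data.frame.
#' @param meta sample metadata (`sample`, `breed`, `dataset`, `coverage`).
#' @param norm_matrices optional named list (by dataset) of normalized
#'   `read_count_matrix` objects for the PCA flag.
#' @param iqr_multiplier Tukey fence multiplier (default 1.5).
#' @param k_mad PCA distance threshold (default 6).
#' @param coverage_rule flag high-coverage samples by the upper Tukey
#'   fence on coverage (default FALSE).
#' @return data.frame of class `qc_report`: one row per sample with
#'   `total_cnvs`, `del_proportion`, flag columns and `pass`.
#' @export
qc_report <- function(calls, meta, norm_matrices = NULL,
                      iqr_multiplier = 1.5, k_mad = 6,
                      coverage_rule = FALSE) {
  out <- lapply(split(meta, meta$dataset), function(m) {
    sub <- calls[calls$sample %in% m$sample, , drop = FALSE]
    total <- vapply(m$sample, function(s) sum(sub$sample == s), integer(1))
    delp <- vapply(m$sample, function(s) {
      k <- sub$sample == s
      if (!any(k)) NA_real_ else mean(sub$cn[k] < 2)
    }, numeric(1))
    rep <- data.frame(sample = m$sample, dataset = m$dataset,
                      total_cnvs = total, del_proportion = delp,
                      stringsAsFactors = FALSE)
    rep$total_cnv_outlier <- iqr_outliers(total, iqr_multiplier)
    rep$del_prop_outlier <- iqr_outliers(delp, iqr_multiplier)
    rep$pca_outlier <- FALSE
    if (!is.null(norm_matrices) && m$dataset[1] %in% names(norm_matrices)) {
      fl <- pca_outliers(norm_matrices[[m$dataset[1]]], k_mad = k_mad)
      rep$pca_outlier <- unname(fl[rep$sample])
      rep$pca_outlier[is.na(rep$pca_outlier)] <- FALSE
    }
    rep$high_coverage_outlier <- FALSE
    if (coverage_rule) {
      q <- quantile(m$coverage, c(0.25, 0.75), type = 7, names = FALSE)
      rep$high_coverage_outlier <-
        m$coverage > q[2] + iqr_multiplier * (q[2] - q[1])
    }
    rep$pass <- !(rep$total_cnv_outlier | rep$del_prop_outlier |
                    rep$pca_outlier | rep$high_coverage_outlier)
    rep
  })
  res <- do.call(rbind, out)
  res <- res[match(meta$sample, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("qc_report", "data.frame")
  res
}

#' Remove all calls from failing samples
#'
#' Every CNV called within a problematic (failing) sample is removed; the
#' operation is idempotent. Removal counts are reported per dataset.
#'
#' @param calls CNV call data.frame.
#' @param meta sample metadata.
#' @param report a [qc_report()] for the same cohort.
#' @return list with `calls` (filtered), `meta` (with `qc_pass` column),
#'   and `removed` (per-dataset counts).
#' @export
apply_qc <- function(calls, meta, report) {
  fail <- report$sample[!report$pass]
  keep <- !(calls$sample %in% fail)
  removed <- stats::aggregate(
    cbind(n_calls = !keep) ~ calls$dataset, FUN = sum)
  names(removed)[1] <- "dataset"
  for (i in seq_len(nrow(removed)))
    message(sprintf("apply_qc [%s]: removed %d call(s) from %d failing sample(s)",
                    removed$dataset[i], removed$n_calls[i],
                    sum(meta$dataset == removed$dataset[i] &
                          meta$sample %in% fail)))
  meta$qc_pass <- !(meta$sample %in% fail)
  list(calls = calls[keep, , drop = FALSE], meta = meta, removed = removed)
}
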