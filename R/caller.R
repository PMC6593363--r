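#' Normalize read counts to a common library size
#'
#' Multi-sample read-depth comparison requires counts on a common scale:
#' each sample is rescaled so that its genome-wide total equals the cohort
#' mean total. Samples with zero total are excluded with a warning.
#'
#' @param rcm a `read_count_matrix` with at least 2 samples.
#' @return a `read_count_matrix` with real-valued normalized counts;
#'   attribute `"scaling_factors"` holds the per-sample factors and
#'   attribute `"excluded"` any dropped zero-total samples.
#' @export
normalize_counts <- function(rcm) {
  if (length(rcm$sample_ids) < 2)
    .stopf("normalize_counts: need at least 2 samples")
  totals <- colSums(rcm$counts)
  zero <- totals == 0
  if (any(zero)) {
    .warnf("normalize_counts: excluded zero-total sample(s): %s",
           paste(rcm$sample_ids[zero], collapse = ", "))
    rcm$counts <- rcm$counts[, !zero, drop = FALSE]
    rcm$sample_ids <- rcm$sample_ids[!zero]
    totals <- totals[!zero]
  }
  target <- mean(totals)
  factors <- target / totals
  rcm$counts <- sweep(rcm$counts, 2, factors, `*`)
  attr(rcm, "scaling_factors") <- setNames(factors, rcm$sample_ids)
  attr(rcm, "excluded") <- names(zero)[zero]
  rcm
}

#' Per-window integer copy-number estimates
#'
#' A deliberately simple stand-in for full mixture-model read-depth
#' callers, keeping their external contract. Per window, the reference
#' rate `lambda_w` is the across-sample median of normalized counts
#' (robust to a minority of carriers; windows where most samples carry a
#' variant will mis-reference — a documented limitation). Per sample, the
#' copy-number estimate is `round(2 * x / lambda_w)` clipped to [0, 8],
#' and the window is flagged significant iff the estimate differs from 2
#' AND the exact two-sided Poisson tail probability of `x` under
#' `lambda_w` is below `alpha`. Windows with `lambda_w = 0` are masked;
#' partial terminal windows are never flagged.
#'
#' @param norm a normalized `read_count_matrix` (see [normalize_counts()]).
#' @param alpha per-window significance level (default 1e-3).
#' @return object of class `window_cn`: list with `windows`, `sample_ids`,
#'   `cn` (integer matrix), `flag` (logical matrix), `lambda`, `masked`.
#' @export
estimate_window_cn <- function(norm, alpha = 1e-3) {
  x <- norm$counts
  lambda <- apply(x, 1, median)
  masked <- lambda == 0
  lam_safe <- ifelse(masked, 1, lambda)
  cn <- round(2 * x / lam_safe)
  cn <- pmin(pmax(cn, 0), 8)
  storage.mode(cn) <- "integer"
  p <- .poisson_two_sided(x, lam_safe)
  flag <- cn != 2L & p < alpha
  flag[masked, ] <- FALSE
  flag[norm$windows$partial, ] <- FALSE
  cn[masked, ] <- NA_integer_
  structure(list(windows = norm$windows, sample_ids = norm$sample_ids,
                 cn = cn, flag = flag, lambda = lambda, masked = masked),
            class = "window_cn")
}

# exact two-sided Poisson tail: 2 * min(P(X <= floor(x)), P(X >= ceiling(x))),
# capped at 1; x may be real-valued after normalization
.poisson_two_sided <- function(x, lambda) {
  lower <- ppois(floor(x), lambda)
  upper <- ppois(ceiling(x) - 1, lambda, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Segment flagged windows into CNV calls
#'
#' Per sample and chromosome, maximal runs of at least
#' `min_adjacent_windows` consecutive significant windows of consistent
#' direction (all estimates < 2 = loss, all > 2 = gain) become one call; a
#' flagged gain window terminates a loss run and vice versa, so mixed
#' adjacent events yield two abutting calls. Call boundaries snap to
#' window boundaries (lengths are multiples of the window length and at
#' least `min_adjacent_windows` windows). The call genotype is the median
#' of the member window estimates, with half-values rounded toward CN2.
#'
#' @param wcn a [estimate_window_cn()] result.
#' @param min_adjacent_windows minimum run length (default 3, the usual
#'   floor that makes the smallest reportable CNV 3 kb at 1 kb windows).
#' @param dataset_id dataset label for the emitted calls.
#' @return data.frame of CNV calls (`chrom`, `start`, `end`, `sample`,
#'   `cn`, `dataset`).
#' @export
segment_calls <- function(wcn, min_adjacent_windows = 3,
                          dataset_id = "dataset1") {
  win <- wcn$windows
  out <- vector("list", length(wcn$sample_ids))
  chrom_f <- factor(win$chrom, levels = unique(win$chrom))
  for (si in seq_along(wcn$sample_ids)) {
    cn <- wcn$cn[, si]
    fl <- wcn$flag[, si]
    dir <- integer(nrow(win))
    dir[fl & !is.na(cn) & cn < 2L] <- -1L
    dir[fl & !is.na(cn) & cn > 2L] <- 1L
    key <- paste0(as.integer(chrom_f), ":", dir)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$lengths >= min_adjacent_windows &
      !endsWith(r$values, ":0")
    if (!any(keep)) next
    calls <- lapply(which(keep), function(k) {
      i1 <- starts[k]; i2 <- ends[k]
      data.frame(chrom = win$chrom[i1], start = win$start[i1],
                 end = win$end[i2], sample = wcn$sample_ids[si],
                 cn = .median_toward_two(cn[i1:i2]),
                 dataset = dataset_id, stringsAsFactors = FALSE)
    })
    out[[si]] <- do.call(rbind, calls)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      sample = character(), cn = integer(),
                      dataset = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# median of integer window estimates; a half-value rounds toward 2
.median_toward_two <- function(v) {
  m <- median(v)
  if (m %% 1 != 0) m <- if (m < 2) ceiling(m) else floor(m)
  as.integer(m)
}

#' Call CNVs from a raw count matrix (normalize, estimate, segment)
#'
#' @param rcm a `read_count_matrix` of raw counts.
#' @param alpha per-window significance level.
#' @param min_adjacent_windows minimum run length.
#' @param dataset_id dataset label.
#' @return data.frame of CNV calls.
#' @export
call_cnvs <- function(rcm, alpha = 1e-3, min_adjacent_windows = 3,
                      dataset_id = "dataset1") {
  norm <- normalize_counts(rcm)
  wcn <- estimate_window_cn(norm, alpha = alpha)
  segment_calls(wcn, min_adjacent_windows = min_adjacent_windows,
                dataset_id = dataset_id)
}
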