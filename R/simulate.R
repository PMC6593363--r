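#' Define CNV loci for cohort simulation
#'
#' A locus is a genomic interval segregating either a deletion allele
#' (carriers lose one copy per allele) or a duplication allele (carriers
#' gain `gain` copies per allele; `gain = 1` gives heterozygote CN3 /
#' homozygote CN4, `gain = 3` emulates a high-amplification multi-copy
#' allele with heterozygote CN5 / homozygote CN8, as seen at loci like the
#' one upstream of KIT). Copy numbers are capped at 8, the top of the
#' genotype scale.
#'
#' @param chrom,start,end locus coordinates (1-based inclusive; vectors).
#' @param type "DEL" or "DUP" per locus.
#' @param gain per-allele copy gain for DUP loci (recycled; default 1).
#' @return data.frame with `locus_id`, `chrom`, `start`, `end`, `type`,
#'   `gain`.
#' @export
cnv_locus_table <- function(chrom, start, end, type, gain = 1) {
  stopifnot(all(type %in% c("DEL", "DUP")), all(end >= start))
  n <- length(chrom)
  data.frame(locus_id = sprintf("L%03d", seq_len(n)),
             chrom = chrom, start = start, end = end,
             type = type, gain = rep_len(gain, n),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-breed cohort with known CNV truth
#'
#' For each breed and locus, diploid genotypes are sampled under
#' Hardy-Weinberg proportions: the number of variant alleles per sample is
#' Binomial(2, q) with q the breed's allele frequency at the locus. True
#' copy number is `2 - alleles` for DEL loci and `min(8, 2 + gain *
#' alleles)` for DUP loci. Reproducible for a fixed seed.
#'
#' @param loci a [cnv_locus_table()].
#' @param af allele frequencies: matrix loci x breeds (rownames optional),
#'   or a single numeric recycled to all loci/breeds; values in [0, 1].
#' @param breed_sizes named integer vector (breed code -> number of
#'   samples), e.g. `c(HER = 10, SIM = 10)`.
#' @param seed RNG seed.
#' @param dataset_id dataset label for the metadata.
#' @param coverage per-sample fold coverage (recycled; default 10).
#' @return list with `meta` (data.frame `sample`, `breed`, `dataset`,
#'   `coverage`) and `truth` (integer matrix loci x samples of true copy
#'   numbers).
#' @export
simulate_cohort <- function(loci, af, breed_sizes, seed = 1,
                            dataset_id = "dataset1", coverage = 10) {
  breeds <- names(breed_sizes)
  if (is.null(breeds)) .stopf("simulate_cohort: breed_sizes must be named")
  if (any(breed_sizes < 1)) .stopf("simulate_cohort: breed_sizes must be >= 1")
  nl <- nrow(loci)
  if (!is.matrix(af)) af <- matrix(af, nrow = nl, ncol = length(breeds))
  colnames(af) <- breeds
  if (any(af < 0 | af > 1)) .stopf("simulate_cohort: allele frequencies must be in [0, 1]")
  set.seed(seed)
  samples <- unlist(lapply(breeds, function(b)
    sprintf("%s%02d", b, seq_len(breed_sizes[[b]]))))
  breed_of <- rep(breeds, times = breed_sizes)
  truth <- matrix(2L, nrow = nl, ncol = length(samples),
                  dimnames = list(loci$locus_id, samples))
  for (b in breeds) {
    cols <- which(breed_of == b)
    for (l in seq_len(nl)) {
      alleles <- rbinom(length(cols), 2, af[l, b])
      cn <- if (loci$type[l] == "DEL") 2L - alleles
            else pmin(8L, 2L + loci$gain[l] * alleles)
      truth[l, cols] <- as.integer(cn)
    }
  }
  meta <- data.frame(sample = samples, breed = breed_of,
                     dataset = dataset_id,
                     coverage = rep_len(coverage, length(samples)),
                     stringsAsFactors = FALSE)
  list(meta = meta, truth = truth)
}

#' Simulate window read counts from a cohort truth table
#'
#' Window read counts follow the standard read-depth model: the expected
#' count of a diploid (CN2) window is `mean_depth` scaled by the sample's
#' relative coverage and its dataset's batch factor; a window inside a CNV
#' of copy number CN has expectation scaled by CN/2. Windows partially
#' covered by a CNV get the length-weighted average copy number, and
#' partial terminal windows are scaled by their width. Noise models:
#' `"poisson"` (counts ~ Poisson(expectation)), `"nbinom"`
#' (negative-binomial with `size = 1/overdispersion`, for overdispersed
#' depth), or `"none"` (counts = expectation exactly; the noise-free
#' oracle mode).
#'
#' @param truth truth matrix from [simulate_cohort()].
#' @param loci the matching [cnv_locus_table()].
#' @param layout a [genome_layout()].
#' @param meta cohort metadata (for per-sample coverage and dataset batch
#'   scaling); optional — without it all samples share `mean_depth`.
#' @param mean_depth expected reads per full diploid window at the cohort
#'   mean coverage (default 100, the usual target when choosing the window
#'   length).
#' @param batch_scale named multiplier per dataset (default none).
#' @param noise "poisson", "nbinom" or "none".
#' @param overdispersion negative-binomial overdispersion (only for
#'   `noise = "nbinom"`).
#' @param seed RNG seed.
#' @return a [new_read_count_matrix()] with the truth attached as
#'   attribute `"truth"`.
#' @export
simulate_counts <- function(truth, loci, layout, meta = NULL,
                            mean_depth = 100, batch_scale = NULL,
                            noise = c("poisson", "nbinom", "none"),
                            overdispersion = 0.05, seed = 1) {
  noise <- match.arg(noise)
  if (mean_depth <= 0) .stopf("simulate_counts: mean_depth must be > 0")
  win <- window_table(layout)
  samples <- colnames(truth)
  wl <- layout$window_length
  # per-sample depth multiplier
  mult <- rep(1, length(samples))
  if (!is.null(meta)) {
    m <- meta[match(samples, meta$sample), , drop = FALSE]
    mult <- m$coverage / mean(m$coverage)
    if (!is.null(batch_scale))
      mult <- mult * unname(batch_scale[m$dataset])
  }
  # length-weighted mean copy number per (window, sample)
  cnw <- matrix(2, nrow = nrow(win), ncol = length(samples))
  gr_w <- .as_granges(win)
  gr_l <- .as_granges(loci)
  hits <- GenomicRanges::findOverlaps(gr_w, gr_l, ignore.strand = TRUE)
  for (h in seq_along(hits)) {
    wi <- S4Vectors::queryHits(hits)[h]
    li <- S4Vectors::subjectHits(hits)[h]
    ov <- min(win$end[wi], loci$end[li]) - max(win$start[wi], loci$start[li]) + 1
    wwidth <- win$end[wi] - win$start[wi] + 1
    frac <- ov / wwidth
    cnw[wi, ] <- cnw[wi, ] + frac * (truth[li, ] - 2)
  }
  wfrac <- (win$end - win$start + 1) / wl
  lambda <- (cnw / 2) * mean_depth * wfrac
  lambda <- sweep(lambda, 2, mult, `*`)
  set.seed(seed)
  counts <- switch(noise,
    poisson = matrix(rpois(length(lambda), lambda), nrow = nrow(lambda)),
    nbinom = matrix(rnbinom(length(lambda), mu = lambda,
                            size = 1 / overdispersion), nrow = nrow(lambda)),
    none = lambda)
  rcm <- new_read_count_matrix(layout, counts, samples)
  attr(rcm, "truth") <- truth
  rcm
}

#' Plant problematic samples into a count matrix
#'
#' Emulates the failure modes that sample QC must catch: `low_coverage`
#' thins a sample's counts to a fraction of the cohort depth (binomial
#' thinning, so Poisson counts stay Poisson at the reduced rate);
#' `batch_outlier` multiplies a random subset of windows of the sample by a
#' bias factor, mimicking platform-specific coverage imbalance.
#'
#' @param rcm a `read_count_matrix`.
#' @param kind "low_coverage" or "batch_outlier".
#' @param samples sample ids to corrupt (may be empty: identity).
#' @param multiplier depth multiplier for `low_coverage` (default 0.3,
#'   i.e. a <5x sample in a ~10x cohort).
#' @param bias window bias factor for `batch_outlier` (default 2).
#' @param frac_windows fraction of windows biased (default 0.1).
#' @param seed RNG seed.
#' @return the modified matrix, with attribute `"planted"` naming the
#'   corrupted samples.
#' @export
plant_problem_samples <- function(rcm, kind = c("low_coverage", "batch_outlier"),
                                  samples, multiplier = 0.3, bias = 2,
                                  frac_windows = 0.1, seed = 1) {
  kind <- match.arg(kind)
  unknown <- setdiff(samples, rcm$sample_ids)
  if (length(unknown) > 0)
    .stopf("plant_problem_samples: unknown sample(s): %s",
           paste(unknown, collapse = ", "))
  set.seed(seed)
  for (s in samples) {
    x <- rcm$counts[, s]
    if (kind == "low_coverage") {
      if (all(x == round(x))) x <- rbinom(length(x), as.integer(x), multiplier)
      else x <- x * multiplier
    } else {
      idx <- sample(length(x), size = max(1, round(frac_windows * length(x))))
      x[idx] <- round(x[idx] * bias)
    }
    rcm$counts[, s] <- x
  }
  attr(rcm, "planted") <- samples
  rcm
}
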