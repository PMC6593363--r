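#' Pairwise reciprocal overlap of two genomic intervals
#'
#' For 1-based inclusive intervals on the same chromosome, the overlap
#' length is `max(0, min(end) - max(start) + 1)` and the reciprocal overlap
#' is that length expressed as a fraction of each interval. A pair satisfies
#' the X% reciprocal-overlap criterion when BOTH fractions are >= X.
#' Intervals on different chromosomes never satisfy the criterion.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return numeric vector `c(frac_a, frac_b)`.
#' @examples
#' reciprocal_overlap(list(chrom = "chr1", start = 1001, end = 5000),
#'                    list(chrom = "chr1", start = 3001, end = 7000))
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(c(0, 0))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
  c(ov / (a$end - a$start + 1), ov / (b$end - b$start + 1))
}

# vectorized: fractions for index pairs (i, j) into a call table
.ro_pair <- function(calls, i, j) {
  ov <- pmax(0, pmin(calls$end[i], calls$end[j]) -
               pmax(calls$start[i], calls$start[j]) + 1)
  ov <- ov * (calls$chrom[i] == calls$chrom[j])
  cbind(ov / (calls$end[i] - calls$start[i] + 1),
        ov / (calls$end[j] - calls$start[j] + 1))
}

#' Cluster CNV calls into CNV regions (CNVRs)
#'
#' CNVRs are the connected components of the graph whose vertices are CNV
#' calls and whose edges join pairs satisfying the pairwise
#' reciprocal-overlap criterion (both fractions >= `ro`, default 50%);
#' merging is genotype-agnostic, so deletion and amplification calls can
#' share a CNVR (then categorized MIX). The CNVR span is the min start /
#' max end over member calls. Output order is deterministic by
#' (chrom, start, end).
#'
#' @param calls data.frame of CNV calls (`chrom`, `start`, `end`, `sample`,
#'   `cn`), typically QC-filtered and from a single dataset.
#' @param ro reciprocal-overlap threshold in (0, 1].
#' @return object of class `cnvr_set`: list with `cnvrs` (data.frame
#'   `cnvr_id`, `chrom`, `start`, `end`, `length`, `category`, `n_samples`)
#'   and `members` (the input calls plus `cnvr_id`).
#' @export
cluster_cnvs <- function(calls, ro = 0.5) {
  stopifnot(is.data.frame(calls))
  if (ro <= 0 || ro > 1) .stopf("cluster_cnvs: ro must be in (0, 1]")
  n <- nrow(calls)
  if (n == 0) return(.new_cnvr_set(calls[0, ], calls))
  gr <- .as_granges(calls)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  if (length(i) > 0) {
    fr <- .ro_pair(calls, i, j)
    sat <- fr[, 1] >= ro & fr[, 2] >= ro
    i <- i[sat]; j <- j[sat]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(i) > 0) g <- igraph::add_edges(g, rbind(i, j))
  comp <- igraph::components(g)$membership
  members <- calls
  members$.comp <- comp
  spans <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(.comp = comp[idx[1]], chrom = calls$chrom[idx[1]],
               start = min(calls$start[idx]), end = max(calls$end[idx]),
               stringsAsFactors = FALSE)
  }))
  spans <- spans[order(spans$chrom, spans$start, spans$end), , drop = FALSE]
  spans$cnvr_id <- sprintf("CNVR_%05d", seq_len(nrow(spans)))
  members$cnvr_id <- spans$cnvr_id[match(members$.comp, spans$.comp)]
  members$.comp <- NULL
  .new_cnvr_set(spans[, c("cnvr_id", "chrom", "start", "end")], members)
}

.new_cnvr_set <- function(spans, members) {
  if (nrow(spans) > 0) {
    spans$length <- spans$end - spans$start + 1
    spans$category <- vapply(spans$cnvr_id, function(id)
      categorize(members$cn[members$cnvr_id == id]), character(1))
    spans$n_samples <- vapply(spans$cnvr_id, function(id)
      length(unique(members$sample[members$cnvr_id == id])), integer(1))
  } else {
    spans <- data.frame(cnvr_id = character(), chrom = character(),
                        start = numeric(), end = numeric(), length = numeric(),
                        category = character(), n_samples = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(spans) <- NULL
  structure(list(cnvrs = spans, members = members), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d CNVRs from %d CNV calls (%s)\n",
              nrow(x$cnvrs), nrow(x$members),
              paste(sprintf("%s=%d", names(table(x$cnvrs$category)),
                            as.integer(table(x$cnvrs$category))), collapse = ", ")))
  invisible(x)
}

#' Categorize a CNVR from its member genotypes
#'
#' DEL if every member copy number is 0 or 1; AMP if every member copy
#' number is >= 3; MIX otherwise.
#'
#' @param member_cn integer copy numbers of the member CNVs (non-empty).
#' @return "DEL", "AMP" or "MIX".
#' @export
categorize <- function(member_cn) {
  if (length(member_cn) == 0) .stopf("categorize: empty member set")
  if (all(member_cn < 2)) return("DEL")
  if (all(member_cn > 2)) return("AMP")
  "MIX"
}

#' Drop CNVRs observed in fewer than `min_samples` distinct samples
#'
#' @param cnvr_set a [cluster_cnvs()] result.
#' @param min_samples minimum number of distinct carrier samples (default 2:
#'   singleton CNVRs are removed).
#' @return filtered `cnvr_set`; the number removed is reported via `message`.
#' @export
filter_singletons <- function(cnvr_set, min_samples = 2) {
  keep <- cnvr_set$cnvrs$n_samples >= min_samples
  message(sprintf("filter_singletons: removed %d of %d CNVRs (< %d samples)",
                  sum(!keep), length(keep), min_samples))
  ids <- cnvr_set$cnvrs$cnvr_id[keep]
  .new_cnvr_set(cnvr_set$cnvrs[keep, c("cnvr_id", "chrom", "start", "end")],
                cnvr_set$members[cnvr_set$members$cnvr_id %in% ids, , drop = FALSE])
}

#' Assign per-sample CNVR genotypes by the largest-aggregate-width rule
#'
#' For each CNVR and each sample carrying member CNVs, member calls are
#' grouped by copy-number class; the class with the largest aggregate width
#' (sum of member lengths) becomes the sample's CNVR genotype. Ties go to
#' the class closest to CN2; a residual tie (equal |cn - 2|, e.g. CN1 vs
#' CN3) resolves to the lower copy number (the deletion). Samples with no
#' member CNV get the provisional reference genotype CN2 (see
#' [cn2_correction()]).
#'
#' @param cnvr_set a `cnvr_set`.
#' @param sample_ids all cohort samples (columns of the result).
#' @return integer matrix CNVRs x samples (rownames = cnvr_id), values 0-8.
#' @export
assign_genotypes <- function(cnvr_set, sample_ids) {
  cnvrs <- cnvr_set$cnvrs
  mem <- cnvr_set$members
  geno <- matrix(2L, nrow = nrow(cnvrs), ncol = length(sample_ids),
                 dimnames = list(cnvrs$cnvr_id, sample_ids))
  if (nrow(mem) == 0) return(geno)
  mem$width <- mem$end - mem$start + 1
  agg <- stats::aggregate(width ~ cnvr_id + sample + cn, data = mem, FUN = sum)
  for (key in split(agg, list(agg$cnvr_id, agg$sample), drop = TRUE)) {
    geno[key$cnvr_id[1], key$sample[1]] <- .pick_genotype(key$cn, key$width)
  }
  geno
}

# largest aggregate width; tie -> closest to CN2; residual tie -> lower cn
.pick_genotype <- function(cn, width) {
  best <- which(width == max(width))
  if (length(best) > 1) {
    d <- abs(cn[best] - 2)
    best <- best[d == min(d)]
    if (length(best) > 1) best <- best[which.min(cn[best])]
  }
  as.integer(cn[best])
}

#' CN2 correction: mark unsupported reference genotypes as CN_ (NA)
#'
#' The reciprocal-overlap criterion permits overlapping CNVRs, so a sample
#' with no CNV in one CNVR may still carry a CNV in an overlapping CNVR;
#' its provisional CN2 there is then unreliable. For each CNVR R and each
#' sample with provisional CN2 at R, the genotype becomes CN_ (encoded
#' `NA`) if the sample has a member CNV in any other CNVR overlapping R by
#' at least 1 bp. Samples with an assigned (non-CN2) genotype keep it. The
#' correction is idempotent.
#'
#' @param cnvr_set a `cnvr_set` (all CNVRs of one dataset, so the overlap
#'   structure is complete).
#' @param genotypes matrix from [assign_genotypes()].
#' @return the corrected genotype matrix (`NA` = CN_).
#' @export
cn2_correction <- function(cnvr_set, genotypes) {
  cnvrs <- cnvr_set$cnvrs
  if (nrow(cnvrs) < 2) return(genotypes)
  gr <- .as_granges(cnvrs)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh != sh
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh) == 0) return(genotypes)
  # carrier membership: cnvr x sample
  carrier <- matrix(FALSE, nrow(cnvrs), ncol(genotypes),
                    dimnames = dimnames(genotypes))
  idx <- cbind(match(cnvr_set$members$cnvr_id, cnvrs$cnvr_id),
               match(cnvr_set$members$sample, colnames(genotypes)))
  carrier[idx] <- TRUE
  for (r in unique(qh)) {
    nb <- sh[qh == r]
    elsewhere <- colSums(carrier[nb, , drop = FALSE]) > 0
    mask <- !carrier[r, ] & elsewhere & genotypes[r, ] == 2L & !is.na(genotypes[r, ])
    genotypes[r, mask] <- NA_integer_
  }
  genotypes
}

#' Merge CNVR sets across datasets
#'
#' `union` mode coalesces overlapping or bookended (end + 1 = start)
#' regions into a non-redundant region set and reports the total genome
#' length covered (and percentage, given a layout). `unique_coords` mode
#' deduplicates CNVRs on exact (chrom, start, end), counting regions with
#' identical coordinates across datasets only once.
#'
#' @param sets list of `cnvr_set` objects (or data.frames with `chrom`,
#'   `start`, `end`).
#' @param mode "union" or "unique_coords".
#' @param layout optional [genome_layout()] for percentage of genome.
#' @return list with `regions` (data.frame), `total_bp`, and `pct_genome`
#'   (union mode) or `n_unique` (unique_coords mode).
#' @export
merge_cnvr_sets <- function(sets, mode = c("union", "unique_coords"),
                            layout = NULL) {
  mode <- match.arg(mode)
  tabs <- lapply(sets, function(s)
    if (inherits(s, "cnvr_set")) s$cnvrs else s)
  all <- do.call(rbind, lapply(tabs, function(t)
    t[, c("chrom", "start", "end"), drop = FALSE]))
  if (mode == "union") {
    red <- GenomicRanges::reduce(.as_granges(all), min.gapwidth = 1L)
    regions <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
                          start = BiocGenerics::start(red),
                          end = BiocGenerics::end(red),
                          stringsAsFactors = FALSE)
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    rownames(regions) <- NULL
    total <- sum(regions$end - regions$start + 1)
    pct <- if (!is.null(layout)) 100 * total / sum(layout$chrom_lengths) else NA_real_
    list(regions = regions, total_bp = total, pct_genome = pct)
  } else {
    uni <- all[!duplicated(all[, c("chrom", "start", "end")]), , drop = FALSE]
    uni <- uni[order(uni$chrom, uni$start, uni$end), , drop = FALSE]
    rownames(uni) <- NULL
    list(regions = uni, n_unique = nrow(uni),
         total_bp = sum(uni$end - uni$start + 1))
  }
}
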