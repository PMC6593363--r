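#' Genotype-class counts for one CNVR
#'
#' Tabulates a genotype vector (integer copy numbers, `NA` = CN_) into a
#' named count vector `CN0` .. `CN8`; CN_ samples are excluded.
#'
#' @param genotypes integer vector of per-sample copy numbers.
#' @return named integer vector of length 9.
#' @export
genotype_counts <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  setNames(vapply(0:8, function(k) sum(g == k), integer(1)), paste0("CN", 0:8))
}

# normalize user-supplied counts (named CN0..CN8 or "0".."8") to length-9
.norm_counts <- function(counts) {
  out <- setNames(integer(9), paste0("CN", 0:8))
  nm <- names(counts)
  if (is.null(nm)) .stopf("genotype counts must be named (CN0..CN8)")
  nm <- ifelse(grepl("^CN", nm), nm, paste0("CN", nm))
  bad <- !(nm %in% names(out))
  if (any(bad)) .stopf("unknown genotype class(es): %s", paste(nm[bad], collapse = ", "))
  out[nm] <- out[nm] + as.integer(counts)
  out
}

#' Hardy-Weinberg chi-squared test on diallelic CNVR genotype counts
#'
#' A CNVR qualifies for the test iff its observed genotype classes are a
#' subset of {CN0, CN1, CN2} (deletion side: minor-allele homozygote,
#' heterozygote, reference homozygote) or of {CN2, CN3, CN4} (duplication
#' side), with at least two classes present; any other spectrum is
#' multi-allelic and not testable. The minor-allele frequency is estimated
#' from the counts and a Pearson goodness-of-fit statistic with 1 degree
#' of freedom compares observed counts to n * (q^2, 2pq, p^2). No
#' continuity correction is applied by default.
#'
#' @param counts named genotype counts (e.g. `c(CN0 = 25, CN1 = 50,
#'   CN2 = 25)`), or an integer genotype vector (then tabulated).
#' @param hwe_alpha significance threshold; the CNVR is "in HWE" iff the
#'   p-value is >= `hwe_alpha` (default 1e-5).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list of class `hwe_result`: `qualifies`, `reason`, `mapping`
#'   ("DEL" or "DUP" side), `q` (minor-allele frequency), `chi2`,
#'   `p_value`, `in_hwe`, `n`.
#' @examples
#' hwe_test(c(CN0 = 25, CN1 = 50, CN2 = 25))   # exact HWE, chi2 = 0
#' hwe_test(c(CN0 = 50, CN1 = 0, CN2 = 50))    # chi2 = 100, far from HWE
#' @export
hwe_test <- function(counts, hwe_alpha = 1e-5, correct = FALSE) {
  if (is.null(names(counts)) && length(counts) > 9)
    counts <- genotype_counts(counts)
  cnt <- .norm_counts(counts)
  present <- which(cnt > 0) - 1  # CN values present
  res <- list(qualifies = FALSE, reason = NA_character_,
              mapping = NA_character_, q = NA_real_, chi2 = NA_real_,
              p_value = NA_real_, in_hwe = NA, n = sum(cnt))
  class(res) <- "hwe_result"
  if (length(present) < 2) {
    res$reason <- "monomorphic"
    return(res)
  }
  if (all(present %in% 0:2)) {
    obs <- unname(cnt[c("CN0", "CN1", "CN2")])  # (aa, Aa, AA)
    res$mapping <- "DEL"
  } else if (all(present %in% 2:4)) {
    obs <- unname(cnt[c("CN4", "CN3", "CN2")])  # (aa, Aa, AA)
    res$mapping <- "DUP"
  } else {
    res$reason <- "multi-allelic"
    return(res)
  }
  n <- sum(obs)
  q <- (2 * obs[1] + obs[2]) / (2 * n)
  expd <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expd)
  res$qualifies <- TRUE
  res$q <- q
  res$chi2 <- chi2
  res$p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  res$in_hwe <- res$p_value >= hwe_alpha
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  if (!x$qualifies)
    cat(sprintf("HWE test: not qualified (%s)\n", x$reason))
  else
    cat(sprintf("HWE test (%s side): q = %.4f, chi2 = %.4g, p = %.3g, %s\n",
                x$mapping, x$q, x$chi2, x$p_value,
                if (x$in_hwe) "in HWE" else "NOT in HWE"))
  invisible(x)
}

#' Parity test on CNVR genotype counts
#'
#' Passes iff the number of samples with even copy-number genotypes
#' (CN0, CN2, CN4, CN6, CN8 — the homozygote-like classes) is at least the
#' number with odd genotypes (CN1, CN3, CN5, CN7 — heterozygote-like);
#' ties pass. Under Hardy-Weinberg proportions the homozygote classes are
#' expected to outnumber the heterozygotes (p^2 + q^2 >= 2pq).
#'
#' @param counts named genotype counts or an integer genotype vector.
#' @return logical (NA when no samples are genotyped), with attributes
#'   `"even"` and `"odd"`.
#' @export
parity_test <- function(counts) {
  if (is.null(names(counts)) && length(counts) > 9)
    counts <- genotype_counts(counts)
  cnt <- .norm_counts(counts)
  even <- sum(cnt[paste0("CN", c(0, 2, 4, 6, 8))])
  odd <- sum(cnt[paste0("CN", c(1, 3, 5, 7))])
  if (even + odd == 0) return(structure(NA, even = 0L, odd = 0L))
  structure(even >= odd, even = even, odd = odd)
}

#' Hierarchical clustering of samples by CNVR genotypes
#'
#' Distance between two samples is 1 minus the Spearman rank correlation
#' of their genotype vectors over CNVRs genotyped in both (CN_ is missing
#' and pairwise-excluded; ties get average ranks). Agglomeration uses the
#' ward.D2 convention (Ward criterion on squared distances). Pairs with no
#' shared genotyped CNVRs or an undefined correlation (a zero-variance
#' vector) get the maximum distance 2 with a warning. Samples are ordered
#' by id before clustering so the result is deterministic.
#'
#' @param genotypes CNVR x sample integer matrix (`NA` = CN_).
#' @return an `hclust` object.
#' @export
cluster_samples <- function(genotypes) {
  if (ncol(genotypes) < 2 || nrow(genotypes) < 2)
    .stopf("cluster_samples: need >= 2 samples and >= 2 CNVRs")
  genotypes <- genotypes[, order(colnames(genotypes)), drop = FALSE]
  rho <- suppressWarnings(
    cor(genotypes, method = "spearman", use = "pairwise.complete.obs"))
  if (any(is.na(rho))) {
    .warnf("cluster_samples: %d sample pair(s) with undefined Spearman correlation; distance set to 2",
           sum(is.na(rho[upper.tri(rho)])))
    rho[is.na(rho)] <- -1
  }
  d <- as.dist(1 - rho)
  hclust(d, method = "ward.D2")
}

#' Fraction of regions in A overlapping regions in B by at least 1 bp
#'
#' Asymmetric by construction: the denominator is the size of `a`.
#'
#' @param a,b CNVR tables or `cnvr_set`s (`chrom`, `start`, `end`).
#' @return proportion in [0, 1]; NA with a message if `a` is empty.
#' @export
overlap_fraction <- function(a, b) {
  ta <- if (inherits(a, "cnvr_set")) a$cnvrs else a
  tb <- if (inherits(b, "cnvr_set")) b$cnvrs else b
  if (nrow(ta) == 0) {
    message("overlap_fraction: empty query set; not applicable")
    return(NA_real_)
  }
  if (nrow(tb) == 0) return(0)
  n_ov <- sum(GenomicRanges::countOverlaps(.as_granges(ta), .as_granges(tb),
                                           ignore.strand = TRUE) > 0)
  n_ov / nrow(ta)
}

#' Breed-specific CNVRs
#'
#' A CNVR is specific to breed b iff at least `min_carriers` samples of b
#' carry it (genotype neither CN2 nor CN_) and no sample of any other
#' breed does.
#'
#' @param genotypes CNVR x sample genotype matrix.
#' @param meta sample metadata with `sample` and `breed`.
#' @param min_carriers minimum carriers within the breed (default 2).
#' @return data.frame `cnvr_id`, `breed`, `n_carriers`.
#' @export
breed_specific <- function(genotypes, meta, min_carriers = 2) {
  breed <- meta$breed[match(colnames(genotypes), meta$sample)]
  carrier <- !is.na(genotypes) & genotypes != 2L
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    b <- unique(breed[carrier[i, ]])
    if (length(b) != 1) return(NULL)
    n <- sum(carrier[i, ])
    if (n < min_carriers) return(NULL)
    data.frame(cnvr_id = rownames(genotypes)[i], breed = b, n_carriers = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cnvr_id = character(), breed = character(),
                      n_carriers = integer(), stringsAsFactors = FALSE)
  out
}

#' Per-chromosome CNVR density summary
#'
#' @param cnvr_set a `cnvr_set` (or CNVR table with `chrom` and
#'   `category`).
#' @param layout a [genome_layout()]; every CNVR chromosome must be known.
#' @return data.frame per chromosome: `n_cnvr`, `n_DEL`, `n_AMP`, `n_MIX`,
#'   `per_mb`.
#' @export
density_by_chromosome <- function(cnvr_set, layout) {
  tab <- if (inherits(cnvr_set, "cnvr_set")) cnvr_set$cnvrs else cnvr_set
  unknown <- setdiff(unique(tab$chrom), layout$chrom_names)
  if (length(unknown) > 0)
    .stopf("density_by_chromosome: unknown chromosome(s): %s",
           paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, n_cnvr = nrow(sub),
               n_DEL = sum(sub$category == "DEL"),
               n_AMP = sum(sub$category == "AMP"),
               n_MIX = sum(sub$category == "MIX"),
               per_mb = nrow(sub) / (layout$chrom_lengths[[ch]] / 1e6),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' HWE and parity tests over a genotype matrix
#'
#' Applies [hwe_test()] and [parity_test()] to every autosomal CNVR of a
#' genotype matrix (CN_ samples excluded per CNVR).
#'
#' @param cnvr_set the matching `cnvr_set` (for chromosome lookup).
#' @param genotypes CNVR x sample genotype matrix.
#' @param hwe_alpha HWE significance threshold (default 1e-5).
#' @return data.frame per CNVR: `cnvr_id`, `autosomal`, `qualifies`,
#'   `mapping`, `chi2`, `p_value`, `in_hwe`, `parity_pass`.
#' @export
cnvr_popgen_tests <- function(cnvr_set, genotypes, hwe_alpha = 1e-5) {
  cnvrs <- cnvr_set$cnvrs
  rows <- lapply(seq_len(nrow(cnvrs)), function(i) {
    id <- cnvrs$cnvr_id[i]
    auto <- is_autosome(cnvrs$chrom[i])
    cnt <- genotype_counts(genotypes[id, ])
    if (!auto) {
      return(data.frame(cnvr_id = id, autosomal = FALSE, qualifies = FALSE,
                        mapping = NA, chi2 = NA, p_value = NA, in_hwe = NA,
                        parity_pass = NA, stringsAsFactors = FALSE))
    }
    h <- hwe_test(cnt, hwe_alpha = hwe_alpha)
    data.frame(cnvr_id = id, autosomal = TRUE, qualifies = h$qualifies,
               mapping = h$mapping, chi2 = h$chi2, p_value = h$p_value,
               in_hwe = h$in_hwe, parity_pass = as.logical(parity_test(cnt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
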