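#' Annotate CNVRs with genes and gene sub-features
#'
#' A CNVR is associated with a gene iff it overlaps the gene body extended
#' by `flank` bp on both sides (clipped at position 1). Hits on the gene
#' body are further classified per sub-feature (CDS, UTR, exon, intron,
#' introns derived from exon gaps at parse time); flank-only hits are
#' labeled `upstream` or `downstream` relative to the gene's strand
#' (strandless genes get `left_flank`/`right_flank` with a warning).
#' Overlap labels combine the feature component with the CNVR category in
#' lower case, e.g. `"cds del"` — the searchable label of the database.
#'
#' @param cnvr_set a `cnvr_set` (or CNVR table).
#' @param track an `annotation_track` from [read_features_gff3()].
#' @param flank flank size in bp added to each gene (default 5e6; the 5-Mb
#'   default is unusually generous and deliberately configurable).
#' @return data.frame of overlap records: `cnvr_id`, `gene_id`,
#'   `feature_id`, `feature_kind`, `overlap_bp`, `overlap_label`.
#' @export
annotate_genes <- function(cnvr_set, track, flank = 5e6) {
  cnvrs <- if (inherits(cnvr_set, "cnvr_set")) cnvr_set$cnvrs else cnvr_set
  genes <- track[track$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0 || nrow(cnvrs) == 0) return(.empty_overlaps())
  ext <- genes
  ext$start <- pmax(1, genes$start - flank)
  ext$end <- genes$end + flank
  hits <- GenomicRanges::findOverlaps(.as_granges(cnvrs), .as_granges(ext),
                                      ignore.strand = TRUE)
  sub <- track[track$kind %in% c("CDS", "exon", "intron",
                                 "five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  kind_lab <- c(CDS = "cds", exon = "exon", intron = "intron",
                five_prime_UTR = "utr", three_prime_UTR = "utr")
  rows <- lapply(seq_along(hits), function(h) {
    ci <- S4Vectors::queryHits(hits)[h]
    gi <- S4Vectors::subjectHits(hits)[h]
    cat <- tolower(cnvrs$category[ci])
    body_ov <- .interval_overlap(cnvrs$start[ci], cnvrs$end[ci],
                                 genes$start[gi], genes$end[gi])
    recs <- list()
    if (body_ov >= 1) {
      recs[[1]] <- .ov_record(cnvrs$cnvr_id[ci], genes$feature_id[gi],
                              genes$feature_id[gi], "gene", body_ov,
                              paste("gene", cat))
      gsub <- sub[!is.na(sub$gene_id) & sub$gene_id == genes$feature_id[gi], , drop = FALSE]
      for (k in seq_len(nrow(gsub))) {
        ov <- .interval_overlap(cnvrs$start[ci], cnvrs$end[ci],
                                gsub$start[k], gsub$end[k])
        if (ov >= 1)
          recs[[length(recs) + 1]] <-
            .ov_record(cnvrs$cnvr_id[ci], genes$feature_id[gi],
                       gsub$feature_id[k], gsub$kind[k], ov,
                       paste(kind_lab[[gsub$kind[k]]], cat))
      }
    } else {
      left <- cnvrs$end[ci] < genes$start[gi]
      strand <- genes$strand[gi]
      if (!strand %in% c("+", "-")) {
        .warnf("annotate_genes: strandless gene %s; using left/right flank labels",
               genes$feature_id[gi])
        side <- if (left) "left_flank" else "right_flank"
      } else {
        side <- if ((left && strand == "+") || (!left && strand == "-"))
          "upstream" else "downstream"
      }
      flank_iv <- if (left) c(pmax(1, genes$start[gi] - flank), genes$start[gi] - 1)
                  else c(genes$end[gi] + 1, genes$end[gi] + flank)
      ov <- .interval_overlap(cnvrs$start[ci], cnvrs$end[ci],
                              flank_iv[1], flank_iv[2])
      recs[[1]] <- .ov_record(cnvrs$cnvr_id[ci], genes$feature_id[gi],
                              genes$feature_id[gi], side, ov,
                              paste(side, cat))
    }
    do.call(rbind, recs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_overlaps())
  out <- out[order(out$cnvr_id, out$feature_kind, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.interval_overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

.ov_record <- function(cnvr_id, gene_id, feature_id, kind, ov, label) {
  data.frame(cnvr_id = cnvr_id, gene_id = gene_id, feature_id = feature_id,
             feature_kind = kind, overlap_bp = ov, overlap_label = label,
             stringsAsFactors = FALSE)
}

.empty_overlaps <- function() {
  data.frame(cnvr_id = character(), gene_id = character(),
             feature_id = character(), feature_kind = character(),
             overlap_bp = numeric(), overlap_label = character(),
             stringsAsFactors = FALSE)
}

#' Annotate CNVRs with BED-like feature tracks
#'
#' Records every >= 1 bp overlap between CNVRs and features of
#' QTL/gap/repeat/segmental-duplication tracks. For assembly-gap tracks, a
#' record is flagged `boundary_in_gap` when a CNVR boundary lies inside
#' the gap — a caveat for boundary interpretation. The record set is a
#' pure function of the inputs (track order never matters); output is
#' sorted by (cnvr_id, feature_kind, feature_id).
#'
#' @param cnvr_set a `cnvr_set` or CNVR table.
#' @param tracks a list of [read_track()] data.frames.
#' @return data.frame: `cnvr_id`, `feature_id`, `feature_kind`,
#'   `overlap_bp`, `overlap_label`, `boundary_in_gap`.
#' @export
annotate_tracks <- function(cnvr_set, tracks) {
  cnvrs <- if (inherits(cnvr_set, "cnvr_set")) cnvr_set$cnvrs else cnvr_set
  rows <- lapply(tracks, function(tr) {
    if (nrow(tr) == 0 || nrow(cnvrs) == 0) return(NULL)
    hits <- GenomicRanges::findOverlaps(.as_granges(cnvrs), .as_granges(tr),
                                        ignore.strand = TRUE)
    ci <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
    if (length(ci) == 0) return(NULL)
    ov <- pmin(cnvrs$end[ci], tr$end[fi]) - pmax(cnvrs$start[ci], tr$start[fi]) + 1
    data.frame(cnvr_id = cnvrs$cnvr_id[ci], feature_id = tr$name[fi],
               feature_kind = tr$kind[fi], overlap_bp = ov,
               overlap_label = paste(tolower(tr$kind[fi]),
                                     tolower(cnvrs$category[ci])),
               boundary_in_gap = tr$kind[fi] == "gap" &
                 ((cnvrs$start[ci] >= tr$start[fi] & cnvrs$start[ci] <= tr$end[fi]) |
                    (cnvrs$end[ci] >= tr$start[fi] & cnvrs$end[ci] <= tr$end[fi])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(cbind(.empty_overlaps()[, c("cnvr_id", "feature_id", "feature_kind",
                                       "overlap_bp", "overlap_label")],
                 boundary_in_gap = logical()))
  out <- out[order(out$cnvr_id, out$feature_kind, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
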