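#' Read gene features from GFF3 with intron derivation
#'
#' Imports `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features (1-based inclusive, as in GFF3), resolves
#' parent-child relations up to the gene, and derives introns as the gaps
#' between consecutive exons of each transcript. Exons or CDS without a
#' resolvable parent transcript are kept (with a warning) but contribute no
#' introns.
#'
#' @param path GFF3 file.
#' @return object of class `annotation_track`: a data.frame with columns
#'   `feature_id`, `kind` (gene/mRNA/exon/CDS/five_prime_UTR/
#'   three_prime_UTR/intron), `chrom`, `start`, `end`, `strand`, `parent`,
#'   `gene_id`.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- c("gene", "mRNA", "transcript", "exon", "CDS",
            "five_prime_UTR", "three_prime_UTR")
  gr <- gr[as.character(gr$type) %in% keep]
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) >= 1) as.character(p[1]) else NA_character_, character(1))
  id <- as.character(gr$ID)
  no_id <- is.na(id) | id == ""
  id[no_id] <- sprintf("%s_%d", tolower(as.character(gr$type[no_id])),
                       which(no_id))
  feats <- data.frame(feature_id = id,
                      kind = as.character(gr$type),
                      chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      strand = as.character(BiocGenerics::strand(gr)),
                      parent = parent,
                      stringsAsFactors = FALSE)
  feats$kind[feats$kind == "transcript"] <- "mRNA"
  # resolve gene_id through at most two parent hops (exon -> mRNA -> gene)
  parent_of <- setNames(feats$parent, feats$feature_id)
  kind_of <- setNames(feats$kind, feats$feature_id)
  resolve_gene <- function(fid) {
    cur <- fid
    for (i in 1:3) {
      if (!is.na(kind_of[cur]) && kind_of[cur] == "gene") return(cur)
      nxt <- parent_of[cur]
      if (is.na(nxt) || !(nxt %in% names(kind_of))) return(NA_character_)
      cur <- nxt
    }
    NA_character_
  }
  feats$gene_id <- vapply(feats$feature_id, resolve_gene, character(1))
  orphan <- feats$kind %in% c("exon", "CDS") &
    (is.na(feats$parent) | !(feats$parent %in% feats$feature_id))
  if (any(orphan))
    .warnf("%d exon/CDS feature(s) without a resolvable parent; kept without intron derivation",
           sum(orphan))
  introns <- .derive_introns(feats)
  out <- rbind(feats, introns)
  rownames(out) <- NULL
  structure(out, class = c("annotation_track", "data.frame"))
}

# gaps between consecutive exons of each parented transcript
.derive_introns <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$parent) &
                feats$parent %in% feats$feature_id, , drop = FALSE]
  if (nrow(ex) == 0) return(feats[0, , drop = FALSE])
  pieces <- lapply(split(ex, ex$parent), function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 2) return(NULL)
    istart <- tx$end[-nrow(tx)] + 1
    iend <- tx$start[-1] - 1
    ok <- istart <= iend
    if (!any(ok)) return(NULL)
    data.frame(feature_id = sprintf("%s_intron%d", tx$parent[1], which(ok)),
               kind = "intron", chrom = tx$chrom[1],
               start = istart[ok], end = iend[ok],
               strand = tx$strand[1], parent = tx$parent[1],
               gene_id = tx$gene_id[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) feats[0, , drop = FALSE] else out
}
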