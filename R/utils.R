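#' @importFrom stats median quantile prcomp mad ppois pchisq pbinom rbinom
#'   rpois runif cor hclust as.dist cutree setNames rnbinom complete.cases
#' @importFrom utils read.delim write.csv read.csv head modifyList
NULL

# modal value of an integer vector (smallest wins ties)
.modal <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# CN integer <-> label; NA encodes CN_ (undetermined after CN2 correction)
cn_label <- function(cn) ifelse(is.na(cn), "CN_", paste0("CN", cn))

cn_from_label <- function(lab) {
  out <- suppressWarnings(as.integer(sub("^CN", "", lab)))
  out[lab == "CN_"] <- NA_integer_
  out
}

#' Is a chromosome an autosome?
#'
#' Sex chromosomes and mitochondria are excluded from the Hardy-Weinberg and
#' parity tests, which assume diploid autosomal genotypes.
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
is_autosome <- function(chrom) {
  core <- sub("^[Cc]hr", "", chrom)
  !(toupper(core) %in% c("X", "Y", "M", "MT", "W", "Z"))
}

# required-column check for parsed tables
.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    .stopf("%s: missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(TRUE)
}

# deterministic seed derivation for sub-streams; keeps results < 2^31
.derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 12347L) %% 2147483647L
}
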