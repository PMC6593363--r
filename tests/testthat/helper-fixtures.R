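# Shared fixture builders: cohorts are always generated in code, never
# stored on disk.

# count matrix with planted per-sample CNV events at exact expectations
# events: data.frame(sample, win_start (1-based window index), n_win, cn)
planted_matrix <- function(n_samples = 20, n_windows = 2000, wl = 1000,
                           lambda = 100, events = NULL,
                           noise = c("none", "poisson"), seed = 1,
                           chrom = "chr1") {
  noise <- match.arg(noise)
  layout <- genome_layout(setNames(n_windows * wl, chrom), wl)
  samples <- sprintf("S%02d", seq_len(n_samples))
  lam <- matrix(lambda, nrow = n_windows, ncol = n_samples,
                dimnames = list(NULL, samples))
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      w <- events$win_start[i]:(events$win_start[i] + events$n_win[i] - 1)
      lam[w, events$sample[i]] <- lambda * events$cn[i] / 2
    }
  }
  counts <- if (noise == "none") lam else {
    set.seed(seed)
    matrix(rpois(length(lam), lam), nrow = n_windows,
           dimnames = dimnames(lam))
  }
  new_read_count_matrix(layout, counts, samples)
}

# brute-force O(n^2) reciprocal-overlap connected components (the oracle
# cluster_cnvs must match); returns an integer partition label per call
brute_force_components <- function(calls, ro = 0.5) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    fr <- reciprocal_overlap(calls[i, ], calls[j, ])
    adj[i, j] <- fr[1] >= ro && fr[2] >= ro
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        lab <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random interval micro-instance on one or two chromosomes
random_calls <- function(n, seed) {
  set.seed(seed)
  start <- (sample(0:60, n, replace = TRUE)) * 1000 + 1
  len <- sample(3:12, n, replace = TRUE) * 1000
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + len - 1,
             sample = sprintf("S%02d", sample(1:8, n, replace = TRUE)),
             cn = sample(c(0, 1, 3, 4), n, replace = TRUE),
             dataset = "d1", stringsAsFactors = FALSE)
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(i) length(unique(b[i])) == 1)) &&
    length(unique(a)) == length(unique(b))
}

# minimal cnvr_set built directly from a call table (via the real pipeline)
make_cnvr_set <- function(calls, min_samples = 1) {
  cs <- cluster_cnvs(calls)
  if (min_samples > 1)
    cs <- suppressMessages(filter_singletons(cs, min_samples))
  cs
}

call_row <- function(chrom, start, end, sample, cn, dataset = "d1") {
  data.frame(chrom = chrom, start = start, end = end, sample = sample,
             cn = cn, dataset = dataset, stringsAsFactors = FALSE)
}

# collect internal link/image targets of an HTML file
html_refs <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, gregexpr('(href|src)="[^"]+"', txt))[[1]]
  refs <- sub('^(href|src)="', "", sub('"$', "", m))
  refs[!grepl("^(https?:|mailto:|#)", refs)]
}

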