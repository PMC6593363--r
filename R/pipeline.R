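#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one place, with the defaults
#' used throughout: 1 kb windows, calls require 3 adjacent significant
#' windows, CNVRs need 50% pairwise reciprocal overlap and at least 2
#' carrier samples, QC fences are 1.5 x IQR, the HWE threshold is P >=
#' 1e-5, gene annotation flanks are 5 Mb, and the database's default
#' filters are 1 kb - 3 Mb length and 2 samples with up to 3 depth plots
#' per genotype.
#'
#' @param ... overrides for any default (e.g. `gene_flank = 5000`).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(window_length = 1000, min_adjacent_windows = 3,
              reciprocal_overlap = 0.5, iqr_multiplier = 1.5,
              alpha = 1e-3, hwe_alpha = 1e-5, gene_flank = 5e6,
              min_samples_per_cnvr = 2, k_mad = 6,
              report_length_filter = c(1000, 3e6), report_min_samples = 2,
              samples_per_genotype_plot = 3, rng_seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    .stopf("pipeline_config: unknown option(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  num <- unlist(cfg[c("window_length", "min_adjacent_windows", "iqr_multiplier",
                      "alpha", "hwe_alpha", "gene_flank", "min_samples_per_cnvr",
                      "k_mad", "samples_per_genotype_plot")])
  if (any(num <= 0)) .stopf("pipeline_config: thresholds must be strictly positive")
  if (cfg$reciprocal_overlap <= 0 || cfg$reciprocal_overlap > 1)
    .stopf("pipeline_config: reciprocal_overlap must be in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the CNVR pipeline dataset-wise
#'
#' Executes, per dataset: CNV calling (when the dataset provides a count
#' matrix; externally provided call tables are used as-is), sample QC and
#' removal of problematic samples, CNVR construction with singleton
#' filtering, genotype assignment with CN2 correction, HWE/parity tests,
#' optional annotation, and the HTML database; then a cross-dataset
#' summary (non-redundant merged regions and unique-coordinate CNVR
#' count). Datasets are processed strictly separately — mixing samples of
#' different datasets into one calling/QC group is refused unless
#' `allow_combined = TRUE` (batch effects corrupt cross-dataset read-depth
#' comparison) — and a manifest with the seed, configuration hash and
#' per-artifact checksums makes reruns verifiable.
#'
#' @param datasets named list; each element a list with `counts` (a
#'   `read_count_matrix`) or `calls` (a call data.frame).
#' @param meta cohort metadata covering every sample.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @param annotation optional list with elements `genes` (an
#'   `annotation_track`) and/or `tracks` (list of [read_track()] tables).
#' @param allow_combined permit a dataset whose samples span multiple
#'   metadata datasets (logged warning).
#' @param build_report write the HTML database per dataset (default TRUE).
#' @return list per dataset with `calls`, `qc`, `cnvr_set`, `genotypes`,
#'   `tests`, plus `merged` (union regions) and `unique_coords` summary;
#'   `manifest` holds the provenance record (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(datasets, meta, outdir, config = pipeline_config(),
                         annotation = NULL, allow_combined = FALSE,
                         build_report = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (ds in names(datasets)) {
    dsdir <- file.path(outdir, ds)
    dir.create(dsdir, showWarnings = FALSE)
    input <- datasets[[ds]]
    norm <- NULL
    if (!is.null(input$counts)) {
      ds_of <- unique(meta$dataset[match(input$counts$sample_ids, meta$sample)])
      if (length(ds_of) > 1) {
        if (!allow_combined)
          .stopf(paste0("run_pipeline: dataset '%s' mixes samples from metadata datasets %s; ",
                        "batch effects corrupt multi-sample read-depth calling. ",
                        "Set allow_combined = TRUE to override."),
                 ds, paste(ds_of, collapse = ", "))
        .warnf("run_pipeline: combining datasets %s in one calling group; batch effects likely",
               paste(ds_of, collapse = ", "))
      }
      norm <- normalize_counts(input$counts)
      wcn <- estimate_window_cn(norm, alpha = config$alpha)
      calls <- segment_calls(wcn, config$min_adjacent_windows, dataset_id = ds)
    } else if (!is.null(input$calls)) {
      calls <- input$calls
      calls$dataset <- ds
    } else {
      .stopf("run_pipeline: dataset '%s' has neither counts nor calls", ds)
    }
    m <- if (any(meta$dataset == ds)) meta[meta$dataset == ds, , drop = FALSE]
         else meta[meta$sample %in% unique(c(calls$sample,
                                             if (!is.null(norm)) norm$sample_ids)), ,
                   drop = FALSE]
    if (!is.null(norm))
      m <- m[m$sample %in% norm$sample_ids, , drop = FALSE]
    m$dataset <- ds
    qc <- qc_report(calls, m,
                    norm_matrices = if (!is.null(norm)) setNames(list(norm), ds),
                    iqr_multiplier = config$iqr_multiplier,
                    k_mad = config$k_mad)
    filtered <- apply_qc(calls, m, qc)
    cs <- cluster_cnvs(filtered$calls, ro = config$reciprocal_overlap)
    cs <- filter_singletons(cs, min_samples = config$min_samples_per_cnvr)
    keep_samples <- filtered$meta$sample[filtered$meta$qc_pass]
    geno <- assign_genotypes(cs, keep_samples)
    geno <- cn2_correction(cs, geno)
    tests <- if (nrow(cs$cnvrs) > 0) cnvr_popgen_tests(cs, geno, config$hwe_alpha)
             else NULL
    overlaps <- NULL
    if (!is.null(annotation)) {
      parts <- list()
      if (!is.null(annotation$genes))
        parts$genes <- annotate_genes(cs, annotation$genes,
                                      flank = config$gene_flank)
      if (!is.null(annotation$tracks))
        parts$tracks <- annotate_tracks(cs, annotation$tracks)
      overlaps <- .rbind_overlaps(parts)
    }
    write_cnv_calls(filtered$calls, file.path(dsdir, "calls.tsv"))
    write.csv(qc, file.path(dsdir, "qc_report.csv"), row.names = FALSE)
    if (nrow(cs$cnvrs) > 0)
      write_cnvr_table(cs, geno, file.path(dsdir, "cnvrs.csv"))
    if (!is.null(tests))
      write.csv(tests, file.path(dsdir, "hwe_parity.csv"), row.names = FALSE)
    if (build_report)
      build_database(cs, geno, filtered$meta[filtered$meta$qc_pass, ],
                     overlaps = overlaps, tests = tests, counts = norm,
                     outdir = file.path(dsdir, "db"),
                     seed = config$rng_seed,
                     length_filter = config$report_length_filter,
                     min_samples = config$report_min_samples,
                     per_genotype = config$samples_per_genotype_plot)
    results[[ds]] <- list(calls = filtered$calls, qc = qc, cnvr_set = cs,
                          genotypes = geno, tests = tests, overlaps = overlaps)
  }
  sets <- lapply(results, `[[`, "cnvr_set")
  layout <- NULL
  for (ds in names(datasets))
    if (!is.null(datasets[[ds]]$counts)) layout <- datasets[[ds]]$counts$layout
  results$merged <- merge_cnvr_sets(sets, mode = "union", layout = layout)
  results$unique_coords <- merge_cnvr_sets(sets, mode = "unique_coords")
  results$manifest <- .write_manifest(outdir, config)
  results
}

.rbind_overlaps <- function(parts) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, parts)
  if (length(parts) == 0) return(NULL)
  cols <- Reduce(intersect, lapply(parts, names))
  out <- do.call(rbind, lapply(parts, function(p) p[, cols, drop = FALSE]))
  rownames(out) <- NULL
  out
}

# provenance record: config hash, seed, package version, artifact checksums
.write_manifest <- function(outdir, config) {
  cfg_file <- tempfile()
  dput(unclass(config), cfg_file)
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "cnvrdb",
    version = as.character(utils::packageVersion("cnvrdb")),
    seed = config$rng_seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    artifacts = as.list(setNames(unname(sums),
                                 sub(paste0("^", outdir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(cfg_file)
  manifest
}
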