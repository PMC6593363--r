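.html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

.html_table <- function(df, id = NULL, links = NULL) {
  idattr <- if (is.null(id)) "" else sprintf(' id="%s"', id)
  head <- paste0("<tr>", paste0("<th>", .html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j) {
      v <- .html_escape(as.character(df[i, j]))
      if (!is.null(links) && names(df)[j] == links$column)
        v <- sprintf('<a href="%s">%s</a>', links$href[i], v)
      paste0("<td>", v, "</td>")
    }, character(1))
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0('<table class="tbl"', idattr, ">\n<thead>", head, "</thead>\n<tbody>\n",
         paste(rows, collapse = "\n"), "\n</tbody></table>\n")
}

.page <- function(title, body, css_rel = "") {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">\n<title>",
         .html_escape(title), "</title>\n<style>\n",
         "body{font-family:sans-serif;margin:1em 2em;color:#222}\n",
         ".panel{border:1px solid #ccc;border-radius:6px;padding:0.8em 1em;margin:1em 0}\n",
         ".panel h2{margin-top:0;font-size:1.1em}\n",
         "table.tbl{border-collapse:collapse;font-size:0.85em}\n",
         "table.tbl th,table.tbl td{border:1px solid #ddd;padding:2px 8px}\n",
         "table.tbl th{background:#f0f4f8}\n",
         "input{margin:2px}\n",
         "</style></head><body>\n", body, "\n</body></html>\n")
}

#' Seeded per-genotype read-depth plots for one CNVR
#'
#' For each observed genotype class of the CNVR, up to `per_genotype`
#' carrier samples are chosen by seeded sampling without replacement and a
#' per-window normalized depth trace (CNVR span highlighted, reference
#' rate dashed, assembly gaps shaded) is written as an SVG. This replaces
#' read-alignment screenshots: the pipeline's input is the count matrix,
#' and the purpose — visual verification of depth support — is preserved.
#'
#' @param cnvr one row of a CNVR table.
#' @param norm a normalized `read_count_matrix` covering the CNVR.
#' @param genotypes genotype matrix (to pick carriers per class).
#' @param outdir output directory for the SVG files.
#' @param per_genotype max samples per genotype class (default 3).
#' @param seed RNG seed; the selection is deterministic given the seed.
#' @param flank_windows windows of context either side (default 10).
#' @param gaps optional assembly-gap track.
#' @return data.frame `genotype`, `sample`, `file`.
#' @export
plot_genotype_coverage <- function(cnvr, norm, genotypes, outdir,
                                   per_genotype = 3, seed = 17,
                                   flank_windows = 10, gaps = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- genotypes[cnvr$cnvr_id, ]
  classes <- sort(unique(g[!is.na(g) & g != 2L]))
  win <- norm$windows
  sel <- win$chrom == cnvr$chrom &
    win$end >= cnvr$start - flank_windows * norm$layout$window_length &
    win$start <= cnvr$end + flank_windows * norm$layout$window_length
  lam <- apply(norm$counts[sel, , drop = FALSE], 1, median)
  set.seed(seed)
  rows <- list()
  for (cls in classes) {
    carriers <- names(g)[!is.na(g) & g == cls]
    if (length(carriers) == 0) next
    chosen <- if (length(carriers) <= per_genotype) sort(carriers)
              else sort(sample(carriers, per_genotype))
    for (s in chosen) {
      svg <- .svg_depth_plot(pos = (win$start[sel] + win$end[sel]) / 2,
                             depth = norm$counts[sel, s],
                             cnvr_start = cnvr$start, cnvr_end = cnvr$end,
                             lambda = stats::median(lam),
                             gaps = if (!is.null(gaps))
                               gaps[gaps$chrom == cnvr$chrom, , drop = FALSE],
                             title = sprintf("%s %s (CN%d)", cnvr$cnvr_id, s, cls))
      f <- file.path(outdir, sprintf("%s_CN%d_%s.svg", cnvr$cnvr_id, cls, s))
      writeLines(svg, f)
      rows[[length(rows) + 1]] <- data.frame(genotype = cls, sample = s,
                                             file = basename(f),
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(genotype = integer(), sample = character(),
                      file = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build the self-contained interactive HTML CNVR database
#'
#' Writes a static directory openable from disk in a browser: an index
#' page with a Filters panel (defaults: CNVR length 1 kb - 3 Mb, minimum
#' 2 samples, sample-exclusion regular expression), a Statistics panel
#' with pre-/post-filter summaries, and searchable CNVR / Overlapping
#' Genes / QTL / Samples tables with CSV export; one detail page per CNVR
#' with Summary, Genotype distribution and Breed distribution bar plots,
#' overlap records, HWE/parity results, a per-sample genotype list, an
#' external genome-browser URL, and (when a count matrix is supplied)
#' seeded per-genotype depth plots. Favorites and comments are handled
#' client-side and can be exported to a text file. All assets are local.
#'
#' @param cnvr_set a `cnvr_set`.
#' @param genotypes corrected genotype matrix.
#' @param meta sample metadata.
#' @param overlaps optional annotation records ([annotate_genes()] /
#'   [annotate_tracks()] output, possibly rbind-ed with shared columns).
#' @param tests optional [cnvr_popgen_tests()] output.
#' @param counts optional normalized `read_count_matrix` for depth plots.
#' @param outdir output directory (created).
#' @param seed seed for depth-plot sample selection.
#' @param length_filter default length filter `c(min, max)` in bp.
#' @param min_samples default minimum-samples filter.
#' @param per_genotype max depth plots per genotype class.
#' @param gaps optional assembly-gap track for plot shading.
#' @param browser_url_template sprintf template with `%s` chrom, `%d`
#'   start, `%d` end for the external genome viewer link.
#' @return the output directory, invisibly.
#' @export
build_database <- function(cnvr_set, genotypes, meta, overlaps = NULL,
                           tests = NULL, counts = NULL, outdir,
                           seed = 17, length_filter = c(1000, 3e6),
                           min_samples = 2, per_genotype = 3, gaps = NULL,
                           browser_url_template = paste0(
                             "https://www.ncbi.nlm.nih.gov/genome/gdv/browser/",
                             "genome/?chr=%s&from=%d&to=%d")) {
  dir.create(file.path(outdir, "cnvr"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "csv"), showWarnings = FALSE)
  dir.create(file.path(outdir, "img"), showWarnings = FALSE)
  tab <- cnvr_table(cnvr_set, genotypes)
  write_cnvr_table(cnvr_set, genotypes, file.path(outdir, "csv", "cnvrs.csv"))
  gdf <- data.frame(cnvr_id = rownames(genotypes),
                    as.data.frame(matrix(cn_label(genotypes),
                                         nrow = nrow(genotypes),
                                         dimnames = dimnames(genotypes)),
                                  check.names = FALSE))
  write.csv(gdf, file.path(outdir, "csv", "genotypes.csv"), row.names = FALSE)
  write.csv(meta, file.path(outdir, "csv", "samples.csv"), row.names = FALSE)
  if (!is.null(overlaps))
    write.csv(overlaps, file.path(outdir, "csv", "overlaps.csv"), row.names = FALSE)

  for (i in seq_len(nrow(tab)))
    .write_detail_page(tab[i, ], cnvr_set, genotypes, meta, overlaps, tests,
                       counts, outdir, seed, per_genotype, gaps,
                       browser_url_template)
  .write_index_page(tab, meta, overlaps, outdir, length_filter, min_samples)
  invisible(outdir)
}

#' Filter summary statistics for a CNVR table
#'
#' The exact arithmetic behind the database's Statistics panel: CNVRs
#' passing the length and minimum-samples filters, counted in total and
#' per category, with the total span. The index page's client-side filter
#' recomputes the same quantities in the browser.
#'
#' @param tab a [cnvr_table()] data.frame.
#' @param min_len,max_len length filter bounds in bp.
#' @param min_samples minimum carrier samples.
#' @return list with `n`, `n_DEL`, `n_AMP`, `n_MIX`, `total_bp`.
#' @export
filter_stats <- function(tab, min_len = 0, max_len = Inf, min_samples = 0) {
  keep <- tab$length >= min_len & tab$length <= max_len &
    tab$n_samples >= min_samples
  sub <- tab[keep, , drop = FALSE]
  list(n = nrow(sub), n_DEL = sum(sub$category == "DEL"),
       n_AMP = sum(sub$category == "AMP"), n_MIX = sum(sub$category == "MIX"),
       total_bp = sum(sub$length))
}

.write_index_page <- function(tab, meta, overlaps, outdir, length_filter,
                              min_samples) {
  n <- nrow(tab)
  fs <- filter_stats(tab)
  stats_pre <- sprintf(
    "%d CNVRs (%d DEL, %d AMP, %d MIX); total span %.3f Mb; median length %s bp",
    fs$n, fs$n_DEL, fs$n_AMP, fs$n_MIX, fs$total_bp / 1e6,
    if (n > 0) format(stats::median(tab$length), big.mark = ",") else "0")
  filters <- paste0(
    '<div class="panel"><h2>Filters</h2>',
    sprintf('Length min <input id="fmin" type="number" value="%d"> ', length_filter[1]),
    sprintf('max <input id="fmax" type="number" value="%d"> ', length_filter[2]),
    sprintf('Min samples <input id="fns" type="number" value="%d"> ', min_samples),
    'Exclude samples (regex) <input id="fex" type="text"> ',
    '<button onclick="applyFilters()">Apply</button>',
    '<button onclick="exportCSV(\'cnvrs\')">Export CSV</button>',
    '<button onclick="saveSettings()">Save settings</button></div>')
  stats <- paste0('<div class="panel"><h2>Statistics</h2>',
                  "<p>Before filters: ", .html_escape(stats_pre), "</p>",
                  '<p>After filters: <span id="poststats"></span></p></div>')
  if (n > 0) {
    dtab <- tab[, c("cnvr_id", "chrom", "start", "end", "length", "category",
                    "n_samples")]
    cn_cols <- grep("^n_CN", names(tab), value = TRUE)
    dtab$genotype_counts <- apply(tab[, cn_cols, drop = FALSE], 1, function(r) {
      k <- r > 0
      paste(sprintf("%s=%d", sub("^n_", "", cn_cols[k]), r[k]), collapse = " ")
    })
    cnvr_html <- .html_table(dtab, id = "cnvrs",
                             links = list(column = "cnvr_id",
                                          href = sprintf("cnvr/%s.html", dtab$cnvr_id)))
  } else {
    cnvr_html <- "<p><em>No CNVRs to display.</em></p>"
  }
  cnvrs <- paste0('<div class="panel"><h2>CNVRs</h2>',
                  'Search <input id="scnvr" onkeyup="filterTable(\'scnvr\',\'cnvrs\')">',
                  cnvr_html, "</div>")
  gpanel <- qpanel <- ""
  if (!is.null(overlaps) && nrow(overlaps) > 0) {
    genes <- overlaps[overlaps$feature_kind %in%
                        c("gene", "CDS", "exon", "intron", "five_prime_UTR",
                          "three_prime_UTR", "upstream", "downstream",
                          "left_flank", "right_flank"), , drop = FALSE]
    if (nrow(genes) > 0)
      gpanel <- paste0('<div class="panel"><h2>Overlapping Genes</h2>',
                       'Search <input id="sg" onkeyup="filterTable(\'sg\',\'genes\')">',
                       '<button onclick="exportCSV(\'genes\')">Export CSV</button>',
                       .html_table(genes, id = "genes",
                                   links = list(column = "cnvr_id",
                                                href = sprintf("cnvr/%s.html",
                                                               genes$cnvr_id))),
                       "</div>")
    qtls <- overlaps[overlaps$feature_kind == "QTL", , drop = FALSE]
    if (nrow(qtls) > 0)
      qpanel <- paste0('<div class="panel"><h2>QTLs</h2>',
                       'Search <input id="sq" onkeyup="filterTable(\'sq\',\'qtls\')">',
                       .html_table(qtls, id = "qtls",
                                   links = list(column = "cnvr_id",
                                                href = sprintf("cnvr/%s.html",
                                                               qtls$cnvr_id))),
                       "</div>")
  }
  spanel <- paste0('<div class="panel"><h2>Samples</h2>',
                   'Search <input id="ss" onkeyup="filterTable(\'ss\',\'samples\')">',
                   .html_table(meta, id = "samples"), "</div>")
  js <- .index_js()
  body <- paste0("<h1>CNVR database</h1>\n", filters, stats, cnvrs, gpanel,
                 qpanel, spanel, js)
  writeLines(.page("CNVR database", body), file.path(outdir, "index.html"))
}

.index_js <- function() {
  paste0("<script>\n",
"function filterTable(inp, tid){\n",
"  var q=document.getElementById(inp).value.toLowerCase();\n",
"  var rows=document.getElementById(tid).tBodies[0].rows;\n",
"  for(var i=0;i<rows.length;i++){\n",
"    rows[i].style.display = rows[i].textContent.toLowerCase().indexOf(q)>=0?'':'none';\n",
"  }\n}\n",
"function applyFilters(){\n",
"  var mn=+document.getElementById('fmin').value, mx=+document.getElementById('fmax').value;\n",
"  var ns=+document.getElementById('fns').value, ex=document.getElementById('fex').value;\n",
"  var re=ex?new RegExp(ex):null;\n",
"  var t=document.getElementById('cnvrs'); if(!t){return;}\n",
"  var rows=t.tBodies[0].rows, shown=0, del=0, amp=0, mix=0, bp=0;\n",
"  for(var i=0;i<rows.length;i++){\n",
"    var len=+rows[i].cells[4].textContent, n=+rows[i].cells[6].textContent;\n",
"    var cat=rows[i].cells[5].textContent;\n",
"    var ok=len>=mn && len<=mx && n>=ns;\n",
"    rows[i].style.display=ok?'':'none';\n",
"    if(ok){shown++; bp+=len; if(cat=='DEL')del++; else if(cat=='AMP')amp++; else mix++;}\n",
"  }\n",
"  document.getElementById('poststats').textContent =\n",
"    shown+' CNVRs ('+del+' DEL, '+amp+' AMP, '+mix+' MIX); total span '+(bp/1e6).toFixed(3)+' Mb';\n",
"}\n",
"function exportCSV(tid){\n",
"  var t=document.getElementById(tid); if(!t){return;}\n",
"  var out=[], rows=t.rows;\n",
"  for(var i=0;i<rows.length;i++){\n",
"    if(rows[i].style.display=='none') continue;\n",
"    var cells=rows[i].cells, line=[];\n",
"    for(var j=0;j<cells.length;j++) line.push('\"'+cells[j].textContent.replace(/\"/g,'\"\"')+'\"');\n",
"    out.push(line.join(','));\n",
"  }\n",
"  var a=document.createElement('a');\n",
"  a.href=URL.createObjectURL(new Blob([out.join('\\n')],{type:'text/csv'}));\n",
"  a.download=tid+'.csv'; a.click();\n",
"}\n",
"function saveSettings(){\n",
"  var s={min:document.getElementById('fmin').value,max:document.getElementById('fmax').value,\n",
"         ns:document.getElementById('fns').value,ex:document.getElementById('fex').value,\n",
"         favorites:window._favs||[],comments:window._comments||{}};\n",
"  var a=document.createElement('a');\n",
"  a.href=URL.createObjectURL(new Blob([JSON.stringify(s,null,1)],{type:'text/plain'}));\n",
"  a.download='cnvrdb_settings.txt'; a.click();\n",
"}\n",
"applyFilters();\n",
"</script>\n")
}

.write_detail_page <- function(row, cnvr_set, genotypes, meta, overlaps,
                               tests, counts, outdir, seed, per_genotype,
                               gaps, browser_url_template) {
  id <- row$cnvr_id
  g <- genotypes[id, ]
  cnt <- genotype_counts(g)
  cnt_show <- cnt[cnt > 0]
  n_un <- sum(is.na(g))
  if (n_un > 0) cnt_show <- c(cnt_show, "CN_" = n_un)
  summ <- sprintf(
    "<p>%s:%s-%s (%s bp), category %s, detected in %d sample(s).</p>",
    row$chrom, format(row$start, big.mark = ","),
    format(row$end, big.mark = ","), format(row$length, big.mark = ","),
    row$category, row$n_samples)
  url <- sprintf(browser_url_template, row$chrom, as.integer(row$start),
                 as.integer(row$end))
  gsvg <- .svg_barplot(cnt_show, title = "samples per genotype")
  breed <- meta$breed[match(names(g), meta$sample)]
  carriers <- !is.na(g) & g != 2L
  bcnt <- table(breed[carriers])
  bsvg <- .svg_barplot(setNames(as.integer(bcnt), names(bcnt)),
                       fill = "#4a9c4a", title = "non-CN2 carriers per breed")
  ovhtml <- ""
  if (!is.null(overlaps)) {
    sub <- overlaps[overlaps$cnvr_id == id, , drop = FALSE]
    if (nrow(sub) > 0)
      ovhtml <- paste0('<div class="panel"><h2>Overlapping genes, QTLs, and features</h2>',
                       .html_table(sub), "</div>")
  }
  thtml <- ""
  if (!is.null(tests)) {
    tr <- tests[tests$cnvr_id == id, , drop = FALSE]
    if (nrow(tr) == 1) {
      hwe_txt <- if (!isTRUE(tr$qualifies))
        "HWE test: not applicable (multi-allelic, monomorphic or non-autosomal)"
      else sprintf("HWE test (%s side): chi2 = %.4g, P = %.3g — %s",
                   tr$mapping, tr$chi2, tr$p_value,
                   if (isTRUE(tr$in_hwe)) "in HWE" else "NOT in HWE")
      par_txt <- if (is.na(tr$parity_pass)) "Parity test: not evaluated"
                 else sprintf("Parity test: %s",
                              if (tr$parity_pass) "pass" else "fail")
      thtml <- paste0('<div class="panel"><h2>Genotype proportion tests</h2><p>',
                      .html_escape(hwe_txt), "</p><p>", .html_escape(par_txt),
                      "</p></div>")
    }
  }
  imghtml <- ""
  if (!is.null(counts)) {
    plots <- plot_genotype_coverage(row, counts, genotypes,
                                    file.path(outdir, "img"),
                                    per_genotype = per_genotype,
                                    seed = .derive_seed(seed, match(id, rownames(genotypes))),
                                    gaps = gaps)
    if (nrow(plots) > 0)
      imghtml <- paste0('<div class="panel"><h2>Read-depth plots</h2>',
                        paste(sprintf('<img src="../img/%s" alt="%s CN%d">',
                                      plots$file, plots$sample, plots$genotype),
                              collapse = "\n"), "</div>")
  }
  stab <- data.frame(sample = names(g), breed = breed, genotype = cn_label(g),
                     stringsAsFactors = FALSE)
  body <- paste0(
    sprintf("<h1>%s</h1>\n", id),
    '<p><a href="../index.html">&larr; back to index</a></p>',
    '<div class="panel"><h2>Summary</h2>', summ,
    sprintf('<p><a href="%s">View region in NCBI Genome Data Viewer</a></p>', url),
    "</div>",
    '<div class="panel"><h2>Genotype distribution</h2>', gsvg, "</div>",
    '<div class="panel"><h2>Breed distribution</h2>', bsvg, "</div>",
    thtml, ovhtml, imghtml,
    '<div class="panel"><h2>Sample list</h2>', .html_table(stab), "</div>")
  writeLines(.page(id, body), file.path(outdir, "cnvr", paste0(id, ".html")))
}
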