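test_that("window tiling is 1-based inclusive with flagged partial tail", {
  gl <- genome_layout(c(chr1 = 2500, chr2 = 2000), window_length = 1000)
  w <- window_table(gl)
  expect_equal(w$start[w$chrom == "chr1"], c(1, 1001, 2001))
  expect_equal(w$end[w$chrom == "chr1"], c(1000, 2000, 2500))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # interval length convention: end - start + 1
  expect_true(all(w$end - w$start + 1 <= 1000))
  expect_error(genome_layout(c(chr1 = 0)), "lengths")
  expect_error(genome_layout(c(1e6)), "named")
})

test_that("read_cnv_calls parses 1-based inclusive calls and rejects CN2", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tsample\tcn",
               "Chr6\t71747001\t71752000\tHER01\t8",
               "Chr6\t71747001\t71752000\tHER02\t2",
               "chr1\t1001\t4000\tSIM01\t1"), f)
  expect_warning(calls <- read_cnv_calls(f, "B"), "reference genotype")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$end[1] - calls$start[1] + 1, 5000)
  expect_equal(calls$cn, c(8L, 1L))
  expect_equal(unique(calls$dataset), "B")
})

test_that("read_cnv_calls error paths name the problem", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tsample", "chr1\t1\t2\tS1"), f)
  expect_error(read_cnv_calls(f), "cn")
  writeLines(c("chrom\tstart\tend\tsample\tcn", "chr1\t5000\t1000\tS1\t0"), f)
  expect_error(read_cnv_calls(f), "line 1")
  writeLines(c("chrom\tstart\tend\tsample\tcn", "chr1\t1\t3000\tS1\t1.5"), f)
  expect_error(read_cnv_calls(f), "non-integer")
  # empty file with valid header: empty result, no error
  writeLines("chrom\tstart\tend\tsample\tcn", f)
  expect_silent(empty <- read_cnv_calls(f))
  expect_equal(nrow(empty), 0)
})

test_that("read_count_matrix infers WL, flags partial windows, round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tS1\tS2",
               "chr1\t1\t1000\t90\t110",
               "chr1\t1001\t2000\t100\t100",
               "chr1\t2001\t2500\t55\t45"), f)
  rcm <- read_count_matrix(f)
  expect_equal(dim(rcm$counts), c(3, 2))
  expect_equal(rcm$layout$window_length, 1000)
  expect_equal(rcm$windows$partial, c(FALSE, FALSE, TRUE))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(rcm, f2)
  rcm2 <- read_count_matrix(f2)
  expect_equal(rcm2$counts, rcm$counts)
  expect_equal(rcm2$windows, rcm$windows)
})

test_that("read_count_matrix rejects malformed window grids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tS1\tS2",
               "chr1\t1\t1000\t1\t2", "chr1\t1\t1000\t1\t2"), f)
  expect_error(read_count_matrix(f), "unsorted|duplicated")
  writeLines(c("chrom\tstart\tend\tS1\tS2",
               "chr1\t1\t1000\t1\t2", "chr1\t500\t1500\t1\t2"), f)
  expect_error(read_count_matrix(f), "overlapping")
  writeLines(c("chrom\tstart\tend\tS1\tS2", "chr1\t1\t1000\t-5\t2"), f)
  expect_error(read_count_matrix(f), "non-negative")
})

test_that("GFF3 parsing derives introns from exon gaps", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\texon\t401\t500\t.\t+\t.\tID=e2;Parent=t1",
    "chr1\tsrc\tgene\t1001\t1200\t.\t+\t.\tID=g2",
    "chr1\tsrc\tmRNA\t1001\t1200\t.\t+\t.\tID=t2;Parent=g2",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tID=e3;Parent=t2"), f)
  tr <- read_features_gff3(f)
  introns <- tr[tr$kind == "intron", ]
  expect_equal(nrow(introns), 1)   # single-exon transcript has no intron
  expect_equal(c(introns$start, introns$end), c(201, 400))
  expect_equal(introns$gene_id, "g1")
})

test_that("orphan CDS is kept with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tCDS\t10\t90\t.\t+\t0\tID=c1;Parent=missing"), f)
  expect_warning(tr <- read_features_gff3(f), "parent")
  expect_equal(sum(tr$kind == "CDS"), 1)
})

test_that("CNVR table counts genotypes and excludes CN_ from n_samples", {
  # a DEL CNVR seen as 4x CN0 + 1x CN1 in a cohort of 7
  calls <- rbind(
    call_row("chr11", 6754001, 6757000, sprintf("S%02d", 1:4), 0),
    call_row("chr11", 6754001, 6757000, "S05", 1))
  cs <- make_cnvr_set(calls)
  geno <- assign_genotypes(cs, sprintf("S%02d", 1:7))
  geno["CNVR_00001", "S06"] <- NA  # one undetermined sample
  tab <- cnvr_table(cs, geno)
  expect_equal(tab$n_samples, 5L)
  expect_equal(tab$n_CN0, 4L)
  expect_equal(tab$n_CN1, 1L)
  expect_equal(tab$`n_CN_`, 1L)
  expect_equal(tab$n_CN2, 1L)
  expect_equal(tab$category, "DEL")
  # write -> read round trip preserves records
  f <- withr::local_tempfile(fileext = ".csv")
  write_cnvr_table(cs, geno, f)
  back <- read_cnvr_table(f)
  expect_equal(back$cnvr_id, tab$cnvr_id)
  expect_equal(back$n_samples, tab$n_samples)
  expect_equal(back[, c("chrom", "start", "end", "length", "category")],
               tab[, c("chrom", "start", "end", "length", "category")])
})
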