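test_that("reciprocal overlap fractions follow the 1-based definition", {
  a <- list(chrom = "chr1", start = 1001, end = 5000)   # 4,000 bp
  b <- list(chrom = "chr1", start = 3001, end = 7000)   # 4,000 bp, overlap 2,000
  expect_equal(reciprocal_overlap(a, b), c(0.5, 0.5))   # boundary case passes
  c2 <- list(chrom = "chr1", start = 4001, end = 12000) # 8,000 bp, overlap 1,000
  expect_equal(reciprocal_overlap(a, c2), c(0.25, 0.125))
  expect_equal(reciprocal_overlap(a, a), c(1, 1))
  d <- list(chrom = "chr2", start = 1001, end = 5000)
  expect_equal(reciprocal_overlap(a, d), c(0, 0))
})

test_that("CNVRs are single-linkage components of the 50% RO graph", {
  # exactly-50% pair merges into one CNVR spanning [1001, 7000]
  calls <- rbind(call_row("chr1", 1001, 5000, "S1", 1),
                 call_row("chr1", 3001, 7000, "S2", 0))
  cs <- cluster_cnvs(calls)
  expect_equal(nrow(cs$cnvrs), 1)
  expect_equal(c(cs$cnvrs$start, cs$cnvrs$end), c(1001, 7000))
  # chain A~B, B~C but not A~C still forms one CNVR (transitive closure)
  chain <- rbind(call_row("chr1", 1001, 8000, "S1", 1),
                 call_row("chr1", 4001, 11000, "S2", 1),
                 call_row("chr1", 7001, 14000, "S3", 1))
  expect_equal(reciprocal_overlap(chain[1, ], chain[3, ]), c(1, 1) / 7)
  cs2 <- cluster_cnvs(chain)
  expect_equal(nrow(cs2$cnvrs), 1)
  expect_equal(same_partition(brute_force_components(chain),
                              rep(1, 3)), TRUE)
  # different chromosomes never merge
  two <- rbind(call_row("chr1", 1001, 5000, "S1", 1),
               call_row("chr2", 1001, 5000, "S2", 1))
  expect_equal(nrow(cluster_cnvs(two)$cnvrs), 2)
})

test_that("cluster_cnvs matches the brute-force component oracle", {
  for (seed in 1:60) {
    calls <- random_calls(n = sample(2:25, 1), seed = seed)
    cs <- cluster_cnvs(calls)
    got <- as.integer(factor(cs$members$cnvr_id))
    want <- brute_force_components(calls)
    expect_true(same_partition(got, want),
                label = sprintf("partition match (seed %d)", seed))
    # partition property: every call in exactly one CNVR
    expect_equal(nrow(cs$members), nrow(calls))
    expect_false(any(is.na(cs$members$cnvr_id)))
    # bookkeeping: DEL + AMP + MIX = total
    expect_equal(sum(table(cs$cnvrs$category)), nrow(cs$cnvrs))
  }
})

test_that("CNVR categories follow the DEL/AMP/MIX definition", {
  expect_equal(categorize(c(0, 1)), "DEL")
  expect_equal(categorize(c(3, 8)), "AMP")
  expect_equal(categorize(c(1, 3)), "MIX")
  expect_equal(categorize(0), "DEL")
  expect_error(categorize(integer(0)), "empty")
})

test_that("singleton filter uses distinct-sample counts", {
  calls <- rbind(call_row("chr1", 1001, 5000, "S1", 1),
                 call_row("chr1", 1001, 5000, "S1", 0),   # same sample twice
                 call_row("chr1", 20001, 25000, "S1", 1),
                 call_row("chr1", 20001, 25000, "S2", 1))
  cs <- cluster_cnvs(calls)
  expect_message(f2 <- filter_singletons(cs, 2), "removed 1 of 2")
  expect_equal(nrow(f2$cnvrs), 1)
  expect_equal(f2$cnvrs$start, 20001)
  expect_message(f1 <- filter_singletons(cs, 1), "removed 0")
  expect_equal(nrow(f1$cnvrs), 2)
})

test_that("genotype assignment: largest aggregate width, ties toward CN2", {
  mk <- function(rows) make_cnvr_set(rows)
  # CN1 x 3kb vs CN3 x 5kb -> CN3
  cs <- mk(rbind(call_row("chr1", 1001, 4000, "S1", 1),
                 call_row("chr1", 1001, 6000, "S1", 3)))
  expect_equal(unname(assign_genotypes(cs, "S1")[1, 1]), 3L)
  # CN0 4kb vs CN3 4kb: tie -> closer to CN2 -> CN3
  cs <- mk(rbind(call_row("chr1", 1001, 4999, "S1", 0),
                 call_row("chr1", 1001, 4999, "S1", 3)))
  expect_equal(unname(assign_genotypes(cs, "S1")[1, 1]), 3L)
  # two CN1 calls (2 + 3 kb) beat one CN0 (4 kb): aggregation across calls
  # (all three satisfy 50% RO with the CN0 call, so they share one CNVR)
  cs <- mk(rbind(call_row("chr1", 1001, 3000, "S1", 1),
                 call_row("chr1", 2001, 5000, "S1", 1),
                 call_row("chr1", 1001, 5000, "S1", 0)))
  expect_equal(unname(assign_genotypes(cs, "S1")[1, 1]), 1L)
  # residual tie CN1 vs CN3 (equal width, equal |cn-2|) -> lower cn (CN1)
  cs <- mk(rbind(call_row("chr1", 1001, 4999, "S1", 1),
                 call_row("chr1", 1001, 4999, "S1", 3)))
  expect_equal(unname(assign_genotypes(cs, "S1")[1, 1]), 1L)
  # non-carriers get provisional CN2
  expect_equal(unname(assign_genotypes(cs, c("S1", "S2"))[1, "S2"]), 2L)
})

test_that("genotype assignment is invariant to member order", {
  calls <- rbind(call_row("chr1", 1001, 4000, "S1", 1),
                 call_row("chr1", 1001, 6000, "S1", 3),
                 call_row("chr1", 2001, 6000, "S2", 0))
  g1 <- assign_genotypes(make_cnvr_set(calls), c("S1", "S2"))
  g2 <- assign_genotypes(make_cnvr_set(calls[c(3, 1, 2), ]), c("S1", "S2"))
  expect_identical(g1, g2)
})

test_that("CN2 correction marks provisional CN2 under overlapping CNVRs", {
  # R = [1001,6000] (S1), R' = [4001,9000] (S2): overlap >= 1 bp
  calls <- rbind(call_row("chr1", 1001, 6000, "S1", 1),
                 call_row("chr1", 1001, 6000, "S3", 1),
                 call_row("chr1", 4001, 9000, "S2", 3),
                 call_row("chr1", 4001, 9000, "S3", 3))
  cs <- cluster_cnvs(calls)   # 50% RO fails -> two CNVRs
  expect_equal(nrow(cs$cnvrs), 2)
  g <- assign_genotypes(cs, c("S1", "S2", "S3"))
  gc <- cn2_correction(cs, g)
  # S2 has no call in R but one in overlapping R' -> CN_ at R
  expect_true(is.na(gc["CNVR_00001", "S2"]))
  expect_true(is.na(gc["CNVR_00002", "S1"]))
  # S3 carries calls in both -> keeps assigned genotypes
  expect_equal(unname(gc["CNVR_00001", "S3"]), 1L)
  expect_equal(unname(gc["CNVR_00002", "S3"]), 3L)
  # idempotent
  expect_identical(cn2_correction(cs, gc), gc)
})

test_that("CN2 correction leaves non-overlapping CNVRs untouched", {
  calls <- rbind(call_row("chr1", 1001, 6000, "S1", 1),
                 call_row("chr1", 900001, 906000, "S2", 3))
  cs <- cluster_cnvs(calls)
  g <- assign_genotypes(cs, c("S1", "S2"))
  expect_identical(cn2_correction(cs, g), g)
})

test_that("merging CNVR sets: union coalesces bookended, unique dedupes", {
  a <- data.frame(chrom = "chr1", start = 1001, end = 2000)
  b <- data.frame(chrom = "chr1", start = 2001, end = 3000)
  m <- merge_cnvr_sets(list(a, b), mode = "union")
  expect_equal(nrow(m$regions), 1)
  expect_equal(c(m$regions$start, m$regions$end), c(1001, 3000))
  # identical coordinates across sets counted once
  u <- merge_cnvr_sets(list(a, a), mode = "unique_coords")
  expect_equal(u$n_unique, 1)
  # coverage arithmetic: 2 kb + 3 kb disjoint on a 100 kb genome = 5%
  gl <- genome_layout(c(chr1 = 1e5), 1000)
  d <- data.frame(chrom = "chr1", start = c(1001, 50001),
                  end = c(3000, 53000))
  m2 <- merge_cnvr_sets(list(d), mode = "union", layout = gl)
  expect_equal(m2$total_bp, 5000)
  expect_equal(m2$pct_genome, 5.0)
})
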