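test_that("HWE test: exact-HWE counts give chi2 = 0", {
  h <- hwe_test(c(CN0 = 25, CN1 = 50, CN2 = 25))
  expect_true(h$qualifies)
  expect_equal(h$mapping, "DEL")
  expect_equal(h$q, 0.5)
  expect_equal(h$chi2, 0)
  expect_true(h$in_hwe)
})

test_that("HWE test matches a hand-computed goodness-of-fit oracle", {
  # counts (1, 10, 89): q = (2 + 10) / 200 = 0.06
  obs <- c(1, 10, 89)
  q <- 0.06
  expd <- 100 * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  expect_equal(expd, c(0.36, 11.28, 88.36))
  chi2_hand <- sum((obs - expd)^2 / expd)
  h <- hwe_test(c(CN0 = 1, CN1 = 10, CN2 = 89))
  expect_equal(h$chi2, chi2_hand)
  expect_equal(h$p_value, pchisq(chi2_hand, 1, lower.tail = FALSE))
  # het deficit (50, 0, 50): chi2 = 100, far out of HWE at alpha 1e-5
  h2 <- hwe_test(c(CN0 = 50, CN1 = 0, CN2 = 50))
  expect_equal(h2$q, 0.5)
  expect_equal(h2$chi2, 100)
  expect_lt(h2$p_value, 1e-5)
  expect_false(h2$in_hwe)
})

test_that("HWE qualification: diallelic spectra only, DUP side mapped", {
  expect_false(hwe_test(c(CN0 = 3, CN3 = 5, CN2 = 10))$qualifies)  # multi-allelic
  expect_equal(hwe_test(c(CN0 = 3, CN3 = 5, CN2 = 10))$reason, "multi-allelic")
  expect_false(hwe_test(c(CN2 = 50))$qualifies)                    # monomorphic
  h <- hwe_test(c(CN2 = 25, CN3 = 50, CN4 = 25))
  expect_true(h$qualifies)
  expect_equal(h$mapping, "DUP")
  expect_equal(h$chi2, 0)
})

test_that("HWE statistic agrees with chisq.test on all small count triples", {
  # independent route: stats::chisq.test against expected HWE proportions
  for (n0 in 0:6) for (n1 in 0:6) for (n2 in 0:6) {
    n <- n0 + n1 + n2
    if (n < 4 || sum(c(n0, n1, n2) > 0) < 2) next
    q <- (2 * n0 + n1) / (2 * n)
    if (q == 0 || q == 1) next
    h <- hwe_test(c(CN0 = n0, CN1 = n1, CN2 = n2))
    ref <- suppressWarnings(
      chisq.test(c(n0, n1, n2), p = c(q^2, 2 * q * (1 - q), (1 - q)^2)))
    expect_equal(h$chi2, unname(ref$statistic))
  }
})

test_that("parity test compares even against odd genotype classes", {
  expect_true(parity_test(c(CN0 = 5, CN1 = 20, CN2 = 75)))   # 80 >= 20
  expect_false(parity_test(c(CN1 = 60, CN2 = 40)))           # 40 < 60
  expect_true(parity_test(c(CN1 = 50, CN2 = 50)))            # tie passes
  expect_true(parity_test(c(CN6 = 3, CN5 = 2)))              # CN6 counts as even
  expect_true(is.na(parity_test(c(CN0 = 0))))
})

test_that("sample clustering: identical genotype vectors merge first at 0", {
  g <- matrix(c(0, 1, 2, 0, 1,
                0, 1, 2, 0, 1,
                2, 2, 0, 1, 3), nrow = 5,
              dimnames = list(sprintf("R%d", 1:5), c("s1", "s2", "s3")))
  hc <- cluster_samples(g)
  expect_equal(hc$height[1], 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
})

test_that("ward.D2 merge heights match the Lance-Williams oracle", {
  set.seed(33)
  g <- matrix(sample(0:4, 4 * 40, replace = TRUE), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  hc <- cluster_samples(g)
  # independent oracle: explicit Lance-Williams recursion on squared
  # Spearman distances (the ward.D2 convention)
  d <- 1 - cor(g, method = "spearman")
  ds <- d^2
  size <- rep(1, 4); active <- 1:4
  heights <- numeric(0)
  for (step in 1:3) {
    best <- c(NA, NA); bh <- Inf
    for (i in active) for (j in active) if (i < j && ds[i, j] < bh) {
      bh <- ds[i, j]; best <- c(i, j)
    }
    heights <- c(heights, sqrt(bh))
    i <- best[1]; j <- best[2]
    for (k in setdiff(active, best)) {
      ds[i, k] <- ds[k, i] <-
        ((size[i] + size[k]) * ds[i, k] + (size[j] + size[k]) * ds[j, k] -
           size[k] * bh) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  expect_equal(hc$height, heights, tolerance = 1e-10)
})

test_that("degenerate genotype vectors get maximum distance with warning", {
  g <- matrix(c(2, 2, 2,
                0, 1, 2,
                1, 0, 2), nrow = 3, byrow = FALSE,
              dimnames = list(sprintf("R%d", 1:3), c("s1", "s2", "s3")))
  # s1 is constant (all CN2 over rows? columns are samples): make s1 constant
  g[, "s1"] <- 2
  expect_warning(hc <- cluster_samples(g), "undefined")
  expect_s3_class(hc, "hclust")
})

test_that("overlap fraction uses the >= 1 bp rule, asymmetrically", {
  a <- data.frame(chrom = "chr1", start = c(1, 100), end = c(10, 200))
  expect_equal(overlap_fraction(a, a), 1.0)
  b <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  expect_equal(overlap_fraction(a, b), 0.0)
  # one shared base counts
  c1 <- data.frame(chrom = "chr1", start = 1, end = 10)
  c2 <- data.frame(chrom = "chr1", start = 10, end = 20)
  expect_equal(overlap_fraction(c1, c2), 1.0)
  expect_message(na <- overlap_fraction(a[0, ], b), "empty")
  expect_true(is.na(na))
})

test_that("breed-specific CNVRs need >= 2 carriers in exactly one breed", {
  meta <- data.frame(sample = c("H1", "H2", "H3", "M1"),
                     breed = c("HER", "HER", "HER", "SIM"))
  g <- matrix(2L, nrow = 3, ncol = 4,
              dimnames = list(sprintf("CNVR_%d", 1:3), meta$sample))
  g[1, c("H1", "H2", "H3")] <- 0L           # 3 HER carriers, 0 others
  g[2, c("H1", "H2", "M1")] <- 3L           # carriers in two breeds
  g[3, "H1"] <- 1L                          # single carrier
  bs <- breed_specific(g, meta)
  expect_equal(bs$cnvr_id, "CNVR_1")
  expect_equal(bs$breed, "HER")
  expect_equal(bs$n_carriers, 3L)
})

test_that("chromosome density table counts and conserves categories", {
  gl <- genome_layout(c(chr1 = 1e7, chr2 = 5e6), 1000)
  tab <- data.frame(chrom = rep("chr1", 10),
                    start = seq(1, by = 1e5, length.out = 10),
                    end = seq(5000, by = 1e5, length.out = 10),
                    category = rep(c("DEL", "AMP", "MIX"), length.out = 10),
                    cnvr_id = sprintf("C%d", 1:10))
  d <- density_by_chromosome(tab, gl)
  expect_equal(d$n_cnvr, c(10, 0))
  expect_equal(d$per_mb, c(1.0, 0))
  expect_equal(d$n_DEL + d$n_AMP + d$n_MIX, d$n_cnvr)
  bad <- tab; bad$chrom[1] <- "chrZZ"
  expect_error(density_by_chromosome(bad, gl), "chrZZ")
})
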