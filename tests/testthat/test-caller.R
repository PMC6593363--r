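test_that("normalization equalizes totals and reports factors", {
  gl <- genome_layout(c(chr1 = 3000), 1000)
  counts <- cbind(S1 = c(100, 100, 100), S2 = c(200, 200, 200),
                  S3 = c(100, 100, 100))
  rcm <- new_read_count_matrix(gl, counts)
  norm <- normalize_counts(rcm)
  tot <- colSums(norm$counts)
  expect_lt(max(abs(tot / mean(tot) - 1)), 1e-9)
  # identical samples -> identity on them; double-total sample halved-ish
  expect_equal(attr(norm, "scaling_factors")[["S2"]],
               mean(c(300, 600, 300)) / 600)
  # two identical samples alone -> exact identity
  norm2 <- normalize_counts(new_read_count_matrix(gl, counts[, c(1, 3)]))
  expect_equal(norm2$counts, counts[, c(1, 3)])
})

test_that("zero-total samples are excluded with a warning", {
  gl <- genome_layout(c(chr1 = 2000), 1000)
  rcm <- new_read_count_matrix(gl, cbind(S1 = c(5, 5), S2 = c(0, 0),
                                         S3 = c(7, 3)))
  expect_warning(norm <- normalize_counts(rcm), "S2")
  expect_equal(norm$sample_ids, c("S1", "S3"))
})

test_that("window CN estimates and significance flags follow the Poisson rule", {
  gl <- genome_layout(c(chr1 = 4000), 1000)
  # columns chosen so the per-window median is exactly 100
  counts <- cbind(A = c(100, 0, 55, 100), B = c(100, 100, 100, 100),
                  C = c(100, 100, 100, 100), D = c(100, 100, 100, 100),
                  E = c(100, 100, 100, 100))
  # fed directly as already-normalized counts to keep the medians exact
  wcn <- estimate_window_cn(new_read_count_matrix(gl, counts), alpha = 1e-3)
  expect_equal(wcn$lambda, rep(100, 4))
  # x = lambda -> CN2, not flagged
  expect_equal(unname(wcn$cn[1, "A"]), 2L)
  expect_false(wcn$flag[1, "A"])
  # x = 0 under lambda=100 -> CN0, flagged
  expect_equal(unname(wcn$cn[2, "A"]), 0L)
  expect_true(wcn$flag[2, "A"])
  # x = 55 under lambda=100: CN1 by rounding; exact two-sided tail
  # computed by direct Poisson mass summation (independent oracle):
  p_oracle <- 2 * sum(exp(-100) * 100^(0:55) / factorial(0:55))
  expect_equal(p_oracle, 1.270592e-06, tolerance = 1e-6)
  expect_equal(unname(wcn$cn[3, "A"]), 1L)
  expect_true(wcn$flag[3, "A"])  # 1.27e-6 < 1e-3
})

test_that("zero-median windows are masked and partial windows never flagged", {
  gl <- genome_layout(c(chr1 = 2500), 1000)
  counts <- cbind(S1 = c(100, 0, 0), S2 = c(100, 0, 0), S3 = c(100, 0, 90))
  wcn <- estimate_window_cn(new_read_count_matrix(gl, counts))
  expect_true(wcn$masked[2])
  expect_false(any(wcn$flag[2, ]))
  expect_false(any(wcn$flag[3, ]))  # partial terminal window
})

test_that("segmentation needs 3 adjacent flagged windows of one direction", {
  ev2 <- data.frame(sample = "S01", win_start = 10, n_win = 2, cn = 1)
  calls2 <- call_cnvs(planted_matrix(events = ev2, n_windows = 50))
  expect_equal(nrow(calls2), 0)  # two adjacent windows: below the floor
  # 5 flagged CN1 windows starting at window 4 -> one call [3001, 8000]
  ev5 <- data.frame(sample = "S01", win_start = 4, n_win = 5, cn = 1)
  calls5 <- call_cnvs(planted_matrix(events = ev5, n_windows = 50))
  expect_equal(nrow(calls5), 1)
  expect_equal(calls5$start, 3001)
  expect_equal(calls5$end, 8000)
  expect_equal(calls5$cn, 1L)
  expect_equal(calls5$end - calls5$start + 1, 5000)
})

test_that("run genotype is the member median, halves rounded toward CN2", {
  # window estimates (1,0,0,0,1) -> CN0
  ev <- data.frame(sample = "S01", win_start = c(10, 11, 14),
                   n_win = c(1, 3, 1), cn = c(1, 0, 1))
  calls <- call_cnvs(planted_matrix(events = ev, n_windows = 50))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cn, 0L)
  # even-length loss run (1,1,0,0): median 0.5 -> toward 2 -> CN1
  ev2 <- data.frame(sample = "S01", win_start = c(10, 12),
                    n_win = c(2, 2), cn = c(1, 0))
  calls2 <- call_cnvs(planted_matrix(events = ev2, n_windows = 50))
  expect_equal(calls2$cn, 1L)
  # gain run (3,3,4,4): median 3.5 -> toward 2 -> CN3
  ev3 <- data.frame(sample = "S01", win_start = c(10, 12),
                    n_win = c(2, 2), cn = c(3, 4))
  calls3 <- call_cnvs(planted_matrix(events = ev3, n_windows = 50))
  expect_equal(calls3$cn, 3L)
})

test_that("opposite directions split into abutting calls", {
  ev <- data.frame(sample = "S01", win_start = c(10, 13), n_win = c(3, 3),
                   cn = c(0, 4))
  calls <- call_cnvs(planted_matrix(events = ev, n_windows = 50))
  calls <- calls[order(calls$start), ]
  expect_equal(nrow(calls), 2)
  expect_equal(calls$cn, c(0L, 4L))
  expect_equal(calls$start[2], calls$end[1] + 1)
})

test_that("noise-free planted CNVs >= 3 windows are recovered exactly", {
  events <- data.frame(sample = c("S01", "S02", "S03", "S04", "S05"),
                       win_start = c(10, 40, 80, 120, 160),
                       n_win = c(3, 5, 8, 4, 2),
                       cn = c(0, 1, 3, 4, 0))
  rcm <- planted_matrix(events = events, n_windows = 200, noise = "none")
  calls <- call_cnvs(rcm)
  # the 2-window event is never reported
  expect_false("S05" %in% calls$sample)
  rec <- events[events$n_win >= 3, ]
  expect_equal(nrow(calls), nrow(rec))
  for (i in seq_len(nrow(rec))) {
    k <- calls$sample == rec$sample[i]
    expect_true(any(k))
    expect_equal(calls$start[k], (rec$win_start[i] - 1) * 1000 + 1)
    expect_equal(calls$end[k], (rec$win_start[i] + rec$n_win[i] - 1) * 1000)
    expect_equal(calls$cn[k], rec$cn[i])
  }
  # contract: all lengths are >= 3 kb and multiples of the window length
  len <- calls$end - calls$start + 1
  expect_true(all(len >= 3000))
  expect_true(all(len %% 1000 == 0))
})
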