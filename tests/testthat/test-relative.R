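toy_table <- function() {
  archive_table(c("a", "b", "c", "d"), c(2.0, 2.5, 3.0, 3.5),
                c(0.1, 0.2, 0.3, 0.4))
}

test_that("overall percentile counts strictly lower entries", {
  t <- toy_table()
  expect_equal(q_relative_all(0.35, t), 75)        # 3 of 4 strictly lower
  expect_equal(q_relative_all(0.05, t), 0)         # below every entry
  expect_equal(q_relative_all(0.4, t), 75)         # tie does not count
  expect_equal(q_relative_all(0.4, t, strict = FALSE), 100)
  expect_equal(q_relative_all(c(0.05, 0.35), t), c(0, 75))
  expect_error(q_relative_all(0.5, t[0, ]), "empty")
})

test_that("overall percentile is monotone with endpoint values fixed", {
  set.seed(44)
  t <- archive_table(sprintf("e%d", 1:500), runif(500, 1, 10), runif(500))
  qs <- sort(runif(30))
  ps <- q_relative_all(qs, t)
  expect_true(all(diff(ps) >= 0))
  expect_equal(q_relative_all(min(t$q) - 0.01, t), 0)
  expect_equal(q_relative_all(max(t$q), t), (500 - 1) / 500 * 100)
})

test_that("windowed percentile matches the toy hand count", {
  t <- archive_table(c("a", "b", "c"), c(2.0, 2.1, 2.2), c(0.5, 0.6, 0.7))
  r <- q_relative_resolution(0.65, 2.1, t, w = 0.5)
  expect_equal(r$n_window, 3L)
  expect_equal(r$percent, 100 * 2 / 3, tolerance = 1e-12)
  # an entry alone in its window has no lower entries: 0%
  lone <- archive_table("x", 7.0, 0.4)
  r2 <- q_relative_resolution(0.4, 7.0, lone, w = 0.5)
  expect_equal(r2$percent, 0)
  expect_equal(r2$n_window, 1L)
  # empty window: undefined signal
  expect_warning(r3 <- q_relative_resolution(0.4, 9.9, lone, w = 0.5),
                 "no archive entries")
  expect_true(is.na(r3$percent))
})

test_that("percentiles equal brute-force counts on random tables", {
  set.seed(55)
  t <- archive_table(sprintf("e%d", 1:1000), runif(1000, 1, 10),
                     runif(1000))
  for (k in 1:25) {
    qq <- runif(1)
    dd <- runif(1, 1, 10)
    expect_identical(q_relative_all(qq, t), 100 * sum(t$q < qq) / 1000)
    win <- abs(t$d - dd) <= 0.25
    r <- q_relative_resolution(qq, dd, t, w = 0.5)
    expect_identical(r$n_window, sum(win))
    expect_identical(r$percent, 100 * sum(t$q[win] < qq) / sum(win))
  }
})

test_that("a window spanning all resolutions reduces to the overall rank", {
  set.seed(66)
  t <- archive_table(sprintf("e%d", 1:200), runif(200, 1, 10), runif(200))
  for (i in sample(200, 10)) {
    r <- q_relative_resolution(t$q[i], t$d[i], t, w = 2 * 9 + 1)
    expect_equal(r$percent, q_relative_all(t$q[i], t))
    expect_equal(r$n_window, 200L)
  }
})

test_that("both metrics are invariant to table row order", {
  set.seed(77)
  t <- archive_table(sprintf("e%d", 1:300), runif(300, 1, 10), runif(300))
  perm <- t[sample(300), ]
  expect_equal(q_relative_all(0.42, t), q_relative_all(0.42, perm))
  expect_equal(q_relative_resolution(0.42, 3.3, t, w = 0.5),
               q_relative_resolution(0.42, 3.3, perm, w = 0.5))
})

test_that("window-size choice: |d_i - d| <= w mode is selectable", {
  t <- archive_table(c("a", "b"), c(2.0, 2.4), c(0.3, 0.5))
  expect_equal(q_relative_resolution(0.6, 2.0, t, w = 0.5)$n_window, 1L)
  expect_equal(q_relative_resolution(0.6, 2.0, t, w = 0.5,
                                     half_width = FALSE)$n_window, 2L)
})

test_that("window entry counts match brute-force per-row counts", {
  set.seed(88)
  t <- archive_table(sprintf("e%d", 1:10), round(runif(10, 1, 10), 1),
                     runif(10))
  wc <- window_entry_counts(t, w = 0.2)
  counts <- vapply(t$d, function(d0) sum(abs(t$d - d0) <= 0.1), integer(1))
  expect_equal(wc$min, min(counts))
  expect_equal(wc$mean, mean(counts))
  expect_equal(wc$max, max(counts))
  # identical resolutions count each other regardless of w
  t3 <- archive_table(c("a", "b", "c"), rep(2.5, 3), c(0.1, 0.2, 0.3))
  expect_equal(window_entry_counts(t3, w = 0.05),
               list(min = 3L, mean = 3, max = 3L))
})

test_that("window count summaries are non-decreasing in window size", {
  t <- suppressWarnings(simulate_archive(2000, seed = 99))
  ws <- c(0.1, 0.3, 0.5, 1.0, 1.5)
  wc <- lapply(ws, function(w) window_entry_counts(t, w))
  for (f in c("min", "mean", "max"))
    expect_true(all(diff(vapply(wc, `[[`, numeric(1), f)) >= 0))
})

test_that("correlation scan equals a brute-force Pearson oracle", {
  set.seed(101)
  n <- 300
  t <- archive_table(sprintf("e%d", 1:n), runif(n, 1, 10), runif(n))
  windows <- c(seq(0.1, 1.0, by = 0.1), 1.2, 1.5)   # the standard scan
  scan <- window_correlation_scan(t, windows = windows)
  expect_equal(scan$w, windows)
  for (wi in c(1L, 5L, 12L)) {
    w <- windows[wi]
    rel <- vapply(seq_len(n), function(i) {
      win <- abs(t$d - t$d[i]) <= w / 2
      100 * sum(t$q[win] < t$q[i]) / sum(win)
    }, numeric(1))
    lo <- t$d < 5
    expect_equal(scan$cor_low_d[wi], pearson_oracle(rel[lo], t$d[lo]),
                 tolerance = 1e-12)
    expect_equal(scan$cor_high_d[wi], pearson_oracle(rel[!lo], t$d[!lo]),
                 tolerance = 1e-12)
  }
})

test_that("scan is near 0 for exchangeable Q and 1 for rank-increasing Q", {
  set.seed(111)
  n <- 2000
  t0 <- archive_table(sprintf("e%d", 1:n), runif(n, 1, 10), runif(n))
  s0 <- window_correlation_scan(t0, windows = c(0.5))
  expect_lt(abs(s0$cor_low_d), 0.1)
  expect_lt(abs(s0$cor_high_d), 0.1)
  # q strictly increasing in d: interior entries sit near their own
  # window's median (~50%), so only the range ends pull the correlation
  # positive -- weakly but with a definite sign
  t1 <- archive_table(sprintf("e%d", 1:n), sort(runif(n, 1, 10)),
                      seq(0, 1, length.out = n))
  s1 <- window_correlation_scan(t1, windows = c(0.5))
  expect_gt(s1$cor_low_d, 0.05)
  expect_gt(s1$cor_high_d, 0.05)
})
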