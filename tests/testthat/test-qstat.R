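test_that("an exact cubic is recovered with R^2 = 1", {
  cf <- c(1.2, -0.35, 0.04, -0.0017)
  d <- seq(1, 10, length.out = 50)
  t <- archive_table(sprintf("e%d", 1:50), d, qmetric:::polyval(cf, d))
  fit <- suppressWarnings(qstat_fit(t))
  expect_equal(coef(fit), cf, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # mean curve evaluated mid-domain matches the generating polynomial
  mid <- mean(fit$domain)
  expect_equal(predict(fit, mid)$q_mean, qmetric:::polyval(cf, mid))
})

test_that("underdetermined fits raise a singular-fit error", {
  t <- archive_table(c("a", "b", "c"), c(2, 3, 4), c(0.5, 0.4, 0.3))
  expect_error(qstat_fit(t, degree = 3), "singular")
  # repeated resolutions are as singular as too few points
  t2 <- archive_table(sprintf("e%d", 1:10), rep(c(2, 3), 5), runif(10))
  expect_error(qstat_fit(t2, degree = 3), "singular")
})

test_that("R^2 matches the normal-equations oracle", {
  arch <- suppressWarnings(simulate_archive(2000, seed = 17))
  fit <- qstat_fit(arch)
  X <- outer(arch$d, 0:3, "^")
  beta <- solve(t(X) %*% X, t(X) %*% arch$q)
  res <- arch$q - X %*% beta
  r2 <- 1 - sum(res^2) / sum((arch$q - mean(arch$q))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(coef(fit), as.numeric(beta), tolerance = 1e-6)
})

test_that("identical residuals collapse all three offsets", {
  off <- compute_offsets(rep(0.07, 100))
  expect_equal(off, list(peak = 0.07, low = 0.07, high = 0.07))
})

test_that("uniform residuals give the closed-form 95% offsets", {
  set.seed(23)
  r <- runif(10000, -0.1, 0.1)
  off <- compute_offsets(r)
  # the peak is arbitrary within a flat density; conditional on it, the
  # per-side percentiles of a uniform on [-0.1, 0.1] have closed forms
  expect_lt(abs(off$low - (-0.1 + 0.05 * (off$peak + 0.1))), 0.002)
  expect_lt(abs(off$high - (0.1 - 0.05 * (0.1 - off$peak))), 0.002)
  expect_true(off$low <= off$peak && off$peak <= off$high)
})

test_that("skewed residuals enclose 95% per side by brute-force count", {
  r <- qmetric:::with_seed(29, qmetric:::rgumbel_mirrored(10000, 0.05))
  off <- compute_offsets(r)
  below <- r[r < off$peak]
  above <- r[r > off$peak]
  expect_equal(mean(below >= off$low), 0.95, tolerance = 0.005)
  expect_equal(mean(above <= off$high), 0.95, tolerance = 0.005)
  # the mode of a left-skewed distribution sits above its mean
  expect_gt(off$peak, mean(r))
})

test_that("overall-percentile mode uses plain 5th/95th percentiles", {
  set.seed(3)
  r <- rnorm(5000, sd = 0.05)
  off <- compute_offsets(r, per_side = FALSE)
  expect_equal(off$low, unname(quantile(r, 0.05, type = 7)))
  expect_equal(off$high, unname(quantile(r, 0.95, type = 7)))
})

test_that("bound curves are exact vertical offsets of the mean curve", {
  arch <- suppressWarnings(simulate_archive(3000, seed = 41))
  fit <- qstat_fit(arch)
  d <- seq(fit$domain[1] + 0.1, fit$domain[2] - 0.1, length.out = 5)
  b <- predict(fit, d)
  expect_equal(b$q_peak - b$q_mean, rep(fit$offsets$peak, 5))
  expect_equal(b$q_low - b$q_mean, rep(fit$offsets$low, 5))
  expect_equal(b$q_high - b$q_mean, rep(fit$offsets$high, 5))
  # vectorized evaluation equals per-point evaluation
  one_by_one <- do.call(rbind, lapply(d, function(di) predict(fit, di)))
  expect_equal(b, one_by_one, ignore_attr = TRUE)
  expect_true(all(!b$extrapolated))
  expect_true(predict(fit, 0.5)$extrapolated)
})

test_that("R^2 is non-decreasing in polynomial degree", {
  arch <- suppressWarnings(simulate_archive(5000, seed = 53))
  r2 <- vapply(1:4, function(k) {
    suppressWarnings(qstat_fit(arch, degree = k)$r_squared)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(r2 > 0 & r2 <= 1))
})

test_that("enclosure fractions hold on the fitted table within 1/n per side", {
  arch <- suppressWarnings(simulate_archive(8000, seed = 61))
  fit <- qstat_fit(arch)
  enc <- qmetric:::enclosure_fractions(fit)
  expect_gte(enc$frac_below, 0.95 - 1 / enc$n_below)
  expect_lte(enc$frac_below, 0.95 + 1 / enc$n_below)
  expect_gte(enc$frac_above, 0.95 - 1 / enc$n_above)
  expect_lte(enc$frac_above, 0.95 + 1 / enc$n_above)
})

test_that("rolling percentiles of a constant-Q table are that constant", {
  t <- archive_table(sprintf("e%d", 1:200), seq(1, 10, length.out = 200),
                     rep(0.4, 200))
  rp <- rolling_percentiles(t, window = 1)
  vals <- unlist(rp[, -1])
  expect_true(all(vals[!is.na(vals)] == 0.4))
})

test_that("rolling percentiles equal hand-sorted values on a toy window", {
  q <- c(0.10, 0.15, 0.22, 0.30, 0.31, 0.35, 0.40, 0.44, 0.50, 0.55,
         0.60, 0.70)
  t <- archive_table(sprintf("e%d", 1:12), rep(3, 12), q)
  rp <- rolling_percentiles(t, window = 0.5, percentiles = c(0.25, 0.5),
                            grid = 3, min_n = 12)
  expect_equal(rp$p25, unname(quantile(q, 0.25, type = 7)))
  expect_equal(rp$p50, unname(quantile(q, 0.5, type = 7)))
  # under-filled windows are gaps
  rp2 <- rolling_percentiles(t, window = 0.5, grid = 3, min_n = 13)
  expect_true(all(is.na(unlist(rp2[, -1]))))
})

test_that("rolling and regression bounds agree on synthetic archives", {
  arch <- suppressWarnings(simulate_archive(10000, seed = 71))
  fit <- qstat_fit(arch)
  grid <- seq(2, 9, by = 0.25)
  rp <- rolling_percentiles(arch, window = 0.5,
                            percentiles = c(0.05, 0.95), grid = grid)
  b <- predict(fit, grid)
  ok <- !is.na(rp$p5)
  rms <- function(x) sqrt(mean(x^2))
  # the skewed lower tail makes the 5th-percentile curve the noisier one
  expect_lt(rms(rp$p5[ok] - b$q_low[ok]), 0.04)
  expect_lt(rms(rp$p95[ok] - b$q_high[ok]), 0.04)
})

test_that("entries classify by strict comparison with the bounds", {
  arch <- suppressWarnings(simulate_archive(4000, seed = 83))
  fit <- qstat_fit(arch)
  b <- predict(fit, 2.4)
  expect_equal(classify_entry(b$q_peak, 2.4, fit), "typical")
  # misfit regime: Q near 0 at 2.4 A is far below the low bound
  expect_equal(classify_entry(0.075, 2.4, fit), "below_low")
  expect_equal(classify_entry(b$q_high + 0.01, 2.4, fit), "above_high")
  expect_equal(classify_entry(b$q_low, 2.4, fit), "typical")  # boundary in
})

test_that("simulate() draws archive tables shaped like the fitted data", {
  arch <- suppressWarnings(simulate_archive(3000, seed = 97))
  fit <- qstat_fit(arch)
  sims <- simulate(fit, nsim = 2, seed = 5, n = 500)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "archive_table")
  expect_equal(nrow(sims[[1]]), 500L)
  expect_true(all(sims[[1]]$d >= fit$domain[1] - 1e-9 &
                  sims[[1]]$d <= fit$domain[2] + 1e-9))
  expect_identical(simulate(fit, nsim = 1, seed = 5)[[1]],
                   simulate(fit, nsim = 1, seed = 5)[[1]])
})
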