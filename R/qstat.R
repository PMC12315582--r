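#' Fit the archive-wide Q-score vs resolution model
#'
#' Fits a polynomial regression of mean model Q-score on reported
#' resolution over an archive of entries, then derives three vertical
#' offsets of the fitted mean curve from its residuals:
#'
#' * `o_peak` -- the offset at which the largest number of residuals fall
#'   within a window of total width `peak_window` (the mode of the
#'   residual distribution; the residuals are skewed, so the mode differs
#'   from the mean);
#' * `o_low` / `o_high` -- offsets such that 95% of the residuals on each
#'   side of the peak lie between them and `o_peak` (per-side enclosure);
#'   with `per_side = FALSE` they are instead the overall 5th and 95th
#'   residual percentiles.
#'
#' Adding the offsets to the mean curve gives the `Q_peak`,
#' `Q_low_95%` and `Q_high_95%` curves used to judge whether an entry's
#' Q-score is commonly observed at its resolution.
#'
#' @param data An `archive_table` (or data frame with columns `d`, `q`).
#' @param formula Model formula; the default `q ~ d` names the Q and
#'   resolution columns of `data`.
#' @param degree Polynomial degree (default 3; the cubic fits archive data
#'   markedly better than degrees 1-2 while degree 4 adds little).
#' @param d_range Resolutions (A) retained for fitting, default `c(1, 10)`.
#' @param peak_window Total width of the mode-search window on residuals.
#' @param peak_grid_step Step of the offset search grid.
#' @param tail_frac Per-side tail fraction excluded by the 95% bounds.
#' @param per_side Logical; per-side enclosure (default) or overall
#'   percentiles.
#' @return An object of class `qstat` with components `coefficients`
#'   (length `degree + 1`, ascending powers), `offsets`
#'   (`peak`, `low`, `high`), `r_squared`, `domain`, `n`, `degree`,
#'   `data` (the fitted rows plus `fitted` and `residual` columns), `call`.
#' @seealso [predict.qstat], [classify_entry], [rolling_percentiles]
#' @export
qstat_fit <- function(data, formula = q ~ d, degree = 3L,
                      d_range = c(1, 10), peak_window = 0.01,
                      peak_grid_step = 0.001, tail_frac = 0.05,
                      per_side = TRUE) {
  mf <- stats::model.frame(formula, as.data.frame(data))
  q <- mf[[1L]]
  d <- mf[[2L]]
  keep <- d >= d_range[1] & d <= d_range[2]
  q <- q[keep]; d <- d[keep]
  n <- length(q)
  if (n < degree + 1L || length(unique(d)) < degree + 1L)
    stop("singular fit: need more than ", degree,
         " rows with distinct resolutions")
  fit <- stats::lm(q ~ stats::poly(d, degree, raw = TRUE))
  if (anyNA(stats::coef(fit))) stop("singular fit: rank-deficient design")
  coeffs <- unname(stats::coef(fit))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((q - mean(q))^2)
  resid <- unname(stats::residuals(fit))
  off <- compute_offsets(resid, peak_window = peak_window,
                         peak_grid_step = peak_grid_step,
                         tail_frac = tail_frac, per_side = per_side)
  obj <- structure(list(
    coefficients = coeffs, offsets = off, r_squared = r2,
    domain = range(d), n = n, degree = as.integer(degree),
    per_side = per_side,
    data = data.frame(d = d, q = q, fitted = unname(stats::fitted(fit)),
                      residual = resid),
    call = match.call()), class = "qstat")
  dd <- seq(obj$domain[1], obj$domain[2], length.out = 200L)
  if (any(diff(polyval(coeffs, dd)) > 0))
    warning("fitted Q_mean curve is not monotonically decreasing over ",
            "the fitted domain")
  obj
}

polyval <- function(coeffs, x) {
  out <- 0
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[k]
  out
}

#' Offsets of the mean curve from its residuals
#'
#' Searches the peak (modal) offset on a grid of step `peak_grid_step`
#' spanning the residual range, counting residuals within
#' `peak_window / 2` of each candidate (ties resolved toward the smallest
#' offset), then takes the 5th percentile of the residuals below the peak
#' and the 95th percentile of those above it (type-7 quantiles). If all
#' residuals are identical the three offsets coincide with that value.
#'
#' @param residuals Numeric residuals about the fitted mean curve.
#' @param peak_window Total window width for the mode search.
#' @param peak_grid_step Offset grid step.
#' @param tail_frac Per-side excluded tail fraction.
#' @param per_side Per-side (default) or overall-percentile bounds.
#' @return Named list `peak`, `low`, `high` (with `low <= peak <= high`).
#' @export
compute_offsets <- function(residuals, peak_window = 0.01,
                            peak_grid_step = 0.001, tail_frac = 0.05,
                            per_side = TRUE) {
  r <- sort(residuals[is.finite(residuals)])
  if (length(r) == 0L) stop("no finite residuals")
  if (r[length(r)] - r[1L] < .Machine$double.eps^0.5) {
    v <- r[1L]
    return(list(peak = v, low = v, high = v))
  }
  grid <- seq(r[1L], r[length(r)], by = peak_grid_step)
  half <- peak_window / 2
  counts <- findInterval(grid + half, r) -
    findInterval(grid - half, r, left.open = TRUE)
  o_peak <- grid[which.max(counts)]
  if (per_side) {
    below <- r[r < o_peak]
    above <- r[r > o_peak]
    o_low <- if (length(below)) unname(stats::quantile(below, tail_frac, type = 7))
             else o_peak
    o_high <- if (length(above)) unname(stats::quantile(above, 1 - tail_frac, type = 7))
              else o_peak
  } else {
    o_low <- unname(stats::quantile(r, tail_frac, type = 7))
    o_high <- unname(stats::quantile(r, 1 - tail_frac, type = 7))
  }
  list(peak = o_peak, low = min(o_low, o_peak), high = max(o_high, o_peak))
}

#' @export
print.qstat <- function(x, ...) {
  cat(sprintf("qstat: degree-%d fit of Q vs resolution, n = %d, R^2 = %.4f\n",
              x$degree, x$n, x$r_squared))
  cat("  coefficients (ascending powers):",
      paste(sprintf("%.5g", x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  offsets: peak %+.4f, low95 %+.4f, high95 %+.4f\n",
              x$offsets$peak, x$offsets$low, x$offsets$high))
  cat(sprintf("  domain: %.2f - %.2f A\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' @export
coef.qstat <- function(object, ...) object$coefficients

#' @export
residuals.qstat <- function(object, ...) object$data$residual

#' @export
summary.qstat <- function(object, ...) {
  enc <- enclosure_fractions(object)
  structure(list(fit = object, enclosure = enc,
                 resid_summary = summary(object$data$residual)),
            class = "summary.qstat")
}

#' @export
print.summary.qstat <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  enclosed below peak: %.1f%% of %d; above peak: %.1f%% of %d\n",
              100 * x$enclosure$frac_below, x$enclosure$n_below,
              100 * x$enclosure$frac_above, x$enclosure$n_above))
  cat("  residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

# Fractions of per-side residuals enclosed by [low, peak] and [peak, high].
enclosure_fractions <- function(object) {
  r <- object$data$residual
  o <- object$offsets
  below <- r[r < o$peak]
  above <- r[r > o$peak]
  list(frac_below = if (length(below)) mean(below >= o$low) else NA_real_,
       n_below = length(below),
       frac_above = if (length(above)) mean(above <= o$high) else NA_real_,
       n_above = length(above))
}

#' Evaluate the fitted mean curve and its offset bounds
#'
#' @param object A `qstat` model.
#' @param newdata Resolutions (A): a numeric vector or a data frame with a
#'   `d` column. Defaults to the fitted resolutions.
#' @param ... Unused.
#' @return Data frame with columns `d`, `q_mean`, `q_peak`, `q_low`,
#'   `q_high`, `extrapolated` (TRUE outside the fitted domain).
#' @export
predict.qstat <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d
       else if (is.data.frame(newdata)) newdata$d else as.numeric(newdata)
  stopifnot(all(d > 0))
  qm <- polyval(object$coefficients, d)
  data.frame(d = d, q_mean = qm,
             q_peak = qm + object$offsets$peak,
             q_low = qm + object$offsets$low,
             q_high = qm + object$offsets$high,
             extrapolated = d < object$domain[1] | d > object$domain[2])
}

#' Simulate archive tables from a fitted qstat model
#'
#' Draws new tables by resampling the fitted resolutions and residuals
#' with replacement and adding the residuals to the mean curve -- a simple
#' bootstrap of the archive preserving the skewed residual distribution.
#'
#' @param object A `qstat` model.
#' @param nsim Number of tables.
#' @param seed Optional integer seed.
#' @param n Rows per table (default: the fitted n).
#' @param ... Unused.
#' @return A list of `archive_table`s (length `nsim`).
#' @export
simulate.qstat <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  sim1 <- function() {
    d <- sample(object$data$d, n, replace = TRUE)
    r <- sample(object$data$residual, n, replace = TRUE)
    archive_table(sprintf("sim%06d", seq_len(n)), d,
                  polyval(object$coefficients, d) + r)
  }
  if (is.null(seed)) replicate(nsim, sim1(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, sim1(), simplify = FALSE))
}

#' Plot an archive fit
#'
#' Scatter of the fitted archive with the mean, peak and 95% bound curves.
#'
#' @param x A `qstat` model.
#' @param ... Passed to [graphics::plot].
#' @export
plot.qstat <- function(x, ...) {
  graphics::plot(x$data$d, x$data$q, pch = 16, cex = 0.3,
                 col = grDevices::grey(0.4, 0.4),
                 xlab = "reported resolution d (Å)", ylab = "Q-score", ...)
  dd <- seq(x$domain[1], x$domain[2], length.out = 200L)
  b <- predict(x, dd)
  graphics::lines(dd, b$q_mean, col = "black", lwd = 2)
  graphics::lines(dd, b$q_peak, col = "orange", lwd = 2)
  graphics::lines(dd, b$q_low, col = "red", lty = 2)
  graphics::lines(dd, b$q_high, col = "blue", lty = 2)
  graphics::legend("topright", bty = "n", lwd = c(2, 2, 1, 1),
                   lty = c(1, 1, 2, 2),
                   col = c("black", "orange", "red", "blue"),
                   legend = c("Q_mean", "Q_peak", "Q_low_95%", "Q_high_95%"))
  invisible(x)
}

#' Rolling-window percentile curves
#'
#' A regression-free alternative to the offset curves: at each grid
#' resolution, empirical percentiles of Q among entries within
#' `window / 2`. Windows with fewer than `min_n` entries yield `NA` (gap).
#'
#' @param data An `archive_table`.
#' @param window Total window width (A).
#' @param percentiles Percentile levels in (0, 1).
#' @param grid Resolutions at which to evaluate; default 0.1 A steps over
#'   the data range.
#' @param min_n Minimum entries per window.
#' @return Data frame with column `d` and one `p<level>` column per
#'   percentile.
#' @export
rolling_percentiles <- function(data, window = 0.5,
                                percentiles = c(0.05, 0.5, 0.95),
                                grid = NULL, min_n = 20L) {
  stopifnot(nrow(data) > 0L, window > 0)
  if (is.null(grid))
    grid <- seq(min(data$d), max(data$d), by = 0.1)
  if (length(grid) == 0L) stop("empty evaluation grid")
  out <- matrix(NA_real_, length(grid), length(percentiles))
  for (i in seq_along(grid)) {
    qi <- data$q[abs(data$d - grid[i]) <= window / 2]
    if (length(qi) >= min_n)
      out[i, ] <- stats::quantile(qi, percentiles, type = 7)
  }
  colnames(out) <- sprintf("p%g", 100 * percentiles)
  cbind(data.frame(d = grid), as.data.frame(out))
}

#' Classify an entry against the archive bounds
#'
#' @param q Model Q-score of the entry.
#' @param d Reported resolution (A).
#' @param fit A `qstat` model.
#' @return `"below_low"`, `"typical"` or `"above_high"` (strict
#'   comparisons against the bounds at `d`).
#' @export
classify_entry <- function(q, d, fit) {
  b <- predict(fit, d)
  ifelse(q < b$q_low, "below_low",
         ifelse(q > b$q_high, "above_high", "typical"))
}
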