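#' Percentile rank of a Q-score against the whole archive
#'
#' `100 * (number of entries with a strictly lower Q) / (total entries)`.
#' Ties do not count toward the numerator; an entry present in the table
#' stays in its own denominator.
#'
#' @param q Q-score(s) to rank (vectorized).
#' @param data An `archive_table`.
#' @param strict Use strict `<` (default); `FALSE` counts ties too.
#' @return Percent value(s) in `[0, 100]`.
#' @export
q_relative_all <- function(q, data, strict = TRUE) {
  if (nrow(data) == 0L) stop("archive table is empty")
  vapply(q, function(qi) {
    100 * (if (strict) sum(data$q < qi) else sum(data$q <= qi)) / nrow(data)
  }, numeric(1))
}

#' Percentile rank within a resolution window
#'
#' Ranks `q` against entries whose reported resolution lies within the
#' window around `d`: `|d_i - d| <= w/2` by default (total window width
#' `w`), or `|d_i - d| <= w` with `half_width = FALSE`.
#'
#' @param q Q-score of the entry.
#' @param d Reported resolution of the entry (A).
#' @param data An `archive_table`.
#' @param w Window size (A); default 0.5 A, below which the metric shows
#'   little correlation with resolution itself.
#' @param strict Strict `<` for "lower than" (default).
#' @param half_width If `TRUE` (default) the comparator set is
#'   `|d_i - d| <= w/2`.
#' @return List with `percent` and `n_window`; `percent` is `NA` (with a
#'   warning) if the window is empty.
#' @export
q_relative_resolution <- function(q, d, data, w = 0.5, strict = TRUE,
                                  half_width = TRUE) {
  if (nrow(data) == 0L) stop("archive table is empty")
  hw <- if (half_width) w / 2 else w
  qs <- data$q[abs(data$d - d) <= hw]
  if (length(qs) == 0L) {
    warning("no archive entries within ", hw, " A of d = ", d)
    return(list(percent = NA_real_, n_window = 0L))
  }
  num <- if (strict) sum(qs < q) else sum(qs <= q)
  list(percent = 100 * num / length(qs), n_window = length(qs))
}

#' Comparator-set sizes across the archive for a window size
#'
#' For each entry with resolution in `d_range`, counts the entries (itself
#' included) within its resolution window, and summarizes the counts.
#'
#' @param data An `archive_table`.
#' @param w Window size (A).
#' @param d_range Entries considered, default `c(1, 10)` A.
#' @param half_width Window convention as in [q_relative_resolution].
#' @return List `min`, `mean`, `max` of per-entry comparator counts.
#' @export
window_entry_counts <- function(data, w, d_range = c(1, 10),
                                half_width = TRUE) {
  d <- data$d[data$d >= d_range[1] & data$d <= d_range[2]]
  if (length(d) == 0L) stop("no entries in resolution range")
  hw <- if (half_width) w / 2 else w
  ds <- sort(d)
  counts <- findInterval(d + hw, ds) - findInterval(d - hw, ds, left.open = TRUE)
  list(min = min(counts), mean = mean(counts), max = max(counts))
}

#' Correlation of the windowed percentile with resolution, by window size
#'
#' For each window size, computes `q_relative_resolution` for every entry,
#' then the Pearson correlation of that percentile with reported
#' resolution, separately for entries below and at/above `split_d`. A good
#' window size leaves the percentile uncorrelated with resolution.
#'
#' @param data An `archive_table`.
#' @param windows Window sizes (A); default the scan
#'   `0.1, 0.2, ..., 1.0, 1.2, 1.5`.
#' @param split_d Stratum boundary (A), default 5.
#' @param strict,half_width Conventions as in [q_relative_resolution].
#' @return Data frame with columns `w`, `cor_low_d` (entries with
#'   `d < split_d`), `cor_high_d` (`d >= split_d`); `NA` where a stratum
#'   has fewer than 3 entries or a constant percentile.
#' @export
window_correlation_scan <- function(data,
                                    windows = c(seq(0.1, 1.0, by = 0.1),
                                                1.2, 1.5),
                                    split_d = 5, strict = TRUE,
                                    half_width = TRUE) {
  stopifnot(nrow(data) >= 3L)
  ord <- order(data$d)
  ds <- data$d[ord]
  qs <- data$q[ord]
  strat <- list(low = which(data$d < split_d), high = which(data$d >= split_d))
  out <- data.frame(w = windows, cor_low_d = NA_real_, cor_high_d = NA_real_)
  for (wi in seq_along(windows)) {
    hw <- if (half_width) windows[wi] / 2 else windows[wi]
    lo <- findInterval(data$d - hw, ds, left.open = TRUE)
    hi <- findInterval(data$d + hw, ds)
    rel <- vapply(seq_len(nrow(data)), function(i) {
      win <- qs[(lo[i] + 1L):hi[i]]
      num <- if (strict) sum(win < data$q[i]) else sum(win <= data$q[i])
      100 * num / length(win)
    }, numeric(1))
    for (s in 1:2) {
      idx <- strat[[s]]
      if (length(idx) >= 3L && stats::sd(rel[idx]) > 0 &&
          stats::sd(data$d[idx]) > 0)
        out[wi, s + 1L] <- stats::cor(rel[idx], data$d[idx])
    }
  }
  out
}
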