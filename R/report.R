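#' Single-entry map/model quality report
#'
#' Combines the whole pipeline for one entry: model Q-score, the archive
#' bounds at its reported resolution, the resulting classification, and
#' the two percentile metrics (overall and within a resolution window).
#'
#' @param map Experimental [density_map] (or `NULL` if `q` is supplied).
#' @param model An `atomic_model` (or `NULL` if `q` is supplied).
#' @param d Reported resolution (A).
#' @param archive An `archive_table` of comparator entries.
#' @param fit Optional pre-fitted `qstat` model; fitted from `archive`
#'   when `NULL`.
#' @param w Resolution-window size (A), default 0.5.
#' @param q Optional precomputed model Q-score (skips scoring).
#' @param protocol A [sampling_protocol] used when scoring.
#' @return A `qreport` list: `entry_id`, `d`, `q`, `bounds` (one-row data
#'   frame from [predict.qstat]), `classification`, `q_rel_all`,
#'   `q_rel_res`, `n_window`, `w`.
#' @export
report_entry <- function(map = NULL, model = NULL, d, archive, fit = NULL,
                         w = 0.5, q = NULL,
                         protocol = sampling_protocol()) {
  if (is.null(q)) {
    if (is.null(map) || is.null(model))
      stop("supply either a precomputed 'q' or both 'map' and 'model'")
    q <- qscore(map, model, protocol)$model_q
  }
  if (is.null(fit)) fit <- qstat_fit(archive)
  rel <- q_relative_resolution(q, d, archive, w = w)
  structure(list(
    entry_id = if (!is.null(model)) attr(model, "entry_id") else "entry",
    d = d, q = q,
    bounds = predict(fit, d),
    classification = classify_entry(q, d, fit),
    q_rel_all = q_relative_all(q, archive),
    q_rel_res = rel$percent, n_window = rel$n_window, w = w),
    class = "qreport")
}

#' @export
print.qreport <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "NA" else paste0(signif(p, 2), "%")
  cat(sprintf("entry %s  resolution %.2f A\n", x$entry_id, x$d))
  cat(sprintf("  Q-score          %.3g  (%s)\n", x$q, x$classification))
  cat(sprintf("  expected bounds  Q_peak %.3f, 95%% range [%.3f, %.3f]\n",
              x$bounds$q_peak, x$bounds$q_low, x$bounds$q_high))
  cat(sprintf("  Q_relative_all   %s\n", pct(x$q_rel_all)))
  cat(sprintf("  Q_relative_res   %s  (window %g A, n = %d)\n",
              pct(x$q_rel_res), x$w, x$n_window))
  invisible(x)
}

#' @export
as.data.frame.qreport <- function(x, ...) {
  data.frame(entry_id = x$entry_id, d = x$d, q = x$q,
             q_mean = x$bounds$q_mean, q_peak = x$bounds$q_peak,
             q_low = x$bounds$q_low, q_high = x$bounds$q_high,
             classification = x$classification,
             q_rel_all = x$q_rel_all, q_rel_res = x$q_rel_res,
             n_window = x$n_window, w = x$w,
             stringsAsFactors = FALSE)
}
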