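#' Summarize a smooth signal per segment
#'
#' Cuts the uniform-grid signal into the half-open windows
#' `[t_start, t_end)` of a segment table and computes descriptive metrics
#' per segment: mean, maximum, minimum, standard deviation (n - 1
#' denominator; `NA` below 2 points) of the non-missing grid values, the
#' missing-data percentage, and the grid-point count. Segments whose
#' missing percentage exceeds `max_missing_pct` are flagged `rejected`,
#' never silently dropped; a segment entirely outside the signal span has
#' 100% missing and is flagged.
#'
#' @param signal A `smooth_signal` from [process_signal()].
#' @param segments A [segment_table()].
#' @param max_missing_pct Maximum tolerable missing-data percentage
#'   (0-100). Dataset-dependent; there is no default.
#' @return A `data.frame`: `segment_id`, `label`, `mean_mm`, `max_mm`,
#'   `min_mm`, `sd_mm`, `missing_pct`, `n_grid_points`, `rejected`
#'   (plus `trial_id` when the table carries one).
#' @export
summarize_segments <- function(signal, segments, max_missing_pct) {
  stopifnot(inherits(signal, "smooth_signal"),
            inherits(segments, "segment_table"))
  if (missing(max_missing_pct) || is.null(max_missing_pct)) {
    stop("max_missing_pct is required and has no default; choose a value ",
         "appropriate for the dataset")
  }
  rows <- lapply(seq_len(nrow(segments)), function(r) {
    seg <- segments[r, ]
    inwin <- signal$timestamp_s >= seg$t_start_s &
             signal$timestamp_s < seg$t_end_s
    v <- signal$diameter_mm[inwin]
    n_grid <- sum(inwin)
    n_ok <- sum(!is.na(v))
    # a window the signal never reaches has no grid points: all missing
    missing_pct <- if (n_grid == 0L) 100 else 100 * (n_grid - n_ok) / n_grid
    data.frame(
      segment_id = seg$segment_id, label = seg$label,
      mean_mm = if (n_ok > 0) mean(v, na.rm = TRUE) else NA_real_,
      max_mm = if (n_ok > 0) max(v, na.rm = TRUE) else NA_real_,
      min_mm = if (n_ok > 0) min(v, na.rm = TRUE) else NA_real_,
      sd_mm = if (n_ok >= 2) stats::sd(v[!is.na(v)]) else NA_real_,
      missing_pct = missing_pct, n_grid_points = n_grid,
      rejected = missing_pct > max_missing_pct,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(segments$trial_id)) out$trial_id <- segments$trial_id
  rownames(out) <- NULL
  out
}

#' Bin a segment of the smooth signal into fixed-width means
#'
#' Averages the signal over consecutive half-open bins of `bin_ms`
#' starting at the segment's `t_start`, producing a coarse time course
#' (e.g. 100-ms means) suitable for multilevel time-course statistics.
#' Bins with no non-missing grid points are `NA`; a trailing partial bin
#' is kept and flagged.
#'
#' @param signal A `smooth_signal`.
#' @param segment One row of a [segment_table()] (or any list with
#'   `segment_id`, `t_start_s`, `t_end_s`).
#' @param bin_ms Bin width in milliseconds.
#' @return A `data.frame`: `segment_id`, `bin_index` (1-based),
#'   `bin_t_center_s`, `mean_mm`, `n_points`, `partial`.
#' @export
bin_timecourse <- function(signal, segment, bin_ms = 100) {
  stopifnot(inherits(signal, "smooth_signal"), bin_ms > 0)
  bw <- bin_ms / 1000
  span <- segment$t_end_s - segment$t_start_s
  n_bins <- ceiling(span / bw - 1e-9)
  inwin <- signal$timestamp_s >= segment$t_start_s &
           signal$timestamp_s < segment$t_end_s
  tt <- signal$timestamp_s[inwin]
  vv <- signal$diameter_mm[inwin]
  # nanosecond slack keeps half-open bin boundaries stable on fp grids
  idx <- pmin(floor((tt - segment$t_start_s) / bw + 1e-9) + 1L, n_bins)
  out <- data.frame(
    segment_id = segment$segment_id,
    bin_index = seq_len(n_bins),
    bin_t_center_s = segment$t_start_s + (seq_len(n_bins) - 0.5) * bw,
    mean_mm = NA_real_, n_points = 0L,
    partial = c(rep(FALSE, n_bins - 1L),
                span - (n_bins - 1L) * bw < bw - 1e-9))
  for (b in seq_len(n_bins)) {
    v <- vv[idx == b & !is.na(vv)]
    out$n_points[b] <- length(v)
    if (length(v) > 0) out$mean_mm[b] <- mean(v)
  }
  out$bin_t_center_s[n_bins] <- if (out$partial[n_bins]) {
    ((n_bins - 1L) * bw + span) / 2 + segment$t_start_s
  } else out$bin_t_center_s[n_bins]
  out
}

#' Pair each response segment with its baseline
#'
#' Restructures a segment-metrics table so that every response segment
#' carries its own metrics plus its baseline's mean, ready for whatever
#' baseline correction (subtractive, divisive) the analysis calls for -
#' no correction is applied here. Baselines and responses are matched
#' within `trial_id` when the metrics carry one; otherwise each response
#' takes the nearest preceding baseline row. A response with no matching
#' baseline gets an `NA` baseline mean and is flagged.
#'
#' @param metrics Output of [summarize_segments()].
#' @param baseline_label,response_label Segment labels identifying the
#'   two roles.
#' @return A `data.frame`: the response rows of `metrics` plus
#'   `baseline_segment_id`, `baseline_mean_mm`, `baseline_missing` flag.
#' @export
pair_baselines <- function(metrics, baseline_label = "baseline",
                           response_label = "trial") {
  base <- metrics[metrics$label == baseline_label, , drop = FALSE]
  resp <- metrics[metrics$label == response_label, , drop = FALSE]
  if (nrow(resp) == 0L) stop("no segments labeled '", response_label, "'")
  find_base <- function(r) {
    if (!is.null(metrics$trial_id)) {
      hit <- base[!is.na(base$trial_id) & base$trial_id == r$trial_id, ]
      if (nrow(hit) > 1L) {
        stop("trial_id ", r$trial_id, " has ", nrow(hit),
             " baseline segments; pairing must be unique")
      }
      if (nrow(hit) == 1L) return(hit)
    } else {
      # adjacency fallback: nearest preceding baseline in row order
      pos <- which(metrics$segment_id == r$segment_id)
      bpos <- which(metrics$label == baseline_label & seq_len(nrow(metrics)) < pos)
      if (length(bpos) > 0L) return(metrics[max(bpos), , drop = FALSE])
    }
    NULL
  }
  out <- resp
  out$baseline_segment_id <- NA_integer_
  out$baseline_mean_mm <- NA_real_
  for (r in seq_len(nrow(resp))) {
    b <- find_base(resp[r, ])
    if (!is.null(b)) {
      out$baseline_segment_id[r] <- b$segment_id
      out$baseline_mean_mm[r] <- b$mean_mm
    }
  }
  out$baseline_missing <- is.na(out$baseline_segment_id)
  rownames(out) <- NULL
  out
}
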