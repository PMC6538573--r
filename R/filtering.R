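#' Dilation speed of a pupil size series
#'
#' For each sample the dilation speed is the maximum absolute
#' size change to the preceding or succeeding sample, normalized by the
#' corresponding time difference (mm/s). Normalizing by the temporal
#' separation makes changes comparable under nonuniform sampling and
#' across gaps. The first and last samples have only one neighbor and use
#' that single-sided speed.
#'
#' @param t Strictly increasing timestamps in seconds, length >= 2.
#' @param d Pupil diameters in mm, no missing entries (call on the
#'   present-sample subsequence of one eye).
#' @return Nonnegative numeric vector, same length as `d`, in mm/s.
#' @export
compute_dilation_speed <- function(t, d) {
  n <- length(t)
  if (n < 2L) stop("insufficient data: need >= 2 samples for dilation speed")
  if (length(d) != n) stop("t and d must have equal length")
  if (anyNA(d)) stop("d must not contain missing values")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  step <- abs(diff(d) / diff(t))          # step[i] between samples i, i+1
  pmax(c(step[1], step), c(step, step[n - 1L]))
}

#' Robust MAD-based outlier threshold
#'
#' `median(x) + multiplier * median(|x - median(x)|)`. The median
#' absolute deviation is an outlier-resilient dispersion estimate, so the
#' threshold is not dragged up by the very artifacts it is meant to
#' catch. Used for both dilation-speed and trend-line-deviation
#' filtering. Note the raw MAD is used, without a consistency constant.
#'
#' @param x Nonnegative numeric vector, length >= 1.
#' @param multiplier Positive scalar `n`.
#' @param epsilon Lower floor for the threshold (default 0, i.e. the
#'   plain formula; see [filter_settings()]).
#' @return Scalar threshold; values strictly above it are outliers.
#' @export
mad_threshold <- function(x, multiplier, epsilon = 0) {
  if (length(x) == 0L) stop("mad_threshold: empty input")
  if (multiplier <= 0) stop("multiplier must be > 0")
  med <- stats::median(x)
  max(med + multiplier * stats::median(abs(x - med)), epsilon)
}

#' Feasible-range gate
#'
#' Pupil diameters outside a physiologically feasible range carry no
#' information and are rejected outright. Bounds are inclusive; missing
#' samples are marked invalid (they hold no diameter).
#'
#' @param d Diameter series in mm (`NA` allowed).
#' @param settings A [filter_settings()].
#' @return Logical stage mask, `TRUE` where the sample survives.
#' @export
filter_range <- function(d, settings = filter_settings()) {
  !is.na(d) & d >= settings$range_min_mm & d <= settings$range_max_mm
}

#' Dilation-speed outlier rejection
#'
#' Computes dilation speeds over the currently valid subsequence and
#' rejects samples whose speed strictly exceeds the MAD threshold.
#' Artifacts such as blinks produce disproportionately large intersample
#' changes, while genuine dilation and constriction are slow.
#'
#' @param t Timestamps (full series, seconds).
#' @param d Diameters (full series, mm; `NA` allowed).
#' @param valid Logical mask of samples surviving prior stages.
#' @param settings A [filter_settings()].
#' @return List: `mask` (logical over the full series; `FALSE` where
#'   rejected here or already invalid), `threshold` (mm/s), `speed`
#'   (full-length, `NA` off the valid subsequence).
#' @export
filter_speed_outliers <- function(t, d, valid = !is.na(d),
                                  settings = filter_settings()) {
  idx <- which(valid)
  speed_full <- rep(NA_real_, length(d))
  if (length(idx) < 2L) {
    return(list(mask = valid, threshold = NA_real_, speed = speed_full))
  }
  sp <- compute_dilation_speed(t[idx], d[idx])
  thr <- mad_threshold(sp, settings$speed_mad_multiplier,
                       settings$min_threshold_epsilon)
  speed_full[idx] <- sp
  mask <- valid
  mask[idx[sp > thr]] <- FALSE
  list(mask = mask, threshold = thr, speed = speed_full)
}

# Qualifying gaps between consecutive present samples: strictly longer
# than min_duration. Returns a 2-column matrix of edge times (t_last,
# t_first). The recording's start and end are not gap edges.
find_gaps <- function(t, present, min_duration_s) {
  tv <- t[present]
  if (length(tv) < 2L) return(matrix(numeric(0), ncol = 2))
  dt <- diff(tv)
  hit <- which(dt > min_duration_s)
  cbind(tv[hit], tv[hit + 1L])
}

#' Gap-edge (blink-edge) rejection
#'
#' Blinks leave missing-data gaps whose bordering samples are often
#' contaminated by eyelid occlusion (spurious dips in apparent pupil
#' size). Samples within the margin (inclusive) of either edge of a
#' qualifying gap - a contiguous missing section strictly longer than
#' `gap_min_duration_ms` - are rejected. Gaps are measured between
#' consecutive present samples after prior rejections.
#'
#' @param t Timestamps (seconds).
#' @param present Logical mask of currently present samples.
#' @param settings A [filter_settings()].
#' @return Logical stage mask over the full series.
#' @export
reject_gap_edges <- function(t, present, settings = filter_settings()) {
  mask <- present
  tv <- t[present]
  if (length(tv) == 0L) return(mask)
  min_dur <- settings$gap_min_duration_ms / 1000
  eps <- 1e-9   # nanosecond slack so the inclusive margin survives fp grids
  margin <- settings$gap_edge_margin_ms / 1000 + eps
  gaps <- find_gaps(t, present, min_dur)
  for (g in seq_len(nrow(gaps))) {
    near <- (t >= gaps[g, 1] - margin & t <= gaps[g, 1]) |
            (t >= gaps[g, 2] & t <= gaps[g, 2] + margin)
    mask[near] <- FALSE
  }
  # a missing run before the first (after the last) sample of this eye is
  # a gap too; only its sample-adjacent edge can produce rejections - the
  # recording's own start and end are not gap edges
  if (tv[1] - t[1] > min_dur) {
    mask[t >= tv[1] & t <= tv[1] + margin] <- FALSE
  }
  if (t[length(t)] - tv[length(tv)] > min_dur) {
    mask[t >= tv[length(tv)] - margin & t <= tv[length(tv)]] <- FALSE
  }
  mask & present
}

#' Build a smooth trend line through valid samples
#'
#' Linear interpolation of the currently valid samples onto a uniform
#' grid followed by the same zero-phase low-pass smoother used for final
#' signal processing (cutoff `trendline_cutoff_hz`). The trend line
#' scores how far each sample strays from the smooth course of the
#' signal; it is never an output itself.
#'
#' @param t_valid,d_valid Valid sample times (s) and diameters (mm),
#'   >= 2 samples.
#' @param settings A [filter_settings()].
#' @return List `(grid, trend, at)` where `at(times)` evaluates the trend
#'   at arbitrary times by interpolation (constant beyond the ends).
#' @export
build_trendline <- function(t_valid, d_valid,
                            settings = filter_settings()) {
  if (length(t_valid) < 2L) {
    stop("insufficient data: need >= 2 valid samples for a trend line")
  }
  rate <- settings$trendline_rate_hz
  up <- upsample(t_valid, d_valid,
                 processing_settings(target_rate_hz = rate,
                                     lowpass_cutoff_hz = settings$trendline_cutoff_hz))
  sm <- tryCatch(
    lowpass_zero_phase(up$diameter_mm, rate,
                       cutoff_hz = settings$trendline_cutoff_hz),
    error = function(e) up$diameter_mm)  # too short to filter: raw interpolant
  at <- function(times) {
    stats::approx(up$timestamp_s, sm, xout = times, rule = 2)$y
  }
  list(grid = up$timestamp_s, trend = sm, at = at)
}

#' Multipass trend-line deviation rejection
#'
#' Clusters of erroneous samples resist dilation-speed filtering (their
#' mutual changes are small) but sit far from the signal's smooth trend
#' line. Each pass builds a trend from the currently valid samples,
#' scores the absolute deviation of every sample considered in the first
#' pass, and rejects those strictly above the MAD threshold of the
#' deviations. Because an outlying cluster pulls the first trend line
#' toward itself, a later pass - with the cluster gone - may reinstate
#' valid samples that the first pass rejected.
#'
#' @param t,d Full series timestamps (s) and diameters (mm).
#' @param valid Logical mask at entry to this stage; this fixes the set
#'   of samples the filter considers (and may reinstate).
#' @param settings A [filter_settings()].
#' @return List: `mask`, `thresholds` (one per pass, mm), `passes`.
#' @export
filter_trendline_deviation <- function(t, d, valid = !is.na(d),
                                       settings = filter_settings()) {
  scope <- valid                     # samples considered in pass 1
  cur <- valid
  thresholds <- numeric(0)
  for (k in seq_len(settings$deviation_passes)) {
    if (sum(cur) < 2L) break
    tl <- build_trendline(t[cur], d[cur], settings)
    dev <- abs(d[scope] - tl$at(t[scope]))
    thr <- mad_threshold(dev, settings$deviation_mad_multiplier,
                         settings$min_threshold_epsilon)
    thresholds <- c(thresholds, thr)
    cur <- scope
    cur[scope] <- dev <= thr
  }
  list(mask = cur, thresholds = thresholds, passes = length(thresholds))
}

#' Sparsity (temporal isolation) rejection
#'
#' A proper pupil size signal is temporally contiguous; short secluded
#' islands of samples inside large gaps are usually glitches (e.g.
#' erroneous pupil detection during closed eyes). The valid samples are
#' split at gaps strictly larger than `sparsity_split_gap_ms`; resulting
#' sections spanning (last minus first timestamp) less than
#' `sparsity_min_section_ms` are wholly rejected. A lone sample spans
#' 0 ms and is always rejected.
#'
#' @param t Timestamps (seconds).
#' @param valid Logical mask of currently valid samples.
#' @param settings A [filter_settings()].
#' @return Logical stage mask over the full series.
#' @export
filter_sparsity <- function(t, valid, settings = filter_settings()) {
  idx <- which(valid)
  mask <- valid
  if (length(idx) == 0L) return(mask)
  tv <- t[idx]
  split_s <- settings$sparsity_split_gap_ms / 1000
  min_s <- settings$sparsity_min_section_ms / 1000
  section <- cumsum(c(0, diff(tv) > split_s))
  for (s in unique(section)) {
    members <- idx[section == s]
    if (t[members[length(members)]] - t[members[1]] < min_s) {
      mask[members] <- FALSE
    }
  }
  mask
}

#' Run the full raw-data filter on one eye
#'
#' Applies, in order: feasible-range gate, dilation-speed outlier
#' rejection, gap-edge rejection, multipass trend-line deviation
#' rejection, and the sparsity filter. Each stage sees only samples still
#' valid (the deviation filter may reinstate within its own scope).
#'
#' @param t,d Timestamps (s) and one eye's diameters (mm, `NA` allowed).
#' @param settings A [filter_settings()].
#' @return A `validity_mask`: list of logical layers `range`, `speed`,
#'   `gap_edge`, `deviation`, `sparsity`, and `combined` (their
#'   conjunction), plus `thresholds` and a per-stage `report`.
#' @export
filter_eye <- function(t, d, settings = filter_settings()) {
  present <- !is.na(d)
  m_range <- filter_range(d, settings)
  sp <- filter_speed_outliers(t, d, m_range, settings)
  m_speed <- sp$mask
  m_gap <- reject_gap_edges(t, m_speed, settings)
  dv <- filter_trendline_deviation(t, d, m_gap, settings)
  m_dev <- dv$mask
  m_sparse <- filter_sparsity(t, m_dev, settings)
  combined <- m_range & m_speed & m_gap & m_dev & m_sparse
  # deviation reinstatement can only act within its scope (m_gap), so the
  # conjunction equals the sequential result
  stopifnot(identical(combined, m_sparse & m_dev))
  n_present <- sum(present)
  stage_counts <- c(
    range = sum(present & !m_range),
    speed = sum(m_range & !m_speed),
    gap_edge = sum(m_speed & !m_gap),
    deviation = sum(m_gap & !m_dev),
    sparsity = sum(m_dev & !m_sparse))
  structure(
    list(range = m_range, speed = m_speed, gap_edge = m_gap,
         deviation = m_dev, sparsity = m_sparse, combined = combined,
         thresholds = list(speed_mm_per_s = sp$threshold,
                           deviation_mm = dv$thresholds),
         report = list(
           n_samples = length(d), n_present = n_present,
           rejected = as.list(stage_counts),
           rejected_pct = as.list(
             if (n_present > 0) 100 * stage_counts / n_present
             else stage_counts * 0),
           n_valid = sum(combined),
           pct_valid = if (n_present > 0) 100 * sum(combined) / n_present
                       else 0)),
    class = "validity_mask")
}

#' Run the raw-data filter on a recording
#'
#' Filters each recorded eye independently with [filter_eye()].
#'
#' @param rec A [raw_recording()].
#' @param settings A [filter_settings()].
#' @return List of class `filter_result`: `left`, `right` (each a
#'   `validity_mask` or `NULL` for an unrecorded eye), `settings`, and a
#'   merged `report`.
#' @export
run_filter_pipeline <- function(rec, settings = filter_settings()) {
  stopifnot(inherits(rec, "raw_recording"))
  eyes <- list()
  for (eye in c("left", "right")) {
    d <- rec[[paste0(eye, "_mm")]]
    if (all(is.na(d))) { eyes[eye] <- list(NULL); next }
    vm <- filter_eye(rec$timestamps, d, settings)
    if (vm$report$n_valid == 0L) {
      warning("all ", eye, "-eye samples rejected by the raw-data filter")
    }
    eyes[[eye]] <- vm
  }
  structure(
    list(left = eyes$left, right = eyes$right, settings = settings,
         report = list(
           settings = unclass(settings),
           left = if (!is.null(eyes$left)) eyes$left$report,
           right = if (!is.null(eyes$right)) eyes$right$report,
           thresholds = list(
             left = if (!is.null(eyes$left)) eyes$left$thresholds,
             right = if (!is.null(eyes$right)) eyes$right$thresholds))),
    class = "filter_result")
}

#' Write a raw-data filter report as JSON
#'
#' @param fr A `filter_result` from [run_filter_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(fr, path) {
  stopifnot(inherits(fr, "filter_result"))
  jsonlite::write_json(fr$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
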