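#' Fuse left- and right-eye samples into a mean pupil size series
#'
#' The two pupils are highly correlated but differ by a slowly varying
#' size offset. At time points where both eyes have a sample (matched by
#' mutual nearest neighbors within half the median inter-sample
#' interval), the fused value is the plain mean `(L + R) / 2`. The signed
#' offset `R - L` observed at those double-coverage points is linearly
#' interpolated (held constant beyond the first/last such point) to times
#' where only one eye has data, so that single-eye stretches contribute
#' `L + offset/2` or `R - offset/2` instead of a biased raw value.
#'
#' @param t_left,d_left Valid left-eye sample times (s) and diameters
#'   (mm); may be empty for monocular data.
#' @param t_right,d_right Ditto for the right eye.
#' @return A `data.frame` with `timestamp_s`, `diameter_mm`, and `source`
#'   (`"both"`, `"left"`, `"right"`), sorted by time.
#' @export
combine_eyes <- function(t_left, d_left, t_right, d_right) {
  mono <- function(t, d, src) {
    data.frame(timestamp_s = t, diameter_mm = d,
               source = rep_len(src, length(t)), stringsAsFactors = FALSE)
  }
  if (length(t_left) == 0L && length(t_right) == 0L) {
    stop("combine_eyes: no valid samples in either eye")
  }
  if (length(t_right) == 0L) return(mono(t_left, d_left, "left"))
  if (length(t_left) == 0L) return(mono(t_right, d_right, "right"))

  tol <- stats::median(c(diff(t_left), diff(t_right))) / 2
  if (!is.finite(tol)) tol <- Inf   # single-sample eyes

  # mutual nearest-neighbor pairing within tol
  nearest <- function(a, b) {
    # for each element of a, index of nearest element of sorted b
    j <- findInterval(a, b)
    j0 <- pmax(j, 1L); j1 <- pmin(j + 1L, length(b))
    ifelse(abs(a - b[j0]) <= abs(b[j1] - a), j0, j1)
  }
  jr <- nearest(t_left, t_right)     # candidate right partner per left
  jl <- nearest(t_right, t_left)     # candidate left partner per right
  i <- seq_along(t_left)
  paired <- jl[jr] == i & abs(t_left - t_right[jr]) <= tol
  pl <- which(paired); pr <- jr[paired]

  if (length(pl) == 0L) {
    warning("no double-coverage points: left-right offset unidentifiable; ",
            "passing through the eye with more samples unadjusted")
    if (length(t_left) >= length(t_right)) return(mono(t_left, d_left, "left"))
    return(mono(t_right, d_right, "right"))
  }

  tp <- (t_left[pl] + t_right[pr]) / 2
  offset <- d_right[pr] - d_left[pl]
  off_at <- function(times) {
    if (length(tp) == 1L) rep(offset, length(times))
    else stats::approx(tp, offset, xout = times, rule = 2)$y
  }
  lo <- setdiff(i, pl)
  ro <- setdiff(seq_along(t_right), pr)
  out <- rbind(
    mono(tp, (d_left[pl] + d_right[pr]) / 2, "both"),
    mono(t_left[lo], d_left[lo] + off_at(t_left[lo]) / 2, "left"),
    mono(t_right[ro], d_right[ro] - off_at(t_right[ro]) / 2, "right"))
  out <- out[order(out$timestamp_s), , drop = FALSE]
  out <- out[!duplicated(out$timestamp_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resample valid samples onto a uniform high-rate grid
#'
#' Linear interpolation of the (nonuniformly spaced) valid samples onto a
#' uniform grid at `target_rate_hz` spanning the closed interval from the
#' first to the last valid timestamp. No extrapolation beyond the data.
#'
#' @param t_valid,d_valid Valid sample times (s) and diameters (mm),
#'   >= 2 samples.
#' @param settings A [processing_settings()].
#' @return List with `timestamp_s` (uniform grid) and `diameter_mm`.
#' @export
upsample <- function(t_valid, d_valid, settings = processing_settings()) {
  if (length(t_valid) < 2L) {
    stop("insufficient data: need >= 2 valid samples to resample")
  }
  step <- 1 / settings$target_rate_hz
  span <- t_valid[length(t_valid)] - t_valid[1]
  grid <- t_valid[1] + step * seq.int(0L, floor(span / step + 1e-9))
  list(timestamp_s = grid,
       diameter_mm = stats::approx(t_valid, d_valid, xout = grid)$y)
}

#' Zero-phase low-pass smoothing
#'
#' A Butterworth low-pass applied forward and backward so the result has
#' zero phase shift (event latencies are preserved) and unit DC gain. The
#' series is odd-reflection padded at both ends before filtering so that
#' filter start-up transients decay inside the padding, not the data.
#'
#' @param x Uniformly sampled series (no missing values).
#' @param rate_hz Sampling rate of `x`.
#' @param cutoff_hz Cutoff frequency; must be below `rate_hz / 2`.
#' @param order Butterworth order per direction (default 1).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, rate_hz, cutoff_hz = 4, order = 1) {
  n <- length(x)
  min_len <- 3 * (2 * order + 1)
  if (n <= min_len) {
    stop("series too short for stable zero-phase filtering (length ", n,
         ", need > ", min_len, ")")
  }
  if (anyNA(x)) stop("x must not contain missing values")
  if (cutoff_hz >= rate_hz / 2) stop("cutoff must be below the Nyquist rate")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(n - 1L, ceiling(3 * rate_hz / cutoff_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Mask grid points interpolated across large gaps
#'
#' Interpolation bridges gaps in the valid samples; across long gaps the
#' bridged values are fabrications, not measurements. Grid points lying
#' strictly between two consecutive raw valid samples separated by more
#' than `max_interp_gap_ms` are set missing.
#'
#' @param grid_t Uniform grid timestamps.
#' @param values Smoothed values on the grid.
#' @param t_valid Raw valid sample timestamps the grid was interpolated
#'   from.
#' @param settings A [processing_settings()].
#' @return List: `diameter_mm` (with `NA` in masked regions) and
#'   `interpolated_over_gap` (logical; which grid points were masked).
#' @export
mask_large_gaps <- function(grid_t, values, t_valid,
                            settings = processing_settings()) {
  max_gap <- settings$max_interp_gap_ms / 1000
  masked <- rep(FALSE, length(grid_t))
  if (length(t_valid) >= 2L) {
    dt <- diff(t_valid)
    for (g in which(dt > max_gap)) {
      masked <- masked | (grid_t > t_valid[g] & grid_t < t_valid[g + 1L])
    }
  }
  values[masked] <- NA_real_
  list(diameter_mm = values, interpolated_over_gap = masked)
}

#' Read a processed-signal CSV back into a smooth_signal
#'
#' Inverse of [write_processed()]; the grid rate is recovered from the
#' median grid spacing.
#'
#' @param path CSV written by [write_processed()].
#' @return A `smooth_signal`.
#' @export
read_processed <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(
    list(timestamp_s = df$timestamp_s, diameter_mm = df$diameter_mm,
         interpolated_over_gap = df$interpolated_over_gap == 1,
         rate_hz = 1 / stats::median(diff(df$timestamp_s)),
         source = df$source[1]),
    class = "smooth_signal")
}

#' Upsample, smooth, and gap-mask one valid-sample series
#'
#' The full valid-sample processing chain: linear resampling to a uniform
#' high-rate grid, zero-phase low-pass smoothing, then masking of grid
#' points that were interpolated across gaps larger than the limit
#' (smoothing happens first so that filter transients inside masked
#' regions are discarded with them).
#'
#' @param t_valid,d_valid Valid sample times (s) and diameters (mm).
#' @param settings A [processing_settings()].
#' @param source Label of the series origin: `"left"`, `"right"`, or
#'   `"mean"`.
#' @return A `smooth_signal`: list with `timestamp_s` (uniform grid),
#'   `diameter_mm` (`NA` in masked regions), `interpolated_over_gap`,
#'   `rate_hz`, `source`.
#' @export
process_signal <- function(t_valid, d_valid,
                           settings = processing_settings(),
                           source = "mean") {
  up <- upsample(t_valid, d_valid, settings)
  sm <- lowpass_zero_phase(up$diameter_mm, settings$target_rate_hz,
                           settings$lowpass_cutoff_hz,
                           settings$lowpass_order)
  mk <- mask_large_gaps(up$timestamp_s, sm, t_valid, settings)
  structure(
    list(timestamp_s = up$timestamp_s, diameter_mm = mk$diameter_mm,
         interpolated_over_gap = mk$interpolated_over_gap,
         rate_hz = settings$target_rate_hz, source = source),
    class = "smooth_signal")
}

#' @export
print.smooth_signal <- function(x, ...) {
  cat(sprintf(
    "<smooth_signal> source=%s, %d points at %g Hz, %.3f-%.3f s, %.1f%% missing\n",
    x$source, length(x$timestamp_s), x$rate_hz, x$timestamp_s[1],
    x$timestamp_s[length(x$timestamp_s)],
    100 * mean(is.na(x$diameter_mm))))
  invisible(x)
}

#' Write a processed signal as CSV
#'
#' Columns: `timestamp_s`, `diameter_mm` (empty where masked), `source`,
#' `interpolated_over_gap` (0/1).
#'
#' @param sig A `smooth_signal`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed provenance line.
#' @return `path`, invisibly.
#' @export
write_processed <- function(sig, path, header_comment = NULL) {
  stopifnot(inherits(sig, "smooth_signal"))
  df <- data.frame(
    timestamp_s = sig$timestamp_s,
    diameter_mm = sig$diameter_mm,
    source = sig$source,
    interpolated_over_gap = as.integer(sig$interpolated_over_gap))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}
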