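#' Describe a synthetic pupillometry recording scenario
#'
#' A scenario fully determines (given its seed) a two-eye synthetic
#' recording: a smooth physiological "true" pupil trace (a base diameter
#' plus slow sinusoids, all well inside the feasible 1.5-9 mm range),
#' Gaussian measurement noise, a slowly varying left-right size offset,
#' and injected artifacts of the classes a raw-data filter must handle:
#'
#' * blinks - missing gaps flanked by ramped occlusion dips on the edge
#'   samples (apparent size drops as the eyelid starts covering the
#'   pupil);
#' * spikes - isolated large-amplitude samples;
#' * clusters - short runs of consecutive samples displaced together;
#' * islands - short runs of retained samples inside large missing
#'   sections (temporally isolated samples).
#'
#' Sampling can be uniform or jittered: each nominal grid timestamp is
#' perturbed by up to `timestamp_jitter_pct` percent of the sampling
#' interval, preserving order.
#'
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @param duration_s,rate_hz Recording length and nominal sampling rate.
#' @param timestamp_jitter_pct Uniform timestamp perturbation, percent of
#'   the nominal interval (0 = uniform sampling; must stay below 50 to
#'   preserve strict ordering).
#' @param base_mm Mean true diameter (must lie in 1.5-9 mm).
#' @param sin_amp_mm,sin_freq_hz Amplitudes (mm) and frequencies (Hz,
#'   <= 1) of the slow sinusoids composing the true trace.
#' @param noise_sd_mm SD of the additive Gaussian measurement noise.
#' @param eye_offset_mm Mean right-minus-left size offset; it drifts
#'   slowly around this value.
#' @param n_blinks,blink_gap_ms,blink_dip_mm,blink_dip_ms Blink count,
#'   gap length, edge-dip depth, and dip ramp duration per edge.
#' @param n_spikes,spike_amp_mm Isolated-spike count and amplitude.
#' @param n_clusters,cluster_len,cluster_offset_mm Deviant-cluster count,
#'   length in samples, and common displacement.
#' @param n_islands,island_ms,island_flank_gap_ms Isolated-island count,
#'   island span, and missing flank length on each side.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               duration_s = 60, rate_hz = 250,
                               timestamp_jitter_pct = 0,
                               base_mm = 4.5,
                               sin_amp_mm = c(0.3, 0.15),
                               sin_freq_hz = c(0.12, 0.31),
                               noise_sd_mm = 0.03,
                               eye_offset_mm = 0.3,
                               n_blinks = 3, blink_gap_ms = 120,
                               blink_dip_mm = 0.6, blink_dip_ms = 12,
                               n_spikes = 5, spike_amp_mm = 0.8,
                               n_clusters = 2, cluster_len = 5,
                               cluster_offset_mm = 0.5,
                               n_islands = 1, island_ms = 40,
                               island_flank_gap_ms = 100) {
  sc <- as.list(environment())
  if (sc$base_mm < 1.5 || sc$base_mm > 9) stop("base_mm must lie in 1.5-9 mm")
  if (any(sc$sin_freq_hz > 1)) stop("true-signal sinusoids must be <= 1 Hz")
  if (length(sc$sin_amp_mm) != length(sc$sin_freq_hz)) {
    stop("sin_amp_mm and sin_freq_hz must have equal length")
  }
  if (sc$timestamp_jitter_pct < 0 || sc$timestamp_jitter_pct >= 50) {
    stop("timestamp_jitter_pct must be in [0, 50)")
  }
  if (sc$duration_s <= 0 || sc$rate_hz <= 0) stop("duration and rate must be > 0")
  structure(sc, class = "synthetic_scenario")
}

# place n_events windows of win_len samples, separated from each other
# and from the recording edges; errors out when they cannot all fit
place_windows <- function(n_samples, n_events, win_len, guard,
                          taken) {
  starts <- integer(0)
  free <- !taken
  lo <- guard + 1L
  hi <- n_samples - guard - win_len
  if (n_events == 0L) return(starts)
  if (hi < lo) stop("artifact windows do not fit in the recording")
  cand <- sample(seq.int(lo, hi))
  for (s in cand) {
    span <- seq.int(max(1L, s - guard), min(n_samples, s + win_len - 1L + guard))
    if (all(free[span])) {
      starts <- c(starts, s)
      free[span] <- FALSE
      if (length(starts) == n_events) break
    }
  }
  if (length(starts) < n_events) {
    stop("could not place ", n_events, " artifact window(s) of ", win_len,
         " samples without overlap; reduce counts or lengths")
  }
  sort(starts)
}

#' Generate a synthetic recording with a ground-truth ledger
#'
#' Realizes a [synthetic_scenario()]: builds the true smooth trace,
#' derives left and right eyes as `true -/+ offset/2`, adds independent
#' Gaussian noise per eye, then injects blinks, spikes, clusters, and
#' islands at non-overlapping random positions (identical positions in
#' both eyes; independent noise). Every sample that differs from
#' true-signal-plus-noise by construction is recorded in the ledger.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `synthetic_recording`:
#'   `recording` (a [raw_recording()]), `ledger` (a `data.frame` with
#'   `index`, `timestamp_s`, `class_left`, `class_right`; classes are
#'   `"clean"`, `"blink_gap"`, `"blink_dip"`, `"spike"`, `"cluster"`,
#'   `"island"`, `"island_gap"`), `true_mm` (the noiseless true mean
#'   trace at each sample time), and `scenario`.
#' @export
generate_recording <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- round(sc$duration_s * sc$rate_hz)
  step <- 1 / sc$rate_hz
  t <- seq.int(0L, n - 1L) * step
  if (sc$timestamp_jitter_pct > 0) {
    t <- t + stats::runif(n, -1, 1) * step * sc$timestamp_jitter_pct / 100
    t <- sort(t)            # jitter < 50% keeps order, sort guards ties
  }

  true_mm <- rep(sc$base_mm, n)
  for (k in seq_along(sc$sin_amp_mm)) {
    phase <- stats::runif(1, 0, 2 * pi)
    true_mm <- true_mm + sc$sin_amp_mm[k] *
      sin(2 * pi * sc$sin_freq_hz[k] * t + phase)
  }
  # slowly drifting right-minus-left offset
  off <- sc$eye_offset_mm + 0.2 * sc$eye_offset_mm *
    sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
  left <- true_mm - off / 2 + stats::rnorm(n, 0, sc$noise_sd_mm)
  right <- true_mm + off / 2 + stats::rnorm(n, 0, sc$noise_sd_mm)

  cls <- rep("clean", n)
  taken <- rep(FALSE, n)
  mark <- function(idx, what) {
    cls[idx] <<- what
    taken[idx] <<- TRUE
  }
  smp <- function(ms) max(1L, round(ms / 1000 * sc$rate_hz))

  # blinks: dip ramp, gap, dip ramp
  gap_len <- smp(sc$blink_gap_ms)
  dip_len <- smp(sc$blink_dip_ms)
  blink_len <- gap_len + 2L * dip_len
  guard <- smp(300)
  for (s in place_windows(n, sc$n_blinks, blink_len, guard, taken)) {
    pre <- seq.int(s, length.out = dip_len)
    gap <- seq.int(s + dip_len, length.out = gap_len)
    post <- seq.int(s + dip_len + gap_len, length.out = dip_len)
    ramp <- sc$blink_dip_mm * seq_len(dip_len) / dip_len
    left[pre] <- left[pre] - ramp;  right[pre] <- right[pre] - ramp
    left[post] <- left[post] - rev(ramp); right[post] <- right[post] - rev(ramp)
    left[gap] <- NA; right[gap] <- NA
    mark(c(pre, post), "blink_dip"); mark(gap, "blink_gap")
  }

  # isolated spikes, alternating sign
  for (s in place_windows(n, sc$n_spikes, 1L, guard, taken)) {
    sgn <- sample(c(-1, 1), 1)
    left[s] <- left[s] + sgn * sc$spike_amp_mm
    right[s] <- right[s] + sgn * sc$spike_amp_mm
    mark(s, "spike")
  }

  # clusters of consecutive displaced samples
  for (s in place_windows(n, sc$n_clusters, sc$cluster_len, guard, taken)) {
    idx <- seq.int(s, length.out = sc$cluster_len)
    sgn <- sample(c(-1, 1), 1)
    left[idx] <- left[idx] + sgn * sc$cluster_offset_mm
    right[idx] <- right[idx] + sgn * sc$cluster_offset_mm
    mark(idx, "cluster")
  }

  # islands: short sample runs flanked by missing sections
  isl_len <- smp(sc$island_ms)
  flank_len <- smp(sc$island_flank_gap_ms)
  for (s in place_windows(n, sc$n_islands, isl_len + 2L * flank_len,
                          guard, taken)) {
    fl1 <- seq.int(s, length.out = flank_len)
    isl <- seq.int(s + flank_len, length.out = isl_len)
    fl2 <- seq.int(s + flank_len + isl_len, length.out = flank_len)
    left[c(fl1, fl2)] <- NA; right[c(fl1, fl2)] <- NA
    mark(c(fl1, fl2), "island_gap"); mark(isl, "island")
  }

  rec <- raw_recording(t, left, right,
                       source_meta = c(generator = "pupilprep synthetic",
                                       seed = as.character(sc$seed)))
  ledger <- data.frame(index = seq_len(n), timestamp_s = t,
                       class_left = cls, class_right = cls,
                       stringsAsFactors = FALSE)
  structure(list(recording = rec, ledger = ledger, true_mm = true_mm,
                 scenario = sc),
            class = "synthetic_recording")
}

#' Read a scenario description from YAML
#'
#' The file holds any subset of [synthetic_scenario()]'s arguments;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `synthetic_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  apply_block(synthetic_scenario, cfg, "scenario")
}

#' Write a synthetic recording's ground-truth ledger as JSON
#'
#' @param srec A `synthetic_recording`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(srec, path) {
  stopifnot(inherits(srec, "synthetic_recording"))
  jsonlite::write_json(
    list(scenario = unclass(srec$scenario), ledger = srec$ledger),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
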