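#' Raw-data filter settings
#'
#' Tunable parameters of the five-stage raw-data filter. Defaults follow
#' the recommended values where guidance exists (feasible diameter range
#' 1.5-9 mm, gap-edge rule 50/75 ms, sparsity criteria 40/50 ms); the MAD
#' multipliers have no universal value and should be tuned per dataset -
#' the filter report echoes whatever was used.
#'
#' @param range_min_mm,range_max_mm Feasible pupil diameter bounds in mm,
#'   inclusive.
#' @param speed_mad_multiplier Multiplier `n` of the MAD in the
#'   dilation-speed outlier threshold.
#' @param gap_edge_margin_ms Samples at most this close (inclusive) to a
#'   qualifying gap edge are rejected.
#' @param gap_min_duration_ms Missing-data sections strictly longer than
#'   this qualify as gaps for edge rejection.
#' @param deviation_mad_multiplier MAD multiplier for the trend-line
#'   deviation filter.
#' @param deviation_passes Number of trend-line deviation passes (>= 1);
#'   later passes may reinstate samples a previous pass rejected.
#' @param trendline_cutoff_hz Low-pass cutoff of the trend-line smoother.
#' @param trendline_rate_hz Uniform grid rate on which the trend line is
#'   built; needs only to comfortably oversample the cutoff.
#' @param sparsity_split_gap_ms The signal is split at gaps strictly
#'   larger than this.
#' @param sparsity_min_section_ms Sections spanning less than this are
#'   wholly rejected.
#' @param min_threshold_epsilon Lower floor on MAD-based thresholds;
#'   default 0 keeps the threshold formula untouched (a degenerate MAD of
#'   0 then makes the threshold equal the median).
#' @return A `filter_settings` list.
#' @export
filter_settings <- function(range_min_mm = 1.5, range_max_mm = 9,
                            speed_mad_multiplier = 16,
                            gap_edge_margin_ms = 50,
                            gap_min_duration_ms = 75,
                            deviation_mad_multiplier = 16,
                            deviation_passes = 2,
                            trendline_cutoff_hz = 4,
                            trendline_rate_hz = 100,
                            sparsity_split_gap_ms = 40,
                            sparsity_min_section_ms = 50,
                            min_threshold_epsilon = 0) {
  s <- list(range_min_mm = range_min_mm, range_max_mm = range_max_mm,
            speed_mad_multiplier = speed_mad_multiplier,
            gap_edge_margin_ms = gap_edge_margin_ms,
            gap_min_duration_ms = gap_min_duration_ms,
            deviation_mad_multiplier = deviation_mad_multiplier,
            deviation_passes = as.integer(deviation_passes),
            trendline_cutoff_hz = trendline_cutoff_hz,
            trendline_rate_hz = trendline_rate_hz,
            sparsity_split_gap_ms = sparsity_split_gap_ms,
            sparsity_min_section_ms = sparsity_min_section_ms,
            min_threshold_epsilon = min_threshold_epsilon)
  durs <- c(s$gap_edge_margin_ms, s$gap_min_duration_ms,
            s$sparsity_split_gap_ms, s$sparsity_min_section_ms)
  if (any(durs <= 0)) stop("all filter durations must be > 0")
  if (s$range_min_mm >= s$range_max_mm) stop("range_min_mm must be < range_max_mm")
  if (s$speed_mad_multiplier <= 0 || s$deviation_mad_multiplier <= 0) {
    stop("MAD multipliers must be > 0")
  }
  if (s$deviation_passes < 1L) stop("deviation_passes must be >= 1")
  if (s$trendline_rate_hz <= 2 * s$trendline_cutoff_hz) {
    stop("trendline_rate_hz must exceed twice trendline_cutoff_hz")
  }
  structure(s, class = "filter_settings")
}

#' Valid-sample processing settings
#'
#' Parameters of the upsample / smooth / mask stage.
#'
#' @param target_rate_hz Uniform resampling rate; a high rate such as
#'   1000 Hz gives 1 ms temporal resolution.
#' @param lowpass_cutoff_hz Cutoff of the zero-phase low-pass smoother.
#' @param max_interp_gap_ms Grid points interpolated across raw-sample
#'   gaps strictly larger than this are set missing.
#' @param lowpass_order Butterworth order per direction of the
#'   forward-backward filter.
#' @return A `processing_settings` list.
#' @export
processing_settings <- function(target_rate_hz = 1000,
                                lowpass_cutoff_hz = 4,
                                max_interp_gap_ms = 250,
                                lowpass_order = 1) {
  s <- list(target_rate_hz = target_rate_hz,
            lowpass_cutoff_hz = lowpass_cutoff_hz,
            max_interp_gap_ms = max_interp_gap_ms,
            lowpass_order = as.integer(lowpass_order))
  if (any(unlist(s) <= 0)) stop("all processing settings must be > 0")
  if (s$target_rate_hz <= 2 * s$lowpass_cutoff_hz) {
    stop("target_rate_hz must exceed twice lowpass_cutoff_hz")
  }
  structure(s, class = "processing_settings")
}

# Merge a named list of overrides into a settings constructor call,
# rejecting unknown keys (typo safety).
apply_block <- function(constructor, block, block_name) {
  if (is.null(block)) return(constructor())
  known <- names(formals(constructor))
  unknown <- setdiff(names(block), known)
  if (length(unknown) > 0) {
    stop("unknown key(s) in '", block_name, "' config block: ",
         paste(unknown, collapse = ", "))
  }
  do.call(constructor, block)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with blocks `io`, `filter`, `processing`,
#' `segmentation`, and optional top-level `seed` and `plots`. Unknown
#' keys in any block are rejected. `segmentation` must supply
#' `max_missing_pct` when segments are summarized; there is no silent
#' default.
#'
#' @param path Config file path; `NULL` yields all defaults.
#' @return A `pipeline_config` list with elements `io` (a
#'   [format_spec()]), `filter`, `processing`, `segmentation`, `seed`,
#'   `plots`.
#' @export
read_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(cfg)) cfg <- list()
    unknown <- setdiff(names(cfg), c("io", "filter", "processing",
                                     "segmentation", "seed", "plots"))
    if (length(unknown) > 0) {
      stop("unknown top-level config key(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  seg <- cfg$segmentation
  if (!is.null(seg)) {
    unknown <- setdiff(names(seg),
                       c("max_missing_pct", "bin_ms", "pairing"))
    if (length(unknown) > 0) {
      stop("unknown key(s) in 'segmentation' config block: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(io = apply_block(format_spec, cfg$io, "io"),
         filter = apply_block(filter_settings, cfg$filter, "filter"),
         processing = apply_block(processing_settings, cfg$processing,
                                  "processing"),
         segmentation = seg,
         seed = cfg$seed,
         plots = if (is.null(cfg$plots)) TRUE else isTRUE(cfg$plots)),
    class = "pipeline_config")
}
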