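#' Construct a raw pupil recording
#'
#' The standardized in-memory representation of a raw eyetracker export:
#' strictly increasing timestamps in seconds plus left and/or right pupil
#' diameter in millimetres. Missing samples are `NA` per eye; a sample row
#' is retained as long as at least one eye could still hold data.
#'
#' @param timestamps Numeric vector of sample times in seconds.
#' @param left_mm,right_mm Numeric vectors of pupil diameter in mm, `NA`
#'   where the eye was not measured. At least one must be non-`NULL`.
#' @param source_meta Named character vector of free-form provenance
#'   strings (file of origin, device, conversion notes).
#' @return An object of class `raw_recording`: a list with elements
#'   `timestamps`, `left_mm`, `right_mm` (always present, possibly
#'   all-`NA`), and `source_meta`.
#' @export
raw_recording <- function(timestamps, left_mm = NULL, right_mm = NULL,
                          source_meta = character()) {
  if (is.null(left_mm) && is.null(right_mm)) {
    stop("at least one eye column (left_mm / right_mm) must be supplied")
  }
  n <- length(timestamps)
  if (n == 0L) stop("empty recording: no samples")
  if (is.null(left_mm)) left_mm <- rep(NA_real_, n)
  if (is.null(right_mm)) right_mm <- rep(NA_real_, n)
  timestamps <- as.numeric(timestamps)
  left_mm <- as.numeric(left_mm)
  right_mm <- as.numeric(right_mm)
  if (length(left_mm) != n || length(right_mm) != n) {
    stop("timestamps and diameter vectors must have equal length")
  }
  if (anyNA(timestamps)) stop("timestamps must not contain NA")
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop("timestamps must be strictly increasing; use load_raw() to ",
         "sort and deduplicate on ingestion")
  }
  bad <- function(d) !is.na(d) & (!is.finite(d) | d <= 0)
  if (any(bad(left_mm)) || any(bad(right_mm))) {
    stop("retained diameters must be finite and > 0; drop invalid ",
         "samples before construction (load_raw() does this)")
  }
  if (all(is.na(left_mm)) && all(is.na(right_mm))) {
    stop("empty recording: no valid samples in either eye")
  }
  structure(
    list(timestamps = timestamps, left_mm = left_mm, right_mm = right_mm,
         source_meta = source_meta),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples, %.3f-%.3f s, left: %d, right: %d valid\n",
    length(x$timestamps), x$timestamps[1],
    x$timestamps[length(x$timestamps)],
    sum(!is.na(x$left_mm)), sum(!is.na(x$right_mm))))
  invisible(x)
}

#' Describe the column layout of a raw eyetracker export
#'
#' A format specification maps the columns of an arbitrary tabular
#' eyetracker export onto the standardized model, declares the timestamp
#' unit, and encodes how the source marks invalid samples.
#'
#' @param time_col Name of the timestamp column.
#' @param left_col,right_col Names of the pupil-diameter columns (mm);
#'   either may be `NULL` for monocular data.
#' @param time_units `"s"` or `"ms"`; timestamps are converted to seconds
#'   on ingestion.
#' @param invalid_sentinels Numeric values in a diameter column that mean
#'   "invalid" (converted to missing). Nonpositive diameters are always
#'   treated as invalid.
#' @param validity_col Optional name of a source validity column.
#' @param validity_invalid Values of `validity_col` marking a sample
#'   invalid.
#' @param validity_scope `"per_row"` (flag invalidates both eyes) or
#'   `"per_eye"` with `validity_col` naming the left column and
#'   `validity_col_right` the right one.
#' @param validity_col_right Right-eye validity column for
#'   `validity_scope = "per_eye"`.
#' @return A `format_spec` list used by [load_raw()].
#' @export
format_spec <- function(time_col = "timestamp_s",
                        left_col = "diameter_left_mm",
                        right_col = "diameter_right_mm",
                        time_units = c("s", "ms"),
                        invalid_sentinels = c(0, -1),
                        validity_col = NULL,
                        validity_invalid = c(0, -1),
                        validity_scope = c("per_eye", "per_row"),
                        validity_col_right = NULL) {
  time_units <- match.arg(time_units)
  validity_scope <- match.arg(validity_scope)
  structure(
    list(time_col = time_col, left_col = left_col, right_col = right_col,
         time_units = time_units, invalid_sentinels = invalid_sentinels,
         validity_col = validity_col, validity_invalid = validity_invalid,
         validity_scope = validity_scope,
         validity_col_right = validity_col_right),
    class = "format_spec")
}

#' Load a raw eyetracker export into the standardized model
#'
#' Reads a delimited text export, maps its columns through a
#' [format_spec()], converts timestamps to seconds, and removes samples
#' that are clearly invalid at the source: nonpositive or sentinel-valued
#' diameters, and samples the eyetracker itself flagged invalid. These
#' need no specialized filtering and are dropped (set missing per eye)
#' before the raw-data filter ever sees them. Rows are sorted by
#' timestamp; exact-duplicate timestamps keep the first occurrence so that
#' sample-to-sample time differences are never zero downstream.
#'
#' @param path Path to a CSV (or other delimited) file with a header row.
#' @param spec A [format_spec()]; the default matches the standardized
#'   format written by [write_standard()].
#' @param sep Field separator, default comma.
#' @return A [raw_recording()]. The `source_meta` records the path and
#'   per-cause drop counts; the counts are also available via
#'   `attr(rec, "ingestion_report")` with elements `rows_in`,
#'   `rows_retained`, `dropped_duplicate_ts`, `dropped_all_invalid`, and
#'   per-eye counts of diameters set missing (`invalidated_left`,
#'   `invalidated_right`).
#' @export
load_raw <- function(path, spec = format_spec(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c(spec$time_col, spec$left_col, spec$right_col,
            spec$validity_col, spec$validity_col_right)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("mapped column(s) absent from '", path, "': ",
         paste(miss, collapse = ", "))
  }
  t <- suppressWarnings(as.numeric(df[[spec$time_col]]))
  if (anyNA(t)) stop("non-numeric timestamps in '", path, "'")
  if (spec$time_units == "ms") t <- t / 1000

  get_eye <- function(col) {
    if (is.null(col)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  left <- get_eye(spec$left_col)
  right <- get_eye(spec$right_col)

  # clearly-invalid removal: sentinels, nonpositive, source validity flags
  invalidate <- function(d, flags_bad) {
    hit <- !is.na(d) & (d <= 0 | d %in% spec$invalid_sentinels)
    hit <- hit | (flags_bad & !is.na(d))
    d[hit] <- NA_real_
    list(d = d, n = sum(hit), hit = hit)
  }
  row_flags <- rep(FALSE, nrow(df))
  left_flags <- right_flags <- row_flags
  if (!is.null(spec$validity_col)) {
    v <- df[[spec$validity_col]]
    bad <- v %in% spec$validity_invalid
    if (spec$validity_scope == "per_row") row_flags <- bad else left_flags <- bad
  }
  if (!is.null(spec$validity_col_right) && spec$validity_scope == "per_eye") {
    right_flags <- df[[spec$validity_col_right]] %in% spec$validity_invalid
  }
  li <- invalidate(left, left_flags | row_flags)
  ri <- invalidate(right, right_flags | row_flags)
  left <- li$d; right <- ri$d
  hit_row <- li$hit | ri$hit

  ord <- order(t)
  t <- t[ord]; left <- left[ord]; right <- right[ord]
  hit_row <- hit_row[ord]
  dup <- duplicated(t)
  n_dup <- sum(dup)
  t <- t[!dup]; left <- left[!dup]; right <- right[!dup]
  hit_row <- hit_row[!dup]

  # rows whose data were all invalidated are dropped; rows that were
  # empty at the source (e.g. a blink gap) stay as missing samples
  empty <- is.na(left) & is.na(right) & hit_row
  n_empty <- sum(empty)
  t <- t[!empty]; left <- left[!empty]; right <- right[!empty]
  if (length(t) == 0L) {
    stop("empty recording: no valid samples survive ingestion of '",
         path, "'")
  }

  rep_ <- list(rows_in = nrow(df), rows_retained = length(t),
               dropped_duplicate_ts = n_dup, dropped_all_invalid = n_empty,
               invalidated_left = li$n, invalidated_right = ri$n)
  rec <- raw_recording(
    t, left, right,
    source_meta = c(path = path,
                    dropped = sprintf("%d duplicate-ts, %d all-invalid rows",
                                      n_dup, n_empty)))
  attr(rec, "ingestion_report") <- rep_
  rec
}

#' Write a recording in the standardized raw format
#'
#' The standard format is a UTF-8 CSV with header
#' `timestamp_s,diameter_left_mm,diameter_right_mm`, "." as decimal
#' separator and empty cells for missing diameters. Timestamps are written
#' at full double precision so that [load_raw()] on the result reproduces
#' the recording exactly.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_standard <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (length(rec$timestamps) == 0L) stop("refusing to write empty recording")
  fmt <- function(x) ifelse(is.na(x), "",
                            formatC(x, digits = 17, format = "g"))
  lines <- c("timestamp_s,diameter_left_mm,diameter_right_mm",
             paste(fmt(rec$timestamps), fmt(rec$left_mm),
                   fmt(rec$right_mm), sep = ","))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Load a segment table
#'
#' Segments are the labeled time windows the smoothed signal is cut into:
#' CSV columns `segment_id` (unique integer), `label`, `t_start_s`,
#' `t_end_s`, plus an optional `trial_id` used for baseline-response
#' pairing. Overlapping windows are allowed (a baseline may lie inside
#' its trial).
#'
#' @param path CSV path.
#' @return A `data.frame` of class `segment_table`.
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("segment_id", "label", "t_start_s", "t_end_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("segment table missing column(s): ",
                             paste(miss, collapse = ", "))
  segment_table(df$segment_id, df$label, df$t_start_s, df$t_end_s,
                trial_id = df$trial_id)
}

#' Construct and validate a segment table
#'
#' @param segment_id Integer vector, unique per row.
#' @param label Character vector of segment labels.
#' @param t_start,t_end Window bounds in seconds, `t_start < t_end`.
#' @param trial_id Optional grouping used by [pair_baselines()].
#' @return A `data.frame` of class `segment_table`.
#' @export
segment_table <- function(segment_id, label, t_start, t_end,
                          trial_id = NULL) {
  segment_id <- as.integer(segment_id)
  if (anyDuplicated(segment_id)) stop("segment_id values must be unique")
  t_start <- as.numeric(t_start); t_end <- as.numeric(t_end)
  if (any(!is.finite(t_start)) || any(!is.finite(t_end))) {
    stop("segment bounds must be finite")
  }
  if (any(t_start >= t_end)) {
    stop("each segment needs t_start < t_end; offending segment_id: ",
         paste(segment_id[t_start >= t_end], collapse = ", "))
  }
  df <- data.frame(segment_id = segment_id, label = as.character(label),
                   t_start_s = t_start, t_end_s = t_end,
                   stringsAsFactors = FALSE)
  if (!is.null(trial_id)) df$trial_id <- trial_id
  class(df) <- c("segment_table", "data.frame")
  df
}
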