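#' Process the valid samples of a filtered recording
#'
#' Extracts each eye's surviving samples from the filter result, fuses
#' them into a mean pupil size series when both eyes were recorded, and
#' runs the upsample / smooth / mask chain on each requested series.
#' With monocular data the "mean" output is the single eye's processed
#' signal.
#'
#' @param rec A [raw_recording()].
#' @param fr A `filter_result` from [run_filter_pipeline()].
#' @param settings A [processing_settings()].
#' @param sources Which signals to produce, subset of
#'   `c("left", "right", "mean")`.
#' @return Named list of `smooth_signal` objects (absent eyes are
#'   skipped).
#' @export
process_recording <- function(rec, fr, settings = processing_settings(),
                              sources = c("left", "right", "mean")) {
  stopifnot(inherits(rec, "raw_recording"), inherits(fr, "filter_result"))
  valid <- function(eye) {
    vm <- fr[[eye]]
    if (is.null(vm)) return(NULL)
    idx <- which(vm$combined)
    list(t = rec$timestamps[idx], d = rec[[paste0(eye, "_mm")]][idx])
  }
  L <- valid("left"); R <- valid("right")
  out <- list()
  if ("left" %in% sources && !is.null(L) && length(L$t) >= 2L) {
    out$left <- process_signal(L$t, L$d, settings, "left")
  }
  if ("right" %in% sources && !is.null(R) && length(R$t) >= 2L) {
    out$right <- process_signal(R$t, R$d, settings, "right")
  }
  if ("mean" %in% sources) {
    fused <- combine_eyes(if (is.null(L)) numeric(0) else L$t,
                          if (is.null(L)) numeric(0) else L$d,
                          if (is.null(R)) numeric(0) else R$t,
                          if (is.null(R)) numeric(0) else R$d)
    if (nrow(fused) >= 2L) {
      out$mean <- process_signal(fused$timestamp_s, fused$diameter_mm,
                                 settings, "mean")
      attr(out$mean, "fused_samples") <- fused
    }
  }
  out
}

#' Run the four-step preprocessing pipeline end to end
#'
#' Standardization, raw-data filtering, valid-sample processing, and
#' segmentation, writing every intermediate product to `out_dir`:
#' `standardized_raw.csv`, `filter_report.json`,
#' `processed_<source>.csv`, `segment_metrics.csv`, `binned_timecourse.csv`,
#' `paired_baselines.csv`, and `run_log.txt` with every effective
#' setting. Diagnostic figures are added by [plot_steps()] unless
#' disabled in the config.
#'
#' @param raw_path Raw export CSV (read through the config's `io` block).
#' @param segments_path Segment table CSV, or `NULL` to skip step 4.
#' @param config A `pipeline_config` from [read_config()], or a path to
#'   a YAML/JSON config file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory products: `recording`,
#'   `filter_result`, `signals`, `metrics`, `binned`, `paired`, `paths`.
#' @export
run_pipeline <- function(raw_path, segments_path = NULL,
                         config = read_config(), out_dir = "pupilprep_out") {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- c(sprintf("pupilprep %s",
                         as.character(utils::packageVersion("pupilprep"))),
                 sprintf("raw: %s", raw_path),
                 sprintf("segments: %s",
                         if (is.null(segments_path)) "(none)" else segments_path),
                 sprintf("seed: %s",
                         if (is.null(config$seed)) "(none)" else config$seed),
                 "settings:",
                 paste0("  filter.", names(config$filter), " = ",
                        unlist(config$filter)),
                 paste0("  processing.", names(config$processing), " = ",
                        unlist(config$processing)),
                 paste0("  segmentation.", names(config$segmentation), " = ",
                        vapply(config$segmentation, function(x)
                          paste(deparse(x), collapse = ""), "")))
  if (!is.null(config$seed)) set.seed(config$seed)

  p <- function(f) file.path(out_dir, f)
  rec <- stage("standardize", load_raw(raw_path, config$io))
  write_standard(rec, p("standardized_raw.csv"))
  fr <- stage("filter", run_filter_pipeline(rec, config$filter))
  write_filter_report(fr, p("filter_report.json"))
  sigs <- stage("process", process_recording(rec, fr, config$processing))
  for (s in names(sigs)) {
    write_processed(sigs[[s]], p(sprintf("processed_%s.csv", s)))
  }

  metrics <- binned <- paired <- NULL
  if (!is.null(segments_path)) {
    seg <- stage("segment", load_segments(segments_path))
    segcfg <- config$segmentation
    if (is.null(segcfg$max_missing_pct)) {
      stop("missing required setting: segmentation.max_missing_pct")
    }
    main <- sigs$mean %||% sigs$left %||% sigs$right
    metrics <- stage("segment",
                     summarize_segments(main, seg, segcfg$max_missing_pct))
    utils::write.csv(metrics, p("segment_metrics.csv"), row.names = FALSE,
                     na = "")
    bin_ms <- segcfg$bin_ms %||% 100
    binned <- do.call(rbind, lapply(seq_len(nrow(seg)), function(r) {
      bin_timecourse(main, seg[r, ], bin_ms)
    }))
    utils::write.csv(binned, p("binned_timecourse.csv"), row.names = FALSE,
                     na = "")
    pairing <- segcfg$pairing
    paired <- tryCatch(
      pair_baselines(metrics,
                     baseline_label = pairing$baseline %||% "baseline",
                     response_label = pairing$response %||% "trial"),
      error = function(e) NULL)
    if (!is.null(paired)) {
      utils::write.csv(paired, p("paired_baselines.csv"), row.names = FALSE,
                       na = "")
    }
  }
  writeLines(log_lines, p("run_log.txt"))
  res <- list(recording = rec, filter_result = fr, signals = sigs,
              metrics = metrics, binned = binned, paired = paired,
              paths = p(""))
  if (config$plots) {
    tryCatch(plot_steps(res, out_dir),
             error = function(e) warning("plotting failed (outputs ",
                                         "unaffected): ", conditionMessage(e)))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diagnostic figures for a pipeline run
#'
#' Two PNG figures: the raw samples of each eye with every filter
#' stage's rejections color-coded, and the raw valid samples overlaid
#' with the smooth fused signal. Reviewing these per dataset is how
#' filter settings get tuned.
#'
#' @param res The list returned by [run_pipeline()] (or any list with
#'   `recording`, `filter_result`, `signals`).
#' @param out_dir Directory for the image files.
#' @return Character vector of files written, invisibly.
#' @export
plot_steps <- function(res, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- res$recording; fr <- res$filter_result
  files <- character(0)
  stage_cols <- c(range = "purple", speed = "red", gap_edge = "orange",
                  deviation = "brown", sparsity = "magenta")

  f1 <- file.path(out_dir, "filter_stages.png")
  grDevices::png(f1, width = 1400, height = 800)
  eyes <- c("left", "right")[!vapply(fr[c("left", "right")], is.null, TRUE)]
  graphics::par(mfrow = c(length(eyes), 1), mar = c(4, 4, 2, 1))
  if (length(eyes) == 0L) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no valid samples in any eye")
  }
  for (eye in eyes) {
    d <- rec[[paste0(eye, "_mm")]]
    vm <- fr[[eye]]
    graphics::plot(rec$timestamps, d, pch = 16, cex = 0.4, col = "grey60",
                   xlab = "time (s)", ylab = "diameter (mm)",
                   main = sprintf("%s eye: raw samples and filter rejections", eye))
    prev <- !is.na(d)
    for (st in names(stage_cols)) {
      rejected_here <- prev & !vm[[st]]
      graphics::points(rec$timestamps[rejected_here], d[rejected_here],
                       pch = 4, cex = 0.8, col = stage_cols[[st]])
      prev <- prev & vm[[st]]
    }
    graphics::points(rec$timestamps[vm$combined], d[vm$combined],
                     pch = 16, cex = 0.4, col = "grey30")
    graphics::legend("topright", legend = names(stage_cols), pch = 4,
                     col = stage_cols, cex = 0.8, horiz = TRUE)
  }
  grDevices::dev.off()
  files <- c(files, f1)

  f2 <- file.path(out_dir, "smooth_signal.png")
  grDevices::png(f2, width = 1400, height = 500)
  graphics::par(mar = c(4, 4, 2, 1))
  main_sig <- res$signals$mean %||% res$signals$left %||% res$signals$right
  if (is.null(main_sig)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no processed signal: empty valid set")
  } else {
    graphics::plot(NA, xlim = range(rec$timestamps),
                   ylim = range(c(rec$left_mm, rec$right_mm), na.rm = TRUE),
                   xlab = "time (s)", ylab = "diameter (mm)",
                   main = "valid raw samples and smooth fused signal")
    for (eye in c("left", "right")) {
      vm <- fr[[eye]]
      if (is.null(vm)) next
      d <- rec[[paste0(eye, "_mm")]]
      graphics::points(rec$timestamps[vm$combined], d[vm$combined],
                       pch = 16, cex = 0.35,
                       col = if (eye == "left") "firebrick" else "steelblue")
    }
    graphics::lines(main_sig$timestamp_s, main_sig$diameter_mm,
                    col = "forestgreen", lwd = 2)
    graphics::legend("topright",
                     legend = c("left raw (valid)", "right raw (valid)",
                                "smooth fused"),
                     col = c("firebrick", "steelblue", "forestgreen"),
                     pch = c(16, 16, NA), lty = c(NA, NA, 1))
  }
  grDevices::dev.off()
  files <- c(files, f2)
  invisible(files)
}
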