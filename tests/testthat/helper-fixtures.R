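# Small in-code fixtures shared across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a smooth physiological-looking trace: slow sinusoids around a base
smooth_trace <- function(t, base = 4.5, amp = c(0.3, 0.15),
                         freq = c(0.12, 0.31), phase = c(0.7, 2.1)) {
  out <- rep(base, length(t))
  for (k in seq_along(amp)) {
    out <- out + amp[k] * sin(2 * pi * freq[k] * t + phase[k])
  }
  out
}

# uniform-rate recording from explicit eye vectors
make_recording <- function(t, left = NULL, right = NULL) {
  raw_recording(t, left, right)
}

# write a minimal raw CSV in the standard layout and return its path
write_raw_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# independent brute-force oracle for the MAD threshold: sort-based
# median, explicit absolute deviations
oracle_mad_threshold <- function(x, n_mult) {
  med <- function(v) {
    v <- sort(v)
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  m0 <- med(x)
  m0 + n_mult * med(abs(x - m0))
}

# independent oracle for dilation speed: explicit per-sample loop
oracle_dilation_speed <- function(t, d) {
  n <- length(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    back <- if (i > 1) abs((d[i] - d[i - 1]) / (t[i] - t[i - 1])) else NA
    fwd <- if (i < n) abs((d[i + 1] - d[i]) / (t[i + 1] - t[i])) else NA
    out[i] <- max(back, fwd, na.rm = TRUE)
  }
  out
}
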