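# Signal conditioning and segmentation: notch, band-pass, integer
# decimation, overlapping/adjacent windowing. All filters are applied
# zero-phase (forward-backward); offline analysis has no causality
# constraint and zero-phase avoids group-delay distortion of the windows.

apply_by_channel <- function(recording, fn) {
  out <- recording
  out$data <- t(apply(recording$data, 1, fn))
  if (ncol(recording$data) == 1) out$data <- t(out$data)
  out
}

#' Notch filter for power-line interference
#'
#' Zero-phase second-order band-stop centered at `freq` with -3 dB width
#' `freq / quality`.
#'
#' @param recording an [emg_recording()].
#' @param freq notch center frequency, Hz (50 or 60 for line interference).
#' @param quality quality factor Q; the stop band is `freq / Q` wide.
#' @return the filtered [emg_recording()], same shape.
#' @export
notch_filter <- function(recording, freq = 50, quality = 30) {
  fs <- recording$fs
  stop_if_not(freq > 0 && freq < fs / 2,
              "notch frequency must lie in (0, Nyquist)", class = "emg_parameter_error")
  stop_if_not(quality > 0, "quality must be > 0", class = "emg_parameter_error")
  bw <- freq / quality
  flt <- butter_cached(2, c(freq - bw / 2, freq + bw / 2) / (fs / 2), "stop")
  apply_by_channel(recording, function(x) zero_phase(flt, x))
}

#' Band-pass filter for motion-artefact and high-frequency noise removal
#'
#' Zero-phase Butterworth band-pass, default 20-450 Hz (the conventional
#' surface-EMG analysis band).
#'
#' @param recording an [emg_recording()].
#' @param low,high band edges, Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return the filtered [emg_recording()], same shape.
#' @export
bandpass_filter <- function(recording, low = 20, high = 450, order = 4) {
  fs <- recording$fs
  stop_if_not(low > 0 && low < high && high < fs / 2,
              "band edges must satisfy 0 < low < high < Nyquist",
              class = "emg_parameter_error")
  flt <- butter_cached(order, c(low, high) / (fs / 2), "pass")
  apply_by_channel(recording, function(x) zero_phase(flt, x))
}

#' Integer-ratio downsampling
#'
#' Anti-alias low-pass filters (8th-order Butterworth at 80% of the target
#' Nyquist, zero-phase) then decimates. Only integer decimation ratios are
#' supported.
#'
#' @param recording an [emg_recording()].
#' @param target_fs target sampling rate, Hz; `fs / target_fs` must be an
#'   integer.
#' @return the decimated [emg_recording()] with
#'   `floor(samples * target_fs / fs)` samples.
#' @export
downsample <- function(recording, target_fs = 1000) {
  fs <- recording$fs
  stop_if_not(target_fs > 0 && target_fs <= fs, "target_fs must be in (0, fs]",
              class = "emg_parameter_error")
  q <- fs / target_fs
  stop_if_not(abs(q - round(q)) < 1e-9,
              "fs / target_fs must be an integer (no rational resampling)",
              class = "emg_parameter_error")
  q <- round(q)
  if (q == 1) return(recording)
  flt <- butter_cached(8, 0.8 / q, "low")
  n_out <- floor(ncol(recording$data) * target_fs / fs)
  out <- recording
  out$data <- t(apply(recording$data, 1, function(x) {
    zero_phase(flt, x)[seq.int(1L, by = q, length.out = n_out)]
  }))
  if (n_out == 1) out$data <- t(out$data)
  out$fs <- target_fs
  out
}

#' Segment recordings into fixed-length windows
#'
#' Slides a `window_ms` window in `increment_ms` steps over each recording
#' independently (no window ever spans a trial boundary), yielding
#' `floor((samples - L) / I) + 1` windows per recording, where `L` and `I`
#' are the window and increment in samples. `increment_ms == window_ms`
#' gives adjacent (non-overlapping) segmentation; smaller increments give
#' overlapping segmentation. Recordings shorter than one window are skipped
#' with a warning.
#'
#' @param recordings a list of [emg_recording()] objects with a common
#'   sampling rate.
#' @param window_ms window length, ms (default 150).
#' @param increment_ms window increment, ms (default 50); must satisfy
#'   `0 < increment_ms <= window_ms`.
#' @return an object of class `window_set`: a list with `windows`
#'   (array `n_windows x channels x window_samples`), `fs`, `window_ms`,
#'   `increment_ms`, and a `meta` data frame aligned with the first array
#'   dimension (subject_id, motion_label, condition_kind, condition_value,
#'   trial_index).
#' @export
segment <- function(recordings, window_ms = 150, increment_ms = 50) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  stop_if_not(length(recordings) >= 1, "no recordings given")
  stop_if_not(increment_ms > 0 && increment_ms <= window_ms,
              "need 0 < increment_ms <= window_ms", class = "emg_parameter_error")
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  stop_if_not(length(fs) == 1, "all recordings must share one sampling rate",
              class = "emg_parameter_error")
  L <- round(window_ms * fs / 1000)
  I <- round(increment_ms * fs / 1000)
  stop_if_not(L >= 1 && I >= 1, "window/increment shorter than one sample",
              class = "emg_parameter_error")
  ch <- unique(vapply(recordings, function(r) nrow(r$data), integer(1)))
  stop_if_not(length(ch) == 1, "all recordings must share one channel count",
              class = "emg_parameter_error")

  counts <- vapply(recordings, function(r) {
    n <- ncol(r$data)
    if (n < L) 0L else as.integer(floor((n - L) / I) + 1)
  }, integer(1))
  if (any(counts == 0)) {
    warning(sprintf("%d recording(s) shorter than one window were skipped",
                    sum(counts == 0)))
  }
  total <- sum(counts)
  stop_if_not(total >= 1, "segmentation produced no windows")

  windows <- array(NA_real_, dim = c(total, ch, L))
  meta <- data.frame(subject_id = rep(NA, total), motion_label = NA_character_,
                     condition_kind = NA_character_, condition_value = NA,
                     trial_index = NA_integer_, stringsAsFactors = FALSE)
  k <- 0L
  for (ri in seq_along(recordings)) {
    if (counts[ri] == 0L) next
    r <- recordings[[ri]]
    starts <- seq.int(1L, by = I, length.out = counts[ri])
    for (st in starts) {
      k <- k + 1L
      windows[k, , ] <- r$data[, st:(st + L - 1L), drop = FALSE]
      meta$subject_id[k] <- r$subject_id
      meta$motion_label[k] <- r$motion_label
      meta$condition_kind[k] <- r$condition_kind
      meta$condition_value[k] <- r$condition_value
      meta$trial_index[k] <- r$trial_index
    }
  }
  structure(list(windows = windows, fs = fs, window_ms = window_ms,
                 increment_ms = increment_ms, meta = meta),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows x %d channels x %d samples (%g/%g ms @ %g Hz)\n",
              d[1], d[2], d[3], x$window_ms, x$increment_ms, x$fs))
  invisible(x)
}
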