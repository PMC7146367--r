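# Synthetic EMG generator: class activation profiles, condition transforms
# (position re-mixing / intensity gain + spectral shift), and trial synthesis.

#' Construct a single-trial EMG recording
#'
#' @param data numeric matrix, channels x samples, millivolts.
#' @param fs sampling rate, Hz.
#' @param subject_id,motion_label,condition_kind,condition_value,trial_index
#'   trial metadata.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(data, fs, subject_id, motion_label,
                          condition_kind, condition_value, trial_index) {
  stop_if_not(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  stop_if_not(nrow(data) >= 1 && ncol(data) >= 1, "data must have >= 1 channel and sample")
  stop_if_not(all(is.finite(data)), "all samples must be finite")
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 motion_label = motion_label, condition_kind = condition_kind,
                 condition_value = condition_value, trial_index = trial_index),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d ch x %d samples @ %g Hz | subject %s, %s, %s=%s, trial %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$subject_id, x$motion_label,
              x$condition_kind, x$condition_value, x$trial_index))
  invisible(x)
}

#' Per-subject class activation profiles
#'
#' Draws, deterministically from the configuration seed, one activation
#' envelope per (motion class, channel): the target mean rectified value
#' (mV) of that channel when the motion is held. The no-motion class row is
#' pinned at the sensor noise floor. A per-subject scale models
#' between-subject amplitude differences, and half of the channels (a
#' seeded subset) are marked as co-located with limb-stabilization
#' musculature and receive baseline activity under position confounds.
#'
#' @param config a [generator_config()].
#' @param subject_index subject number, 1-based, `<= config$n_subjects`.
#' @return an object of class `class_profile` with fields `base_amplitude`
#'   (classes x channels, mV), `subject_scale`, `stab_channels`,
#'   `subject_index`.
#' @export
make_class_profiles <- function(config, subject_index) {
  stop_if_not(inherits(config, "generator_config"), "config must be a generator_config")
  stop_if_not(is_count(subject_index) && subject_index <= config$n_subjects,
              "subject_index must be in 1..n_subjects")
  k <- length(config$motion_classes)
  ch <- config$n_channels
  with_seed(derive_seed(config$seed, 101L, subject_index), {
    base <- matrix(stats::runif(k * ch, min = 0.2, max = 1.2), nrow = k,
                   dimnames = list(config$motion_classes, NULL))
    base[config$no_motion, ] <- config$noise_floor
    subject_scale <- exp(stats::rnorm(1, mean = 0, sd = 0.15))
    stab <- sort(sample.int(ch, size = max(1L, ch %/% 2L)))
    structure(list(base_amplitude = base,
                   subject_scale = subject_scale,
                   stab_channels = stab,
                   subject_index = as.integer(subject_index)),
              class = "class_profile")
  })
}

#' Condition transform for one confound condition
#'
#' Encodes how one condition perturbs the reference recording setup.
#' Position conditions re-mix channels with `W = (1 - alpha) I + alpha M`
#' (`M` a seeded row-stochastic perturbation unique to the
#' (subject, position) pair) and add stabilization baseline activity
#' proportional to the position's index distance from the reference (first)
#' condition. Intensity conditions leave channels unmixed and apply gain
#' `level^gamma`, interpolating the low-frequency spectral-peak location
#' and the Laplacian mixture weight linearly across the configured level
#' range.
#'
#' @param config a [generator_config()].
#' @param condition_value one of `config$conditions`.
#' @param subject_index subject number, 1-based.
#' @return an object of class `condition_transform` with fields
#'   `mixing_matrix`, `baseline_gain`, `gain`, `spectral_peak`,
#'   `laplacian_weight`, `condition_value`.
#' @export
make_condition_transform <- function(config, condition_value, subject_index) {
  stop_if_not(inherits(config, "generator_config"), "config must be a generator_config")
  pos <- match(condition_value, config$conditions)
  stop_if_not(!is.na(pos), "unknown condition_value", class = "emg_condition_error")
  ch <- config$n_channels
  if (config$condition_kind == "position") {
    alpha <- config$position_mixing_strength
    if (alpha == 0 || pos == 1L) {
      W <- diag(ch)
    } else {
      M <- with_seed(derive_seed(config$seed, 202L, subject_index, pos), {
        m <- matrix(stats::runif(ch * ch), ch, ch)
        # keep a dominant diagonal so mixing perturbs rather than scrambles
        m <- m + diag(ch) * ch / 2
        m / rowSums(m)
      })
      W <- (1 - alpha) * diag(ch) + alpha * M
    }
    baseline_gain <- config$baseline_activity_level * abs(pos - 1L)
    gain <- 1
    spectral_peak <- config$peak_shift_range[1]
    laplacian_weight <- config$laplacian_weight_range[1]
  } else {
    W <- diag(ch)
    baseline_gain <- 0
    gain <- condition_value ^ config$intensity_gain_exponent
    rng <- range(config$conditions)
    frac <- if (diff(rng) == 0) 0 else (condition_value - rng[1]) / diff(rng)
    spectral_peak <- config$peak_shift_range[1] +
      frac * diff(config$peak_shift_range)
    laplacian_weight <- config$laplacian_weight_range[1] +
      frac * diff(config$laplacian_weight_range)
  }
  structure(list(mixing_matrix = W, baseline_gain = baseline_gain, gain = gain,
                 spectral_peak = spectral_peak,
                 laplacian_weight = laplacian_weight,
                 condition_value = condition_value),
            class = "condition_transform")
}

# --- innovation + shaping helpers ------------------------------------------

# Laplace(0, b) with unit variance (b = 1/sqrt(2)) via inverse CDF.
rlaplace_unit <- function(n) {
  u <- stats::runif(n, min = -0.5, max = 0.5)
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# Per-sample (1 - w) Gaussian + w Laplacian mixture, unit variance components.
rmixture <- function(n, w) {
  pick <- stats::runif(n) < w
  x <- stats::rnorm(n)
  if (any(pick)) x[pick] <- rlaplace_unit(sum(pick))
  x
}

# Cached Butterworth designs (signal::butter); key on the design parameters.
.filter_cache <- new.env(parent = emptyenv())

butter_cached <- function(order, w, type) {
  key <- paste(type, order, paste(format(w, digits = 12), collapse = ","), sep = "|")
  flt <- get0(key, envir = .filter_cache, inherits = FALSE)
  if (is.null(flt)) {
    flt <- signal::butter(order, w, type = type)
    assign(key, flt, envir = .filter_cache)
  }
  flt
}

# Zero-phase (forward-backward) IIR filtering with reflection padding.
# The pad must cover the filter's settling time; narrowband designs (the
# line notch) ring for hundreds of samples.
zero_phase <- function(flt, x, pad = 512L) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    xp <- x
  }
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

# EMG passband (20-450 Hz capped below Nyquist) shaping of white innovations.
emg_band_filter <- function(fs) {
  high <- min(450, 0.45 * fs)
  butter_cached(4, c(20, high) / (fs / 2), "pass")
}

# Narrow resonant filter isolating the low-frequency firing-rate peak.
peak_filter <- function(fs, peak_hz, half_bw = 3) {
  lo <- max(0.5, peak_hz - half_bw)
  hi <- peak_hz + half_bw
  butter_cached(2, c(lo, hi) / (fs / 2), "pass")
}

# Relative mean-rectified contribution of the resonant peak component.
PEAK_REL <- 0.5

#' Synthesize one EMG trial
#'
#' Draws, per channel, a white (1 - w) Gaussian + w Laplacian innovation
#' sequence (`w` the transform's Laplacian weight), shapes it with a
#' 4th-order 20-450 Hz band-pass plus a resonant component at the
#' transform's low-frequency spectral peak, normalizes the channel so its
#' mean rectified value equals `gain x base_amplitude x subject_scale`
#' (mV), mixes channels with the transform's mixing matrix, adds
#' stabilization baseline activity on the profile's stabilization channels,
#' and finally white sensor noise at the configured noise floor.
#'
#' @param profile a [make_class_profiles()] result.
#' @param transform a [make_condition_transform()] result.
#' @param motion_label one of `config$motion_classes`.
#' @param config a [generator_config()].
#' @param trial_seed integer seed; identical seeds give bit-identical trials.
#' @param trial_index trial index stored in the metadata (default 1).
#' @return an [emg_recording()].
#' @export
synthesize_trial <- function(profile, transform, motion_label, config,
                             trial_seed, trial_index = 1L) {
  stop_if_not(motion_label %in% config$motion_classes, "unknown motion_label")
  n <- round(config$trial_duration * config$fs)
  stop_if_not(n >= 1, "trial too short: duration below one sample",
              class = "emg_size_error")
  ch <- config$n_channels
  amp <- profile$base_amplitude[motion_label, ] * profile$subject_scale *
    transform$gain
  bp <- emg_band_filter(config$fs)
  pk <- peak_filter(config$fs, transform$spectral_peak)
  w <- transform$laplacian_weight
  with_seed(trial_seed, {
    X <- matrix(0, nrow = ch, ncol = n)
    for (c_i in seq_len(ch)) {
      u <- zero_phase(bp, rmixture(n, w), pad = 128L)
      v <- zero_phase(pk, stats::rnorm(n), pad = 128L)
      mu <- mean(abs(u)); mv <- mean(abs(v))
      if (mu > 0) u <- u / mu
      if (mv > 0) v <- v / mv
      s <- u + PEAK_REL * v
      ms <- mean(abs(s))
      if (ms > 0) s <- s / ms
      X[c_i, ] <- s * amp[c_i]
    }
    X <- transform$mixing_matrix %*% X
    if (transform$baseline_gain > 0) {
      for (c_i in profile$stab_channels) {
        b <- zero_phase(bp, stats::rnorm(n), pad = 128L)
        mb <- mean(abs(b))
        if (mb > 0) b <- b / mb
        X[c_i, ] <- X[c_i, ] + transform$baseline_gain * b
      }
    }
    if (config$noise_floor > 0) {
      X <- X + matrix(stats::rnorm(ch * n, sd = config$noise_floor), ch, n)
    }
    emg_recording(X, fs = config$fs,
                  subject_id = profile$subject_index,
                  motion_label = motion_label,
                  condition_kind = config$condition_kind,
                  condition_value = transform$condition_value,
                  trial_index = as.integer(trial_index))
  })
}

#' Generate a full synthetic dataset
#'
#' Produces the balanced grid of
#' `n_subjects x conditions x motion_classes x reps_per_condition`
#' recordings. Every trial's seed is a deterministic function of the
#' configuration seed and the trial's coordinates, so the whole dataset is
#' bit-reproducible.
#'
#' @param config a [generator_config()].
#' @return a list of [emg_recording()] objects.
#' @examples
#' cfg <- generator_config(n_subjects = 1, motion_classes = c("rest", "grip"),
#'                         conditions = 1:2, reps_per_condition = 1,
#'                         trial_duration = 0.2)
#' length(generate_dataset(cfg))  # 1 x 2 x 2 x 1 = 4
#' @export
generate_dataset <- function(config) {
  stop_if_not(inherits(config, "generator_config"), "config must be a generator_config")
  out <- vector("list",
                config$n_subjects * length(config$conditions) *
                  length(config$motion_classes) * config$reps_per_condition)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    profile <- make_class_profiles(config, s)
    for (ci in seq_along(config$conditions)) {
      transform <- make_condition_transform(config, config$conditions[ci], s)
      for (mi in seq_along(config$motion_classes)) {
        for (r in seq_len(config$reps_per_condition)) {
          i <- i + 1L
          out[[i]] <- synthesize_trial(
            profile, transform, config$motion_classes[mi], config,
            trial_seed = derive_seed(config$seed, 303L, s, ci, mi, r),
            trial_index = r)
        }
      }
    }
  }
  out
}

#' Estimate the low-frequency spectral-peak location
#'
#' Locates the dominant low-frequency power peak (a proxy for the motor-unit
#' firing-rate peak) of a single channel via a smoothed periodogram
#' restricted to `[f_min, f_max]`.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param f_min,f_max search band, Hz.
#' @return peak frequency estimate, Hz.
#' @export
estimate_lowfreq_peak <- function(x, fs, f_min = 3, f_max = 60) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                          taper = 0.1, detrend = TRUE, plot = FALSE)
  keep <- sp$freq >= f_min & sp$freq <= f_max
  stop_if_not(any(keep), "search band contains no spectral estimates")
  sp$freq[keep][which.max(sp$spec[keep])]
}
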