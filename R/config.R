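#' Configuration for the synthetic EMG generator
#'
#' Builds a validated configuration describing one synthetic multi-subject
#' EMG study. The defaults emulate a 5-limb-position study shape common in
#' the myoelectric-control literature: 8 bipolar channels, 8 motion classes
#' (one rest/no-motion class), 10 repetitions of each motion in each of 5
#' limb positions, sampled at 1000 Hz.
#'
#' Two condition kinds are supported. For `"position"` conditions the
#' confound is a row-stochastic re-mixing of channels (electrode/fiber
#' topography shift, strength `alpha`) plus stabilization-muscle baseline
#' activity on half of the channels (gain `beta` per unit position distance
#' from the reference position, the first condition). For `"intensity"`
#' conditions (values are MVC fractions in (0, 1]) the confound is an
#' amplitude gain `level^gamma`, a low-frequency spectral peak whose
#' location interpolates linearly across `peak_shift_range` (default 10 to
#' 40 Hz over the level range), and a Gaussian/Laplacian amplitude-mixture
#' weight interpolating across `laplacian_weight_range`.
#'
#' @param n_subjects number of subjects.
#' @param n_channels number of EMG channels.
#' @param motion_classes character vector of class names.
#' @param no_motion name of the rest class; must appear exactly once in
#'   `motion_classes`.
#' @param condition_kind `"position"` or `"intensity"`.
#' @param conditions ordered condition values: position indices, or MVC
#'   fractions strictly in (0, 1]. The first entry is the reference
#'   condition.
#' @param reps_per_condition repetitions (trials) per motion per condition.
#' @param fs sampling rate, Hz.
#' @param trial_duration trial length, seconds.
#' @param position_mixing_strength mixing strength `alpha` in \[0, 1\].
#' @param baseline_activity_level stabilization baseline gain `beta`
#'   (mV of mean rectified baseline per unit position distance).
#' @param intensity_gain_exponent exponent `gamma` of the amplitude gain
#'   `level^gamma`; 1 gives the linear amplitude law.
#' @param peak_shift_range length-2 numeric, Hz: low-frequency spectral-peak
#'   location at the lowest and highest intensity level.
#' @param laplacian_weight_range length-2 numeric in \[0, 1\]: Laplacian
#'   mixture weight at the lowest and highest intensity level.
#' @param noise_floor sensor noise RMS, mV.
#' @param seed integer master seed; every random draw in the generator is a
#'   deterministic function of it.
#' @return an object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_subjects = 1, reps_per_condition = 2)
#' cfg$n_channels
#' @export
generator_config <- function(n_subjects = 2,
                             n_channels = 8,
                             motion_classes = c("no-motion", "power", "pinch",
                                                "key", "point", "wrist-flex",
                                                "wrist-ext", "supinate"),
                             no_motion = motion_classes[1],
                             condition_kind = c("position", "intensity"),
                             conditions = NULL,
                             reps_per_condition = 10,
                             fs = 1000,
                             trial_duration = 1,
                             position_mixing_strength = 0.7,
                             baseline_activity_level = 0.3,
                             intensity_gain_exponent = 1,
                             peak_shift_range = c(10, 40),
                             laplacian_weight_range = c(0.1, 0.5),
                             noise_floor = 0.01,
                             seed = 1L) {
  condition_kind <- match.arg(condition_kind)
  if (is.null(conditions)) {
    conditions <- if (condition_kind == "position") 1:5 else seq(0.2, 0.8, by = 0.1)
  }
  stop_if_not(is_count(n_subjects), "n_subjects must be a positive integer")
  stop_if_not(is_count(n_channels), "n_channels must be a positive integer")
  stop_if_not(length(motion_classes) >= 2 && !anyDuplicated(motion_classes),
              "motion_classes must be >= 2 distinct names")
  stop_if_not(sum(motion_classes == no_motion) == 1,
              "exactly one motion class must be the no-motion class")
  stop_if_not(length(conditions) >= 1, "conditions must be nonempty")
  stop_if_not(!anyDuplicated(conditions), "conditions must be distinct")
  if (condition_kind == "intensity") {
    stop_if_not(all(conditions > 0 & conditions <= 1),
                "intensity conditions are MVC fractions strictly in (0, 1]")
  }
  stop_if_not(is_count(reps_per_condition), "reps_per_condition must be a positive integer")
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  stop_if_not(is.numeric(trial_duration) && trial_duration > 0,
              "trial_duration must be > 0")
  stop_if_not(position_mixing_strength >= 0 && position_mixing_strength <= 1,
              "position_mixing_strength must lie in [0, 1]")
  stop_if_not(baseline_activity_level >= 0, "baseline_activity_level must be >= 0")
  stop_if_not(intensity_gain_exponent > 0, "intensity_gain_exponent must be > 0")
  stop_if_not(length(peak_shift_range) == 2 && all(peak_shift_range > 0) &&
                all(peak_shift_range < fs / 2),
              "peak_shift_range must be two frequencies below Nyquist")
  stop_if_not(length(laplacian_weight_range) == 2 &&
                all(laplacian_weight_range >= 0 & laplacian_weight_range <= 1),
              "laplacian_weight_range must lie in [0, 1]")
  stop_if_not(noise_floor >= 0, "noise_floor must be >= 0")
  stop_if_not(is_count(abs(seed) + 1), "seed must be an integer")
  # at least one 150 ms analysis window must fit in a trial
  stop_if_not(round(trial_duration * fs) >= round(0.150 * fs),
              "trial_duration x fs must cover at least one 150 ms window")

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels),
    motion_classes = motion_classes,
    no_motion = no_motion,
    condition_kind = condition_kind,
    conditions = conditions,
    reps_per_condition = as.integer(reps_per_condition),
    fs = fs,
    trial_duration = trial_duration,
    position_mixing_strength = position_mixing_strength,
    baseline_activity_level = baseline_activity_level,
    intensity_gain_exponent = intensity_gain_exponent,
    peak_shift_range = peak_shift_range,
    laplacian_weight_range = laplacian_weight_range,
    noise_floor = noise_floor,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d subject(s), %d channel(s), %d motion class(es) (rest: %s)\n",
              x$n_subjects, x$n_channels, length(x$motion_classes), x$no_motion))
  cat(sprintf("  %s conditions: %s; %d rep(s) each\n", x$condition_kind,
              paste(x$conditions, collapse = ", "), x$reps_per_condition))
  cat(sprintf("  fs %g Hz, trial %g s, seed %d\n", x$fs, x$trial_duration, x$seed))
  invisible(x)
}
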