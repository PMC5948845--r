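#' The nine activity classes
#'
#' The closed class vocabulary of the classification task: four
#' low-acceleration activities of daily life (ADLs), four high-acceleration
#' ADLs, and the pooled fall class. The order here is the canonical row and
#' column order of every confusion matrix produced by the package.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' activity_levels()
activity_levels <- function() {
  c("walk", "stand", "lie", "sit", "run",
    "stair_ascension", "stair_descension", "jump", "fall")
}

#' The eight simulated fall types
#'
#' Falls are performed from a static stand (in four directions), from
#' walking, and from running, the latter two with or without a stumble
#' before the fall.
#'
#' @return Character vector of length 8.
#' @export
fall_types <- function() {
  c("walk_fall", "walk_stumble_fall", "run_fall", "run_stumble_fall",
    "front_stand_fall", "back_stand_fall", "left_stand_fall",
    "right_stand_fall")
}

#' Construct a sensor trial
#'
#' A trial is one labelled recording from the insole system: a tibble with
#' one row per sample and columns `t` (seconds), `ax`, `ay`, `az`
#' (acceleration in g; x = medial/lateral, y = anterior/posterior,
#' z = vertical) and `fsr1`..`fsr4` (force-sensitive-resistor analog levels,
#' integers 0-4095; channel 1 is the heel quadrant). Subject, activity and
#' fall-type labels plus the sampling rate travel as attributes.
#'
#' @param samples Data frame with columns `t, ax, ay, az, fsr1, fsr2, fsr3,
#'   fsr4`.
#' @param subject_id Subject identifier (character).
#' @param activity One of [activity_levels()].
#' @param fall_type One of [fall_types()], or `NA` for ADL trials.
#' @param fs Sampling frequency in Hz (the hardware streams at 20 Hz).
#' @param validate Check range invariants (accelerations within +-8 g, FSR
#'   levels within 0-4095, `t` non-negative and equally spaced).
#'
#' @return A tibble of class `insole_trial`.
#' @export
new_trial <- function(samples, subject_id = NA_character_,
                      activity = NA_character_, fall_type = NA_character_,
                      fs = 20, validate = TRUE) {
  cols <- trial_columns()
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("samples is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  trial <- tibble::as_tibble(samples[cols])
  attr(trial, "subject_id") <- as.character(subject_id)
  attr(trial, "activity") <- as.character(activity)
  attr(trial, "fall_type") <- as.character(fall_type)
  attr(trial, "fs") <- fs
  class(trial) <- c("insole_trial", class(trial))
  if (validate) validate_trial(trial)
  trial
}

trial_columns <- function() c("t", "ax", "ay", "az",
                              "fsr1", "fsr2", "fsr3", "fsr4")

#' Validate a trial's range invariants
#'
#' @param trial An `insole_trial` (or any data frame with the trial columns).
#' @return The trial, invisibly; errors report the first offending row.
#' @export
validate_trial <- function(trial) {
  if (nrow(trial) == 0) return(invisible(trial))
  for (axis in c("ax", "ay", "az")) {
    bad <- which(abs(trial[[axis]]) > 8)
    if (length(bad) > 0) {
      abort(sprintf("%s out of sensor range (+-8 g) at row %d: %g",
                    axis, bad[1], trial[[axis]][bad[1]]))
    }
  }
  for (k in paste0("fsr", 1:4)) {
    v <- trial[[k]]
    bad <- which(v < 0 | v > 4095 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf("%s outside analog range 0-4095 at row %d: %g",
                    k, bad[1], v[bad[1]]))
    }
  }
  if (any(trial$t < 0)) abort("t must be non-negative")
  if (nrow(trial) > 2) {
    dt <- diff(trial$t)
    if (max(abs(dt - dt[1])) > 1e-6) {
      abort("samples must be equally spaced in time")
    }
  }
  invisible(trial)
}

#' Trial metadata accessors
#'
#' @param trial An `insole_trial`.
#' @return The subject id, activity label, fall type, sampling rate, or
#'   duration (time span from first to last sample, in seconds).
#' @export
trial_subject <- function(trial) attr(trial, "subject_id")

#' @rdname trial_subject
#' @export
trial_activity <- function(trial) attr(trial, "activity")

#' @rdname trial_subject
#' @export
trial_fall_type <- function(trial) attr(trial, "fall_type")

#' @rdname trial_subject
#' @export
trial_fs <- function(trial) attr(trial, "fs") %||% 20

#' @rdname trial_subject
#' @export
trial_duration <- function(trial) (nrow(trial) - 1) / trial_fs(trial)

#' Calibration parameters for the insole system
#'
#' The accelerometer is calibrated by laying the insole flat and static:
#' the reading should then be 0 g on the x- and y-axes and 1 g on the
#' vertical z-axis, and any residual is removed as a per-axis additive
#' offset. The force sensors are used as on/off switches with a non-zero
#' threshold (default 100 of the 4096 analog levels) so that residual load
#' in an unloaded shoe does not register as foot contact; no force-unit
#' calibration is performed.
#'
#' @param imu_offsets Numeric length-3 additive offsets (g) for ax, ay, az.
#' @param fsr_on_threshold Analog level in 0-4095 above which a force
#'   sensor counts as "on" (strictly greater than).
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(imu_offsets = c(0, 0, 0), fsr_on_threshold = 100) {
  stopifnot(length(imu_offsets) == 3, is.numeric(imu_offsets))
  if (fsr_on_threshold < 0 || fsr_on_threshold > 4095) {
    abort("fsr_on_threshold must lie in [0, 4095]")
  }
  structure(list(imu_offsets = as.numeric(imu_offsets),
                 fsr_on_threshold = fsr_on_threshold),
            class = "calibration_spec")
}

#' Apply accelerometer offset calibration
#'
#' Shifts each acceleration axis by its additive offset so that a flat,
#' static insole reads (0, 0, 1) g. An affine per-axis shift; FSR channels
#' are untouched.
#'
#' @param trial An `insole_trial`.
#' @param cal A [calibration_spec()].
#' @return The calibrated trial.
#' @export
apply_imu_offset <- function(trial, cal = calibration_spec()) {
  trial$ax <- trial$ax + cal$imu_offsets[1]
  trial$ay <- trial$ay + cal$imu_offsets[2]
  trial$az <- trial$az + cal$imu_offsets[3]
  trial
}

#' Threshold a force-sensor reading into an on/off contact state
#'
#' A channel is "on" (foot contact) when its analog level strictly exceeds
#' the threshold; a reading exactly at the threshold is off, so residual
#' load at the threshold level never registers as contact.
#'
#' @param reading Integer analog level(s) in 0-4095.
#' @param threshold On/off threshold (default 100).
#' @return Logical vector, `TRUE` = on.
#' @export
#' @examples
#' fsr_on_state(c(0, 100, 101, 4095))
fsr_on_state <- function(reading, threshold = 100) {
  if (any(reading < 0 | reading > 4095)) {
    abort("FSR reading outside analog range 0-4095")
  }
  reading > threshold
}
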