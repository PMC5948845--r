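#' Sum Vector Magnitude of a tri-axial acceleration
#'
#' The orientation-invariant magnitude sqrt(ax^2 + ay^2 + az^2), in g. A
#' static sensor in any orientation reads 1 g; free fall reads near 0 g.
#' (The acronym collision with "support vector machine" is the field's; the
#' package spells out which is meant everywhere it matters.)
#'
#' @param ax,ay,az Accelerations in g (vectorized).
#' @return Numeric vector of magnitudes, in g.
#' @export
#' @examples
#' sum_vector_magnitude(0, 0, 1)
#' sum_vector_magnitude(0.6, 0, 0.8)
sum_vector_magnitude <- function(ax, ay, az) {
  sqrt(ax^2 + ay^2 + az^2)
}

#' Low-pass filter specification
#'
#' Defaults to the 1st-order Butterworth with a 1 Hz cutoff at 20 Hz
#' sampling that defines the filtered Sum Vector Magnitude signal. Phase
#' mode `"zero"` applies the filter forward and backward
#' ([signal::filtfilt()]), which keeps the signal's minima where the events
#' are (no group delay) at the cost of doubling the effective order;
#' `"causal"` is a single forward pass.
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cutoff frequency in Hz, 0 < cutoff < fs/2.
#' @param fs Sampling frequency in Hz.
#' @param phase `"zero"` (default) or `"causal"`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 1, cutoff = 1, fs = 20,
                        phase = c("zero", "causal")) {
  phase <- arg_match(phase)
  if (order < 1) abort("order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2) abort("cutoff must lie in (0, fs/2)")
  structure(list(order = order, cutoff = cutoff, fs = fs, phase = phase),
            class = "filter_spec")
}

#' Low-pass filter a signal
#'
#' Butterworth low-pass with unit DC gain. With the default zero-phase mode
#' the effective magnitude response is |H(f)|^2 of the one-pass filter.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, spec = filter_spec()) {
  n <- length(x)
  min_len <- 3 * spec$order * ceiling(spec$fs / spec$cutoff)
  if (n < min_len) {
    abort(sprintf("signal too short to filter: %d samples, need >= %d",
                  length(x), min_len))
  }
  bf <- signal::butter(spec$order, spec$cutoff / (spec$fs / 2), type = "low")
  # start the recursion at the first sample's DC steady state (unit DC
  # gain) so a constant signal passes through exactly
  run <- function(z) as.numeric(signal::filter(bf, z - z[1])) + z[1]
  if (spec$phase == "zero") {
    # forward-backward pass over a reflection-padded signal so the filter
    # transient is absorbed by the padding, not the data
    pad <- min(min_len, n - 1)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- rev(run(rev(run(xp))))
    y[(pad + 1):(pad + n)]
  } else {
    run(x)
  }
}

#' Add raw and filtered Sum Vector Magnitude columns to a trial
#'
#' Computes the per-sample magnitude and its low-pass-filtered version over
#' the *whole* trial (the filter must see the full trial before any window
#' is cut, because the window is centered on the trial-level filtered
#' minimum).
#'
#' @param trial An `insole_trial`.
#' @param spec A [filter_spec()]; its `fs` is overridden by the trial's.
#' @return The trial with `svm` and `fsvm` columns added.
#' @export
add_svm_signals <- function(trial, spec = filter_spec()) {
  spec$fs <- trial_fs(trial)
  trial$svm <- sum_vector_magnitude(trial$ax, trial$ay, trial$az)
  trial$fsvm <- lowpass_filter(trial$svm, spec)
  trial
}

#' Locate the window center of a trial
#'
#' The index of the global minimum of the filtered Sum Vector Magnitude;
#' ties are broken toward the earliest index. For fall trials this minimum
#' sits in the free-fall/impact phase, so the analysis window is centered
#' on the fall.
#'
#' @param fsvm Filtered Sum Vector Magnitude sequence.
#' @return 1-based index of the minimum.
#' @export
locate_window_center <- function(fsvm) {
  if (length(fsvm) == 0) abort("empty signal")
  which.min(fsvm)
}

#' Window length in samples
#'
#' 121 samples = 6.05 s at 20 Hz: the event sample plus 60 samples (3 s)
#' on either side.
#' @return 121L
#' @export
window_length <- function() 121L

#' Extract the 121-sample analysis window from a trial
#'
#' Cuts samples `center - 60 ... center + 60` (inclusive). When the center
#' sits within 60 samples of either trial edge the window is shifted just
#' enough to fit ("clamped") rather than padded, so it always contains 121
#' real samples. The `svm`/`fsvm` columns are computed on the full trial
#' first and sliced, never re-filtered inside the window.
#'
#' @param trial An `insole_trial` of length >= 121.
#' @param center 1-based center index; default = [locate_window_center()]
#'   of the trial's filtered magnitude.
#' @param spec A [filter_spec()] used if the trial lacks `svm`/`fsvm`.
#' @return A tibble of class `insole_window` with 121 rows and attributes
#'   `center_index` (trial-level) and `window_start`.
#' @export
extract_window <- function(trial, center = NULL, spec = filter_spec()) {
  n <- nrow(trial)
  len <- window_length()
  if (n < len) {
    abort(sprintf("trial has %d samples; windowing needs >= %d", n, len))
  }
  if (is.null(trial[["fsvm"]])) trial <- add_svm_signals(trial, spec)
  if (is.null(center)) center <- locate_window_center(trial$fsvm)
  half <- (len - 1L) %/% 2L
  start <- min(max(center - half, 1L), n - len + 1L)
  win <- trial[start:(start + len - 1L), , drop = FALSE]
  attr(win, "subject_id") <- trial_subject(trial)
  attr(win, "activity") <- trial_activity(trial)
  attr(win, "fall_type") <- trial_fall_type(trial)
  attr(win, "fs") <- trial_fs(trial)
  attr(win, "center_index") <- center
  attr(win, "window_start") <- start
  class(win) <- unique(c("insole_window", class(win)))
  win
}
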