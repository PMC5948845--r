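#' The 45-feature registry
#'
#' All candidate features computed from a 121-sample window, in canonical
#' order: 1-4 per-axis and total means, 5-8 variances, 9-12 skewness, 13-16
#' kurtosis, 17-20 spectral energies, 21-23 axis-pair correlations, 24-25
#' raw Sum-Vector-Magnitude extrema, 26-27 filtered extrema, 28 percent of
#' the window with filtered magnitude below 0.9 g, 29 variance of the
#' filtered magnitude over the final 2 s, 30-33 FSR on-duration percent,
#' 34-37 FSR on/off switch counts, 38-41 FSR window means, 42-45 FSR
#' final-2-s means. "Total" is the per-sample raw Sum Vector Magnitude.
#'
#' @return A tibble with columns `index`, `name`, `group`.
#' @export
feature_registry <- function() {
  axes <- c("X", "Y", "Z", "Total")
  fsr <- paste0("FSR", 1:4)
  tibble::tibble(
    index = 1:45,
    name = c(paste0("mean_", axes),
             paste0("variance_", axes),
             paste0("skewness_", axes),
             paste0("kurtosis_", axes),
             paste0("energy_", axes),
             c("correlationX_Y", "correlationX_Z", "correlationY_Z"),
             c("min_SVM", "max_SVM", "min_fSVM", "max_fSVM"),
             c("fSVM_dip_pct", "fSVM_tail_var"),
             paste0(fsr, "_on_pct"),
             paste0(fsr, "_switches"),
             paste0("mean_", fsr),
             paste0("mean_", fsr, "_final2s")),
    group = c(rep("moment", 16), rep("energy", 4), rep("correlation", 3),
              rep("svm_extrema", 4), "dip", "tail_var",
              rep("fsr_on", 4), rep("fsr_switch", 4),
              rep("fsr_mean", 4), rep("fsr_tail_mean", 4))
  )
}

feature_names <- function() feature_registry()$name

# number of trailing samples forming the "final 2 s" tail (2 s at 20 Hz)
tail_samples <- function(fs = 20) as.integer(round(2 * fs))

# central moments with spec'd conventions: variance n-1; skewness and excess
# kurtosis from bias-uncorrected standardized moments; constant signal -> 0
moment_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  v <- if (n > 1) sum(d^2) / (n - 1) else 0
  if (m2 < 1e-24) {
    c(mean = m, variance = v, skewness = 0, kurtosis = 0)
  } else {
    c(mean = m, variance = v,
      skewness = mean(d^3) / m2^1.5,
      kurtosis = mean(d^4) / m2^2 - 3)
  }
}

window_channels <- function(window) {
  list(X = window$ax, Y = window$ay, Z = window$az,
       Total = window$svm %||% sum_vector_magnitude(window$ax, window$ay,
                                                    window$az))
}

#' Moment features (1-16)
#'
#' Mean, variance (unbiased), skewness and excess kurtosis of each
#' acceleration axis and of the total (raw Sum Vector Magnitude) channel.
#' Constant channels get skewness and kurtosis 0 so feature matrices stay
#' finite.
#'
#' @param window An `insole_window`.
#' @return Named numeric vector of 16 features.
#' @export
axis_moment_features <- function(window) {
  ch <- window_channels(window)
  stats <- lapply(ch, moment_stats)
  out <- c(vapply(stats, `[[`, 0, "mean"),
           vapply(stats, `[[`, 0, "variance"),
           vapply(stats, `[[`, 0, "skewness"),
           vapply(stats, `[[`, 0, "kurtosis"))
  names(out) <- feature_names()[1:16]
  out
}

#' Spectral energy features (17-20)
#'
#' Sum of squared DFT magnitudes excluding the zero-frequency (DC) term,
#' divided by the squared window length; equivalently the mean squared
#' deviation from the window mean (Parseval). A constant channel has zero
#' energy; a sinusoid of amplitude A spanning integer periods has energy
#' A^2/2.
#'
#' @param window An `insole_window`.
#' @return Named numeric vector of 4 features.
#' @export
energy_features <- function(window) {
  ch <- window_channels(window)
  out <- vapply(ch, function(x) {
    n <- length(x)
    sp <- Mod(fft(x))^2
    sum(sp[-1]) / n^2
  }, 0)
  names(out) <- feature_names()[17:20]
  out
}

#' Axis-pair correlation features (21-23)
#'
#' Pearson correlation between the (x,y), (x,z) and (y,z) acceleration
#' pairs; pairs involving a constant axis are defined as 0.
#'
#' @param window An `insole_window`.
#' @return Named numeric vector of 3 features.
#' @export
axis_correlation_features <- function(window) {
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }
  out <- c(safe_cor(window$ax, window$ay),
           safe_cor(window$ax, window$az),
           safe_cor(window$ay, window$az))
  names(out) <- feature_names()[21:23]
  out
}

#' Sum-Vector-Magnitude extrema features (24-27)
#'
#' Minimum and maximum of the raw and of the low-pass-filtered Sum Vector
#' Magnitude over the window. The filtered minimum (feature 26) is the
#' quantity the window was centered on; for falls it is typically far below
#' the 0.9 g threshold.
#'
#' @param window An `insole_window` carrying `svm` and `fsvm` columns.
#' @return Named numeric vector of 4 features.
#' @export
svm_extrema_features <- function(window) {
  out <- c(min(window$svm), max(window$svm),
           min(window$fsvm), max(window$fsvm))
  names(out) <- feature_names()[24:27]
  out
}

#' Sub-threshold dip fraction (feature 28)
#'
#' Percent of window samples whose filtered Sum Vector Magnitude lies
#' strictly below the threshold (default 0.9 g). Separates jumping, stair
#' climbing and falls (which dip) from running and the low-acceleration
#' activities (which do not).
#'
#' @param window An `insole_window`.
#' @param threshold Dip threshold in g.
#' @return Named numeric scalar, in percent of the window.
#' @export
dip_fraction_feature <- function(window, threshold = 0.9) {
  out <- 100 * mean(window$fsvm < threshold)
  names(out) <- feature_names()[28]
  out
}

#' Filtered-magnitude tail variance (feature 29)
#'
#' Variance of the filtered Sum Vector Magnitude over the final 2 s (last
#' 40 samples at 20 Hz) of the window. Falls end in a static lying posture,
#' so their tail variance is near zero while other high-acceleration
#' activities keep moving.
#'
#' @param window An `insole_window`.
#' @return Named numeric scalar.
#' @export
tail_variance_feature <- function(window) {
  k <- tail_samples(attr(window, "fs") %||% 20)
  out <- var(tail(window$fsvm, k))
  names(out) <- feature_names()[29]
  out
}

#' Force-sensor features (30-45)
#'
#' Per FSR channel: percent of the window the channel is on (strictly above
#' the calibration threshold), total count of on/off transitions between
#' adjacent samples, mean analog level over the window, and mean analog
#' level over the final 2 s.
#'
#' @param window An `insole_window`.
#' @param cal A [calibration_spec()] supplying the on/off threshold.
#' @return Named numeric vector of 16 features.
#' @export
fsr_features <- function(window, cal = calibration_spec()) {
  k <- tail_samples(attr(window, "fs") %||% 20)
  chans <- lapply(paste0("fsr", 1:4), function(nm) window[[nm]])
  on <- lapply(chans, fsr_on_state, threshold = cal$fsr_on_threshold)
  out <- c(vapply(on, function(s) 100 * mean(s), 0),
           vapply(on, function(s) sum(diff(s) != 0), 0),
           vapply(chans, mean, 0),
           vapply(chans, function(x) mean(tail(x, k)), 0))
  names(out) <- feature_names()[30:45]
  out
}

#' Compute the full 45-feature vector of a window
#'
#' Assembles all registry features in canonical order.
#'
#' @param window An `insole_window`.
#' @param cal A [calibration_spec()].
#' @param dip_threshold Threshold in g for the dip-fraction feature.
#' @return A 1-row tibble with the 45 named feature columns.
#' @export
feature_vector <- function(window, cal = calibration_spec(),
                           dip_threshold = 0.9) {
  vals <- c(axis_moment_features(window),
            energy_features(window),
            axis_correlation_features(window),
            svm_extrema_features(window),
            dip_fraction_feature(window, dip_threshold),
            tail_variance_feature(window),
            fsr_features(window, cal))
  stopifnot(identical(names(vals), feature_names()))
  tibble::as_tibble(as.list(vals))
}

#' Featurize a trial dataset
#'
#' The main pipeline verb: for every trial, apply offset calibration,
#' compute the raw and filtered Sum Vector Magnitude, cut the 121-sample
#' window centered on the filtered minimum, and compute the 45 features.
#'
#' @param dataset A nested trial dataset (columns `trial_id, subject_id,
#'   activity, fall_type, data`).
#' @param cal A [calibration_spec()] (offsets applied before featurizing).
#' @param spec A [filter_spec()].
#' @param dip_threshold Threshold in g for the dip-fraction feature.
#' @return A tibble with the metadata columns followed by the 45 features,
#'   one row per trial.
#' @export
featurize_trials <- function(dataset, cal = calibration_spec(),
                             spec = filter_spec(), dip_threshold = 0.9) {
  recal <- any(cal$imu_offsets != 0)
  feats <- purrr::map(dataset$data, function(tr) {
    tr <- apply_imu_offset(tr, cal)
    if (recal) tr$svm <- tr$fsvm <- NULL  # stale after axis shifts
    win <- extract_window(tr, spec = spec)
    feature_vector(win, cal, dip_threshold)
  })
  dplyr::bind_cols(
    dataset[c("trial_id", "subject_id", "activity", "fall_type")],
    dplyr::bind_rows(feats)
  )
}

#' Metadata columns of a feature table
#' @return Character vector of the non-feature column names.
#' @export
feature_meta_columns <- function() {
  c("trial_id", "subject_id", "activity", "fall_type")
}

# numeric feature column names of a feature table, in table order
feature_data_columns <- function(features) {
  setdiff(names(features), feature_meta_columns())
}
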