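# Synthetic protocol simulator.
#
# The generative model is deliberately minimal: per activity, the raw Sum
# Vector Magnitude is a 1 g gravity baseline plus a cadence-locked periodic
# component (fundamental + one harmonic), activity-specific dip/impact
# transients (raised-cosine pulses: stance unweighting on stairs, flight
# phases in jumping, the free-fall/impact sequence of falls), and white
# Gaussian noise. Acceleration is that magnitude projected onto a slowly
# varying body-orientation unit vector, which is what gives the per-axis
# moment features their class signal. FSR channels follow per-activity load
# patterns (constant loaded/unloaded, cyclic gait, cyclic flight,
# load-then-unload). This reproduces every signal property the classifier
# consumes without attempting biomechanical fidelity.

#' Per-activity signal profiles of the simulator
#'
#' One row per ADL with the frozen constants of the generative model:
#' `cadence` (step or jump rate, Hz), `osc1`/`osc2` (amplitude in g of the
#' fundamental and second harmonic of the periodic component), `dip_depth`
#' and `dip_width` (depth in g and width in seconds of the per-stride
#' unweighting pulse, stairs only), `flight_frac` (fraction of the jump
#' cycle spent airborne), `am` (slow amplitude-modulation depth in g),
#' `noise_sd` (per-axis accelerometer noise, g), `fsr_pattern`, `tilt_deg`
#' (body tilt from vertical), and `dip_target` (the per-activity mean
#' percent of a window with filtered magnitude below 0.9 g that the
#' constants were calibrated against, recorded for reference).
#'
#' @return A tibble with 8 rows (one per ADL).
#' @export
activity_profiles <- function() {
  tibble::tribble(
    ~activity, ~cadence, ~osc1, ~osc2, ~dip_depth, ~dip_width,
    ~flight_frac, ~am, ~noise_sd, ~fsr_pattern, ~tilt_deg, ~dip_target,
    "walk", 1.8, 0.15, 0.10, 0, 0, 0, 0.006, 0.020, "cyclic_gait", 0, 0,
    "stand", 0, 0, 0, 0, 0, 0, 0, 0.008, "constant_loaded", 0, 0,
    "lie", 0, 0, 0, 0, 0, 0, 0, 0.008, "constant_unloaded", 80, 0,
    "sit", 0, 0, 0, 0, 0, 0, 0, 0.008, "constant_unloaded", 12, 0,
    "run", 2.7, 0.45, 0.35, 0, 0, 0, 0.008, 0.025, "cyclic_gait", 0, 0.15,
    "stair_ascension", 1.4, 0.28, 0.14, 0.43, 0.30,
    0, 0.010, 0.020, "cyclic_gait", 0, 23.68,
    "stair_descension", 1.4, 0.28, 0.14, 0.34, 0.26,
    0, 0.010, 0.020, "cyclic_gait", 0, 14.60,
    "jump", 0.87, 0.12, 0, 0.92, 0,
    0.44, 0.010, 0.020, "cyclic_flight", 0, 56.30
  )
}

adl_profile <- function(activity) {
  pr <- activity_profiles()
  row <- pr[pr$activity == activity, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown ADL activity: ", activity))
  }
  as.list(row)
}

#' Per-subject heterogeneity parameters
#'
#' Subjects differ by multiplicative log-normal scales (sigma = 0.1) on
#' cadence, movement amplitude and FSR load baseline, emulating the
#' uncoached between-subject deviation of the protocol.
#'
#' @param subject_id Subject identifier.
#' @param seed Integer seed controlling the subject's scales.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  scales <- exp(rnorm(3, 0, 0.1))
  structure(list(subject_id = as.character(subject_id),
                 cadence_scale = scales[1],
                 amp_scale = scales[2],
                 fsr_scale = scales[3],
                 seed = seed),
            class = "subject_params")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s) + 1L
}

# raised-cosine pulse shape on phase x in [0, 1]: 0 at edges, 1 at center
raised_cosine <- function(x) 0.5 * (1 - cos(2 * pi * pmin(pmax(x, 0), 1)))

# magnitude target (g) for one ADL; assumes set.seed() was already called
adl_svm_target <- function(profile, t, subject) {
  n <- length(t)
  s <- rep(1, n)
  cad <- profile$cadence * subject$cadence_scale
  amp <- subject$amp_scale
  if (cad > 0) {
    ph <- runif(1)
    s <- s + amp * profile$osc1 * sin(2 * pi * (cad * t + ph)) +
      amp * profile$osc2 * sin(4 * pi * (cad * t + ph) + 1.3)
  }
  if (profile$am > 0) {
    s <- s + profile$am * sin(2 * pi * (0.13 * t + runif(1)))
  }
  if (profile$dip_depth > 0 && profile$flight_frac == 0) {
    # one unweighting dip per stride (stride rate = step cadence / 2)
    rate <- cad / 2
    phase <- (t * rate + runif(1)) %% 1
    w <- profile$dip_width * rate
    s <- s - profile$dip_depth * raised_cosine(phase / w) * (phase < w)
  }
  if (profile$flight_frac > 0) {
    # jump cycle: flight phase near free fall, then a landing spike
    phase <- (t * cad + runif(1)) %% 1
    f <- profile$flight_frac
    flight <- phase < f
    edge <- 0.15
    u <- phase / f
    shape <- pmin(u / edge, (1 - u) / edge, 1)
    s <- ifelse(flight, 1 - profile$dip_depth * pmin(pmax(shape, 0), 1), s)
    spike_w <- 0.09
    in_spike <- phase >= f & phase < f + spike_w
    s <- s + (amp * 2.1) * sin(pi * (phase - f) / spike_w) * in_spike
  }
  s
}

# raised-cosine on/off envelope: subjects start from and return to rest
# over `ramp` seconds at the stream boundaries, so the periodic component
# never collides with the filter's boundary handling
boundary_envelope <- function(t, ramp = 0.75) {
  dur <- t[length(t)]
  e <- rep(1, length(t))
  lead <- t < ramp
  e[lead] <- 0.5 * (1 - cos(pi * t[lead] / ramp))
  lag <- t > dur - ramp
  e[lag] <- 0.5 * (1 - cos(pi * (dur - t[lag]) / ramp))
  e
}

# orientation unit vectors for a tilt angle (deg) and an xy direction
orientation_matrix <- function(n, tilt_deg, direction = c(0, 1)) {
  th <- tilt_deg * pi / 180
  cbind(ax = sin(th) * direction[1],
        ay = sin(th) * direction[2],
        az = rep(cos(th), n))
}

# project magnitude onto orientation, add gait sway and noise, clip to +-8 g
compose_acceleration <- function(s, orient, profile, subject, t) {
  cad <- profile$cadence * subject$cadence_scale
  ax <- s * orient[, "ax"]
  ay <- s * orient[, "ay"]
  az <- s * orient[, "az"]
  if (cad > 0) {
    ax <- ax + 0.06 * subject$amp_scale * sin(2 * pi * (cad / 2 * t + runif(1)))
    ay <- ay + 0.08 * subject$amp_scale * sin(2 * pi * (cad * t + runif(1)))
  }
  nsd <- profile$noise_sd
  n <- length(s)
  tibble::tibble(
    t = t,
    ax = pmin(pmax(ax + rnorm(n, 0, nsd), -8), 8),
    ay = pmin(pmax(ay + rnorm(n, 0, nsd), -8), 8),
    az = pmin(pmax(az + rnorm(n, 0, nsd), -8), 8)
  )
}

fsr_base_levels <- function(subject) {
  round(c(1500, 1100, 1300, 900) * subject$fsr_scale)
}

# FSR analog levels for one pattern; returns n x 4 integer matrix
gen_fsr <- function(pattern, t, profile, subject) {
  n <- length(t)
  base <- fsr_base_levels(subject)
  cad <- profile$cadence * subject$cadence_scale
  off_level <- function() pmax(round(30 + rnorm(n, 0, 10)), 0)
  loaded <- function(k, frac = rep(TRUE, n)) {
    lv <- ifelse(frac, base[k] + rnorm(n, 0, 40), 30 + rnorm(n, 0, 10))
    pmin(pmax(round(lv), 0), 4095)
  }
  m <- switch(
    pattern,
    constant_loaded = vapply(1:4, function(k) loaded(k), numeric(n)),
    constant_unloaded = vapply(1:4, function(k) {
      pmin(pmax(round(45 + rnorm(n, 0, 15)), 0), 4095)
    }, numeric(n)),
    cyclic_gait = {
      rate <- max(cad / 2, 0.1)
      offs <- c(0, 0.10, 0.15, 0.25)   # heel contacts first
      ph0 <- runif(1)
      vapply(1:4, function(k) {
        phase <- (t * rate + ph0 + offs[k]) %% 1
        loaded(k, phase < 0.62)
      }, numeric(n))
    },
    cyclic_flight = {
      rate <- max(cad, 0.1)
      ph0 <- runif(1)
      vapply(1:4, function(k) {
        phase <- (t * rate + ph0) %% 1
        loaded(k, phase >= profile$flight_frac)
      }, numeric(n))
    },
    abort(paste0("unknown fsr pattern: ", pattern))
  )
  colnames(m) <- paste0("fsr", 1:4)
  m
}

#' Generate a synthetic ADL sensor stream
#'
#' Produces one labelled trial of the requested activity of daily life with
#' the signal structure the classifier relies on: static postures read
#' ~1 g with near-zero variance, walking and running oscillate with
#' filtered-magnitude troughs above 0.9 g, stair climbing and jumping dip
#' below 0.9 g for a calibrated fraction of the time, and the FSR channels
#' follow the activity's load pattern (standing loaded, sitting/lying
#' unloaded, gait and jumping cyclic).
#'
#' @param activity One of the 8 ADLs (see [activity_levels()]).
#' @param duration Stream duration in seconds; `round(duration * fs)`
#'   samples are generated, at least 121.
#' @param subject A [subject_params()].
#' @param seed Integer seed; identical arguments give identical streams.
#' @param fs Sampling frequency in Hz.
#' @return An `insole_trial`.
#' @export
generate_adl_stream <- function(activity, duration,
                                subject = subject_params(), seed = 1,
                                fs = 20) {
  profile <- adl_profile(activity)
  n <- round(duration * fs)
  if (n < window_length()) {
    abort(sprintf("duration %.2f s gives %d samples; need >= %d",
                  duration, n, window_length()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, match(activity, activity_levels())))
  t <- (seq_len(n) - 1) / fs
  s <- 1 + (adl_svm_target(profile, t, subject) - 1) * boundary_envelope(t)
  orient <- orientation_matrix(n, profile$tilt_deg)
  acc <- compose_acceleration(s, orient, profile, subject, t)
  fsr <- gen_fsr(profile$fsr_pattern, t, profile, subject)
  new_trial(dplyr::bind_cols(acc, tibble::as_tibble(fsr)),
            subject_id = subject$subject_id, activity = activity, fs = fs)
}

fall_prefall_activity <- function(fall_type) {
  switch(fall_type,
         walk_fall = , walk_stumble_fall = "walk",
         run_fall = , run_stumble_fall = "run",
         front_stand_fall = , back_stand_fall = ,
         left_stand_fall = , right_stand_fall = "stand",
         abort(paste0("unknown fall type: ", fall_type)))
}

fall_direction <- function(fall_type) {
  switch(fall_type,
         back_stand_fall = c(0, -1),
         left_stand_fall = c(-1, 0),
         right_stand_fall = c(1, 0),
         c(0, 1))   # forward by default
}

#' Generate a synthetic fall trial
#'
#' A fall trial is a pre-fall locomotion segment matching the fall type
#' (static standing, walking, or running, the stumble variants adding a
#' >2 g transient peak shortly before the fall), followed by an impact
#' sequence -- a deep free-fall dip in the Sum Vector Magnitude (filtered
#' minimum around 0.18 g), an impact spike, and a short ring-down -- and
#' finally at least 2 s of static lying: filtered magnitude near 1 g with
#' near-zero variance, body tilted to horizontal, and all FSR channels
#' unloaded. The trial's global filtered-magnitude minimum always lies in
#' the impact segment, which is what lets the windowing stage center on the
#' fall. Attributes `impact_start`/`impact_end` record the impact segment's
#' sample range.
#'
#' @param fall_type One of [fall_types()].
#' @param subject A [subject_params()].
#' @param seed Integer seed.
#' @param fs Sampling frequency in Hz.
#' @return An `insole_trial` with activity label `"fall"`.
#' @export
generate_fall_trial <- function(fall_type, subject = subject_params(),
                                seed = 1, fs = 20) {
  pre_act <- fall_prefall_activity(fall_type)
  profile <- adl_profile(pre_act)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 100 + match(fall_type, fall_types())))

  pre_dur <- switch(pre_act, stand = runif(1, 2.8, 3.6),
                    walk = runif(1, 4.5, 5.5), run = runif(1, 4.0, 5.0))
  dip_w <- 0.90          # free-fall dip width, s
  spike_w <- 0.15        # impact spike width, s
  ring_w <- 0.30         # ring-down, s
  tail_dur <- runif(1, 2.8, 3.4)

  n_pre <- round(pre_dur * fs)
  n_dip <- round(dip_w * fs)
  n_spike <- round(spike_w * fs)
  n_ring <- round(ring_w * fs)
  n_tail <- round(tail_dur * fs)
  n <- n_pre + n_dip + n_spike + n_ring + n_tail
  t <- (seq_len(n) - 1) / fs

  # magnitude target per segment
  s <- rep(1, n)
  pre_idx <- seq_len(n_pre)
  s[pre_idx] <- 1 + (adl_svm_target(profile, t[pre_idx], subject) - 1) *
    pmin(t[pre_idx] / 0.75, 1)   # ramp in from rest
  if (grepl("stumble", fall_type)) {
    # stumble transient ~0.8 s before the fall: a sharp >2 g peak
    st_c <- n_pre - round(0.8 * fs)
    st_w <- round(0.2 * fs)
    idx <- pmax(st_c - st_w, 1):pmin(st_c + st_w, n_pre)
    s[idx] <- s[idx] +
      (1.9 + 0.4 * runif(1)) * raised_cosine((idx - (st_c - st_w)) /
                                               (2 * st_w))
  }
  dip_idx <- n_pre + seq_len(n_dip)
  s[dip_idx] <- 1 - (0.94 - 0.04 * runif(1)) *
    raised_cosine(seq_len(n_dip) / n_dip)
  spike_idx <- n_pre + n_dip + seq_len(n_spike)
  s[spike_idx] <- 1 + (1.8 + 0.6 * runif(1)) *
    sin(pi * seq_len(n_spike) / n_spike)
  ring_idx <- n_pre + n_dip + n_spike + seq_len(n_ring)
  s[ring_idx] <- 1 + 0.35 * exp(-3 * seq_len(n_ring) / n_ring) *
    cos(2 * pi * 4 * t[ring_idx])

  # orientation: upright through the pre-fall, rotating to horizontal
  # lying across the impact sequence
  dir <- fall_direction(fall_type)
  tilt <- rep(0, n)
  rot_idx <- n_pre + seq_len(n_dip + n_spike + n_ring)
  tilt[rot_idx] <- 80 * seq_along(rot_idx) / length(rot_idx)
  tilt[(n - n_tail + 1):n] <- 80
  th <- tilt * pi / 180
  orient <- cbind(ax = sin(th) * dir[1], ay = sin(th) * dir[2],
                  az = cos(th))

  # quiet accelerometer noise in the static tail
  tail_profile <- profile
  tail_profile$cadence <- 0
  acc_active <- compose_acceleration(s, orient, profile, subject, t)
  nsd_tail <- 0.006
  tail_idx <- (n - n_tail + 1):n
  acc <- acc_active
  acc$ax[tail_idx] <- s[tail_idx] * orient[tail_idx, "ax"] +
    rnorm(n_tail, 0, nsd_tail)
  acc$ay[tail_idx] <- s[tail_idx] * orient[tail_idx, "ay"] +
    rnorm(n_tail, 0, nsd_tail)
  acc$az[tail_idx] <- s[tail_idx] * orient[tail_idx, "az"] +
    rnorm(n_tail, 0, nsd_tail)

  # FSR: locomotion pattern before the fall, unloaded from impact onward
  fsr <- gen_fsr(profile$fsr_pattern, t, profile, subject)
  post_idx <- (n_pre + 1):n
  for (k in 1:4) {
    fsr[post_idx, k] <- pmin(pmax(round(35 + rnorm(length(post_idx), 0, 12)),
                                  0), 4095)
  }

  trial <- new_trial(dplyr::bind_cols(acc, tibble::as_tibble(fsr)),
                     subject_id = subject$subject_id, activity = "fall",
                     fall_type = fall_type, fs = fs)
  attr(trial, "impact_start") <- n_pre + 1L
  attr(trial, "impact_end") <- n_pre + n_dip + n_spike
  trial
}

#' Protocol configuration for the synthetic dataset
#'
#' Defaults mirror the study protocol: 20 subjects, 2 minutes of each of
#' the 8 ADLs (segmented into 20 windowable trials per activity), and 5
#' trials of each of the 8 fall types per subject -- 3200 ADL trials,
#' 800 fall trials, and 320 ADL minutes in total.
#'
#' @param n_subjects Number of subjects.
#' @param adl_minutes Minutes of each ADL per subject.
#' @param trials_per_fall_type Fall trials per type per subject.
#' @param fall_types Character vector of fall types.
#' @param fs Sampling frequency in Hz.
#' @param seed Master seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(n_subjects = 20, adl_minutes = 2,
                            trials_per_fall_type = 5,
                            fall_types = insolefall::fall_types(),
                            fs = 20, seed = 1) {
  stopifnot(n_subjects >= 1, adl_minutes > 0, trials_per_fall_type >= 1)
  structure(list(n_subjects = n_subjects, adl_minutes = adl_minutes,
                 trials_per_fall_type = trials_per_fall_type,
                 fall_types = fall_types, fs = fs, seed = seed),
            class = "protocol_config")
}

# segment a long ADL stream into trials of 121 samples at stride 120, so
# each trial spans exactly 6 s and adjacent trials share one endpoint
# sample. The filtered Sum Vector Magnitude is computed on the continuous
# stream before cutting, so trial windows keep their true stream context
# instead of a filter boundary transient.
segment_stream <- function(stream, len = window_length(),
                           spec = filter_spec()) {
  stream <- add_svm_signals(stream, spec)
  n <- nrow(stream)
  stride <- len - 1L
  n_trials <- (n - 1L) %/% stride
  fs <- trial_fs(stream)
  purrr::map(seq_len(n_trials), function(i) {
    idx <- ((i - 1L) * stride + 1L):((i - 1L) * stride + len)
    seg <- tibble::as_tibble(stream)[idx, ]
    seg$t <- (seq_len(len) - 1) / fs
    trial <- new_trial(seg, subject_id = trial_subject(stream),
                       activity = trial_activity(stream), fs = fs,
                       validate = FALSE)
    trial$svm <- seg$svm
    trial$fsvm <- seg$fsvm
    trial
  })
}

#' Generate the full synthetic protocol dataset
#'
#' Runs the whole study protocol: for each subject, one `adl_minutes`-long
#' stream of every ADL, segmented into 121-sample trials spanning 6 s each
#' (adjacent trials share one endpoint sample, so a 2-min stream yields
#' exactly 20 trials), plus `trials_per_fall_type` falls of each type. The
#' result is bit-identical for a fixed configuration.
#'
#' @param config A [protocol_config()].
#' @return A nested tibble with columns `trial_id, subject_id, activity,
#'   fall_type, data` (one `insole_trial` per row).
#' @export
generate_protocol_dataset <- function(config = protocol_config()) {
  adls <- setdiff(activity_levels(), "fall")
  stream_dur <- config$adl_minutes * 60 + 1 / config$fs  # inclusive endpoint
  rows <- purrr::map(seq_len(config$n_subjects), function(si) {
    sid <- sprintf("S%02d", si)
    subj <- subject_params(sid, seed = derive_seed(config$seed, si))
    adl_rows <- purrr::imap(adls, function(act, ai) {
      stream <- generate_adl_stream(
        act, stream_dur, subj,
        seed = derive_seed(config$seed, si, ai), fs = config$fs)
      trials <- segment_stream(stream)
      tibble::tibble(
        trial_id = sprintf("%s_%s_T%02d", sid, act, seq_along(trials)),
        subject_id = sid, activity = act, fall_type = NA_character_,
        data = trials)
    })
    fall_rows <- purrr::imap(config$fall_types, function(ft, fi) {
      trials <- purrr::map(seq_len(config$trials_per_fall_type), function(ri) {
        generate_fall_trial(ft, subj,
                            seed = derive_seed(config$seed, si, 50 + fi, ri),
                            fs = config$fs)
      })
      tibble::tibble(
        trial_id = sprintf("%s_%s_T%02d", sid, ft, seq_along(trials)),
        subject_id = sid, activity = "fall", fall_type = ft,
        data = trials)
    })
    dplyr::bind_rows(adl_rows, fall_rows)
  })
  dplyr::bind_rows(rows)
}

#' Append pure-noise feature columns to a feature table
#'
#' Adds `k` standard-normal columns (`noise_01` ...) with no class signal,
#' used to test whether wrapper feature selection can tell informative
#' features from noise.
#'
#' @param features A feature table (as from [featurize_trials()]).
#' @param k Number of noise columns.
#' @param seed Integer seed; identical seeds give identical columns.
#' @param subject_sd Standard deviation of an optional per-subject offset
#'   added to each noise column (default 0 = i.i.d. noise).
#' @param subject_scale_log_sd Log-scale standard deviation of an optional
#'   per-subject, per-column multiplier on the noise magnitude (default 0 =
#'   homoscedastic). A positive value emulates unreliable sensor channels
#'   that are quiet for most subjects but wild for some: still free of any
#'   class signal, but ruinous to a classifier that relies on them when the
#'   wild subject is the held-out fold -- the kind of channel wrapper
#'   selection should discard.
#' @return The feature table with `k` extra columns.
#' @export
plant_noise_features <- function(features, k, seed = 1, subject_sd = 0,
                                 subject_scale_log_sd = 0) {
  stopifnot(k >= 0)
  if (k == 0) return(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 777))
  noise <- matrix(rnorm(nrow(features) * k), ncol = k,
                  dimnames = list(NULL, sprintf("noise_%02d", seq_len(k))))
  subjects <- unique(features$subject_id)
  si <- match(features$subject_id, subjects)
  if (subject_scale_log_sd > 0) {
    scales <- matrix(exp(rnorm(length(subjects) * k, 0,
                               subject_scale_log_sd)), ncol = k)
    noise <- noise * scales[si, , drop = FALSE]
  }
  if (subject_sd > 0) {
    offsets <- matrix(rnorm(length(subjects) * k, 0, subject_sd), ncol = k)
    noise <- noise + offsets[si, , drop = FALSE]
  }
  dplyr::bind_cols(features, tibble::as_tibble(noise))
}

#' Simulate a modal-fall feature matrix for selection validation
#'
#' Generates a two-class (walk vs fall) feature table in the regime wrapper
#' feature selection is designed for. Falls are heterogeneous: every fall
#' row belongs to one of `n_informative` fall modes, and informative
#' feature `j` carries a strong mean shift (`effect`, in within-class
#' standard deviations) only for falls of mode `j` -- the way the real
#' registry works, where distinct features capture the free-fall dip, the
#' post-fall stillness, or the unloaded insole. Dropping any informative
#' feature therefore hides one fall mode from the classifier, while
#' per-subject offsets supply the heterogeneity grouped CV must generalize
#' over. Pair with [plant_noise_features()] to test whether [ga_select()]
#' recovers the informative columns.
#'
#' @param n_subjects Number of subjects.
#' @param windows_per_subject Feature rows per subject.
#' @param n_informative Number of informative feature columns
#'   (`inf_01` ...), one per fall mode.
#' @param effect Mean shift of a mode'"'"'s falls on its feature, in sd units.
#' @param subject_sd Standard deviation of per-subject feature offsets.
#' @param fall_fraction Fraction of rows labelled `fall`.
#' @param seed Integer seed.
#' @return A feature table with the usual metadata columns and
#'   `n_informative` feature columns.
#' @export
simulate_feature_task <- function(n_subjects = 8, windows_per_subject = 40,
                                  n_informative = 18, effect = 8,
                                  subject_sd = 0.4, fall_fraction = 1 / 2,
                                  seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 999))
  n_fall <- round(fall_fraction * windows_per_subject)
  rows <- purrr::map(seq_len(n_subjects), function(si) {
    labels <- c(rep("walk", windows_per_subject - n_fall),
                rep("fall", n_fall))
    # spread this subject'"'"'s falls across the fall modes
    mode <- rep(0L, windows_per_subject)
    mode[labels == "fall"] <- 1L +
      (sample(rep_len(seq_len(n_informative), n_fall)) - 1L +
         (si - 1L)) %% n_informative
    offsets <- rnorm(n_informative, 0, subject_sd)
    vals <- vapply(seq_len(n_informative), function(j) {
      offsets[j] + effect * (mode == j) + rnorm(windows_per_subject)
    }, numeric(windows_per_subject))
    colnames(vals) <- sprintf("inf_%02d", seq_len(n_informative))
    dplyr::bind_cols(
      tibble::tibble(
        trial_id = sprintf("S%02d_T%02d", si, seq_len(windows_per_subject)),
        subject_id = sprintf("S%02d", si),
        activity = labels, fall_type = NA_character_),
      tibble::as_tibble(vals))
  })
  dplyr::bind_rows(rows)
}
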