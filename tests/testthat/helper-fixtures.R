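# Shared fixtures, built lazily and memoized so expensive synthetic
# datasets are generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# the full study-scale protocol dataset and its feature table
default_dataset <- function() {
  memoize("default_dataset", function() {
    generate_protocol_dataset(protocol_config(seed = 1))
  })
}

default_features <- function() {
  memoize("default_features", function() featurize_trials(default_dataset()))
}

# a small dataset for classifier mechanics (fast to LOSO repeatedly)
small_dataset <- function() {
  memoize("small_dataset", function() {
    generate_protocol_dataset(
      protocol_config(n_subjects = 4, adl_minutes = 0.35,
                      trials_per_fall_type = 1, seed = 7))
  })
}

small_features <- function() {
  memoize("small_features", function() featurize_trials(small_dataset()))
}

# build a window directly from signal vectors (121 samples unless stated),
# bypassing trial plumbing, for feature-formula tests
manual_window <- function(ax, ay, az,
                          fsr1 = rep(0L, length(ax)),
                          fsr2 = fsr1, fsr3 = fsr1, fsr4 = fsr1,
                          svm = sum_vector_magnitude(ax, ay, az),
                          fsvm = svm, fs = 20) {
  w <- tibble::tibble(t = (seq_along(ax) - 1) / fs,
                      ax = ax, ay = ay, az = az,
                      fsr1 = as.integer(fsr1), fsr2 = as.integer(fsr2),
                      fsr3 = as.integer(fsr3), fsr4 = as.integer(fsr4),
                      svm = svm, fsvm = fsvm)
  attr(w, "fs") <- fs
  class(w) <- c("insole_window", class(w))
  w
}

# a reproducible pseudo-random window with varied channels; fsvm is the
# filtered magnitude, as in the real pipeline
random_window <- function(seed = 1) {
  withr::with_seed(seed, {
    n <- 121
    ax <- rnorm(n, 0, 0.3); ay <- rnorm(n, 0.1, 0.4); az <- rnorm(n, 1, 0.5)
    svm <- sum_vector_magnitude(ax, ay, az)
    manual_window(ax = ax, ay = ay, az = az,
                  fsr1 = sample(0:4095, n, replace = TRUE),
                  fsr2 = sample(0:300, n, replace = TRUE),
                  fsr3 = sample(0:4095, n, replace = TRUE),
                  fsr4 = rep(1500L, n),
                  svm = svm, fsvm = lowpass_filter(svm))
  })
}

# a uniformly random 3x3 rotation matrix (QR of a Gaussian matrix)
random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    qr_dec <- qr(matrix(rnorm(9), 3))
    q <- qr.Q(qr_dec)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

rotate_window <- function(w, rot) {
  acc <- as.matrix(w[, c("ax", "ay", "az")]) %*% t(rot)
  w2 <- w
  w2$ax <- acc[, 1]; w2$ay <- acc[, 2]; w2$az <- acc[, 3]
  w2$svm <- sum_vector_magnitude(w2$ax, w2$ay, w2$az)
  w2$fsvm <- lowpass_filter(w2$svm)
  w2
}
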