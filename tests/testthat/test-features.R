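test_that("the registry enumerates exactly 45 named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 45)
  expect_equal(reg$index, 1:45)
  expect_false(any(duplicated(reg$name)))
  expect_equal(reg$name[3], "mean_Z")
  expect_equal(reg$name[28], "fSVM_dip_pct")
  expect_equal(reg$name[42], "mean_FSR1_final2s")
})

test_that("moments of constant and symmetric signals follow conventions", {
  n <- 121
  w <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n))
  m <- axis_moment_features(w)
  expect_equal(unname(m["mean_Z"]), 1)
  expect_equal(unname(m["variance_Z"]), 0)
  expect_equal(unname(m["skewness_Z"]), 0)
  expect_equal(unname(m["kurtosis_Z"]), 0)

  # symmetric two-point signal has zero skewness (even sample count)
  w2 <- manual_window(ax = rep(0, 120), ay = rep(0, 120),
                      az = rep(c(0.9, 1.1), 60))
  expect_equal(unname(axis_moment_features(w2)["skewness_Z"]), 0)
})

test_that("moment features match a direct-summation oracle", {
  w <- random_window(3)
  m <- axis_moment_features(w)
  oracle <- function(x) {
    n <- length(x)
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    c(mu, sum((x - mu)^2) / (n - 1),
      (sum((x - mu)^3) / n) / m2^1.5,
      (sum((x - mu)^4) / n) / m2^2 - 3)
  }
  for (ch in list(c("X", "ax"), c("Y", "ay"), c("Z", "az"))) {
    ref <- oracle(w[[ch[2]]])
    got <- unname(m[paste0(c("mean_", "variance_", "skewness_",
                             "kurtosis_"), ch[1])])
    expect_lt(max(abs(got - ref)), 1e-9)
  }
  ref_tot <- oracle(w$svm)
  got_tot <- unname(m[c("mean_Total", "variance_Total", "skewness_Total",
                        "kurtosis_Total")])
  expect_lt(max(abs(got_tot - ref_tot)), 1e-9)
})

test_that("spectral energy matches Parseval identities", {
  n <- 121
  const <- manual_window(ax = rep(0.5, n), ay = rep(0, n), az = rep(1, n))
  expect_equal(unname(energy_features(const)), rep(0, 4), tolerance = 1e-12)

  # sinusoid with integer periods in the window: energy = A^2 / 2
  n2 <- 120
  a <- 0.7
  x <- a * sin(2 * pi * 6 * (0:(n2 - 1)) / n2)
  w <- manual_window(ax = x, ay = rep(0, n2), az = rep(1, n2))
  expect_lt(abs(unname(energy_features(w)["energy_X"]) - a^2 / 2), 1e-9)

  # any signal: energy equals mean squared deviation = var * (n-1)/n
  wr <- random_window(9)
  e <- energy_features(wr)
  for (ch in list(c("energy_X", "ax"), c("energy_Y", "ay"),
                  c("energy_Z", "az"), c("energy_Total", "svm"))) {
    x <- wr[[ch[2]]]
    expect_lt(abs(unname(e[ch[1]]) - var(x) * (length(x) - 1) / length(x)),
              1e-9)
  }
})

test_that("axis correlations handle exact and degenerate dependence", {
  n <- 121
  x <- seq(-1, 1, length.out = n)
  w <- manual_window(ax = x, ay = 2 * x + 1, az = rep(1, n))
  co <- axis_correlation_features(w)
  expect_equal(unname(co["correlationX_Y"]), 1)
  expect_equal(unname(co["correlationX_Z"]), 0)  # constant z-axis
  expect_equal(unname(co["correlationY_Z"]), 0)

  wr <- random_window(5)
  got <- axis_correlation_features(wr)
  oracle <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_lt(abs(unname(got["correlationX_Y"]) - oracle(wr$ax, wr$ay)), 1e-9)
  expect_lt(abs(unname(got["correlationY_Z"]) - oracle(wr$ay, wr$az)), 1e-9)
})

test_that("magnitude extrema features are ordered and fall windows dip", {
  n <- 121
  w <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n))
  expect_equal(unname(svm_extrema_features(w)), c(1, 1, 1, 1))

  wr <- random_window(7)
  ex <- svm_extrema_features(wr)
  expect_lte(ex["min_SVM"], ex["max_SVM"])
  expect_lte(ex["min_fSVM"], ex["max_fSVM"])

  fall_win <- extract_window(generate_fall_trial("back_stand_fall",
                                                 seed = 2))
  expect_lt(feature_vector(fall_win)$min_fSVM, 0.9)
})

test_that("dip fraction counts strict sub-threshold samples", {
  n <- 121
  base <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                        fsvm = rep(1, n))
  expect_equal(unname(dip_fraction_feature(base)), 0)
  all_low <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                           fsvm = rep(0.5, n))
  expect_equal(unname(dip_fraction_feature(all_low)), 100)
  some <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                        fsvm = c(rep(0.8, 24), rep(1, n - 24)))
  expect_equal(unname(dip_fraction_feature(some)), 100 * 24 / 121)
  # exactly at threshold does not count
  at <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                      fsvm = rep(0.9, n))
  expect_equal(unname(dip_fraction_feature(at)), 0)
})

test_that("tail variance matches the direct formula and separates classes", {
  n <- 121
  static <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                          fsvm = rep(1, n))
  expect_equal(unname(tail_variance_feature(static)), 0)

  alt <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                       fsvm = c(rep(1, 81), rep(c(0.9, 1.1), 20)))
  tail_vals <- rep(c(0.9, 1.1), 20)
  expect_lt(abs(unname(tail_variance_feature(alt)) -
                  sum((tail_vals - mean(tail_vals))^2) / 39), 1e-12)

  # falls end static; running keeps moving (Monte Carlo over seeds)
  fall_tails <- sapply(1:20, function(s) {
    feature_vector(extract_window(
      generate_fall_trial(fall_types()[(s %% 8) + 1], seed = s)
    ))$fSVM_tail_var
  })
  run_tails <- sapply(1:20, function(s) {
    feature_vector(extract_window(
      generate_adl_stream("run", 12.05, seed = s)))$fSVM_tail_var
  })
  expect_true(all(fall_tails < run_tails))
})

test_that("FSR features count on-time, switches and means", {
  n <- 121
  w <- manual_window(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                     fsr1 = rep(1500L, n), fsr2 = rep(0L, n),
                     fsr3 = rep(1500L, n), fsr4 = rep(50L, n))
  f <- fsr_features(w)
  expect_equal(unname(f["FSR1_on_pct"]), 100)
  expect_equal(unname(f["FSR2_on_pct"]), 0)
  expect_equal(unname(f["FSR1_switches"]), 0)
  expect_equal(unname(f["mean_FSR1"]), 1500)
  expect_equal(unname(f["mean_FSR1_final2s"]), 1500)
  expect_equal(unname(f["FSR4_on_pct"]), 0)  # 50 below threshold

  # on,on,off,on pattern -> 2 switches; brute-force oracle on random states
  states <- c(200L, 200L, 0L, 200L)
  w2 <- manual_window(ax = rep(0, 4), ay = rep(0, 4), az = rep(1, 4),
                      fsr1 = states)
  expect_equal(unname(fsr_features(w2)["FSR1_switches"]), 2)
  withr::with_seed(13, {
    for (i in 1:5) {
      v <- sample(c(0L, 2000L), 121, replace = TRUE)
      w3 <- manual_window(ax = rep(0, 121), ay = rep(0, 121),
                          az = rep(1, 121), fsr1 = v)
      brute <- sum(vapply(2:121, function(j) {
        (v[j] > 100) != (v[j - 1] > 100)
      }, logical(1)))
      got <- unname(fsr_features(w3)["FSR1_switches"])
      expect_equal(got, brute)
      expect_lte(got, 120)
    }
  })
})

test_that("walking windows switch the heel channel once per gait cycle edge", {
  subj <- subject_params("S01", 1)
  tr <- generate_adl_stream("walk", 12.05, subj, seed = 4)
  win <- extract_window(tr)
  switches <- feature_vector(win)$FSR1_switches
  profile <- activity_profiles()
  cadence <- profile$cadence[profile$activity == "walk"] *
    subj$cadence_scale
  cycles <- 6.05 * cadence / 2   # one stance per stride on one foot
  expect_gte(switches, 2 * cycles - 2)
  expect_lte(switches, 2 * cycles + 2)
})

test_that("the assembled feature vector is complete and compositional", {
  w <- random_window(21)
  fv <- feature_vector(w)
  expect_equal(ncol(fv), 45)
  expect_identical(names(fv), feature_registry()$name)
  expect_identical(fv, feature_vector(w))  # deterministic

  expect_equal(as.numeric(fv[1, 1:16]),
               unname(axis_moment_features(w)))
  expect_equal(as.numeric(fv[1, 17:20]), unname(energy_features(w)))
  expect_equal(as.numeric(fv[1, 21:23]),
               unname(axis_correlation_features(w)))
  expect_equal(as.numeric(fv[1, 24:27]), unname(svm_extrema_features(w)))
  expect_equal(fv$fSVM_dip_pct, unname(dip_fraction_feature(w)))
  expect_equal(fv$fSVM_tail_var, unname(tail_variance_feature(w)))
  expect_equal(as.numeric(fv[1, 30:45]), unname(fsr_features(w)))
})

test_that("axis rotation changes axis features but not magnitude features", {
  w <- random_window(31)
  rot <- random_rotation(99)
  fv <- feature_vector(w)
  fv_rot <- feature_vector(rotate_window(w, rot))
  magnitude_feats <- feature_registry()$name[24:29]
  for (nm in magnitude_feats) {
    expect_lt(abs(fv[[nm]] - fv_rot[[nm]]), 1e-9)
  }
  expect_gt(abs(fv$mean_Z - fv_rot$mean_Z), 1e-6)
})
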