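test_that("feature masks and rosters have the expected structure", {
  m <- optimal_feature_mask()
  expect_length(m, 45)
  expect_equal(sum(m), 18)
  expect_true(all(c("mean_Z", "min_fSVM", "fSVM_dip_pct",
                    "mean_FSR1_final2s") %in% names(which(m))))
  expect_false(any(c("energy_X", "min_SVM", "max_SVM") %in%
                     names(which(m))))
  roster <- feature_set_masks()
  expect_named(roster, c("imu", "imu_optimized", "fsr", "imu_fsr", "all",
                         "optimal"))
  expect_equal(sum(roster$imu), 26)
  expect_equal(sum(roster$fsr), 16)
  expect_equal(sum(roster$all), 45)
  expect_error(feature_mask("not_a_feature"), "unknown features")
})

test_that("min-max normalization fits on training data only", {
  train <- cbind(a = c(0, 10), b = c(5, 5))
  test <- cbind(a = c(5, 20), b = c(7, 5))
  out <- normalize_fit_transform(train, test)
  expect_equal(out$train[, "a"], c(0, 1))
  expect_equal(out$test[, "a"], c(0.5, 2))   # outside [0,1] permitted
  expect_equal(out$train[, "b"], c(0, 0))    # constant column maps to 0
  expect_equal(out$test[, "b"], c(0, 0))
  expect_error(normalize_fit_transform(train[0, ]), "empty")
})

test_that("the SVM separates a separable toy problem and validates input", {
  fx <- small_features()
  fit <- train_svm(fx, optimal_feature_mask())
  expect_equal(ncol(fit$norm$train), 18)
  pred <- predict(fit, fx)
  expect_gt(mean(as.character(pred) == fx$activity), 0.95)

  expect_error(train_svm(fx, feature_mask(integer(0))), "no features")
  one_class <- fx[fx$activity == "walk", ]
  expect_error(train_svm(one_class), "single class")
})

test_that("training is invariant to row order", {
  fx <- small_features()
  fit1 <- train_svm(fx, optimal_feature_mask())
  perm <- withr::with_seed(5, sample(nrow(fx)))
  fit2 <- train_svm(fx[perm, ], optimal_feature_mask())
  p1 <- as.character(predict(fit1, fx))
  p2 <- as.character(predict(fit2, fx))
  expect_identical(p1, p2)
})

test_that("LOSO folds never see the test subject and pool correctly", {
  fx <- small_features()
  cv <- leave_one_subject_out_cv(fx, optimal_feature_mask())
  expect_equal(cv$folds, 4)
  expect_equal(sum(cv$confusion), nrow(fx))
  # no leakage: each fold's training subjects exclude its test subject
  leak <- cv$predictions %>%
    dplyr::mutate(leaked = purrr::map2_lgl(subject_id, train_subjects,
                                           ~ .x %in% .y))
  expect_false(any(leak$leaked))
  # row totals equal per-class trial counts
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.integer(table(
                 factor(fx$activity, levels = activity_levels())))))
  expect_error(leave_one_subject_out_cv(fx[fx$subject_id == "S01", ]),
               ">= 2 subjects")
})

test_that("a duplicated subject's fold reduces to resubstitution", {
  fx <- small_features()
  # make S01 an exact feature copy of S02: testing S01 is then testing
  # data the model has literally seen via S02
  cols <- setdiff(names(fx), insolefall::feature_meta_columns())
  dup <- fx
  s1 <- which(dup$subject_id == "S01")
  s2 <- which(dup$subject_id == "S02")
  k <- min(length(s1), length(s2))
  dup[s1[1:k], cols] <- dup[s2[1:k], cols]
  dup$activity[s1[1:k]] <- dup$activity[s2[1:k]]
  cv <- leave_one_subject_out_cv(dup, optimal_feature_mask())
  fold_acc <- cv$predictions %>%
    dplyr::filter(subject_id == "S01") %>%
    dplyr::slice(1:k)
  fit_all <- train_svm(dup[-s1[1:k], ], optimal_feature_mask())
  resub <- as.character(predict(fit_all, dup[s1[1:k], ]))
  expect_identical(fold_acc$pred, resub)
})

test_that("trivially separable two-subject data yields zero fall errors", {
  fx <- small_features() %>% dplyr::filter(subject_id %in% c("S01", "S02"))
  cv <- leave_one_subject_out_cv(fx, optimal_feature_mask())
  expect_equal(cv$fall_fp, 0)
  expect_equal(cv$fall_fn, 0)
})

test_that("GA fitness rewards separation and penalizes the empty mask", {
  fx <- small_features()
  cols <- setdiff(names(fx), feature_meta_columns())
  expect_equal(ga_fitness(optimal_feature_mask(), fx), 0)
  empty <- feature_mask(integer(0), names = cols)
  expect_gte(ga_fitness(empty, fx), sum(fx$activity == "fall"))
})

test_that("reference mask fitness is no worse than all features", {
  fits <- sapply(1:5, function(s) {
    task <- simulate_feature_task(n_subjects = 6, windows_per_subject = 20,
                                  seed = s)
    aug <- plant_noise_features(task, 27, seed = s,
                                subject_scale_log_sd = 3)
    cols <- setdiff(names(aug), feature_meta_columns())
    c(info = ga_fitness(feature_mask(1:18, names = cols), aug,
                        inner_folds = 3),
      all = ga_fitness(feature_mask(seq_along(cols), names = cols), aug,
                       inner_folds = 3))
  })
  expect_gte(sum(fits["info", ] <= fits["all", ]), 4)
})

test_that("GA selection is deterministic, elitist and stall-limited", {
  task <- simulate_feature_task(n_subjects = 4, windows_per_subject = 16,
                                n_informative = 6, seed = 3)
  cfg <- ga_config(generations = 10, population_size = 8, stall_limit = 60,
                   inner_folds = 3, seed = 21)
  a <- ga_select(task, cfg)
  b <- ga_select(task, cfg)
  expect_identical(which(a$mask), which(b$mask))
  expect_true(all(diff(a$trace$best_fitness) <= 0))

  # constant fitness landscape: stall counter stops the run immediately
  flat <- task
  flat$activity <- rep(c("walk", "fall"), length.out = nrow(flat))
  flat[, grep("^inf_", names(flat))] <- 0
  res <- ga_select(flat, ga_config(generations = 50, population_size = 6,
                                   stall_limit = 1, inner_folds = 2,
                                   seed = 2))
  expect_lte(res$generations_run, 2)
})

test_that("feature-set comparison reports one row per roster entry", {
  fx <- small_features()
  masks <- feature_set_masks()[c("optimal", "all")]
  comp <- feature_set_comparison(fx, masks)
  expect_equal(comp$feature_set, c("optimal", "all"))
  expect_equal(comp$n_features, c(18, 45))
  expect_true(all(comp$fall_fp >= 0))
  # on separable synthetic data the optimal mask is never dominated
  expect_true(comp$fall_fp[1] <= comp$fall_fp[2])
  expect_true(comp$fall_fn[1] <= comp$fall_fn[2])
})
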