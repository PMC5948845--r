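#' Feature masks
#'
#' A feature mask is the binary genome of wrapper selection: a named
#' logical vector over the feature columns, `TRUE` meaning the feature is
#' used by the classifier.
#'
#' @param indices Integer indices (or character names) of selected
#'   features.
#' @param names Feature names the mask is defined over; defaults to the
#'   45-feature registry.
#' @return A named logical vector of class `feature_mask`.
#' @export
#' @examples
#' sum(optimal_feature_mask())
feature_mask <- function(indices, names = feature_names()) {
  m <- rlang::set_names(rep(FALSE, length(names)), names)
  if (is.character(indices)) {
    bad <- setdiff(indices, names)
    if (length(bad) > 0) abort(paste0("unknown features: ",
                                      paste(bad, collapse = ", ")))
    m[indices] <- TRUE
  } else {
    stopifnot(all(indices >= 1), all(indices <= length(names)))
    m[as.integer(indices)] <- TRUE
  }
  structure(m, class = c("feature_mask", "logical"))
}

#' The reference optimal 18-feature mask
#'
#' The published optimum of the genetic-algorithm wrapper for this task:
#' 14 accelerometer-derived features (mean_Z; variance of X, Z and total;
#' skewness of X, Z and total; kurtosis of X and total; the X-Z
#' correlation; filtered-magnitude min, max, sub-0.9 dip percent and tail
#' variance) plus 4 FSR features (FSR4 on-duration, FSR3 switch count,
#' FSR3 window mean, FSR1 final-2-s mean).
#'
#' @return A `feature_mask` selecting 18 of the 45 registry features.
#' @export
optimal_feature_mask <- function() {
  feature_mask(c(3, 5, 7, 8, 9, 11, 12, 13, 16, 22,
                 26, 27, 28, 29, 33, 36, 40, 42))
}

#' Named roster of benchmark feature sets
#'
#' The feature combinations compared in the study: accelerometer-only
#' (1-25 plus 29), a reduced accelerometer subset, FSR-only (30-45),
#' accelerometer plus FSR, all 45, and the 18-feature optimum.
#'
#' @return A named list of `feature_mask` objects.
#' @export
feature_set_masks <- function() {
  list(
    imu = feature_mask(c(1:25, 29)),
    imu_optimized = feature_mask(c(3, 7, 8, 9, 12, 16, 21, 22, 24)),
    fsr = feature_mask(30:45),
    imu_fsr = feature_mask(c(1:25, 29:45)),
    all = feature_mask(1:45),
    optimal = optimal_feature_mask()
  )
}

#' Classifier configuration
#'
#' A polynomial-kernel support vector machine (libsvm via e1071) with
#' one-vs-one multiclass decomposition. Features are min-max normalized to
#' \[0, 1\] with parameters fit on the training fold only. Kernel
#' `(gamma * <u, v> + coef0)^degree` with degree 3, gamma 1, coef0 1 and
#' cost 1 by default.
#'
#' @param degree Polynomial degree (>= 1).
#' @param cost Regularization weight (> 0).
#' @param gamma,coef0 Kernel scale and offset.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(degree = 3, cost = 1, gamma = 1, coef0 = 1) {
  stopifnot(degree >= 1, cost > 0)
  structure(list(degree = degree, cost = cost, gamma = gamma, coef0 = coef0),
            class = "svm_config")
}

#' Min-max normalization fit on training data only
#'
#' Each feature is affinely mapped so the training column spans \[0, 1\];
#' the same map is applied to the test matrix (test values may fall outside
#' \[0, 1\]; no clipping). Constant training columns map to 0 everywhere.
#'
#' @param train Numeric matrix or data frame of training features.
#' @param test Optional matrix with the same columns.
#' @return A list with elements `train`, `test` (or `NULL`), `min`,
#'   `range`.
#' @export
normalize_fit_transform <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0) abort("empty training matrix")
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) abort("column count mismatch")
  }
  mins <- apply(train, 2, min)
  ranges <- apply(train, 2, max) - mins
  scale_mat <- function(m) {
    out <- sweep(m, 2, mins, "-")
    out <- sweep(out, 2, ifelse(ranges == 0, 1, ranges), "/")
    out[, ranges == 0] <- 0
    out
  }
  list(train = scale_mat(train),
       test = if (!is.null(test)) scale_mat(test),
       min = mins, range = ranges)
}

activity_factor <- function(labels) {
  bad <- setdiff(unique(labels), activity_levels())
  if (length(bad) > 0) abort(paste0("unknown class labels: ",
                                    paste(bad, collapse = ", ")))
  factor(labels, levels = activity_levels())
}

#' Train the multiclass fall-detection SVM
#'
#' Fits the polynomial-kernel one-vs-one SVM on the masked, normalized
#' feature matrix. Normalization parameters are stored in the returned
#' model so prediction applies the same map.
#'
#' @param features A feature table (metadata columns plus feature columns).
#' @param mask A `feature_mask` over the table's feature columns; `NULL`
#'   uses all features.
#' @param config An [svm_config()].
#' @return A list of class `fall_svm` with elements `model`, `mask`,
#'   `norm`, `config`.
#' @export
train_svm <- function(features, mask = NULL, config = svm_config()) {
  cols <- feature_data_columns(features)
  if (is.null(mask)) mask <- feature_mask(cols, names = cols)
  if (!identical(names(mask), cols)) {
    abort("mask is not defined over the table's feature columns")
  }
  if (sum(mask) == 0) abort("mask selects no features")
  y <- activity_factor(features$activity)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  x <- as.matrix(features[cols])[, mask, drop = FALSE]
  norm <- normalize_fit_transform(x)
  fit <- e1071::svm(x = norm$train, y = y, kernel = "polynomial",
                    degree = config$degree, gamma = config$gamma,
                    coef0 = config$coef0, cost = config$cost,
                    scale = FALSE)
  structure(list(model = fit, mask = mask, norm = norm, config = config),
            class = "fall_svm")
}

#' @export
predict.fall_svm <- function(object, newdata, ...) {
  cols <- names(object$mask)
  x <- as.matrix(newdata[cols])[, object$mask, drop = FALSE]
  xs <- sweep(x, 2, object$norm$min, "-")
  xs <- sweep(xs, 2, ifelse(object$norm$range == 0, 1, object$norm$range),
              "/")
  xs[, object$norm$range == 0] <- 0
  predict(object$model, xs)
}

count_fall_errors <- function(truth, pred) {
  list(fp = sum(truth != "fall" & pred == "fall"),
       fn = sum(truth == "fall" & pred != "fall"))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the model is trained on all other subjects and
#' tested on the held-out subject, so no information from the test subject
#' (including its normalization statistics) reaches training. Fold
#' predictions are pooled into a 9x9 confusion matrix, and fall false
#' positives / false negatives are counted with fall as the positive
#' class.
#'
#' @param features A feature table with >= 2 subjects.
#' @param mask A `feature_mask` (default all features).
#' @param config An [svm_config()].
#' @return A list of class `fall_cv`: `predictions` (tibble with
#'   `subject_id`, `trial_id`, `truth`, `pred`, `fold`), `confusion`,
#'   `fall_fp`, `fall_fn`, `folds`.
#' @export
leave_one_subject_out_cv <- function(features, mask = NULL,
                                     config = svm_config()) {
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 2) abort("need >= 2 subjects for LOSO-CV")
  preds <- purrr::imap(subjects, function(sid, fold) {
    test_rows <- features$subject_id == sid
    if (!any(test_rows)) return(NULL)
    fit <- train_svm(features[!test_rows, ], mask, config)
    tibble::tibble(subject_id = sid,
                   trial_id = features$trial_id[test_rows],
                   truth = features$activity[test_rows],
                   pred = as.character(predict(fit, features[test_rows, ])),
                   fold = fold,
                   train_subjects = list(
                     sort(unique(features$subject_id[!test_rows]))))
  })
  predictions <- dplyr::bind_rows(preds)
  cm <- build_confusion(predictions$truth, predictions$pred)
  err <- count_fall_errors(predictions$truth, predictions$pred)
  structure(list(predictions = predictions, confusion = cm,
                 fall_fp = err$fp, fall_fn = err$fn,
                 folds = length(subjects)),
            class = "fall_cv")
}

#' @export
print.fall_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Leave-one-subject-out CV: %d folds, %d windows\n", x$folds, g$n))
  cat(sprintf(
    "fall sensitivity %.3f, specificity %.3f, accuracy %.3f (FP %d, FN %d)\n",
    g$fall_sensitivity, g$fall_specificity, g$fall_accuracy,
    x$fall_fp, x$fall_fn))
  invisible(x)
}

# deterministic round-robin assignment of subjects to inner CV folds
subject_folds <- function(subjects, k) {
  subjects <- sort(unique(subjects))
  k <- min(k, length(subjects))
  rlang::set_names(rep_len(seq_len(k), length(subjects)), subjects)
}

#' Wrapper-selection fitness of a feature mask
#'
#' The quantity the genetic algorithm minimizes: fall false positives plus
#' fall false negatives from subject-grouped k-fold cross-validation (folds
#' never split a subject, so the fitness respects subject independence). A
#' mask selecting no features receives the dataset size as penalty.
#'
#' @param mask A `feature_mask` over the table's feature columns.
#' @param features A feature table (training subjects only; the outer test
#'   subject must already be excluded).
#' @param config An [svm_config()].
#' @param inner_folds Number of subject-grouped folds (default 5).
#' @return Non-negative integer fitness (lower is better).
#' @export
ga_fitness <- function(mask, features, config = svm_config(),
                       inner_folds = 5) {
  if (sum(mask) == 0) return(nrow(features))
  fold_of <- subject_folds(features$subject_id, inner_folds)
  total <- 0
  for (f in sort(unique(fold_of))) {
    test_rows <- fold_of[features$subject_id] == f
    fit <- train_svm(features[!test_rows, ], mask, config)
    pred <- predict(fit, features[test_rows, ])
    err <- count_fall_errors(features$activity[test_rows],
                             as.character(pred))
    total <- total + err$fp + err$fn
  }
  total
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study's stated settings (1000 generations, 60-stall
#' generation limit, 0.8 crossover fraction, 0.01 mutation rate) with the
#' common companion defaults for what the study leaves unstated: population
#' 50, elite count 2, stochastic-universal-sampling parent selection on
#' rank-scaled fitness, uniform (scattered) crossover, per-gene bit-flip
#' mutation.
#'
#' @param generations Maximum generations.
#' @param stall_limit Stop after this many generations without best-fitness
#'   improvement.
#' @param crossover_fraction Fraction of non-elite offspring produced by
#'   crossover (the remainder are mutation-only children).
#' @param mutation_rate Per-gene bit-flip probability.
#' @param population_size Individuals per generation.
#' @param elite_count Best individuals copied unchanged (>= 1 guarantees a
#'   non-increasing best-fitness trace).
#' @param inner_folds Subject-grouped folds used by [ga_fitness()].
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(generations = 1000, stall_limit = 60,
                      crossover_fraction = 0.8, mutation_rate = 0.01,
                      population_size = 50, elite_count = 2,
                      inner_folds = 5, seed = 1) {
  stopifnot(crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, population_size >= 2, elite_count >= 1)
  structure(list(generations = generations, stall_limit = stall_limit,
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 population_size = population_size,
                 elite_count = elite_count, inner_folds = inner_folds,
                 seed = seed),
            class = "ga_config")
}

# stochastic universal sampling over rank-scaled fitness (minimization)
sus_select <- function(fitness, n) {
  ranks <- rank(fitness, ties.method = "first")
  w <- 1 / sqrt(ranks)
  w <- w / sum(w)
  edges <- cumsum(w)
  pointers <- (runif(1) / n) + (seq_len(n) - 1) / n
  findInterval(pointers, edges) + 1L
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary feature masks to minimize [ga_fitness()] (fall false
#' positives plus false negatives under subject-grouped cross-validation).
#' Elitism keeps the best masks unchanged, so the best-so-far fitness trace
#' is non-increasing; the run stops at the generation limit or after
#' `stall_limit` generations without improvement. Fitness values are cached
#' per mask, so converged populations cost little.
#'
#' @param features A feature table of the training subjects.
#' @param config A [ga_config()].
#' @param svm A [svm_config()].
#' @return A list of class `ga_result`: `mask` (best `feature_mask`),
#'   `fitness`, `trace` (tibble with per-generation best/mean fitness),
#'   `evaluations` (number of distinct masks evaluated).
#' @export
ga_select <- function(features, config = ga_config(), svm = svm_config()) {
  cols <- feature_data_columns(features)
  g <- length(cols)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% .Machine$integer.max)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(genome) {
    key <- paste(as.integer(genome), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- ga_fitness(feature_mask(which(genome), names = cols), features,
                      svm, config$inner_folds)
    cache[[key]] <- val
    val
  }

  pop <- lapply(seq_len(config$population_size), function(i) {
    genome <- runif(g) < 0.5
    if (!any(genome)) genome[sample.int(g, 1)] <- TRUE
    genome
  })
  fitness <- vapply(pop, evaluate, 0)
  best_fit <- min(fitness)
  best_genome <- pop[[which.min(fitness)]]
  trace <- list(tibble::tibble(generation = 0L, best_fitness = best_fit,
                               mean_fitness = mean(fitness)))
  stall <- 0L
  gen <- 0L
  while (gen < config$generations && stall < config$stall_limit) {
    gen <- gen + 1L
    ord <- order(fitness)
    elites <- pop[ord[seq_len(config$elite_count)]]
    n_rest <- config$population_size - config$elite_count
    n_cross <- round(config$crossover_fraction * n_rest)
    parents <- sus_select(fitness, 2 * n_cross + (n_rest - n_cross))
    children <- vector("list", n_rest)
    pi <- 1L
    for (i in seq_len(n_cross)) {
      p1 <- pop[[parents[pi]]]; p2 <- pop[[parents[pi + 1L]]]
      pi <- pi + 2L
      pick <- runif(g) < 0.5
      children[[i]] <- ifelse(pick, p1, p2)
    }
    for (i in seq_len(n_rest - n_cross)) {
      children[[n_cross + i]] <- pop[[parents[pi]]]
      pi <- pi + 1L
    }
    # canonical order: crossover first, then bit-flip mutation on every
    # non-elite child
    children <- lapply(children, function(child) {
      xor(child, runif(g) < config$mutation_rate)
    })
    pop <- c(elites, children)
    fitness <- vapply(pop, evaluate, 0)
    if (min(fitness) < best_fit) {
      best_fit <- min(fitness)
      best_genome <- pop[[which.min(fitness)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace[[length(trace) + 1L]] <-
      tibble::tibble(generation = gen, best_fitness = best_fit,
                     mean_fitness = mean(fitness))
  }
  structure(list(mask = feature_mask(which(best_genome), names = cols),
                 fitness = best_fit,
                 trace = dplyr::bind_rows(trace),
                 evaluations = length(ls(cache)),
                 generations_run = gen),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "GA wrapper selection: %d generations, best fitness %d, %d features\n",
    x$generations_run, x$fitness, sum(x$mask)))
  invisible(x)
}

#' Compare benchmark feature sets under LOSO-CV
#'
#' Runs [leave_one_subject_out_cv()] for each mask in a roster and tabulates
#' fall false positives and false negatives.
#'
#' @param features A feature table.
#' @param masks Named list of `feature_mask` objects (default
#'   [feature_set_masks()]).
#' @param config An [svm_config()].
#' @return A tibble with columns `feature_set`, `n_features`, `fall_fp`,
#'   `fall_fn`, and a list column `cv` holding each `fall_cv`.
#' @export
feature_set_comparison <- function(features, masks = feature_set_masks(),
                                   config = svm_config()) {
  rows <- purrr::imap(masks, function(m, nm) {
    cv <- leave_one_subject_out_cv(features, m, config)
    tibble::tibble(feature_set = nm, n_features = sum(m),
                   fall_fp = cv$fall_fp, fall_fn = cv$fall_fn,
                   cv = list(cv))
  })
  dplyr::bind_rows(rows)
}
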