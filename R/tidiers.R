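#' Tidy a confusion matrix into long form
#'
#' @param x A `fall_confusion`.
#' @param ... Unused.
#' @return A tibble with columns `truth`, `pred`, `n`.
#' @method tidy fall_confusion
#' @export
tidy.fall_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x),
                                        responseName = "n")) %>%
    mutate(truth = as.character(.data$truth),
           pred = as.character(.data$pred))
}

#' Per-class metrics of a cross-validation result
#'
#' @param x A `fall_cv`.
#' @param ... Unused.
#' @return The [class_metrics()] tibble of the pooled confusion matrix.
#' @method tidy fall_cv
#' @export
tidy.fall_cv <- function(x, ...) class_metrics(x$confusion)

#' One-row summary of a cross-validation result
#'
#' @param x A `fall_cv`.
#' @param ... Unused.
#' @return A tibble with the fall-class sensitivity, specificity and
#'   accuracy, the fall FP/FN counts, fold count and window count.
#' @method glance fall_cv
#' @export
glance.fall_cv <- function(x, ...) {
  m <- class_metrics(x$confusion)
  fall <- m[m$class == "fall", ]
  tibble::tibble(fall_sensitivity = fall$sensitivity,
                 fall_specificity = fall$specificity,
                 fall_accuracy = fall$accuracy,
                 fall_fp = x$fall_fp, fall_fn = x$fall_fn,
                 folds = x$folds, n = sum(x$confusion))
}

#' Fitness trace of a genetic-algorithm run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return The per-generation trace tibble.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$trace

#' One-row summary of a genetic-algorithm run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble with best fitness, number of selected features,
#'   generations run and distinct masks evaluated.
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$fitness, n_selected = sum(x$mask),
                 generations = x$generations_run,
                 evaluations = x$evaluations)
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `fall_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fall_confusion
#' @export
autoplot.fall_confusion <- function(object, ...) {
  dat <- tidy.fall_confusion(object) %>%
    mutate(truth = factor(.data$truth, levels = rev(activity_levels())),
           pred = factor(.data$pred, levels = activity_levels()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pred, y = .data$truth,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "true", fill = "windows") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot.fall_confusion
#' @method autoplot fall_cv
#' @export
autoplot.fall_cv <- function(object, ...) autoplot(object$confusion, ...)

#' Plot a genetic-algorithm fitness trace
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per generation.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$trace, -"generation",
                             names_to = "series", values_to = "fitness")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation,
                                    y = .data$fitness,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fall FP + FN") +
    ggplot2::theme_minimal()
}

#' Bar plot of the per-activity dip-fraction summary
#'
#' @param summary Output of [dip_fraction_summary()].
#' @return A ggplot.
#' @export
plot_dip_summary <- function(summary) {
  dat <- mutate(summary,
                activity = factor(.data$activity,
                                  levels = summary$activity))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$activity,
                                    y = .data$mean_dip_pct)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_dip_pct - .data$sd_dip_pct, 0),
      ymax = .data$mean_dip_pct + .data$sd_dip_pct), width = 0.3) +
    ggplot2::labs(x = NULL,
                  y = "% of window with filtered magnitude < 0.9 g") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
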