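#' Build a 9x9 confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the canonical
#' [activity_levels()] order.
#'
#' @param truth,pred Equal-length label vectors from the 9-class
#'   vocabulary.
#' @return An integer matrix of class `fall_confusion`.
#' @export
build_confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("label vectors differ in length")
  cm <- table(truth = activity_factor(truth), pred = activity_factor(pred))
  cm <- matrix(as.integer(cm), nrow = 9,
               dimnames = list(truth = activity_levels(),
                               pred = activity_levels()))
  structure(cm, class = c("fall_confusion", class(cm)))
}

new_confusion <- function(counts) {
  counts <- matrix(as.integer(counts), nrow = 9,
                   dimnames = list(truth = activity_levels(),
                                   pred = activity_levels()))
  structure(counts, class = c("fall_confusion", class(counts)))
}

#' Reference confusion matrix fixture
#'
#' The pooled leave-one-subject-out confusion matrix reported for this
#' task by the insole-sensor study the package models (20 subjects, 400
#' windows per ADL, 800 falls; 797 falls detected with zero false alarms).
#' Shipped so the metric computations can be verified against published
#' per-class values.
#'
#' @return A `fall_confusion` matrix.
#' @export
reference_confusion <- function() {
  counts <- rbind(
    walk             = c(382,   1,   0,   0,  14,   1,   2,   0,   0),
    stand            = c(  3, 369,   1,  27,   0,   0,   0,   0,   0),
    lie              = c(  0,   3, 397,   0,   0,   0,   0,   0,   0),
    sit              = c(  2,  53,   0, 343,   0,   0,   2,   0,   0),
    run              = c( 38,   0,   0,   0, 362,   0,   0,   0,   0),
    stair_ascension  = c(  2,   0,   0,   0,   1, 349,  48,   0,   0),
    stair_descension = c(  0,   0,   0,   0,   2,  56, 340,   2,   0),
    jump             = c(  0,   0,   8,   0,   0,   6,  11, 375,   0),
    fall             = c(  0,   0,   0,   0,   0,   2,   0,   1, 797)
  )
  new_confusion(counts)
}

#' Per-class sensitivity, specificity and accuracy
#'
#' One-vs-rest metrics per class: sensitivity TP/(TP+FN) over the class
#' row, specificity TN/(TN+FP) over the rest, accuracy (TP+TN)/total.
#' Classes with no trials get `NA` where the denominator vanishes.
#'
#' @param cm A `fall_confusion` matrix.
#' @return A tibble with one row per class: `class`, `total`, `tp`, `fn`,
#'   `fp`, `tn`, `sensitivity`, `specificity`, `accuracy`.
#' @export
class_metrics <- function(cm) {
  grand <- sum(cm)
  if (grand == 0) abort("empty confusion matrix")
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  rows <- purrr::map(activity_levels(), function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- grand - tp - fn - fp
    tibble::tibble(class = cl, total = tp + fn, tp = tp, fn = fn, fp = fp,
                   tn = tn,
                   sensitivity = safe_div(tp, tp + fn),
                   specificity = safe_div(tn, tn + fp),
                   accuracy = safe_div(tp + tn, grand))
  })
  dplyr::bind_rows(rows)
}

#' Per-activity summary of the sub-0.9 dip fraction
#'
#' Mean and standard deviation of the dip-fraction feature (percent of the
#' window with filtered Sum Vector Magnitude below 0.9 g) per activity
#' class. On protocol data this reproduces the characteristic ordering
#' jump > stair ascension > stair descension > fall > all remaining
#' classes.
#'
#' @param features A feature table with the `fSVM_dip_pct` column.
#' @return A tibble with `activity`, `n`, `mean_dip_pct`, `sd_dip_pct`,
#'   sorted by decreasing mean.
#' @export
dip_fraction_summary <- function(features) {
  present <- intersect(activity_levels(), unique(features$activity))
  missing_cls <- setdiff(activity_levels(), present)
  if (length(missing_cls) > 0) {
    warn(paste0("no trials for: ", paste(missing_cls, collapse = ", ")))
  }
  features %>%
    group_by(activity) %>%
    summarise(n = dplyr::n(),
              mean_dip_pct = mean(.data$fSVM_dip_pct),
              sd_dip_pct = sd(.data$fSVM_dip_pct),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$mean_dip_pct))
}

round_half_up <- function(x, digits = 3) {
  # epsilon guards against 0.0005 landing just below .5 in binary
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Render a classification report
#'
#' Produces the confusion table with per-class sensitivity and the
#' specificity/accuracy footer (display values rounded half-up to 3
#' decimals) as plain text, plus a machine-readable JSON twin carrying the
#' raw counts and unrounded metrics.
#'
#' @param cv A `fall_cv` result or a `fall_confusion` matrix.
#' @param path Optional path; when given, the JSON twin is written there.
#' @return A list of class `fall_report` with elements `text` (character
#'   lines) and `json` (JSON string), invisibly printed.
#' @export
render_report <- function(cv, path = NULL) {
  cm <- if (inherits(cv, "fall_confusion")) cv else cv$confusion
  if (sum(cm) == 0) abort("empty result; nothing to report")
  metrics <- class_metrics(cm)
  fmt3 <- function(x) ifelse(is.na(x), "-",
                             sprintf("%.3f", round_half_up(x)))
  cls <- activity_levels()
  header <- c("truth", cls, "total", "sensitivity")
  body <- t(vapply(cls, function(cl) {
    c(cl, as.character(cm[cl, ]), as.character(sum(cm[cl, ])),
      fmt3(metrics$sensitivity[metrics$class == cl]))
  }, character(12)))
  footer <- rbind(
    c("total", as.character(colSums(cm)), as.character(sum(cm)), ""),
    c("specificity", fmt3(metrics$specificity), "", ""),
    c("accuracy", fmt3(metrics$accuracy), "", "")
  )
  tab <- rbind(header, body, footer)
  widths <- apply(nchar(tab), 2, max)
  text <- apply(tab, 1, function(r) {
    paste(mapply(formatC, r, width = widths), collapse = "  ")
  })
  json <- jsonlite::toJSON(
    list(schema = "insolefall-report/1",
         class_order = cls,
         counts = unclass(cm),
         metrics = metrics),
    dataframe = "columns", matrix = "rowmajor", auto_unbox = TRUE,
    digits = NA)
  if (!is.null(path)) writeLines(json, path)
  structure(list(text = unname(text), json = json), class = "fall_report")
}

#' @export
print.fall_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Parse a report's JSON twin back into counts and metrics
#'
#' @param json JSON string or file path produced by [render_report()].
#' @return A list with `confusion` (a `fall_confusion`) and `metrics`.
#' @export
parse_report_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  list(confusion = new_confusion(obj$counts),
       metrics = tibble::as_tibble(obj$metrics))
}
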