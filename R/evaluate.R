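#' F-measure
#'
#' Harmonic mean of precision and recall, 2PR / (P + R), the single score
#' balancing both concerns; 0 by convention when P + R = 0.
#'
#' @param precision,recall Values in \[0, 1\] (vectorized).
#' @return F-measure in \[0, 1\].
#' @examples
#' f_measure(0.942, 0.919)  # 0.930 to 3 d.p.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

as_activity_factor <- function(x) {
  if (is.factor(x) && identical(levels(x), GAIT_ACTIVITIES)) return(x)
  parse_activity(x)
}

#' Confusion matrix
#'
#' Counts of (true, predicted) pairs over the five activities. The
#' normalized form divides each row by its sum (per-class recall profile);
#' rows with zero support stay zero.
#'
#' @param truth,predicted Label sequences of equal length.
#' @param normalized Return row-normalized proportions instead of counts.
#' @return 5x5 matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, normalized = FALSE) {
  truth <- as_activity_factor(truth)
  predicted <- as_activity_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  cm <- table(truth = truth, predicted = predicted)
  cm <- matrix(as.numeric(cm), nrow = 5, dimnames = dimnames(cm))
  if (normalized) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
  }
  cm
}

#' Attractor/repeller statistic per class
#'
#' From a row-normalized confusion matrix each row contributes 1, so a
#' class predicted exactly as often as expected has column sum 1. The
#' statistic is (column sum - 1): positive values mark attractor classes
#' (drawing more predictions than expected), negative values repellers.
#'
#' @param cm 5x5 confusion matrix (counts or normalized).
#' @return Named numeric vector of per-class attraction values.
#' @export
attraction_index <- function(cm) {
  rs <- rowSums(cm)
  norm <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
  colSums(norm) - 1
}

#' Classification report
#'
#' Per-class precision, recall, F-measure and support, overall accuracy,
#' macro (unweighted) and support-weighted averages, the standard
#' deviation of the five per-class F-measures (population form, the spread
#' printed alongside weighted averages), and the confusion matrix. The
#' same schema is used by the shallow and the CNN pipeline.
#'
#' Precision and recall are 0 by convention when their denominator is 0
#' (flagged in `zero_division`).
#'
#' @param truth,predicted Label sequences of equal length.
#' @param metadata Optional named list recorded verbatim in the report
#'   (treatment, algorithm, seed, feature configuration, ...).
#' @return An object of class `evaluation_report`.
#' @export
classification_report <- function(truth, predicted, metadata = list()) {
  truth <- as_activity_factor(truth)
  predicted <- as_activity_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  cm <- confusion_matrix(truth, predicted)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(pred_tot == 0, 0, tp / pred_tot)
  recall <- ifelse(support == 0, 0, tp / support)
  f <- f_measure(precision, recall)
  total <- sum(support)
  w <- if (total > 0) support / total else rep(0, 5)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(classes = GAIT_ACTIVITIES,
         precision = stats::setNames(precision, GAIT_ACTIVITIES),
         recall = stats::setNames(recall, GAIT_ACTIVITIES),
         f_measure = stats::setNames(f, GAIT_ACTIVITIES),
         support = stats::setNames(as.integer(support), GAIT_ACTIVITIES),
         accuracy = if (total > 0) sum(tp) / total else NA_real_,
         macro_avg = c(precision = mean(precision), recall = mean(recall),
                       f_measure = mean(f)),
         weighted_avg = c(precision = sum(w * precision),
                          recall = sum(w * recall),
                          f_measure = sum(w * f)),
         f_sigma = pop_sd(f),
         confusion = cm,
         zero_division = any(pred_tot == 0 & support > 0),
         metadata = metadata),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report>\n")
  df <- data.frame(precision = round(x$precision, digits),
                   recall = round(x$recall, digits),
                   f_measure = round(x$f_measure, digits),
                   support = x$support)
  print(df)
  cat(sprintf("accuracy     %.*f  (n = %d)\n", digits, x$accuracy,
              sum(x$support)))
  cat(sprintf("macro avg    P %.*f  R %.*f  F %.*f\n", digits,
              x$macro_avg["precision"], digits, x$macro_avg["recall"],
              digits, x$macro_avg["f_measure"]))
  cat(sprintf("weighted avg P %.*f  R %.*f  F %.*f  (sigma %.*f)\n", digits,
              x$weighted_avg["precision"], digits, x$weighted_avg["recall"],
              digits, x$weighted_avg["f_measure"], digits, x$f_sigma))
  invisible(x)
}

#' Compare evaluation reports
#'
#' Side-by-side distribution summary of the per-class F-measures of two or
#' more reports: median, mean, spread (population sd) and extreme classes
#' per report, suitable for treatment-vs-approach comparisons.
#'
#' @param reports List of [classification_report()] objects; names are
#'   used as report identifiers.
#' @return Data frame with one row per report.
#' @export
compare_reports <- function(reports) {
  if (length(reports) < 2)
    stop("need at least two reports to compare", call. = FALSE)
  ids <- names(reports)
  if (is.null(ids)) ids <- paste0("report_", seq_along(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    f <- r$f_measure
    data.frame(report = ids[i],
               accuracy = r$accuracy,
               median_f = stats::median(f),
               mean_f = mean(f),
               f_sigma = r$f_sigma,
               min_f = min(f), max_f = max(f),
               best_class = names(which.max(f)),
               worst_class = names(which.min(f)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(classes = report$classes,
         precision = unname(report$precision),
         recall = unname(report$recall),
         f_measure = unname(report$f_measure),
         support = unname(report$support),
         accuracy = report$accuracy,
         macro_avg = as.list(report$macro_avg),
         weighted_avg = as.list(report$weighted_avg),
         f_sigma = report$f_sigma,
         confusion = report$confusion,
         metadata = report$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
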