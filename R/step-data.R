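#' Construct a labeled step segment
#'
#' A step segment holds the six synchronized sensor series recorded over one
#' step (successive ground contacts of opposite feet): triaxial acceleration
#' in g and triaxial angular velocity in deg/s, sampled at `sampling_rate`
#' Hz (100 Hz for the target sensors).
#'
#' For segments marked `provenance = "real"` a soft range check is applied
#' against the sensor dynamic ranges (|acc| <= 4 g, |gyr| <= 500 deg/s):
#' violations raise a warning, not an error, since clipping artifacts do
#' occur in real exports.
#'
#' @param acc Numeric matrix with n rows and 3 columns (x, y, z), in g.
#' @param gyr Numeric matrix with n rows and 3 columns (x, y, z), in deg/s.
#' @param label Activity label, parsed via [parse_activity()].
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param subject_id Optional subject identifier.
#' @param provenance One of `"real"`, `"synthetic"`, `"augmented"`.
#' @return An object of class `step_segment`.
#' @export
step_segment <- function(acc, gyr, label, sampling_rate = 100,
                         subject_id = NA_character_,
                         provenance = c("real", "synthetic", "augmented")) {
  provenance <- match.arg(provenance)
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  storage.mode(acc) <- "double"
  storage.mode(gyr) <- "double"
  if (ncol(acc) != 3L || ncol(gyr) != 3L)
    stop("acc and gyr must each have three columns (x, y, z)", call. = FALSE)
  if (nrow(acc) != nrow(gyr))
    stop("acc and gyr must have the same number of samples", call. = FALSE)
  if (nrow(acc) < 4L)
    stop("a step segment needs at least 4 samples, got ", nrow(acc),
         call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar [Hz]", call. = FALSE)
  dimnames(acc) <- dimnames(gyr) <- list(NULL, c("x", "y", "z"))
  if (provenance == "real") {
    if (any(abs(acc) > 4))
      warning("acceleration exceeds the +/-4 g dynamic range", call. = FALSE)
    if (any(abs(gyr) > 500))
      warning("angular velocity exceeds the +/-500 deg/s dynamic range",
              call. = FALSE)
  }
  structure(
    list(acc = acc, gyr = gyr,
         label = parse_activity(label),
         sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         provenance = provenance),
    class = "step_segment")
}

#' @export
length.step_segment <- function(x) nrow(x$acc)

#' @export
print.step_segment <- function(x, ...) {
  cat(sprintf("<step_segment> %s, %d samples @ %g Hz, %s\n",
              as.character(x$label), nrow(x$acc), x$sampling_rate,
              x$provenance))
  invisible(x)
}

#' Construct a step dataset
#'
#' An ordered collection of [step_segment()] objects with a name.
#'
#' @param segments List of `step_segment` objects.
#' @param name Dataset name.
#' @return An object of class `step_dataset`.
#' @export
step_dataset <- function(segments = list(), name = "steps") {
  ok <- vapply(segments, inherits, logical(1), what = "step_segment")
  if (!all(ok))
    stop("all elements of `segments` must be step_segment objects",
         call. = FALSE)
  structure(list(segments = segments, name = as.character(name)),
            class = "step_dataset")
}

#' @export
length.step_dataset <- function(x) length(x$segments)

#' @export
print.step_dataset <- function(x, ...) {
  cat(sprintf("<step_dataset> '%s': %d segments\n", x$name,
              length(x$segments)))
  h <- class_histogram(x)
  for (cl in names(h)) cat(sprintf("  %-13s %d\n", cl, h[[cl]]))
  invisible(x)
}

#' Labels of all segments in a dataset
#'
#' @param dataset A `step_dataset`.
#' @return Factor of labels, one per segment, levels `gait_activities()`.
#' @export
dataset_labels <- function(dataset) {
  stopifnot(inherits(dataset, "step_dataset"))
  factor(vapply(dataset$segments, function(s) as.character(s$label),
                character(1)),
         levels = GAIT_ACTIVITIES)
}

#' Per-class instance counts
#'
#' Counts segments per activity; classes absent from the dataset are
#' reported as 0, so the counts always sum to the dataset size.
#'
#' @param dataset A `step_dataset`.
#' @return Named integer vector over the five activities.
#' @examples
#' d <- generate_dataset(50, generator_params(
#'   class_proportions = rep(1, 5), seed = 1))
#' class_histogram(d)
#' @export
class_histogram <- function(dataset) {
  table(dataset_labels(dataset)) |> c()
}

# default long-format column layout for delimited step files
default_dialect <- function() {
  list(step_id = "step_id", t_index = "t_index",
       acc = c("acc_x", "acc_y", "acc_z"),
       gyr = c("gyr_x", "gyr_y", "gyr_z"),
       label = "label", subject_id = "subject_id",
       provenance = "provenance")
}

#' Read step segments from a long-format CSV file
#'
#' The file holds one row per sample; rows sharing a `step_id` form one
#' segment, with row order (or the optional `t_index` column) giving sample
#' order. The `dialect` names the columns: six sensor columns, the label
#' column and the step-id column are required; `subject_id`, `provenance`
#' and `t_index` are optional.
#'
#' Steps with fewer than 4 rows are rejected with a warning; unknown label
#' text is an error listing the valid labels.
#'
#' @param path Path to a CSV file (UTF-8, "." decimal point).
#' @param dialect Named list mapping roles to column names; see
#'   `gaitstep:::default_dialect()` for the default layout.
#' @param name Name for the resulting dataset; defaults to the file name.
#' @param sampling_rate Sampling rate to attach to every segment [Hz].
#' @return A [step_dataset()].
#' @export
read_steps <- function(path, dialect = default_dialect(),
                       name = basename(path), sampling_rate = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c(dialect$step_id, dialect$acc, dialect$gyr, dialect$label)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(step_dataset(list(), name = name))
  if (!is.null(dialect$t_index) && dialect$t_index %in% names(df))
    df <- df[order(df[[dialect$step_id]], df[[dialect$t_index]]), ]
  groups <- split(df, factor(df[[dialect$step_id]],
                             levels = unique(df[[dialect$step_id]])))
  segs <- list()
  for (g in groups) {
    sid <- g[[dialect$step_id]][1]
    if (nrow(g) < 4L) {
      warning("step '", sid, "' has fewer than 4 samples; skipped",
              call. = FALSE)
      next
    }
    prov <- if (!is.null(dialect$provenance) &&
                dialect$provenance %in% names(g))
      g[[dialect$provenance]][1] else "real"
    subj <- if (!is.null(dialect$subject_id) &&
                dialect$subject_id %in% names(g))
      as.character(g[[dialect$subject_id]][1]) else NA_character_
    segs[[length(segs) + 1L]] <- step_segment(
      acc = as.matrix(g[, dialect$acc]),
      gyr = as.matrix(g[, dialect$gyr]),
      label = g[[dialect$label]][1],
      sampling_rate = sampling_rate,
      subject_id = subj,
      provenance = prov)
  }
  step_dataset(segs, name = name)
}

#' Write a step dataset to a long-format CSV file
#'
#' Inverse of [read_steps()] under the default dialect: one row per sample,
#' columns `step_id`, `t_index`, the six sensor columns, `label`,
#' `subject_id`, `provenance`. Values round-trip within 1e-9; labels,
#' lengths and provenance round-trip exactly.
#'
#' @param dataset A [step_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(dataset, path) {
  stopifnot(inherits(dataset, "step_dataset"))
  d <- default_dialect()
  header <- c(d$step_id, d$t_index, d$acc, d$gyr, d$label, d$subject_id,
              d$provenance)
  if (length(dataset) == 0L) {
    utils::write.csv(
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(header))),
                      header),
      path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(seq_along(dataset$segments), function(i) {
    s <- dataset$segments[[i]]
    n <- nrow(s$acc)
    data.frame(step_id = i, t_index = seq_len(n),
               acc_x = s$acc[, 1], acc_y = s$acc[, 2], acc_z = s$acc[, 3],
               gyr_x = s$gyr[, 1], gyr_y = s$gyr[, 2], gyr_z = s$gyr[, 3],
               label = as.character(s$label),
               subject_id = s$subject_id,
               provenance = s$provenance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
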