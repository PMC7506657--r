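#' Feature configuration for the shallow pipeline
#'
#' Selects which sensors (accelerometer, gyroscope) and which derived
#' signals (forward-direction FD, magnitude vector XYZ) contribute
#' features. Each selected (sensor, signal) pair contributes four
#' descriptors (height, mean, standard deviation, power); the step width
#' is shared, so the feature dimensionality is 4 x sensors x signals + 1
#' (5, 9 or 17).
#'
#' @param sensors Non-empty subset of `c("acc", "gyr")`.
#' @param signals Non-empty subset of `c("fd", "xyz")`.
#' @return An object of class `feature_config`.
#' @examples
#' feature_dimension(feature_config("acc", "fd"))            # 5
#' feature_dimension(feature_config(c("acc", "gyr"),
#'                                  c("fd", "xyz")))          # 17
#' @export
feature_config <- function(sensors = c("acc", "gyr"),
                           signals = c("fd", "xyz")) {
  if (length(sensors) == 0 || length(signals) == 0)
    stop("at least one sensor and one signal must be selected",
         call. = FALSE)
  sensors <- match.arg(sensors, c("acc", "gyr"), several.ok = TRUE)
  signals <- match.arg(signals, c("fd", "xyz"), several.ok = TRUE)
  structure(list(sensors = sensors, signals = signals),
            class = "feature_config")
}

#' @rdname feature_config
#' @param config A `feature_config`.
#' @export
feature_dimension <- function(config) {
  4L * length(config$sensors) * length(config$signals) + 1L
}

#' Extract statistical step features
#'
#' The five descriptive features of a step signal: (i) width of the
#' segment (duration in samples, counted once whatever the signal
#' selection), and per selected (sensor, signal): (ii) height (max - min),
#' (iii) mean, (iv) standard deviation, and (v) power (mean of squared
#' values, including the DC component).
#'
#' @param step A [preprocess_step()] result.
#' @param config A [feature_config()].
#' @return Named numeric vector of length `feature_dimension(config)`.
#' @export
extract_features <- function(step, config = feature_config()) {
  stopifnot(inherits(step, "processed_step"),
            inherits(config, "feature_config"))
  out <- c(width = length(step$acc_fd))
  for (sensor in config$sensors) {
    for (sig in config$signals) {
      v <- step[[paste0(sensor, "_", sig)]]
      feats <- c(max(v) - min(v), mean(v), stats::sd(v), mean(v^2))
      names(feats) <- paste0(sensor, "_", sig, "_",
                             c("height", "mean", "sd", "power"))
      out <- c(out, feats)
    }
  }
  out
}

#' Feature table for a collection of processed steps
#'
#' @param steps List of `processed_step` objects.
#' @param config A [feature_config()].
#' @return Data frame of features with a final `label` factor column.
#' @export
extract_feature_table <- function(steps, config = feature_config()) {
  feats <- t(vapply(steps, extract_features, config = config,
                    FUN.VALUE = numeric(feature_dimension(config))))
  df <- as.data.frame(feats)
  df$label <- factor(vapply(steps, function(s) as.character(s$label),
                            character(1)),
                     levels = GAIT_ACTIVITIES)
  df
}

#' Shallow classifier algorithms
#'
#' @return Names of the four inference algorithms: naive Bayes, an
#'   entropy-split decision tree (C4.5-style), a radial-kernel support
#'   vector machine, and k-nearest neighbours.
#' @export
shallow_algorithms <- function() {
  c("naive_bayes", "decision_tree", "svm", "knn")
}

#' Train a shallow gait classifier
#'
#' Fits one of the four algorithms on a feature table. Features are
#' standardized (z-score) using statistics of the training data; the same
#' transform is applied at prediction time, so fold-local scaling carries
#' no information across folds. Defaults: entropy splitting without
#' pruning for the tree, RBF kernel with C = 1 for the SVM, k = 5 for kNN.
#'
#' @param features Data frame from [extract_feature_table()] (numeric
#'   feature columns plus a `label` factor).
#' @param algorithm One of [shallow_algorithms()].
#' @param k Neighbourhood size for kNN.
#' @param cost SVM regularization constant.
#' @return An object of class `gait_classifier` with a `predict` method.
#' @export
train_classifier <- function(features, algorithm = shallow_algorithms(),
                             k = 5, cost = 1) {
  algorithm <- match.arg(algorithm)
  if (!"label" %in% names(features))
    stop("features must contain a `label` column", call. = FALSE)
  y <- droplevels(factor(features$label))
  if (nlevels(y) < 2)
    stop("training data must contain at least 2 classes", call. = FALSE)
  x <- as.matrix(features[, setdiff(names(features), "label"), drop = FALSE])
  if (anyNA(x)) stop("features contain missing values", call. = FALSE)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)
  xs_df <- as.data.frame(xs)
  fit <- switch(algorithm,
    naive_bayes = e1071::naiveBayes(xs_df, y),
    decision_tree = rpart::rpart(
      label ~ ., data = cbind(xs_df, label = y), method = "class",
      parms = list(split = "information"),
      control = rpart::rpart.control(cp = 0, xval = 0, minsplit = 10)),
    svm = e1071::svm(xs, y, kernel = "radial", cost = cost, scale = FALSE),
    knn = list(x = xs, y = y, k = k))
  structure(list(algorithm = algorithm, fit = fit, center = center,
                 scale = scale_, features = colnames(x),
                 levels = levels(y)),
            class = "gait_classifier")
}

#' @export
predict.gait_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(
      newdata[, setdiff(names(newdata), "label"), drop = FALSE])
  }
  if (ncol(newdata) != length(object$features))
    stop("feature dimensionality mismatch: model expects ",
         length(object$features), " features, got ", ncol(newdata),
         call. = FALSE)
  xs <- scale(newdata, center = object$center, scale = object$scale)
  pred <- switch(object$algorithm,
    naive_bayes = stats::predict(object$fit, as.data.frame(xs)),
    decision_tree = {
      p <- stats::predict(object$fit, as.data.frame(xs), type = "class")
      p
    },
    svm = stats::predict(object$fit, xs),
    knn = class::knn(object$fit$x, xs, object$fit$y, k = object$fit$k))
  factor(as.character(pred), levels = GAIT_ACTIVITIES)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 0)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Five-fold cross-validated shallow classification
#'
#' Applies a data treatment, preprocesses every step, extracts features,
#' and evaluates one algorithm under stratified k-fold cross-validation
#' (train on (k-1)/k of the instances, test on the rest, k times). The
#' report aggregates predictions over all test folds, so every instance is
#' tested exactly once.
#'
#' By default the treatment is applied before splitting, mirroring the
#' evaluated procedure; `split_before_augment = TRUE` instead assigns
#' folds on the original data and augments only the training portion of
#' each fold, which removes any synthetic/source leakage across folds.
#'
#' @param dataset A [step_dataset()].
#' @param treatment One of `"unbalanced"`, `"sampled"`, `"augmented"`.
#' @param config A [feature_config()].
#' @param algorithm One of [shallow_algorithms()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling treatment randomness and fold
#'   assignment.
#' @param cutoff,smooth_width Preprocessing parameters.
#' @param aug_config An [augmentation_config()].
#' @param stratified Stratify folds by class (default TRUE).
#' @param split_before_augment Assign folds before applying the augmented
#'   treatment (default FALSE).
#' @param ... Passed to [train_classifier()].
#' @return A [classification_report()] with run metadata.
#' @export
run_cross_validation <- function(dataset,
                                 treatment = "unbalanced",
                                 config = feature_config(),
                                 algorithm = "svm",
                                 folds = 5, seed = 1,
                                 cutoff = 10, smooth_width = 5,
                                 aug_config = augmentation_config(),
                                 stratified = TRUE,
                                 split_before_augment = FALSE, ...) {
  set.seed(seed)
  meta <- list(treatment = treatment, algorithm = algorithm, seed = seed,
               sensors = paste(config$sensors, collapse = "+"),
               signals = paste(config$signals, collapse = "+"),
               folds = folds)
  if (split_before_augment && treatment == "augmented") {
    labels <- dataset_labels(dataset)
    check_fold_support(labels, folds)
    fold <- if (stratified) stratified_folds(labels, folds)
            else sample(rep_len(seq_len(folds), length(labels)))
    truth <- list(); pred <- list()
    for (f in seq_len(folds)) {
      train_ds <- step_dataset(dataset$segments[fold != f])
      train_ds <- balance_by_augmentation(train_ds, aug_config)
      test_ds <- step_dataset(dataset$segments[fold == f])
      ft_train <- extract_feature_table(
        preprocess_dataset(train_ds, cutoff, smooth_width), config)
      ft_test <- extract_feature_table(
        preprocess_dataset(test_ds, cutoff, smooth_width), config)
      model <- train_classifier(ft_train, algorithm, ...)
      truth[[f]] <- ft_test$label
      pred[[f]] <- predict(model, ft_test)
    }
    return(classification_report(unlist_factor(truth), unlist_factor(pred),
                                 metadata = meta))
  }
  treated <- apply_treatment(dataset, treatment, aug_config)
  ft <- extract_feature_table(
    preprocess_dataset(treated, cutoff, smooth_width), config)
  labels <- ft$label
  check_fold_support(labels, folds)
  fold <- if (stratified) stratified_folds(labels, folds)
          else sample(rep_len(seq_len(folds), length(labels)))
  truth <- list(); pred <- list()
  for (f in seq_len(folds)) {
    model <- train_classifier(ft[fold != f, , drop = FALSE], algorithm, ...)
    truth[[f]] <- labels[fold == f]
    pred[[f]] <- predict(model, ft[fold == f, , drop = FALSE])
  }
  classification_report(unlist_factor(truth), unlist_factor(pred),
                        metadata = meta)
}

check_fold_support <- function(labels, folds) {
  h <- table(labels)
  h <- h[h > 0]
  low <- names(h)[h < folds]
  if (length(low) > 0)
    stop("class(es) with fewer than ", folds, " instances: ",
         paste(low, collapse = ", "), call. = FALSE)
}

unlist_factor <- function(lst) {
  factor(unlist(lapply(lst, as.character)), levels = GAIT_ACTIVITIES)
}
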