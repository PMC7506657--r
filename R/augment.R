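#' Augmentation configuration
#'
#' Parameters of the synthetic-data operators. Every operator perturbs its
#' input through a Gaussian variation factor f ~ N(factor_mean, factor_sd),
#' defaulting to N(1, 0.2) — a spread narrow enough to respect the
#' restrictions of human movement and of step-based segmentation. Window
#' and edge-cut lengths are derived from the step length divided by
#' `window_divisor` (the "total time / 10" rule).
#'
#' @param factor_mean Mean of the variation factor (default 1).
#' @param factor_sd Standard deviation of the variation factor (default
#'   0.2); must be >= 0.
#' @param window_divisor Integer divisor of the step length used by the
#'   smoothing and cutting operators (default 10); must be >= 1.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(factor_mean = 1, factor_sd = 0.2,
                                window_divisor = 10) {
  if (factor_sd < 0) stop("factor_sd must be >= 0", call. = FALSE)
  if (window_divisor < 1) stop("window_divisor must be >= 1", call. = FALSE)
  structure(list(factor_mean = factor_mean, factor_sd = factor_sd,
                 window_divisor = as.integer(window_divisor)),
            class = "augmentation_config")
}

#' Names of the five augmentation techniques
#'
#' Three operators modify the magnitude of the signal (DMM: scaling,
#' jittering, smoothing) and two modify its frequency/length (DMF:
#' downsampling, cutting).
#'
#' @return Character vector of technique names.
#' @export
augmentation_techniques <- function() {
  c("scaling", "jittering", "smoothing", "downsampling", "cutting")
}

#' Draw variation factors
#'
#' Draws from N(factor_mean, factor_sd). Non-positive draws (probability
#' ~3e-7 under the defaults) are redrawn, since a sign flip or zero factor
#' is not a plausible human-movement variation.
#'
#' @param n Number of factors.
#' @param config An [augmentation_config()].
#' @return Numeric vector of n positive factors.
#' @export
draw_factor <- function(n, config = augmentation_config()) {
  f <- stats::rnorm(n, config$factor_mean, config$factor_sd)
  while (any(f <= 0))
    f[f <= 0] <- stats::rnorm(sum(f <= 0), config$factor_mean,
                              config$factor_sd)
  f
}

#' Scaling operator (DMM)
#'
#' Multiplies all elements of a signal by one factor; length (and hence
#' signal frequency) is unchanged.
#'
#' @param series Numeric vector.
#' @param factor Scalar multiplier (drawn by the caller).
#' @return Scaled series.
#' @export
scale_signal <- function(series, factor) {
  stopifnot(is.finite(factor))
  series * factor
}

#' Jittering operator (DMM)
#'
#' Multiplies each element by an independent factor ~ N(factor_mean,
#' factor_sd), i.e. multiplicative noise; length is unchanged.
#'
#' @param series Numeric vector.
#' @param config An [augmentation_config()].
#' @return Jittered series.
#' @export
jitter_signal <- function(series, config = augmentation_config()) {
  series * draw_factor(length(series), config)
}

#' Smoothing window length rule
#'
#' Window length used by the smoothing operator: the step length divided by
#' `window_divisor`, times a variation factor, rounded and clipped to
#' `[1, series_length]`.
#'
#' @param series_length Step length in samples.
#' @param config An [augmentation_config()].
#' @param factor Variation factor.
#' @return Integer window length.
#' @export
smoothing_window_length <- function(series_length,
                                    config = augmentation_config(),
                                    factor = 1) {
  wlen <- round((series_length / config$window_divisor) * factor)
  max(1L, min(as.integer(wlen), as.integer(series_length)))
}

hann_window <- function(n) {
  if (n < 3) return(1)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  w / sum(w)
}

#' Smoothing operator (DMM)
#'
#' Filters the signal with a normalized Hann window whose length is
#' (step length / window_divisor) times a drawn variation factor, clipped
#' to the valid range. Lengths below 3 degenerate to the identity (a Hann
#' window needs at least three points of support). Length is unchanged.
#'
#' @param series Numeric vector.
#' @param config An [augmentation_config()].
#' @param factor Optional fixed factor (for reproducible single calls);
#'   drawn from the config when `NULL`.
#' @return Smoothed series, same length.
#' @export
smooth_signal <- function(series, config = augmentation_config(),
                          factor = NULL) {
  n <- length(series)
  if (n < config$window_divisor)
    stop("series shorter than window_divisor", call. = FALSE)
  if (is.null(factor)) factor <- draw_factor(1, config)
  wlen <- smoothing_window_length(n, config, factor)
  w <- hann_window(wlen)
  if (length(w) == 1L) return(series)
  # Hann endpoints are zero; trim them so the effective kernel is centred
  w <- w[w > 0]
  if (length(w) %% 2L == 0L) w <- c(w, 0)
  if (((length(w) - 1L) %/% 2L) >= n) w <- hann_window(3)[2]  # degenerate
  if (length(w) == 1L) return(series)
  reflect_convolve(series, w / sum(w))
}

#' Downsampling operator (DMF)
#'
#' Uniformly subsamples all six series of a step at one common rate: the
#' retained count is L' = round(L / f) with f ~ N(factor_mean, factor_sd)
#' redrawn until 4 <= L' < L, and retained indices are evenly spaced from a
#' random start offset. Every output value exists in the corresponding
#' input (magnitudes are unchanged).
#'
#' @param step_signals Numeric matrix with 6 columns (acc x/y/z, gyr
#'   x/y/z), one row per sample; L >= 8 rows.
#' @param config An [augmentation_config()].
#' @return Matrix with the same 6 columns and L' < L rows.
#' @export
downsample_signal <- function(step_signals, config = augmentation_config()) {
  m <- as.matrix(step_signals)
  L <- nrow(m)
  if (L < 8L) stop("need at least 8 samples to downsample", call. = FALSE)
  for (attempt in 1:100) {
    f <- draw_factor(1, config)
    Lp <- as.integer(round(L / f))
    if (Lp >= 4L && Lp < L) break
    Lp <- NA_integer_
  }
  if (is.na(Lp))
    stop("could not draw a valid downsampling rate", call. = FALSE)
  s <- L / Lp  # > 1, so floor() of the arithmetic grid is strictly increasing
  u <- stats::runif(1, 1, 1 + (s - 1))
  idx <- floor(u + (0:(Lp - 1)) * s)
  idx <- pmin(idx, L)
  m[idx, , drop = FALSE]
}

#' Cutting operator (DMF)
#'
#' Removes n = round((L / window_divisor) * f) frames from the edges of
#' all six series, ceil(n/2) from the start and floor(n/2) from the end,
#' with f ~ N(factor_mean, factor_sd) redrawn while fewer than 4 samples
#' would remain. The output is a contiguous block of the input.
#'
#' @inheritParams downsample_signal
#' @return Matrix with the same 6 columns and L - n rows.
#' @export
cut_signal <- function(step_signals, config = augmentation_config()) {
  m <- as.matrix(step_signals)
  L <- nrow(m)
  if (L < 5L) stop("need at least 5 samples to cut", call. = FALSE)
  for (attempt in 1:100) {
    f <- draw_factor(1, config)
    n_remove <- as.integer(round((L / config$window_divisor) * f))
    if (L - n_remove >= 4L) break
    n_remove <- NA_integer_
  }
  if (is.na(n_remove))
    stop("could not draw a valid cut length", call. = FALSE)
  if (n_remove == 0L) return(m)
  from <- ceiling(n_remove / 2) + 1L
  to <- L - floor(n_remove / 2)
  m[from:to, , drop = FALSE]
}

segment_matrix <- function(segment) cbind(segment$acc, segment$gyr)

matrix_segment <- function(m, template) {
  step_segment(acc = m[, 1:3, drop = FALSE], gyr = m[, 4:6, drop = FALSE],
               label = template$label,
               sampling_rate = template$sampling_rate,
               subject_id = template$subject_id,
               provenance = "synthetic")
}

#' Generate one synthetic step from a source step
#'
#' Applies one of the five augmentation techniques to a step segment. DMM
#' techniques (scaling, jittering, smoothing) draw one independent factor
#' per signal and preserve length; DMF techniques (downsampling, cutting)
#' draw once per step, apply the same frame selection to all six signals,
#' and preserve per-sample values. The result carries
#' `provenance = "synthetic"` and the source label.
#'
#' @param segment A [step_segment()].
#' @param technique One of [augmentation_techniques()].
#' @param config An [augmentation_config()].
#' @return A synthetic [step_segment()].
#' @export
augment_step <- function(segment, technique = augmentation_techniques(),
                         config = augmentation_config()) {
  stopifnot(inherits(segment, "step_segment"))
  technique <- match.arg(technique)
  m <- segment_matrix(segment)
  out <- switch(technique,
    scaling = apply(m, 2, function(v) scale_signal(v, draw_factor(1, config))),
    jittering = apply(m, 2, jitter_signal, config = config),
    smoothing = apply(m, 2, smooth_signal, config = config),
    downsampling = downsample_signal(m, config),
    cutting = cut_signal(m, config))
  matrix_segment(out, segment)
}

#' Per-class plan for a data treatment
#'
#' Pure arithmetic on a class histogram: target per-class counts and, for
#' the augmented treatment, the number of synthetic instances required per
#' class to reach the majority-class count.
#'
#' @param histogram Named counts over the five activities (as returned by
#'   [class_histogram()]).
#' @param treatment One of `"unbalanced"`, `"sampled"`, `"augmented"`.
#' @return List with `target` (per-class counts after treatment),
#'   `synthetic` (per-class synthetic instances needed; zero except for the
#'   augmented treatment) and `total`.
#' @examples
#' h <- c(down_incline = 2098, up_incline = 1890, level = 9865,
#'        down_stairs = 882, up_stairs = 956)
#' treatment_plan(h, "augmented")$total  # 49325
#' @export
treatment_plan <- function(histogram,
                           treatment = c("unbalanced", "sampled",
                                         "augmented")) {
  treatment <- match.arg(treatment)
  h <- as.numeric(histogram)
  names(h) <- names(histogram)
  target <- switch(treatment,
    unbalanced = h,
    sampled = stats::setNames(rep(min(h), length(h)), names(h)),
    augmented = stats::setNames(rep(max(h), length(h)), names(h)))
  synthetic <- pmax(target - h, 0)
  if (treatment != "augmented") synthetic[] <- 0
  list(target = target, synthetic = synthetic, total = sum(target))
}

#' Balance a dataset by augmentation
#'
#' Raises every class to the majority-class count by generating synthetic
#' steps: the five techniques are applied in round-robin order to source
#' steps drawn uniformly (with replacement) from the original instances of
#' the deficient class. Originals are retained unmodified; synthetic steps
#' never seed further synthesis.
#'
#' @param dataset A [step_dataset()].
#' @param config An [augmentation_config()].
#' @return A balanced [step_dataset()].
#' @export
balance_by_augmentation <- function(dataset, config = augmentation_config()) {
  stopifnot(inherits(dataset, "step_dataset"))
  if (length(dataset) == 0)
    stop("cannot synthesize instances from an empty dataset: ",
         "every class to balance needs at least one source step",
         call. = FALSE)
  h <- class_histogram(dataset)
  h <- h[h > 0]  # balance among classes present; nothing can be
                 # synthesized for a class with no source instances
  plan <- treatment_plan(h, "augmented")
  labels <- dataset_labels(dataset)
  techs <- augmentation_techniques()
  synth <- list()
  for (cl in names(h)) {
    need <- plan$synthetic[[cl]]
    if (need == 0) next
    pool <- which(labels == cl)
    src <- sample(pool, need, replace = TRUE)
    for (j in seq_len(need)) {
      synth[[length(synth) + 1L]] <- augment_step(
        dataset$segments[[src[j]]],
        technique = techs[((j - 1L) %% 5L) + 1L],
        config = config)
    }
  }
  step_dataset(c(dataset$segments, synth),
               name = paste0(dataset$name, "_augmented"))
}

#' Balance a dataset by subsampling to the minority class
#'
#' Downsamples every class without replacement to the minority-class
#' count. Deterministic under a fixed RNG seed.
#'
#' @param dataset A [step_dataset()].
#' @return A subsampled [step_dataset()].
#' @export
subsample_to_minority <- function(dataset) {
  stopifnot(inherits(dataset, "step_dataset"))
  h <- class_histogram(dataset)
  h <- h[h > 0]
  k <- min(h)
  labels <- dataset_labels(dataset)
  keep <- unlist(lapply(names(h), function(cl) {
    pool <- which(labels == cl)
    if (length(pool) == k) pool else sample(pool, k)
  }))
  keep <- sort(keep)
  step_dataset(dataset$segments[keep],
               name = paste0(dataset$name, "_sampled"))
}

#' Apply a data treatment
#'
#' The three treatments for class imbalance: `"unbalanced"` leaves the
#' dataset as is, `"sampled"` balances down to the minority class, and
#' `"augmented"` balances up to the majority class with synthetic data.
#'
#' @param dataset A [step_dataset()].
#' @param treatment One of `"unbalanced"`, `"sampled"`, `"augmented"`.
#' @param config An [augmentation_config()] (used by the augmented
#'   treatment).
#' @return A treated [step_dataset()].
#' @export
apply_treatment <- function(dataset,
                            treatment = c("unbalanced", "sampled",
                                          "augmented"),
                            config = augmentation_config()) {
  treatment <- match.arg(treatment)
  switch(treatment,
         unbalanced = dataset,
         sampled = subsample_to_minority(dataset),
         augmented = balance_by_augmentation(dataset, config))
}
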