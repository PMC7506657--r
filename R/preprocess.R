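#' Zero-phase low-pass filtering
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase), so dominant peaks keep their position within the step.
#' Human gait energy is concentrated well below 10 Hz, the default cutoff
#' at 100 Hz sampling.
#'
#' @param series Numeric vector, length >= 4.
#' @param sampling_rate Sampling rate [Hz].
#' @param cutoff Cutoff frequency [Hz]; must satisfy 0 < cutoff <
#'   sampling_rate / 2.
#' @param order Filter order (default 4).
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(series, sampling_rate = 100, cutoff = 10,
                           order = 4) {
  if (length(series) < 4L)
    stop("series must have at least 4 samples", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= sampling_rate / 2)
    stop("cutoff must lie in (0, sampling_rate/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  # Forward-backward passes with symmetric (DC-preserving) edge reflection
  # and offset-adjusted starts, keeping startup transients off the short
  # step segment; phases cancel between the two passes.
  n <- length(series)
  pad <- min(n - 1L, 30L)
  ext <- c(series[(pad + 1):2], series, series[(n - 1):(n - pad)])
  one_pass <- function(x) {
    as.numeric(signal::filter(bf, x - x[1])) + x[1]
  }
  out <- rev(one_pass(rev(one_pass(ext))))
  out[(pad + 1):(pad + n)]
}

gaussian_kernel <- function(width) {
  half <- floor(width / 2)
  if (half == 0L) return(1)
  sigma <- width / 4
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# same-length convolution with reflective boundary handling
reflect_convolve <- function(series, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  if (half == 0L) return(series * kernel)
  n <- length(series)
  if (half >= n)
    stop("kernel wider than series", call. = FALSE)
  ext <- c(series[(half + 1):2], series, series[(n - 1):(n - half)])
  stats::convolve(ext, rev(kernel), type = "filter")
}

#' Pseudo-Gaussian smoothing
#'
#' Convolves the series with a normalized discrete Gaussian kernel
#' (sigma = width / 4, truncated at +/- width / 2) with reflective boundary
#' handling, preserving length. `width = 1` is the identity.
#'
#' @param series Numeric vector.
#' @param width Kernel width in samples; must not exceed the series length.
#' @return Smoothed series, same length.
#' @export
pseudo_gaussian_smooth <- function(series, width = 5) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  if (width > length(series))
    stop("smoothing width (", width, ") exceeds series length (",
         length(series), ")", call. = FALSE)
  reflect_convolve(series, gaussian_kernel(width))
}

#' Select the forward-direction (FD) axis
#'
#' The axis aligned with the sagittal plane records the greatest
#' acceleration magnitude during a step; it is identified as the axis of
#' maximal mean-removed power (mean squared deviation from the series
#' mean). Mean removal keeps the gravity-aligned DC offset of one
#' accelerometer axis from dominating the choice. Ties break to the lowest
#' axis index.
#'
#' @param triad Numeric matrix with three columns (axes).
#' @return List with `axis` (1-based column index) and `series` (that
#'   column).
#' @export
select_forward_direction <- function(triad) {
  triad <- as.matrix(triad)
  if (ncol(triad) != 3L)
    stop("triad must have exactly three columns", call. = FALSE)
  pw <- apply(triad, 2, function(v) mean((v - mean(v))^2))
  # which.max takes the first maximum: low-index tie-break
  axis <- unname(which.max(pw))
  list(axis = axis, series = unname(triad[, axis]))
}

#' Magnitude vector of a sensor triad
#'
#' Per-sample Euclidean norm sqrt(x^2 + y^2 + z^2), combining the three
#' axes into a single rotation-invariant series.
#'
#' @param triad Numeric matrix with three columns.
#' @return Non-negative numeric vector, one value per sample.
#' @export
magnitude_vector <- function(triad) {
  triad <- as.matrix(triad)
  if (ncol(triad) != 3L)
    stop("triad must have exactly three columns", call. = FALSE)
  sqrt(rowSums(triad^2))
}

#' Preprocess a step segment
#'
#' Runs the first pipeline stage on all six axes: low-pass filtering then
#' pseudo-Gaussian smoothing, followed by forward-direction selection
#' (independently for accelerometer and gyroscope) and magnitude-vector
#' computation from the filtered, smoothed triads. Yields the four derived
#' signals used by both classification pipelines: AccFD, AccXYZ, GyrFD,
#' GyrXYZ.
#'
#' @param segment A [step_segment()].
#' @param cutoff Low-pass cutoff [Hz].
#' @param smooth_width Smoothing kernel width [samples].
#' @return An object of class `processed_step` with fields `acc_fd`,
#'   `acc_xyz`, `gyr_fd`, `gyr_xyz`, `fd_axis_acc`, `fd_axis_gyr`, `label`,
#'   `sampling_rate`, `source`.
#' @export
preprocess_step <- function(segment, cutoff = 10, smooth_width = 5) {
  stopifnot(inherits(segment, "step_segment"))
  clean <- function(m) {
    apply(m, 2, function(v)
      pseudo_gaussian_smooth(
        lowpass_filter(v, segment$sampling_rate, cutoff),
        min(smooth_width, nrow(m))))
  }
  acc <- clean(segment$acc)
  gyr <- clean(segment$gyr)
  fd_acc <- select_forward_direction(acc)
  fd_gyr <- select_forward_direction(gyr)
  structure(
    list(acc_fd = fd_acc$series, acc_xyz = magnitude_vector(acc),
         gyr_fd = fd_gyr$series, gyr_xyz = magnitude_vector(gyr),
         fd_axis_acc = fd_acc$axis, fd_axis_gyr = fd_gyr$axis,
         label = segment$label, sampling_rate = segment$sampling_rate,
         source = segment),
    class = "processed_step")
}

#' @export
print.processed_step <- function(x, ...) {
  cat(sprintf("<processed_step> %s, %d samples, FD axes acc=%d gyr=%d\n",
              as.character(x$label), length(x$acc_fd), x$fd_axis_acc,
              x$fd_axis_gyr))
  invisible(x)
}

#' Preprocess every segment of a dataset
#'
#' @param dataset A [step_dataset()].
#' @inheritParams preprocess_step
#' @return List of `processed_step` objects.
#' @export
preprocess_dataset <- function(dataset, cutoff = 10, smooth_width = 5) {
  stopifnot(inherits(dataset, "step_dataset"))
  lapply(dataset$segments, preprocess_step, cutoff = cutoff,
         smooth_width = smooth_width)
}
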