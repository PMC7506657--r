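#' Rescale a series to the unit interval [-1, 1]
#'
#' The Gramian Angular Field encoding first maps the series through
#' x~_i = ((x_i - max X) + (x_i - min X)) / (max X - min X),
#' which sends the maximum to 1 and the minimum to -1 and removes offset
#' and positive scale. A constant series (max = min) maps to all zeros by
#' convention (the neutral angle pi/2). Values are clipped to [-1, 1] to
#' guard against floating-point overshoot.
#'
#' @param series Numeric vector, length >= 1.
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' rescale_unit(c(1, 2, 3))  # -1 0 1
#' @export
rescale_unit <- function(series) {
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(rep(0, length(series)))
  x <- ((series - hi) + (series - lo)) / (hi - lo)
  pmin(1, pmax(-1, x))
}

#' Polar representation of a rescaled series
#'
#' Maps each rescaled value to an angle phi = arccos(x~) in \[0, pi\] and
#' each sample index to a radius r = t / N. The radius locates samples
#' along the polar spiral for visualization; only the angles enter the
#' GAF matrix.
#'
#' @param rescaled Numeric vector with values in \[-1, 1\].
#' @return List with `phi` (angles, radians) and `r` (radii, strictly
#'   increasing in (0, 1\]).
#' @export
to_polar <- function(rescaled) {
  n <- length(rescaled)
  list(phi = acos(pmin(1, pmax(-1, rescaled))),
       r = seq_len(n) / n)
}

#' Gramian Angular Field matrix
#'
#' The summation-form GAF: G_ij = cos(phi_i + phi_j) with
#' phi = arccos(x~). The matrix is symmetric with entries in \[-1, 1\] and
#' diagonal 2 x~^2 - 1.
#'
#' @param rescaled Numeric vector with values in \[-1, 1\] (from
#'   [rescale_unit()]).
#' @return N x N numeric matrix.
#' @examples
#' gaf_matrix(c(-1, 0, 1))
#' @export
gaf_matrix <- function(rescaled) {
  phi <- acos(pmin(1, pmax(-1, rescaled)))
  cos(outer(phi, phi, "+"))
}

#' Resample a series to a fixed length
#'
#' Shrinking uses piecewise aggregate approximation (mean per bin);
#' stretching uses linear interpolation. Output values stay within the
#' input range, and a length-preserving call is the identity.
#'
#' @param series Numeric vector, length >= 2.
#' @param n Target length, >= 2.
#' @return Numeric vector of length `n`.
#' @export
resample_fixed <- function(series, n) {
  if (n < 2) stop("target length must be >= 2", call. = FALSE)
  L <- length(series)
  if (L < 2) stop("series must have at least 2 samples", call. = FALSE)
  if (n == L) return(series)
  if (n < L) {
    # fractional-boundary bin means: each sample contributes to a bin in
    # proportion to its overlap, so the series mean is conserved exactly
    b <- seq(0, L, length.out = n + 1)
    vapply(seq_len(n), function(k) {
      i <- (floor(b[k]) + 1):ceiling(b[k + 1])
      w <- pmin(i, b[k + 1]) - pmax(i - 1, b[k])
      sum(w * series[i]) / sum(w)
    }, numeric(1))
  } else {
    stats::approx(seq_len(L), series, n = n)$y
  }
}

#' Quantize GAF values to 8-bit intensities
#'
#' Linear map from \[-1, 1\] to integer intensities \[0, 255\].
#'
#' @param g Numeric array with values in \[-1, 1\].
#' @return Integer array of the same shape.
#' @export
quantize_gaf <- function(g) {
  q <- as.integer(round((g + 1) / 2 * 255))
  q <- pmin(255L, pmax(0L, q))
  array(q, dim = dim(g))
}

#' Compose the three-channel GAF feature image of a step
#'
#' Encodes the three derived signals of a processed step as one RGB
#' feature image: each signal is resampled to the image side, rescaled to
#' \[-1, 1\], GAF-encoded and quantized to 8-bit. The fixed channel map is
#' R = AccXYZ (acceleration magnitude), G = GyrXYZ (angular-velocity
#' magnitude), B = AccFD (forward-direction acceleration).
#'
#' @param step A [preprocess_step()] result.
#' @param side Image side length N (default 64).
#' @return An object of class `gaf_image`: integer array `side x side x 3`
#'   in \[0, 255\] plus the step label.
#' @export
compose_feature_image <- function(step, side = 64) {
  stopifnot(inherits(step, "processed_step"))
  channel <- function(series)
    quantize_gaf(gaf_matrix(rescale_unit(resample_fixed(series, side))))
  img <- array(0L, dim = c(side, side, 3))
  img[, , 1] <- channel(step$acc_xyz)
  img[, , 2] <- channel(step$gyr_xyz)
  img[, , 3] <- channel(step$acc_fd)
  structure(list(intensity = img, label = step$label, side = side),
            class = "gaf_image")
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("<gaf_image> %dx%dx3, label %s\n", x$side, x$side,
              as.character(x$label)))
  invisible(x)
}

#' Encode a dataset as GAF feature images
#'
#' @param dataset A [step_dataset()] (preprocessed internally) or a list
#'   of `processed_step` objects.
#' @param side Image side length.
#' @param cutoff,smooth_width Preprocessing parameters (used when
#'   `dataset` is a `step_dataset`).
#' @return List of [compose_feature_image()] results.
#' @export
encode_dataset <- function(dataset, side = 64, cutoff = 10,
                           smooth_width = 5) {
  steps <- if (inherits(dataset, "step_dataset"))
    preprocess_dataset(dataset, cutoff, smooth_width)
  else dataset
  lapply(steps, compose_feature_image, side = side)
}

#' Export a GAF feature image as PNG
#'
#' Writes the RGB image (or one channel as grayscale) as an 8-bit PNG.
#' Requires the `png` package.
#'
#' @param image A `gaf_image`.
#' @param path Output path.
#' @param channel `NULL` for the RGB image, or 1/2/3 for a single channel
#'   (R = AccXYZ, G = GyrXYZ, B = AccFD) as grayscale.
#' @return `path`, invisibly.
#' @export
write_gaf_png <- function(image, path, channel = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package `png` is required for PNG export", call. = FALSE)
  stopifnot(inherits(image, "gaf_image"))
  a <- if (is.null(channel)) image$intensity / 255
       else image$intensity[, , channel] / 255
  png::writePNG(a, target = path)
  invisible(path)
}
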