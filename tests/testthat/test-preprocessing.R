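test_that("low-pass filter passes DC and low bands, attenuates high bands", {
  fs <- 100
  t <- (0:199) / fs
  expect_equal(lowpass_filter(rep(2.5, 200), fs, 10), rep(2.5, 200),
               tolerance = 1e-6)
  rms <- function(x) sqrt(mean(x^2))
  hi <- sin(2 * pi * 20 * t)
  lo <- sin(2 * pi * 1 * t)
  expect_lt(rms(lowpass_filter(hi, fs, 10)), 0.1 * rms(hi))
  expect_gt(rms(lowpass_filter(lo, fs, 10)), 0.95 * rms(lo))
  # interior (steady-state) attenuation agrees with the squared filter
  # magnitude response: |H(f)|^2 for the forward-backward application
  bf <- signal::butter(4, 10 / (fs / 2), type = "low")
  Hmag2 <- function(f_hz) {
    z <- exp(-1i * 2 * pi * f_hz / fs * (0:4))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }
  mid <- 60:140
  expect_equal(rms(lowpass_filter(hi, fs, 10)[mid]) / rms(hi[mid]),
               Hmag2(20), tolerance = 0.5)
  expect_lt(rms(lowpass_filter(hi, fs, 10)[mid]) / rms(hi[mid]), 0.01)
  expect_equal(rms(lowpass_filter(lo, fs, 10)[mid]) / rms(lo[mid]),
               Hmag2(1), tolerance = 0.01)
  expect_error(lowpass_filter(lo, fs, 60), "cutoff")
  expect_error(lowpass_filter(lo, fs, 0), "cutoff")
})

test_that("pseudo-Gaussian smoothing is a normalized symmetric kernel", {
  expect_equal(pseudo_gaussian_smooth(rep(3, 30), 5), rep(3, 30))
  x <- rnorm(30)
  expect_identical(pseudo_gaussian_smooth(x, 1), x)
  # unit impulse at the centre reproduces the kernel: symmetric bell
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- pseudo_gaussian_smooth(imp, 5)
  expect_equal(which.max(out), 11L)
  expect_equal(out[11 - (1:4)], out[11 + (1:4)])
  expect_true(all(diff(out[9:11]) > 0))
  expect_equal(sum(out), 1)  # kernel weights sum to 1
  # matches explicit kernel convolution away from the boundary
  k <- gaitstep:::gaussian_kernel(5)
  expect_equal(out[9:13], rev(k), tolerance = 1e-12)
  expect_error(pseudo_gaussian_smooth(rnorm(4), 10), "width")
})

test_that("forward-direction selection maximizes mean-removed power", {
  n <- 50
  sq <- rep(c(1, -1), length.out = n)
  triad <- cbind(rep(2, n), sq, rep(-1, n))
  expect_equal(select_forward_direction(triad)$axis, 2L)
  # all equal -> lowest index
  same <- cbind(sq, sq, sq)
  expect_equal(select_forward_direction(same)$axis, 1L)
  # sinusoid amplitudes 0.5 / 1 / 2 -> last axis, matching direct power
  t <- (0:99) / 100
  tri <- cbind(0.5 * sin(2 * pi * 2 * t), 1 * sin(2 * pi * 2 * t),
               2 * sin(2 * pi * 2 * t))
  pw <- apply(tri, 2, function(v) mean((v - mean(v))^2))
  expect_equal(select_forward_direction(tri)$axis, unname(which.max(pw)))
  expect_equal(select_forward_direction(tri)$axis, 3L)
  # invariant to adding a constant offset to any axis (gravity DC)
  tri_dc <- tri
  tri_dc[, 1] <- tri_dc[, 1] + 9.81
  expect_equal(select_forward_direction(tri_dc)$axis, 3L)
})

test_that("magnitude vector is the per-sample Euclidean norm", {
  n <- 25
  expect_equal(magnitude_vector(cbind(rep(3, n), rep(4, n), rep(0, n))),
               rep(5, n))
  expect_equal(magnitude_vector(matrix(0, n, 3)), rep(0, n))
  set.seed(8)
  tri <- matrix(rnorm(3 * n), n, 3)
  brute <- vapply(seq_len(n), function(i) sqrt(sum(tri[i, ]^2)), numeric(1))
  expect_equal(magnitude_vector(tri), brute, tolerance = 1e-12)
  # rotation invariance
  for (r in 1:5) {
    R <- random_rotation()
    expect_equal(magnitude_vector(tri %*% R), magnitude_vector(tri),
                 tolerance = 1e-9)
  }
})

test_that("preprocessing yields the four derived signals with source length", {
  seg <- make_segment(60, seed = 10)
  seg$acc[, 2] <- 3 * sin(2 * pi * 2 * (0:59) / 100)  # dominant power on y
  ps <- preprocess_step(seg)
  expect_equal(ps$fd_axis_acc, 2L)
  for (nm in c("acc_fd", "acc_xyz", "gyr_fd", "gyr_xyz"))
    expect_length(ps[[nm]], length(seg))
  expect_true(all(ps$acc_xyz >= 0) && all(ps$gyr_xyz >= 0))

  const <- make_segment(30, constant = 0)
  const$acc <- matrix(rep(c(1, 2, 2), each = 30), 30, 3)
  ps2 <- preprocess_step(const)
  expect_equal(ps2$acc_xyz, rep(3, 30), tolerance = 1e-6)

  # high-frequency energy above the cutoff is attenuated
  t <- (0:79) / 100
  noisy <- make_segment(80, seed = 11)
  noisy$acc[, 1] <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 30 * t)
  ps3 <- preprocess_step(noisy)
  band_power <- function(x) {
    sp <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) * 100 / length(x)
    sum(sp[f > 15 & f < 50])
  }
  raw_col <- select_forward_direction(noisy$acc)$series
  expect_lt(band_power(ps3$acc_fd), 0.05 * band_power(raw_col))
})
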