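test_that("variation factors follow the N(1, 0.2) law", {
  set.seed(101)
  f <- draw_factor(10000)
  expect_equal(mean(f), 1, tolerance = 0.01)
  expect_equal(sd(f), 0.2, tolerance = 0.01)
  expect_true(all(f > 0))
  ks <- suppressWarnings(stats::ks.test(f, "pnorm", 1, 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("scaling multiplies all elements by one factor", {
  x <- c(1, 2, 3)
  expect_identical(scale_signal(x, 1), x)
  expect_equal(scale_signal(x, 2), c(2, 4, 6))
  expect_length(scale_signal(rnorm(50), 0.7), 50)
})

test_that("jittering applies independent multiplicative noise per element", {
  x <- rnorm(40)
  cfg0 <- augmentation_config(factor_sd = 0)
  expect_equal(jitter_signal(x, cfg0), x)
  expect_equal(jitter_signal(rep(0, 30)), rep(0, 30))
  set.seed(7)
  xs <- rep(2, 10000)
  ratios <- jitter_signal(xs) / xs
  expect_equal(mean(ratios), 1, tolerance = 0.01)
  expect_equal(sd(ratios), 0.2, tolerance = 0.01)
})

test_that("smoothing uses the length/divisor Hann window and keeps length", {
  cfg <- augmentation_config()
  expect_equal(smoothing_window_length(100, cfg, factor = 1), 10L)
  expect_equal(smoothing_window_length(100, cfg, factor = 1.5), 15L)
  expect_equal(smoothing_window_length(100, cfg, factor = 50), 100L)
  x <- rep(4, 100)
  set.seed(2)
  expect_equal(smooth_signal(x), x)
  # a 25 Hz tone at 100 Hz sampling loses energy through a 10-sample window
  t <- (0:99) / 100
  tone <- sin(2 * pi * 25 * t)
  out <- smooth_signal(tone, cfg, factor = 1)
  expect_length(out, 100)
  expect_lt(sqrt(mean(out^2)), sqrt(mean(tone^2)))
})

test_that("downsampling keeps one common uniform index set across signals", {
  set.seed(31)
  L <- 100
  m <- matrix(seq_len(6 * L), L, 6)  # distinct values identify indices
  out <- downsample_signal(m)
  expect_lt(nrow(out), L)
  expect_gte(nrow(out), 4)
  # same retained rows for all six columns
  rows <- out[, 1]
  for (j in 2:6) expect_equal(out[, j], m[rows, j])
  # each output is a strictly increasing subsequence of its input
  expect_true(all(diff(rows) > 0))
  expect_true(all(out[, 3] %in% m[, 3]))
  expect_true(min(out[, 5]) >= min(m[, 5]) && max(out[, 5]) <= max(m[, 5]))
  # deterministic under a fixed seed
  set.seed(99); a <- downsample_signal(m)
  set.seed(99); b <- downsample_signal(m)
  expect_identical(a, b)
})

test_that("cutting removes edge frames, keeping a contiguous block", {
  set.seed(17)
  L <- 100
  m <- matrix(seq_len(6 * L), L, 6)
  out <- cut_signal(m)
  n_remove <- L - nrow(out)
  expect_gte(nrow(out), 4)
  # contiguity: output equals input[from:to] with the asymmetric edge rule
  from <- ceiling(n_remove / 2) + 1
  expect_equal(out, m[from:(from + nrow(out) - 1), ])
  # factor 1 on length 100 removes 10 frames (the length/10 edge rule)
  cfg <- augmentation_config(factor_sd = 0)
  out2 <- cut_signal(m, cfg)
  expect_equal(nrow(out2), 90)
  expect_equal(out2, m[6:95, ])
})

test_that("augment_step honours the DMM/DMF contracts", {
  seg <- make_segment(60, label = "up_stairs", seed = 5)
  for (tech in c("scaling", "jittering", "smoothing")) {
    out <- augment_step(seg, tech)
    expect_equal(length(out), length(seg))  # DMM preserves length
    expect_identical(as.character(out$label), "up_stairs")
    expect_identical(out$provenance, "synthetic")
  }
  for (tech in c("downsampling", "cutting")) {
    out <- augment_step(seg, tech)
    expect_lte(length(out), length(seg))
    for (j in 1:3) {  # DMF values all exist in the source axis
      expect_true(all(out$acc[, j] %in% seg$acc[, j]))
      expect_true(all(out$gyr[, j] %in% seg$gyr[, j]))
    }
  }
  # degenerate scaling: sd 0 gives factor exactly 1 -> values unchanged
  out <- augment_step(seg, "scaling", config = augmentation_config(factor_sd = 0))
  expect_equal(out$acc, seg$acc)
  expect_identical(out$provenance, "synthetic")
  # stochastic operators are reproducible bit-for-bit under a fixed seed
  for (tech in augmentation_techniques()) {
    set.seed(55); a <- augment_step(seg, tech)
    set.seed(55); b <- augment_step(seg, tech)
    expect_identical(a, b)
  }
})

test_that("augmentation balancing reaches the majority count, keeping originals", {
  d <- make_dataset(c(down_incline = 3, up_incline = 7, level = 12,
                      down_stairs = 5, up_stairs = 6), n = 30, seed = 9)
  set.seed(1)
  out <- balance_by_augmentation(d)
  h <- class_histogram(out)
  expect_true(all(h == 12))
  expect_equal(sum(h), 60L)
  # originals are retained unmodified at the head of the dataset
  expect_identical(out$segments[seq_along(d$segments)], d$segments)
  # synthetic additions are marked as such
  prov <- vapply(out$segments, `[[`, character(1), "provenance")
  expect_true(all(prov[-seq_along(d$segments)] == "synthetic"))
  # two-class arithmetic: {3, 5} -> {5, 5}
  d2 <- make_dataset(c(level = 3, up_stairs = 5), n = 20)
  h2 <- class_histogram(balance_by_augmentation(d2))
  expect_equal(unname(h2[c("level", "up_stairs")]), c(5L, 5L))
  # already balanced dataset: zero synthetic instances
  bal <- make_dataset(stats::setNames(rep(3, 5), gait_activities()), n = 20)
  expect_equal(length(balance_by_augmentation(bal)), length(bal))
  # cannot synthesize from nothing
  expect_error(balance_by_augmentation(step_dataset()), "empty dataset")
})

test_that("subsampling reaches the minority count deterministically", {
  d <- make_dataset(c(down_incline = 9, up_incline = 7, level = 20,
                      down_stairs = 4, up_stairs = 6), n = 25, seed = 3)
  set.seed(10)
  out <- subsample_to_minority(d)
  expect_true(all(class_histogram(out) == 4))
  set.seed(77); a <- subsample_to_minority(d)
  set.seed(77); b <- subsample_to_minority(d)
  expect_identical(a, b)
  # already balanced input keeps its counts
  bal <- make_dataset(stats::setNames(rep(4, 5), gait_activities()), n = 20)
  expect_true(all(class_histogram(subsample_to_minority(bal)) == 4))
})

test_that("treatment plans and realized treatments agree", {
  d <- make_dataset(c(down_incline = 6, up_incline = 5, level = 14,
                      down_stairs = 4, up_stairs = 5), n = 30, seed = 12)
  h <- class_histogram(d)
  for (tr in c("unbalanced", "sampled", "augmented")) {
    plan <- treatment_plan(h, tr)
    set.seed(8)
    realized <- class_histogram(apply_treatment(d, tr))
    expect_equal(as.numeric(realized), unname(plan$target), label = tr)
    expect_equal(sum(realized), plan$total)
  }
  expect_identical(apply_treatment(d, "unbalanced"), d)
})
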