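test_that("F-measure is the harmonic mean with the zero convention", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(0.5, 0.5), 0.5)
  p <- 0.8; r <- 0.4
  expect_equal(f_measure(p, r), 2 * p * r / (p + r))
  expect_error(f_measure(1.2, 0.5))
})

test_that("classification reports populate every aggregate consistently", {
  set.seed(40)
  truth <- sample(gait_activities(), 200, replace = TRUE,
                  prob = c(0.13, 0.12, 0.63, 0.06, 0.06))
  pred <- truth
  flip <- sample(200, 60)
  pred[flip] <- sample(gait_activities(), 60, replace = TRUE)
  rep <- classification_report(truth, pred)
  expect_equal(sum(rep$support), 200L)
  expect_equal(rowSums(rep$confusion), as.numeric(rep$support),
               ignore_attr = TRUE)
  # micro-averaged recall equals accuracy for single-label problems
  expect_equal(sum(rep$recall * rep$support) / sum(rep$support),
               rep$accuracy, tolerance = 1e-12)
  # stored aggregates equal recomputed ones
  expect_equal(unname(rep$macro_avg["f_measure"]), mean(rep$f_measure))
  expect_equal(unname(rep$weighted_avg["f_measure"]),
               sum(rep$f_measure * rep$support) / sum(rep$support))
  expect_equal(rep$f_sigma,
               sqrt(mean((rep$f_measure - mean(rep$f_measure))^2)))
  # permutation invariance
  ord <- sample(200)
  rep2 <- classification_report(truth[ord], pred[ord])
  expect_equal(rep2$confusion, rep$confusion)
  expect_equal(rep2$f_measure, rep$f_measure)
  # degenerate cases
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f_sigma, 0)
  expect_true(all(diag(perfect$confusion) == perfect$support))
  const <- classification_report(truth, rep("level", 200))
  expect_equal(unname(const$recall["level"]), 1)
  expect_equal(unname(const$recall["up_stairs"]), 0)
  expect_true(const$zero_division)
  expect_error(classification_report(truth, pred[1:10]), "equal length")
})

test_that("normalized confusion rows sum to one except empty classes", {
  truth <- c("level", "level", "up_stairs", "down_stairs")
  pred <- c("level", "up_stairs", "up_stairs", "level")
  cm <- confusion_matrix(truth, pred, normalized = TRUE)
  rs <- rowSums(cm)
  expect_equal(unname(rs[c("level", "up_stairs", "down_stairs")]),
               c(1, 1, 1))
  expect_equal(unname(rs[c("down_incline", "up_incline")]), c(0, 0))
})

test_that("attraction index flags over- and under-predicted classes", {
  # toy problem over three classes with hand-computed column sums:
  # normalized rows: level -> (0.5 level, 0.5 up_stairs),
  # up_stairs -> all up_stairs, down_stairs -> all up_stairs
  truth <- c("level", "level", "up_stairs", "down_stairs")
  pred <- c("level", "up_stairs", "up_stairs", "up_stairs")
  ai <- attraction_index(confusion_matrix(truth, pred))
  expect_equal(unname(ai["up_stairs"]), 0.5 + 1 + 1 - 1)  # strong attractor
  expect_equal(unname(ai["level"]), 0.5 - 1)              # repeller
  expect_equal(unname(ai["down_stairs"]), -1)             # never predicted
})

test_that("report comparison summarizes per-class F distributions", {
  mk_rep <- function(f) {
    structure(list(classes = gait_activities(),
                   f_measure = stats::setNames(f, gait_activities()),
                   accuracy = mean(f),
                   f_sigma = sqrt(mean((f - mean(f))^2))),
              class = "evaluation_report")
  }
  a <- mk_rep(rep(0.9, 5)); b <- mk_rep(rep(0.5, 5))
  cmp <- compare_reports(list(A = a, B = b))
  expect_equal(cmp$median_f[1] - cmp$median_f[2], 0.4)
  same <- compare_reports(list(x = a, y = a))
  expect_equal(same$median_f[1], same$median_f[2])
  expect_equal(same$f_sigma[1], same$f_sigma[2])
  expect_error(compare_reports(list(a)), "at least two")
})

test_that("reports serialize to JSON and read back consistently", {
  truth <- sample(gait_activities(), 50, replace = TRUE)
  pred <- sample(gait_activities(), 50, replace = TRUE)
  rep <- classification_report(truth, pred,
                               metadata = list(algorithm = "svm", seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$f_measure, unname(rep$f_measure))
  expect_equal(back$metadata$algorithm, "svm")
})
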