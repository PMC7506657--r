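tiny_config <- function(side = 8, epochs = 2, seed = 5, lr = 1e-3)
  cnn_config(side = side, conv_channels = c(2, 2, 2, 2, 2), fc_width = 8,
             epochs = epochs, batch_size = 8, learning_rate = lr,
             val_fraction = 0, seed = seed)

# distinct deterministic base pattern per class, plus pixel noise
tiny_images <- function(n_per_class, side = 8, seed = 1, noise = 0.05) {
  set.seed(seed)
  base <- lapply(1:5, function(k) {
    g <- outer(seq_len(side), seq_len(side), function(i, j)
      sin(k * i / side * pi) * cos(k * j / side * pi))
    array(rep((g + 1) / 2, 3), dim = c(side, side, 3))
  })
  imgs <- list()
  for (k in 1:5) {
    for (r in seq_len(n_per_class)) {
      a <- base[[k]] + array(rnorm(side * side * 3, 0, noise),
                             c(side, side, 3))
      a <- pmin(pmax(a, 0), 1)
      imgs[[length(imgs) + 1L]] <- structure(
        list(intensity = array(as.integer(round(a * 255)),
                               c(side, side, 3)),
             label = parse_activity(gait_activities()[k]), side = side),
        class = "gaf_image")
    }
  }
  imgs
}

test_that("the model maps images to five class scores with a fixed census", {
  m <- build_model(cnn_config(side = 32))
  expect_equal(sum(grepl("^w[1-5]$", names(m$params))), 5L)  # 5 conv layers
  expect_equal(ncol(m$params$W7), 5L)                        # 5-way output
  expect_equal(dim(m$params$w1), c(3, 3, 3, 16))
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- gaitstep:::cnn_forward(m$params, x)
  expect_equal(dim(out$logits), c(5, 2))
  # three poolings: flattened width is (side/8)^2 * last channels
  expect_equal(nrow(m$params$W6), (32 / 8)^2 * 64)
  expect_error(cnn_config(side = 30), "divisible by 8")
  # identical seeds give identical initial parameters
  m2 <- build_model(cnn_config(side = 32))
  expect_identical(m$params, m2$params)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  set.seed(2)
  x <- array(runif(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  y <- c(1L, 3L, 5L, 2L)
  lg <- gaitstep:::cnn_loss_grad(m$params, x, y)
  loss_at <- function(params) {
    fw <- gaitstep:::cnn_forward(params, x)
    p <- gaitstep:::softmax_cols(fw$logits)
    -mean(log(p[cbind(y, 1:4)] + 1e-12))
  }
  eps <- 1e-5
  for (nm in c("w1", "w3", "w5", "W6", "W7", "b2", "b7")) {
    idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("stratified splitting gives rounded per-class shares", {
  imgs <- tiny_images(20, side = 8, seed = 3)
  sp <- split_train_test(imgs, 0.8, seed = 1)
  lab <- function(xs) table(factor(vapply(xs, function(i)
    as.character(i$label), character(1)), levels = gait_activities()))
  expect_true(all(lab(sp$train) == 16))
  expect_true(all(lab(sp$test) == 4))
  expect_equal(length(sp$train) + length(sp$test), 100L)
  # disjoint and exhaustive by construction of index complement
  expect_error(split_train_test(imgs, 1.0), "strictly between")
  # non-stratified split still partitions the data
  sp2 <- split_train_test(imgs, 0.8, seed = 1, stratified = FALSE)
  expect_equal(length(sp2$train), 80L)
})

test_that("training reduces loss on separable images and is reproducible", {
  imgs <- tiny_images(10, seed = 7)
  cfg <- tiny_config(epochs = 5, lr = 3e-3)
  m <- train_cnn(build_model(cfg), imgs)
  expect_equal(nrow(m$trace), 5L)
  expect_lt(m$trace$train_loss[5], m$trace$train_loss[1])
  m2 <- train_cnn(build_model(cfg), imgs)
  expect_identical(m$trace, m2$trace)
  expect_identical(m$params, m2$params)
  # zero learning rate freezes the parameters and the loss
  m0 <- train_cnn(build_model(tiny_config(epochs = 3, lr = 0)), imgs)
  expect_lt(diff(range(m0$trace$train_loss)), 1e-6)
})

test_that("evaluation reports cover the full test set", {
  imgs <- tiny_images(8, seed = 9)
  m <- train_cnn(build_model(tiny_config(epochs = 2)), imgs)
  r <- evaluate_model(m, imgs)
  expect_s3_class(r, "evaluation_report")
  expect_equal(sum(r$support), length(imgs))
  expect_true(all(abs(rowSums(confusion_matrix(
    rep(gait_activities(), each = 8),
    predict(m, imgs), normalized = TRUE)) - 1) < 1e-9))
  expect_error(evaluate_model(m, list()), "empty test set")
})
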