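#' Configuration of the convolutional classifier
#'
#' The network maps an N x N x 3 GAF feature image to scores over the
#' five activities through five 3x3 convolution layers with rectified
#' linear activations, three 2x2 max-pooling layers (after convolutions
#' 1, 3 and 5, so the side must be divisible by 8) and two fully connected
#' layers. Training minimizes softmax cross-entropy with Adam.
#'
#' @param side Image side N; must be divisible by 8.
#' @param conv_channels Output channels of the five convolution layers.
#' @param fc_width Width of the hidden fully connected layer.
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of the training set held out for the
#'   per-epoch validation-loss trace.
#' @param seed Integer seed for initialization, shuffling and the
#'   validation split.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(side = 64, conv_channels = c(16, 32, 32, 64, 64),
                       fc_width = 128, epochs = 30, batch_size = 32,
                       learning_rate = 1e-3, val_fraction = 0.1,
                       seed = 1) {
  if (side %% 8 != 0)
    stop("image side must be divisible by 8 (three 2x2 poolings)",
         call. = FALSE)
  if (length(conv_channels) != 5)
    stop("conv_channels must name five layers", call. = FALSE)
  structure(list(side = as.integer(side),
                 conv_channels = as.integer(conv_channels),
                 fc_width = as.integer(fc_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

#' Build the convolutional classifier
#'
#' Initializes all parameters (He-scaled Gaussian weights, zero biases)
#' deterministically from the config seed. The layer census of the
#' returned model is fixed: 5 convolution + ReLU, 3 max-pooling, 2 fully
#' connected.
#'
#' @param config A [cnn_config()].
#' @return An object of class `gait_cnn`.
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  set.seed(config$seed)
  ch <- c(3L, config$conv_channels)
  params <- list()
  for (l in 1:5) {
    fan_in <- 9 * ch[l]
    params[[paste0("w", l)]] <- he_init(c(3, 3, ch[l], ch[l + 1]), fan_in)
    params[[paste0("b", l)]] <- numeric(ch[l + 1])
  }
  flat <- (config$side / 8)^2 * config$conv_channels[5]
  params$W6 <- matrix(stats::rnorm(flat * config$fc_width, 0,
                                   sqrt(2 / flat)),
                      flat, config$fc_width)
  params$b6 <- numeric(config$fc_width)
  params$W7 <- matrix(stats::rnorm(config$fc_width * 5, 0,
                                   sqrt(2 / config$fc_width)),
                      config$fc_width, 5)
  params$b7 <- numeric(5)
  structure(list(config = config, params = params, trained = FALSE),
            class = "gait_cnn")
}

#' @export
print.gait_cnn <- function(x, ...) {
  cat(sprintf(paste0("<gait_cnn> side %d: 5 conv (%s) + ReLU, ",
                     "3 max-pool 2x2, FC %d -> 5%s\n"),
              x$config$side,
              paste(x$config$conv_channels, collapse = ","),
              x$config$fc_width,
              if (x$trained) " [trained]" else ""))
  invisible(x)
}

#' Stack GAF images into a training batch array
#'
#' @param images List of [compose_feature_image()] results with a common
#'   side.
#' @return List with `x` (array side x side x 3 x N of intensities scaled
#'   to \[0, 1\]) and `y` (factor of labels).
#' @export
images_to_batch <- function(images) {
  side <- images[[1]]$side
  n <- length(images)
  x <- array(0, dim = c(side, side, 3, n))
  for (i in seq_len(n)) x[, , , i] <- images[[i]]$intensity / 255
  y <- factor(vapply(images, function(im) as.character(im$label),
                     character(1)),
              levels = GAIT_ACTIVITIES)
  list(x = x, y = y)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

cnn_forward <- function(params, x, keep = FALSE) {
  cache <- if (keep) list(a0 = x) else NULL
  a <- x
  pool_after <- c(1, 3, 5)
  for (l in 1:5) {
    z <- conv_forward(a, params[[paste0("w", l)]], params[[paste0("b", l)]])
    a <- relu(z)
    if (keep) cache[[paste0("a", l)]] <- a
    if (l %in% pool_after) {
      pl <- maxpool_forward(a)
      a <- pl$y
      if (keep) {
        cache[[paste0("pool_arg", l)]] <- pl$argmax
        cache[[paste0("p", l)]] <- a
      }
    }
  }
  n <- dim(a)[4]
  flat <- matrix(a, ncol = n)
  z6 <- crossprod(params$W6, flat) + params$b6
  a6 <- relu(z6)
  z7 <- crossprod(params$W7, a6) + params$b7
  if (keep) {
    cache$flat <- flat
    cache$flat_dim <- dim(a)
    cache$a6 <- a6
  }
  list(logits = z7, cache = cache)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss and full parameter gradient for one minibatch
cnn_loss_grad <- function(params, x, y_idx) {
  fw <- cnn_forward(params, x, keep = TRUE)
  cache <- fw$cache
  n <- length(y_idx)
  p <- softmax_cols(fw$logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(y_idx, seq_len(n))] + eps))
  dz7 <- p
  dz7[cbind(y_idx, seq_len(n))] <- dz7[cbind(y_idx, seq_len(n))] - 1
  dz7 <- dz7 / n
  grads <- list()
  grads$W7 <- cache$a6 %*% t(dz7)
  grads$b7 <- rowSums(dz7)
  da6 <- params$W7 %*% dz7
  dz6 <- da6 * (cache$a6 > 0)
  grads$W6 <- cache$flat %*% t(dz6)
  grads$b6 <- rowSums(dz6)
  dflat <- params$W6 %*% dz6
  da <- array(dflat, dim = cache$flat_dim)
  pool_after <- c(1, 3, 5)
  for (l in 5:1) {
    if (l %in% pool_after) {
      da <- maxpool_backward(cache[[paste0("pool_arg", l)]], da,
                             dim(cache[[paste0("a", l)]]))
    }
    dz <- da * (cache[[paste0("a", l)]] > 0)
    below <- if (l == 1) cache$a0 else {
      if ((l - 1) %in% pool_after) cache[[paste0("p", l - 1)]]
      else cache[[paste0("a", l - 1)]]
    }
    bw <- conv_backward(below, params[[paste0("w", l)]], dz)
    grads[[paste0("w", l)]] <- bw$dw
    grads[[paste0("b", l)]] <- bw$db
    da <- bw$dx
  }
  list(loss = loss, grads = grads)
}

cnn_batch_loss <- function(params, x, y_idx, batch = 64) {
  n <- length(y_idx)
  total <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- cnn_forward(params, x[, , , idx, drop = FALSE])
    p <- softmax_cols(fw$logits)
    total <- total -
      sum(log(p[cbind(y_idx[idx], seq_along(idx))] + 1e-12))
  }
  total / n
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Stratified train/test split of GAF images
#'
#' With `stratified = TRUE` (default) the per-class training share is
#' round(fraction x class count), so test supports follow per-class 20
#' percent rounding under the default fraction; with `stratified = FALSE`
#' a single uniform draw over all instances is used. Train and test are
#' disjoint and exhaustive.
#'
#' @param images List of [compose_feature_image()] results.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify the split by class.
#' @return List with `train` and `test` image lists.
#' @export
split_train_test <- function(images, fraction = 0.8, seed = 1,
                             stratified = TRUE) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1 ",
         "(both partitions must be non-empty)", call. = FALSE)
  labels <- factor(vapply(images, function(im) as.character(im$label),
                          character(1)),
                   levels = GAIT_ACTIVITIES)
  h <- table(labels)
  low <- names(h)[h > 0 & h < 2]
  if (length(low) > 0)
    stop("class(es) with fewer than 2 instances: ",
         paste(low, collapse = ", "), call. = FALSE)
  set.seed(seed)
  if (stratified) {
    train_idx <- unlist(lapply(levels(labels), function(cl) {
      pool <- which(labels == cl)
      if (length(pool) == 0) return(integer(0))
      k <- round(fraction * length(pool))
      k <- min(max(k, 1L), length(pool) - 1L)
      sample(pool, k)
    }))
  } else {
    k <- round(fraction * length(images))
    k <- min(max(k, 1L), length(images) - 1L)
    train_idx <- sample(seq_along(images), k)
  }
  train_idx <- sort(train_idx)
  list(train = images[train_idx], test = images[-train_idx])
}

#' Train the convolutional classifier
#'
#' Minibatch Adam on softmax cross-entropy for `config$epochs` epochs. A
#' stratified `val_fraction` of the training images is held out for the
#' per-epoch validation-loss trace; the remainder is shuffled each epoch.
#' Training is reproducible bit-for-bit under a fixed seed. A non-finite
#' loss aborts with diagnostics.
#'
#' @param model A [build_model()] result.
#' @param images Training images (list of [compose_feature_image()]).
#' @param verbose Print the per-epoch losses.
#' @return The trained `gait_cnn` with a `trace` data frame (epoch,
#'   train_loss, val_loss).
#' @export
train_cnn <- function(model, images, verbose = FALSE) {
  stopifnot(inherits(model, "gait_cnn"))
  if (length(images) == 0) stop("empty training set", call. = FALSE)
  config <- model$config
  set.seed(config$seed)
  labels <- factor(vapply(images, function(im) as.character(im$label),
                          character(1)),
                   levels = GAIT_ACTIVITIES)
  n <- length(images)
  n_val <- round(config$val_fraction * n)
  val_idx <- if (n_val > 0 && n - n_val > 0)
    sort(sample(seq_len(n), n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  btr <- images_to_batch(images[tr_idx])
  y_tr <- as.integer(btr$y)
  if (length(val_idx) > 0) {
    bval <- images_to_batch(images[val_idx])
    y_val <- as.integer(bval$y)
  }
  params <- model$params
  state <- adam_init(params)
  trace <- data.frame(epoch = seq_len(config$epochs),
                      train_loss = NA_real_, val_loss = NA_real_)
  ntr <- length(tr_idx)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(ntr)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, ntr)]
      lg <- cnn_loss_grad(params, btr$x[, , , idx, drop = FALSE],
                          y_tr[idx])
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", ep,
             " (batch starting at ", start, "); lower the learning rate",
             call. = FALSE)
      st <- adam_step(params, lg$grads, state, config$learning_rate)
      params <- st$params
      state <- st$state
      ep_loss <- ep_loss + lg$loss * length(idx)
      nb <- nb + length(idx)
    }
    trace$train_loss[ep] <- ep_loss / nb
    trace$val_loss[ep] <- if (length(val_idx) > 0)
      cnn_batch_loss(params, bval$x, y_val) else NA_real_
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep,
                      trace$train_loss[ep], trace$val_loss[ep]))
  }
  model$params <- params
  model$trace <- trace
  model$trained <- TRUE
  model
}

#' Predict activity labels for GAF images
#'
#' @param object A trained `gait_cnn`.
#' @param newdata List of GAF images (or a batch from
#'   [images_to_batch()]).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.gait_cnn <- function(object, newdata, batch_size = 64, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x
       else images_to_batch(newdata)$x
  if (dim(x)[1] != object$config$side)
    stop("image side mismatch: model expects ", object$config$side,
         call. = FALSE)
  n <- dim(x)[4]
  pred <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- cnn_forward(object$params, x[, , , idx, drop = FALSE])
    pred[idx] <- apply(fw$logits, 2, which.max)
  }
  factor(GAIT_ACTIVITIES[pred], levels = GAIT_ACTIVITIES)
}

#' Evaluate a trained CNN on test images
#'
#' @param model A trained `gait_cnn`.
#' @param test_images List of GAF images.
#' @param metadata Optional metadata recorded in the report.
#' @return A [classification_report()].
#' @export
evaluate_model <- function(model, test_images, metadata = list()) {
  if (length(test_images) == 0)
    stop("empty test set", call. = FALSE)
  truth <- factor(vapply(test_images, function(im) as.character(im$label),
                         character(1)),
                  levels = GAIT_ACTIVITIES)
  pred <- predict(model, test_images)
  classification_report(truth, pred,
                        metadata = c(list(model = "cnn",
                                          side = model$config$side,
                                          epochs = model$config$epochs),
                                     metadata))
}
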