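# fixtures built in code: tiny deterministic segments and datasets

make_segment <- function(n = 20, label = "level", provenance = "synthetic",
                         seed = NULL, constant = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(constant)) {
    acc <- matrix(constant, n, 3)
    gyr <- matrix(constant, n, 3)
  } else {
    acc <- matrix(stats::rnorm(n * 3, 0, 0.5), n, 3)
    gyr <- matrix(stats::rnorm(n * 3, 0, 50), n, 3)
  }
  step_segment(acc, gyr, label = label, provenance = provenance)
}

make_dataset <- function(counts, n = 20, seed = 1) {
  set.seed(seed)
  segs <- list()
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]]))
      segs[[length(segs) + 1L]] <- make_segment(n, label = cl)
  }
  step_dataset(segs)
}

# processed step with prescribed series, bypassing filtering
make_processed <- function(acc_fd, acc_xyz = abs(acc_fd),
                           gyr_fd = acc_fd, gyr_xyz = abs(acc_fd),
                           label = "level") {
  structure(list(acc_fd = acc_fd, acc_xyz = acc_xyz, gyr_fd = gyr_fd,
                 gyr_xyz = gyr_xyz, fd_axis_acc = 1L, fd_axis_gyr = 1L,
                 label = parse_activity(label), sampling_rate = 100,
                 source = NULL),
            class = "processed_step")
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(m))
}
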