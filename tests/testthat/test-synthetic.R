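test_that("noise-free single-harmonic windows are bounded unit sinusoids and generation is deterministic", {
  spec <- synthetic_spec(n_classes = 2, n_subjects = 3, windows_per_class = 5,
                         channels = 2, window_length = 128, sample_rate = 32,
                         class_params = list(
                           list(base_freq_hz = 1, amplitude = 1,
                                harmonic_weights = 1, noise_sd = 0),
                           list(base_freq_hz = 2, amplitude = 1,
                                harmonic_weights = 1, noise_sd = 0)),
                         subject_jitter = 0, seed = 3)
  ds <- generate_activity_dataset(spec)
  expect_equal(dim(ds$windows), c(10, 2, 128))
  expect_lte(max(abs(ds$windows)), 1)
  # exact periodicity at the class frequency (32 Hz, 1 Hz -> period 32)
  w <- ds$windows[1, 1, ]
  expect_equal(w[1:96], w[33:128], tolerance = 1e-12)
  ds2 <- generate_activity_dataset(spec)
  expect_identical(ds$windows, ds2$windows)
  expect_identical(ds$labels, ds2$labels)
})

test_that("class counts, labels and subjects come out exactly as requested, including imbalance", {
  spec <- tiny_spec(windows_per_class = 10)
  spec$windows_per_class <- c(10L, 4L, 7L)
  ds <- generate_activity_dataset(spec)
  expect_equal(as.vector(table(ds$labels)), c(10, 4, 7))
  expect_true(all(ds$labels %in% 0:2))
  expect_true(all(ds$subject_ids %in% 1:4))
})

test_that("a dominant-frequency nearest-centroid classifier separates the generated classes", {
  # independent oracle: argmax of the FFT magnitude, nearest class frequency
  spec <- synthetic_spec(n_classes = 3, n_subjects = 5,
                         windows_per_class = 40, channels = 1,
                         window_length = 256, sample_rate = 32,
                         class_params = lapply(c(1, 2, 4), function(f)
                           list(base_freq_hz = f, amplitude = 1,
                                harmonic_weights = 1, noise_sd = 0.05)),
                         subject_jitter = 0.02, seed = 21)
  ds <- generate_activity_dataset(spec)
  n <- dim(ds$windows)[1]
  Tn <- dim(ds$windows)[3]
  freqs <- (seq_len(Tn %/% 2)) * spec$sample_rate / Tn
  pred <- vapply(seq_len(n), function(i) {
    mag <- Mod(stats::fft(ds$windows[i, 1, ]))[2:(Tn %/% 2 + 1)]
    fdom <- freqs[which.max(mag)]
    which.min(abs(fdom - c(1, 2, 4))) - 1L
  }, 0L)
  expect_gt(mean(pred == ds$labels), 0.9)
})

test_that("generator validates its specification with the offending field named", {
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(synthetic_spec(window_length = 4), "window_length")
  expect_error(synthetic_spec(
    n_classes = 2,
    class_params = list(list(base_freq_hz = 1, amplitude = 0,
                             harmonic_weights = 1, noise_sd = 0),
                        list(base_freq_hz = 2, amplitude = 1,
                             harmonic_weights = 1, noise_sd = 0))),
    "amplitude")
  expect_error(synthetic_spec(n_classes = 3, windows_per_class = c(1, 2)),
               "windows_per_class")
})

test_that("segmentation follows the stride convention, drops the remainder, and matches brute force", {
  s <- matrix(seq_len(188), nrow = 1)
  ws <- segment_series(s, window = 100, overlap = 78)
  expect_equal(dim(ws$windows)[1], 5)
  expect_equal(ws$meta$starts, c(0, 22, 44, 66, 88))
  expect_equal(ws$windows[2, 1, 1], 23)  # start 22, 1-based value

  ws2 <- segment_series(matrix(rnorm(1500), 1), window = 500, overlap = 0)
  expect_equal(dim(ws2$windows)[1], 3)

  expect_warning(ws3 <- segment_series(matrix(0, 1, 99), window = 100),
                 "0 windows")
  expect_equal(dim(ws3$windows)[1], 0)

  # property: count formula equals brute-force start enumeration
  set.seed(5)
  for (i in 1:25) {
    Tn <- sample(10:300, 1)
    win <- sample(2:Tn, 1)
    ov <- sample(0:(win - 1), 1)
    stride <- win - ov
    expected <- length(seq(0, Tn - win, by = stride))
    got <- dim(segment_series(matrix(0, 1, Tn), win, ov)$windows)[1]
    expect_equal(got, expected, info = sprintf("T=%d w=%d o=%d", Tn, win, ov))
  }
})

test_that("rate downsampling preserves constants, endpoints and linear ramps", {
  expect_equal(downsample_rate(rep(3, 1000), 100, 33), rep(3, 330))
  ramp <- seq(0, 1, length.out = 1000)
  out <- downsample_rate(ramp, 100, 33)
  expect_equal(length(out), 330)
  expect_equal(out, seq(0, 1, length.out = 330), tolerance = 1e-12)
  expect_error(downsample_rate(ramp, 0, 33), "positive")
  expect_error(downsample_rate(ramp, 33, 100), "below")
})

test_that("leave-one-subject-out folds form an exact partition", {
  ds <- tiny_dataset(n_subjects = 4, windows_per_class = 8)
  folds <- make_loso_splits(ds)
  expect_length(folds, 4)
  n <- dim(ds$windows)[1]
  seen <- integer(0)
  for (f in folds) {
    expect_false(any(f$test$subject_ids != f$subject))
    expect_false(f$subject %in% f$train$subject_ids)
    expect_equal(dim(f$train$windows)[1] + dim(f$test$windows)[1], n)
    # identify test windows by their content signature
    seen <- c(seen, which(ds$subject_ids == f$subject))
  }
  expect_equal(sort(seen), seq_len(n))
  one <- subset_window_set(ds, ds$subject_ids == 1)
  expect_error(make_loso_splits(one), "subjects")
})

test_that("window sets survive a write/read round trip", {
  ds <- tiny_dataset(windows_per_class = 4)
  dir <- file.path(tempdir(), "ws_roundtrip")
  write_window_set(ds, dir)
  back <- read_window_set(dir)
  expect_equal(back$windows, ds$windows)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$subject_ids, ds$subject_ids)
  unlink(dir, recursive = TRUE)
})
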