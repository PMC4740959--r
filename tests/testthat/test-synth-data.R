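test_that("EEG-like generator matches the printed segment geometry", {
  ds <- gen_eeg_like(3, duration_s = 23.6, fs = 173.61, seed = 1)
  expect_length(ds$segments, 6L)
  expect_true(all(vapply(ds$segments, ncol, integer(1)) == 4097L))
  expect_true(all(vapply(ds$segments, nrow, integer(1)) == 1L))
  expect_identical(sort(unique(ds$labels)), c(0L, 1L))
})

test_that("EEG burst class dominates the background class in variance", {
  ds <- gen_eeg_like(8, duration_s = 6, fs = 173.61, seed = 2)
  v <- vapply(ds$segments, function(s) stats::var(as.numeric(s)),
              numeric(1))
  v0 <- v[ds$labels == 0]
  v1 <- v[ds$labels == 1]
  expect_true(all(outer(v1, v0, ">")))     # every pair ordered
  # the ~3 Hz rhythmic component of burst segments has amplitude at least
  # 3x the background scale (narrowband extraction by FFT masking)
  narrowband <- function(s, fs, lo, hi) {
    x <- as.numeric(s)
    n <- length(x)
    sp <- stats::fft(x)
    f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
    sp[f < lo | f > hi] <- 0
    Re(stats::fft(sp, inverse = TRUE)) / n
  }
  burst_amp <- vapply(ds$segments[ds$labels == 1], function(s)
    max(abs(narrowband(s, ds$fs, 2, 4))), numeric(1))
  bg_scale <- vapply(ds$segments[ds$labels == 0], function(s)
    stats::sd(as.numeric(s)), numeric(1))
  expect_gt(min(burst_amp) / max(bg_scale), 3)
  expect_true(all(vapply(ds$segments, function(s) all(is.finite(s)),
                         logical(1))))
})

test_that("generators are deterministic in the seed", {
  a <- gen_eeg_like(4, duration_s = 3, fs = 173.61, seed = 7)
  b <- gen_eeg_like(4, duration_s = 3, fs = 173.61, seed = 7)
  expect_identical(a$segments, b$segments)
  c_ <- gen_eeg_like(4, duration_s = 3, fs = 173.61, seed = 8)
  expect_false(identical(a$segments, c_$segments))
  e1 <- gen_emg_like(2, 3, 4, duration_s = 2, fs = 1200, seed = 5)
  e2 <- gen_emg_like(2, 3, 4, duration_s = 2, fs = 1200, seed = 5)
  expect_identical(e1$segments, e2$segments)
})

test_that("EMG-like generator respects counts, band, and ADC range", {
  ds <- gen_emg_like(3, 5, 8, duration_s = 2, fs = 4000, seed = 9)
  expect_length(ds$segments, 15L)
  expect_identical(as.integer(table(ds$labels)), rep(3L, 5L))
  expect_true(all(vapply(ds$segments, nrow, integer(1)) == 8L))
  expect_true(all(vapply(ds$segments, ncol, integer(1)) == 8000L))
  # 12-bit integer range
  allv <- unlist(ds$segments)
  expect_true(all(allv == round(allv)))
  expect_true(all(abs(allv) <= 2047))
  # spectral mass outside 20-450 Hz below 5 percent per channel
  seg <- ds$segments[[1L]]
  for (k in c(1L, 4L, 8L)) {
    sp <- stats::spec.pgram(seg[k, ], taper = 0, plot = FALSE,
                            detrend = FALSE)
    f_hz <- sp$freq * 4000
    out_band <- sum(sp$spec[f_hz < 20 | f_hz > 450]) / sum(sp$spec)
    expect_lt(out_band, 0.05)
  }
  # class envelope profiles are pairwise distinct
  prof <- vapply(split(seq_along(ds$labels), ds$labels), function(i) {
    rowMeans(vapply(ds$segments[i], function(s) apply(abs(s), 1, mean),
                    numeric(8)))
  }, numeric(8))
  dmin <- min(dist(t(prof)))
  expect_gt(dmin, 0)
  expect_error(gen_emg_like(2, 5, 8, duration_s = 2, fs = 800, seed = 1),
               "band")
  expect_error(gen_emg_like(2, 1, 8, duration_s = 2, fs = 4000, seed = 1),
               "n_classes")
})

test_that("segment splitting follows the floor arithmetic", {
  # 24 segments of 20 s per class at 4 s parts -> 120 parts per class
  ds <- gen_emg_like(24, 2, 1, duration_s = 20, fs = 250, seed = 3,
                     band = c(20, 100))
  parts <- split_segments(ds, 4)
  expect_identical(as.integer(table(parts$labels)), c(120L, 120L))
  expect_true(all(vapply(parts$segments, ncol, integer(1)) == 1000L))
  one <- signal_dataset(list(matrix(rnorm(40), 1)), labels = "a", fs = 10)
  expect_length(split_segments(one, 4)$segments, 1L)
  ten <- signal_dataset(list(matrix(rnorm(100), 1)), labels = "a", fs = 10)
  expect_length(split_segments(ten, 4)$segments, 2L)  # 2 s tail discarded
  expect_error(split_segments(one, 10), "exceeds")
})

test_that("train/test split is stratified, disjoint, and seeded", {
  ds <- gen_eeg_like(10, duration_s = 2, fs = 100, seed = 4)
  sp <- train_test_split(ds, 8, 2, seed = 5)
  expect_identical(as.integer(table(sp$train$labels)), c(8L, 8L))
  expect_identical(as.integer(table(sp$test$labels)), c(2L, 2L))
  key <- function(d) vapply(d$segments, function(s) sum(s), numeric(1))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- train_test_split(ds, 8, 2, seed = 5)
  expect_identical(sp$train$segments, sp2$train$segments)
  expect_error(train_test_split(ds, 15, 5, seed = 1), "need")
})
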