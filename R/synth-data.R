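#' Labelled multichannel signal dataset
#'
#' The common container for segmented biosignals: a list of channels x
#' samples matrices, one class label per segment, and a shared sampling
#' rate.
#'
#' @param segments List of K x T numeric matrices (same K throughout).
#' @param labels Per-segment class labels (same length as `segments`).
#' @param fs Sampling rate in Hz.
#' @param meta Optional list of generator parameters (seed etc.).
#' @return An object of class `"signal_dataset"`.
#' @export
signal_dataset <- function(segments, labels = NULL, fs, meta = list()) {
  if (!is.list(segments) || !all(vapply(segments, is.matrix, logical(1))))
    stop("signal_dataset: 'segments' must be a list of matrices")
  if (length(segments) > 0L) {
    K <- vapply(segments, nrow, integer(1))
    if (length(unique(K)) != 1L)
      stop("signal_dataset: all segments must share the channel count")
  }
  if (!is.null(labels) && length(labels) != length(segments))
    stop("signal_dataset: 'labels' must have one entry per segment")
  structure(list(segments = segments, labels = labels, fs = fs,
                 meta = meta), class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  ns <- length(x$segments)
  cat("Signal dataset:", ns, "segments")
  if (ns > 0L)
    cat(",", nrow(x$segments[[1L]]), "channel(s) x",
        ncol(x$segments[[1L]]), "samples @", x$fs, "Hz")
  cat("\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(names(tab), "(", tab, ")", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# 1/f-shaped noise via spectral shaping, standardized to unit sd.
pink_noise <- function(n) {
  spec <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k)          # two-sided frequency index
  spec <- spec / sqrt(pmax(f, 1))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Noise band-limited to [f_lo, f_hi] Hz by hard FFT masking, unit sd.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  spec <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  spec[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s
}

#' Generate an EEG-like two-class dataset
#'
#' Single-channel segments emulating the structure of scalp EEG seizure
#' benchmarks: class 0 is a 1/f ("pink") background with a
#' moderate-amplitude band-limited alpha-range oscillation; class 1
#' superimposes high-amplitude rhythmic bursts around `burst_freq` (about
#' 3 Hz) covering most of the segment (at least half; the default 0.9
#' emulates ictal activity that spans the recording), with a
#' burst-to-background amplitude ratio of at least 3 at the defaults.
#' Deliberately easier than real EEG: the generator validates the pipeline,
#' not clinical difficulty — per-time-step accuracy is bounded above by
#' roughly `(1 + burst_frac) / 2`, so low coverage makes the task
#' unclassifiable at the step level regardless of the classifier.
#'
#' @param n_per_class Segments per class.
#' @param duration_s Segment duration (s); default 23.6 as in the emulated
#'   recordings.
#' @param fs Sampling rate (Hz); default 173.61.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param burst_freq Burst oscillation frequency (Hz).
#' @param burst_amp_ratio Burst amplitude as a multiple of the background
#'   standard deviation (>= 3 keeps the classes well separated).
#' @param burst_frac Fraction of the segment covered by bursts (>= 0.5).
#' @return A [signal_dataset()] with labels 0 (background) and 1 (burst).
#' @export
gen_eeg_like <- function(n_per_class, duration_s = 23.6, fs = 173.61,
                         seed = 1L, burst_freq = 3, burst_amp_ratio = 4,
                         burst_frac = 0.9) {
  if (!is.numeric(duration_s) || !is.numeric(fs) || duration_s <= 0 ||
      fs <= 0 || duration_s * fs < 10)
    stop("gen_eeg_like: need duration_s * fs >= 10 samples")
  set.seed(seed)
  n <- floor(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  background <- function() {
    osc <- 0.6 * sin(2 * pi * stats::runif(1, 8, 12) * tt +
                       stats::runif(1, 0, 2 * pi))
    pink_noise(n) + osc
  }
  burst_mask <- function() {
    # contiguous bursts of ~2 s until the requested coverage is reached
    m <- numeric(n)
    target <- burst_frac * n
    while (sum(m) < target) {
      len <- min(n, round(stats::runif(1, 1.5, 2.5) * fs))
      at <- sample.int(n - len + 1L, 1L)
      m[at:(at + len - 1L)] <- 1
    }
    # smooth edges to avoid clicks
    stats::filter(m, rep(1 / 9, 9), sides = 2) -> sm
    sm[is.na(sm)] <- m[is.na(sm)]
    as.numeric(sm)
  }
  segs <- vector("list", 2L * n_per_class)
  labels <- integer(2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    segs[[i]] <- matrix(background(), 1L)
    labels[i] <- 0L
  }
  for (i in seq_len(n_per_class)) {
    bg <- background()
    burst <- burst_amp_ratio * stats::sd(bg) *
      sin(2 * pi * burst_freq * tt + stats::runif(1, 0, 2 * pi)) *
      burst_mask()
    segs[[n_per_class + i]] <- matrix(bg + burst, 1L)
    labels[n_per_class + i] <- 1L
  }
  signal_dataset(segs, labels, fs,
                 meta = list(generator = "eeg_like", seed = seed,
                             duration_s = duration_s,
                             burst_freq = burst_freq,
                             burst_amp_ratio = burst_amp_ratio,
                             burst_frac = burst_frac))
}

#' Generate an EMG-like multichannel multi-class dataset
#'
#' Emulates multichannel surface EMG gesture recordings: each class is
#' defined by a distinct per-channel activation profile (a Gaussian bump of
#' muscle activity across the electrode array) that scales 20-450 Hz
#' band-limited noise, slowly modulated in time. Signals are quantized to
#' the 12-bit ADC integer range.
#'
#' @param n_segments_per_class Segments per class (default 24).
#' @param n_classes Number of movement classes (>= 2; default 5).
#' @param channels Electrode channels (default 8).
#' @param duration_s Segment duration (s; default 20).
#' @param fs Sampling rate (Hz; default 4000).
#' @param seed Integer seed.
#' @param band Passband in Hz (default `c(20, 450)`); the upper edge must
#'   stay below `fs / 2`.
#' @param bits ADC resolution (default 12).
#' @return A [signal_dataset()] with labels `1..n_classes`.
#' @export
gen_emg_like <- function(n_segments_per_class = 24L, n_classes = 5L,
                         channels = 8L, duration_s = 20, fs = 4000,
                         seed = 1L, band = c(20, 450), bits = 12L) {
  if (n_classes < 2L) stop("gen_emg_like: need n_classes >= 2")
  if (channels < 1L) stop("gen_emg_like: need channels >= 1")
  if (band[2L] >= fs / 2 || band[1L] <= 0 || band[1L] >= band[2L])
    stop("gen_emg_like: invalid band [", band[1L], ", ", band[2L],
         "] Hz for fs = ", fs, " Hz")
  set.seed(seed)
  n <- floor(duration_s * fs)
  qmax <- 2^(bits - 1L) - 1L
  centers <- (seq_len(n_classes) - 0.5) * channels / n_classes
  profile <- function(cls)
    0.15 + 0.85 * exp(-((seq_len(channels) - centers[cls])^2) / (2 * 1.2^2))
  slow_envelope <- function() {
    e <- bandlimited_noise(n, fs, 0.2, 1.5)
    0.7 + 0.3 * e / max(abs(e), 1e-12)
  }
  segs <- vector("list", n_classes * n_segments_per_class)
  labels <- integer(length(segs))
  i <- 0L
  for (cls in seq_len(n_classes)) {
    gains <- profile(cls)
    for (s in seq_len(n_segments_per_class)) {
      seg <- matrix(0, channels, n)
      for (k in seq_len(channels))
        seg[k, ] <- gains[k] * slow_envelope() *
          bandlimited_noise(n, fs, band[1L], band[2L])
      seg <- round(seg / max(abs(seg)) * qmax)
      i <- i + 1L
      segs[[i]] <- seg
      labels[i] <- cls
    }
  }
  signal_dataset(segs, labels, fs,
                 meta = list(generator = "emg_like", seed = seed,
                             band = band, bits = bits,
                             duration_s = duration_s))
}

#' Split segments into fixed-length parts
#'
#' Cuts every segment into consecutive non-overlapping parts of
#' `part_len_s` seconds, discarding any leftover tail shorter than a part.
#' Labels are inherited by each part.
#'
#' @param ds A [signal_dataset()].
#' @param part_len_s Part length in seconds.
#' @return A new [signal_dataset()] of parts.
#' @export
split_segments <- function(ds, part_len_s) {
  stopifnot(inherits(ds, "signal_dataset"))
  part <- floor(part_len_s * ds$fs)
  if (part < 1) stop("split_segments: part_len_s * fs must be >= 1")
  lens <- vapply(ds$segments, ncol, integer(1))
  if (any(lens < part))
    stop("split_segments: part length ", part,
         " samples exceeds the shortest segment (", min(lens), ")")
  segs <- list()
  labels <- c()
  for (i in seq_along(ds$segments)) {
    n_parts <- ncol(ds$segments[[i]]) %/% part
    for (j in seq_len(n_parts)) {
      segs[[length(segs) + 1L]] <-
        ds$segments[[i]][, ((j - 1L) * part + 1L):(j * part), drop = FALSE]
      labels <- c(labels, ds$labels[i])
    }
  }
  signal_dataset(segs, labels, ds$fs,
                 meta = c(ds$meta, list(part_len_s = part_len_s)))
}

#' Stratified train/test split
#'
#' Draws a disjoint, seeded, per-class split of the dataset's segments.
#'
#' @param ds A [signal_dataset()] with labels.
#' @param n_train_per_class,n_test_per_class Segments drawn per class.
#' @param seed Integer seed; identical seeds give identical membership.
#' @return List with elements `train` and `test`, both [signal_dataset()]s.
#' @export
train_test_split <- function(ds, n_train_per_class, n_test_per_class,
                             seed = 1L) {
  stopifnot(inherits(ds, "signal_dataset"))
  if (is.null(ds$labels)) stop("train_test_split: dataset has no labels")
  set.seed(seed)
  tr_idx <- te_idx <- integer(0)
  for (cls in sort(unique(ds$labels))) {
    idx <- which(ds$labels == cls)
    need <- n_train_per_class + n_test_per_class
    if (length(idx) < need)
      stop("train_test_split: class ", cls, " has ", length(idx),
           " segments, need ", need)
    pick <- sample(idx, need)
    tr_idx <- c(tr_idx, pick[seq_len(n_train_per_class)])
    te_idx <- c(te_idx, pick[n_train_per_class + seq_len(n_test_per_class)])
  }
  sub <- function(i) signal_dataset(ds$segments[i], ds$labels[i], ds$fs,
                                    ds$meta)
  list(train = sub(tr_idx), test = sub(te_idx))
}
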