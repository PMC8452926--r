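#' Synthetic data with the statistical structure the method assumes
#'
#' The classifier assumes class-conditional features that are (a) well
#' modelled by skew-normal distributions and (b) conditionally independent
#' given the class, with the feature matching the attended target shifted
#' upward. The generator draws exactly from that model: one skew-normal
#' feature per class, with a separation `delta` added to the location of
#' feature `i` under class `i`. Samples are organised into trials to
#' support leave-one-trial-out cross-validation; `t` advances by the step
#' of the emulated sliding window.
#'
#' @name synthetic
NULL

#' Synthetic feature-table configuration
#'
#' Defaults emulate a three-target SSVEP session: 3 classes, 5 trials per
#' class, 200 sliding-window samples per class, unit-scale skew-normal
#' noise (shape 3, a mild right skew typical of power and correlation
#' features) and separation `delta = 2`, with the 1 s window / 0.125 s
#' step timing.
#'
#' @param n_classes Number of classes (= number of features).
#' @param delta Location boost of feature `i` under class `i` (feature
#'   units); 0 removes all class signal.
#' @param location,scale,shape Baseline skew-normal parameters, recycled
#'   over (feature, class) pairs.
#' @param samples_per_class Total samples per class (split over trials).
#' @param trials_per_class Trials per class.
#' @param timing A [timing_config()] used to lay out `t`.
#' @param boost_feature Optional integer vector (one per class) naming
#'   which feature is boosted under each class; defaults to the matching
#'   feature. The method itself does not require the match, so tests may
#'   permute it.
#' @param seed Integer seed.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 3L, delta = 2,
                             location = 0, scale = 1, shape = 3,
                             samples_per_class = 200L,
                             trials_per_class = 5L,
                             timing = timing_config(),
                             boost_feature = NULL,
                             seed = 1L) {
  stopifnot(n_classes >= 2L, scale > 0, samples_per_class >= 1L,
            trials_per_class >= 1L)
  if (is.null(boost_feature)) boost_feature <- seq_len(n_classes)
  stopifnot(length(boost_feature) == n_classes)
  structure(list(n_classes = as.integer(n_classes), delta = delta,
                 location = location, scale = scale, shape = shape,
                 samples_per_class = as.integer(samples_per_class),
                 trials_per_class = as.integer(trials_per_class),
                 timing = timing, boost_feature = as.integer(boost_feature),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labelled feature table
#'
#' Features are drawn independently per feature given the class, so the
#' conditional-independence assumption of the joint model holds by
#' construction.
#'
#' @param cfg A [synthetic_config()].
#' @return Feature table `data.frame` with columns `trial`, `t`, `label`,
#'   `f1`..`fN`. Deterministic given `cfg$seed`.
#' @export
generate_features <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_classes
  per_trial <- diff(round(seq(0, cfg$samples_per_class,
                              length.out = cfg$trials_per_class + 1L)))
  rows <- vector("list", n * cfg$trials_per_class)
  k <- 0L
  for (cls in seq_len(n)) {
    for (tr in seq_len(cfg$trials_per_class)) {
      m <- per_trial[tr]
      if (m == 0L) next
      feats <- matrix(0, nrow = m, ncol = n)
      for (f in seq_len(n)) {
        loc <- cfg$location + if (f == cfg$boost_feature[cls]) cfg$delta else 0
        feats[, f] <- rskewnorm(m, xi = loc, omega = cfg$scale,
                                alpha = cfg$shape)
      }
      colnames(feats) <- paste0("f", seq_len(n))
      k <- k + 1L
      rows[[k]] <- data.frame(trial = tr,
                              t = cfg$timing$w +
                                cfg$timing$s * (seq_len(m) - 1L),
                              label = cls, feats)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Generate synthetic SSVEP-like EEG
#'
#' Sum of sinusoids at the first `n_harmonics` harmonics of the attended
#' frequency plus seeded 1/f noise, per channel. Exercises the PSDA/CCA
#' feature-extraction front end without real recordings.
#'
#' @param frequency Attended stimulus frequency (Hz).
#' @param fs Sampling rate (Hz); must exceed twice the highest harmonic.
#' @param duration Seconds of signal.
#' @param n_channels Number of channels.
#' @param amplitudes Amplitude per harmonic (recycled to `n_harmonics`).
#' @param n_harmonics Number of harmonics of `frequency` to include.
#' @param noise_level Standard deviation of the 1/f noise (0 = clean).
#' @param seed Integer seed.
#' @return List of class `"eeg_signal"`: `samples` (channels x time
#'   matrix, arbitrary units), `fs`, `duration`.
#' @export
generate_ssvep_eeg <- function(frequency, fs = 256, duration = 15,
                               n_channels = 2L, amplitudes = 1,
                               n_harmonics = 3L, noise_level = 0.5,
                               seed = 1L) {
  if (fs <= 2 * frequency * n_harmonics) {
    stop("sampling rate must exceed twice the highest harmonic (",
         frequency * n_harmonics, " Hz)")
  }
  set.seed(seed)
  amplitudes <- rep_len(amplitudes, n_harmonics)
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1L) / fs
  clean <- rowSums(vapply(seq_len(n_harmonics), function(h) {
    amplitudes[h] * sin(2 * pi * h * frequency * tt)
  }, numeric(n)))
  samples <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    samples[ch, ] <- clean + noise_level * pink_noise(n)
  }
  structure(list(samples = samples, fs = fs, duration = duration,
                 frequency = frequency),
            class = "eeg_signal")
}

## 1/f ("pink") noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}
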