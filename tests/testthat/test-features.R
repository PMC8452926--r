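sine_signal <- function(freq, fs = 256, duration = 2, channels = 2,
                        amp = 1) {
  tt <- (seq_len(fs * duration) - 1) / fs
  samples <- matrix(rep(amp * sin(2 * pi * freq * tt), channels),
                    nrow = channels, byrow = TRUE)
  structure(list(samples = samples, fs = fs, duration = duration),
            class = "eeg_signal")
}

test_that("re-referencing subtracts the reference channel", {
  set.seed(32)
  sig <- generate_ssvep_eeg(8, fs = 128, duration = 1, n_channels = 3,
                            seed = 32)
  out <- preprocess_rereference(sig, reference = 3, targets = 1:2)
  expect_equal(out$samples[1, ], sig$samples[1, ] - sig$samples[3, ])
  expect_equal(out$samples[3, ], sig$samples[3, ])
  # zero reference leaves targets unchanged
  sig0 <- sig
  sig0$samples[3, ] <- 0
  expect_equal(preprocess_rereference(sig0, 3, 1:2)$samples[1, ],
               sig0$samples[1, ])
  # target equal to reference cancels
  sig$samples[1, ] <- sig$samples[3, ]
  expect_true(all(preprocess_rereference(sig, 3, 1)$samples[1, ] == 0))
  expect_error(preprocess_rereference(sig, 9, 1), "missing channel")
})

test_that("sliding windows tile the signal at the expected count", {
  sig <- sine_signal(8, fs = 256, duration = 15)
  wins <- sliding_windows(sig, w = 1, step = 0.125)
  expect_length(wins, 113)  # floor((15 - 1)/0.125) + 1
  expect_equal(wins[[1]]$t0, 0)
  expect_equal(wins[[2]]$t0, 0.125)
  expect_equal(ncol(wins[[1]]$samples), 256)
  expect_length(sliding_windows(sine_signal(8, duration = 1), w = 1,
                                step = 0.5), 1)
  expect_warning(w0 <- sliding_windows(sine_signal(8, duration = 0.5),
                                       w = 1, step = 0.125), "shorter")
  expect_length(w0, 0)
})

test_that("PSDA powers sit at the stimulated harmonic and scale quadratically", {
  win <- sliding_windows(sine_signal(8), w = 1, step = 1)[[1]]
  f_on <- psda_features(win, 8)
  expect_gt(f_on[1], 1000 * max(f_on[2], f_on[3], 1e-15))
  expect_equal(f_on[4], sum(f_on[1:3]))
  f_off <- psda_features(win, 14)
  expect_lt(sum(f_off[1:3]), 1e-10 * f_on[1])
  win2 <- sliding_windows(sine_signal(8, amp = 2), w = 1, step = 1)[[1]]
  expect_equal(psda_features(win2, 8)[1] / f_on[1], 4, tolerance = 1e-9)
  expect_error(psda_features(win, 60), "Nyquist")
})

test_that("total periodogram power obeys Parseval", {
  set.seed(33)
  x <- rnorm(256)
  spec <- Mod(stats::fft(x))^2 / 256^2
  expect_equal(sum(spec), mean(x^2), tolerance = 1e-10)
})

test_that("CCA correlation is near 1 on target, small off target, scale-invariant", {
  sig <- sine_signal(8, duration = 1)
  sig$samples[2, ] <- sig$samples[2, ] * 0.5 + 1e-3 * sin(2 * pi * 11 *
    (seq_len(256) - 1) / 256)
  win <- sliding_windows(sig, w = 1, step = 1)[[1]]
  expect_gt(cca_features(win, 8), 0.999)
  # channel scaling does not change canonical correlation
  win_scaled <- win
  win_scaled$samples <- win$samples * 7
  expect_equal(cca_features(win_scaled, 8), cca_features(win, 8),
               tolerance = 1e-9)
  # white noise has modest correlation with any reference set
  set.seed(34)
  noise <- structure(list(samples = matrix(rnorm(2 * 1024), nrow = 2),
                          fs = 256, duration = 4), class = "eeg_signal")
  nwin <- list(samples = noise$samples, fs = 256, t0 = 0)
  expect_lt(cca_features(nwin, 8), 0.5)
  const <- list(samples = matrix(1, 2, 256), fs = 256, t0 = 0)
  expect_error(cca_features(const, 8), "degenerate")
})

test_that("one-vs-rest LDA distances are positive for the own class when separated", {
  set.seed(35)
  n <- 60
  labels <- rep(1:3, each = n)
  blocks <- lapply(1:3, function(k) {
    base <- matrix(rnorm(3 * n * 2, sd = 0.3), ncol = 2)
    base[labels == k, ] <- base[labels == k, ] + 5
    base
  })
  comb <- combine_features_lda(blocks, labels)
  for (k in 1:3) {
    expect_true(all(comb[labels == k, k] > 0))
    expect_true(all(comb[labels != k, k] < 0))
  }
  # deterministic: same inputs, same outputs
  expect_identical(comb, combine_features_lda(blocks, labels))
})

test_that("LDA direction agrees with an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(36)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 2), ncol = 2))
  y <- factor(rep(c(FALSE, TRUE), each = 50), levels = c(FALSE, TRUE))
  ours <- ibbci:::ovr_lda_direction(x, y)$direction
  ref <- MASS::lda(x, grouping = y)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  # directions match up to sign
  expect_equal(abs(sum(ours * ref)), 1, tolerance = 1e-8)
})

test_that("the raw-signal pipeline classifies high-SNR synthetic SSVEP", {
  freqs <- c(8, 11, 14)
  segs <- list()
  labels <- integer(0)
  trials <- integer(0)
  for (tr in 1:3) {
    for (k in seq_along(freqs)) {
      segs[[length(segs) + 1L]] <-
        generate_ssvep_eeg(freqs[k], fs = 128, duration = 8,
                           n_channels = 2, noise_level = 0.7,
                           seed = 1000 + 10 * tr + k)
      labels <- c(labels, k)
      trials <- c(trials, tr)
    }
  }
  feats <- extract_feature_table(segs, labels, trials, freqs,
                                 w = 1, step = 0.25)
  clf <- fit_ib_classifier(feats, estimator = "sturges",
                           config = ib_config(restarts = 5, seed = 37))
  pred <- predict_c1(clf, feature_matrix(feats))
  expect_gte(mean(pred == feats$label, na.rm = TRUE), 0.95)
})
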