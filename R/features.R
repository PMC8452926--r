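#' Sliding-window PSDA and CCA feature extraction
#'
#' A minimal front end so the classifier can run from raw multichannel
#' signals: channel re-referencing, a sliding window (1 s length, 0.125 s
#' step by default), periodogram power at the first three harmonics of
#' each target frequency (PSDA), the maximal canonical correlation with
#' sine/cosine references (CCA), and a per-class one-vs-rest LDA
#' combination producing one feature per class. This is a simplified front
#' end, not a replication of any particular recording pipeline.
#'
#' @name features
NULL

#' Re-reference channels by subtracting a reference channel
#'
#' @param signal An `"eeg_signal"` or channels x time matrix.
#' @param reference Row index (or name) of the reference channel.
#' @param targets Row indices (or names) of the channels to re-reference.
#' @return Same shape as the input with `targets` replaced by
#'   `target - reference`.
#' @export
preprocess_rereference <- function(signal, reference, targets) {
  mat <- if (inherits(signal, "eeg_signal")) signal$samples else signal
  if (is.character(reference) || is.character(targets)) {
    if (is.null(rownames(mat))) stop("channel names requested but absent")
  }
  ref_idx <- if (is.character(reference)) match(reference, rownames(mat))
             else reference
  tgt_idx <- if (is.character(targets)) match(targets, rownames(mat))
             else targets
  if (anyNA(ref_idx) || anyNA(tgt_idx) ||
      any(c(ref_idx, tgt_idx) < 1) || any(c(ref_idx, tgt_idx) > nrow(mat))) {
    stop("missing channel in re-referencing")
  }
  mat[tgt_idx, ] <- sweep(mat[tgt_idx, , drop = FALSE], 2L, mat[ref_idx, ])
  if (inherits(signal, "eeg_signal")) {
    signal$samples <- mat
    signal
  } else {
    mat
  }
}

#' Cut a signal into overlapping sliding windows
#'
#' Windows start at `t0 = 0, step, 2*step, ...`; there are
#' `floor((duration - w)/step) + 1` of them.
#'
#' @param signal An `"eeg_signal"`.
#' @param w Window length (s).
#' @param step Step between window starts (s).
#' @return List of windows, each a list with `samples` (channels x time),
#'   `fs` and `t0`.
#' @export
sliding_windows <- function(signal, w = 1, step = 0.125) {
  stopifnot(inherits(signal, "eeg_signal"), w > 0, step > 0)
  n <- ncol(signal$samples)
  wlen <- round(w * signal$fs)
  slen <- step * signal$fs
  if (wlen > n) {
    warning("signal shorter than one window")
    return(list())
  }
  n_win <- floor((n - wlen) / slen) + 1
  lapply(seq_len(n_win), function(i) {
    start <- round((i - 1) * slen) + 1L
    list(samples = signal$samples[, start:(start + wlen - 1L),
                                  drop = FALSE],
         fs = signal$fs, t0 = (i - 1) * step)
  })
}

## One-sided-ish periodogram power at the FFT bin nearest freq:
## |X_k|^2 / n^2 per bin, so the sum over all bins equals the mean square
## of the signal (Parseval).
periodogram_power <- function(x, fs, freq) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n^2
  k <- round(freq * n / fs) + 1L          # 1-based bin index
  if (k < 1L || k > n) return(0)
  spec[k]
}

#' PSDA features: harmonic powers and their sum
#'
#' Periodogram power (rectangular window, nearest frequency bin, averaged
#' over channels) at each of the first `n_harmonics` harmonics of the
#' target frequency, plus their sum.
#'
#' @param window A window from [sliding_windows()].
#' @param target_freq Target stimulus frequency (Hz).
#' @param n_harmonics Number of harmonics (default 3).
#' @return Numeric vector of length `n_harmonics + 1`.
#' @export
psda_features <- function(window, target_freq, n_harmonics = 3L) {
  if (target_freq * n_harmonics >= window$fs / 2) {
    stop("harmonic ", target_freq * n_harmonics,
         " Hz at or above the Nyquist frequency")
  }
  powers <- vapply(seq_len(n_harmonics), function(h) {
    mean(apply(window$samples, 1L, periodogram_power, fs = window$fs,
               freq = h * target_freq))
  }, numeric(1))
  c(powers, sum(powers))
}

#' CCA feature: maximal canonical correlation with harmonic references
#'
#' Reference set: sine and cosine at the first `n_harmonics` harmonics of
#' the target frequency (`2 * n_harmonics` columns).
#'
#' @inheritParams psda_features
#' @return Scalar in `[0, 1]`.
#' @export
cca_features <- function(window, target_freq, n_harmonics = 3L) {
  if (target_freq * n_harmonics >= window$fs / 2) {
    stop("harmonic above the Nyquist frequency")
  }
  x <- t(window$samples)                    # time x channels
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stop("degenerate input: constant channel")
  }
  n <- nrow(x)
  tt <- (seq_len(n) - 1L) / window$fs
  refs <- do.call(cbind, lapply(seq_len(n_harmonics), function(h) {
    cbind(sin(2 * pi * h * target_freq * tt),
          cos(2 * pi * h * target_freq * tt))
  }))
  cc <- stats::cancor(scale(x, scale = FALSE), scale(refs, scale = FALSE))
  max(min(cc$cor[1], 1), 0)
}

#' Combine per-target feature blocks into one feature per class
#'
#' Fits a one-vs-rest linear discriminant per class on that class's
#' feature block and returns the signed distance to the decision border
#' (positive on the class side). With perfectly collinear features the
#' within-class covariance is regularised by a small ridge.
#'
#' @param blocks Named list, one numeric matrix per class (rows = samples,
#'   aligned across blocks).
#' @param labels True class per sample.
#' @param apply_blocks Optional blocks to project (defaults to `blocks`).
#' @return Matrix with one column per class: the combined features.
#' @export
combine_features_lda <- function(blocks, labels, apply_blocks = blocks) {
  classes <- sort(unique(labels))
  stopifnot(length(blocks) == length(classes))
  out <- matrix(0, nrow = nrow(apply_blocks[[1]]), ncol = length(classes))
  colnames(out) <- paste0("f", seq_along(classes))
  for (k in seq_along(classes)) {
    xb <- as.matrix(blocks[[k]])
    yb <- factor(labels == classes[k], levels = c(FALSE, TRUE))
    w <- ovr_lda_direction(xb, yb)
    proj_train <- xb %*% w$direction
    # border at the midpoint of the class means on the discriminant axis
    mu_in <- mean(proj_train[yb == TRUE])
    mu_out <- mean(proj_train[yb == FALSE])
    border <- (mu_in + mu_out) / 2
    sgn <- if (mu_in >= mu_out) 1 else -1
    out[, k] <- sgn * (as.matrix(apply_blocks[[k]]) %*% w$direction - border)
  }
  out
}

## Fisher discriminant direction for a binary split with ridge fallback.
ovr_lda_direction <- function(x, y) {
  x <- as.matrix(x)
  mu1 <- colMeans(x[y == TRUE, , drop = FALSE])
  mu0 <- colMeans(x[y == FALSE, , drop = FALSE])
  cw <- stats::cov(x[y == TRUE, , drop = FALSE]) * (sum(y == TRUE) - 1) +
    stats::cov(x[y == FALSE, , drop = FALSE]) * (sum(y == FALSE) - 1)
  cw <- cw / (nrow(x) - 2)
  dir <- tryCatch(solve(cw, mu1 - mu0), error = function(e) NULL)
  regularised <- FALSE
  if (is.null(dir) || !all(is.finite(dir))) {
    ridge <- diag(mean(diag(cw)) * 1e-6 + 1e-12, ncol(x))
    dir <- solve(cw + ridge, mu1 - mu0)
    regularised <- TRUE
  }
  nrm <- sqrt(sum(dir^2))
  if (nrm > 0) dir <- dir / nrm
  list(direction = dir, regularised = regularised)
}

#' Extract a feature table from labelled EEG segments
#'
#' Runs the sliding window over each segment, computes PSDA and CCA
#' features for every target frequency, and combines them with
#' [combine_features_lda()] into one feature per class.
#'
#' @param segments List of `"eeg_signal"` objects.
#' @param labels True class per segment (index into `frequencies`).
#' @param trials Trial id per segment.
#' @param frequencies Target frequencies (Hz), one per class.
#' @param w,step Sliding-window length and step (s).
#' @param n_harmonics Number of harmonics.
#' @return Feature table `data.frame` (`trial`, `t`, `label`, `f1`..`fN`).
#' @export
extract_feature_table <- function(segments, labels, trials, frequencies,
                                  w = 1, step = 0.125, n_harmonics = 3L) {
  stopifnot(length(segments) == length(labels),
            length(segments) == length(trials))
  n_classes <- length(frequencies)
  rows_label <- integer(0)
  rows_trial <- integer(0)
  rows_t <- numeric(0)
  blocks <- lapply(seq_len(n_classes), function(k) NULL)
  for (s in seq_along(segments)) {
    wins <- sliding_windows(segments[[s]], w = w, step = step)
    for (win in wins) {
      rows_label <- c(rows_label, labels[s])
      rows_trial <- c(rows_trial, trials[s])
      rows_t <- c(rows_t, win$t0 + w)
      for (k in seq_len(n_classes)) {
        feat <- c(psda_features(win, frequencies[k], n_harmonics),
                  cca_features(win, frequencies[k], n_harmonics))
        blocks[[k]] <- rbind(blocks[[k]], feat)
      }
    }
  }
  combined <- combine_features_lda(blocks, rows_label)
  out <- data.frame(trial = rows_trial, t = rows_t, label = rows_label)
  cbind(out, as.data.frame(combined))
}
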