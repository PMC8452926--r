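#' Discretising continuous feature values
#'
#' The classifier works on binned feature values. Bins are computed per
#' feature from the training data: equal-width bins spanning the training
#' range, with the bin count chosen by averaging a per-class estimator
#' (Freedman-Diaconis or Sturges) over classes. Class-conditional bin
#' probabilities P(B_i = b | C_k) are then estimated either by counting
#' (histogram) or from a fitted skew-normal CDF.
#'
#' @name discretise
NULL

#' Freedman-Diaconis bin count
#'
#' Bin width is `2 * IQR / n^(1/3)`; the count is the range divided by the
#' width, rounded up. Degenerate samples (zero IQR or zero range) fall back
#' to a single bin.
#'
#' @param samples Numeric sample.
#' @return Integer bin count (>= 1).
#' @export
fd_bin_count <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 1L) stop("fd_bin_count: empty sample")
  iqr <- stats::IQR(samples, type = 7)
  rng <- diff(range(samples))
  if (iqr <= 0 || rng <= 0) return(1L)
  width <- 2 * iqr / n^(1 / 3)
  max(1L, as.integer(ceiling(rng / width)))
}

#' Sturges' bin count
#'
#' `ceiling(log2(n)) + 1`.
#'
#' @param n Sample size (>= 1).
#' @return Integer bin count.
#' @export
sturges_bin_count <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("sturges_bin_count: n must be a positive integer")
  }
  as.integer(ceiling(log2(n)) + 1)
}

## Columns of a feature table holding feature values, in order f1, f2, ...
feature_columns <- function(features) {
  nm <- grep("^f[0-9]+$", names(features), value = TRUE)
  if (length(nm) == 0L) stop("feature table has no f1..fN columns")
  nm[order(as.integer(sub("^f", "", nm)))]
}

check_feature_table <- function(features) {
  need <- c("trial", "t", "label")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(features)
}

#' Build a binning specification from training data
#'
#' For every feature, the bin count estimator (`fd` or `sturges`) is applied
#' to each class-conditional sample separately and the mean of the per-class
#' counts, rounded to the nearest integer (halves up), gives the feature's
#' bin count. Edges are equally spaced between the feature's overall
#' training minimum and maximum.
#'
#' @param features Feature table (`trial`, `t`, `label`, `f1`..`fN`).
#' @param estimator `"fd"` (Freedman-Diaconis) or `"sturges"`.
#' @return An object of class `"binning_spec"`: list with `edges` (list of
#'   numeric edge vectors), `n_bins` (integer vector) and `estimator`.
#' @export
build_binning <- function(features, estimator = c("fd", "sturges")) {
  estimator <- match.arg(estimator)
  check_feature_table(features)
  fcols <- feature_columns(features)
  classes <- sort(unique(features$label))
  if (length(classes) < 1L) stop("no classes in training data")
  edges <- vector("list", length(fcols))
  n_bins <- integer(length(fcols))
  for (i in seq_along(fcols)) {
    vals <- features[[fcols[i]]]
    counts <- vapply(classes, function(k) {
      v <- vals[features$label == k]
      if (length(v) == 0L) stop("class ", k, " has no samples for ", fcols[i])
      if (estimator == "fd") fd_bin_count(v) else sturges_bin_count(length(v))
    }, numeric(1))
    # mean of per-class counts, halves rounding up
    nb <- max(1L, as.integer(floor(mean(counts) + 0.5)))
    lo <- min(vals)
    hi <- max(vals)
    if (hi <= lo) hi <- lo + .Machine$double.eps * max(1, abs(lo))
    edges[[i]] <- seq(lo, hi, length.out = nb + 1L)
    n_bins[i] <- nb
  }
  structure(list(edges = edges, n_bins = n_bins, estimator = estimator,
                 features = fcols),
            class = "binning_spec")
}

#' @export
print.binning_spec <- function(x, ...) {
  cat("Binning specification (", x$estimator, " estimator)\n", sep = "")
  for (i in seq_along(x$edges)) {
    cat(sprintf("  %s: %d bins on [%.4g, %.4g]\n", x$features[i],
                x$n_bins[i], x$edges[[i]][1],
                x$edges[[i]][length(x$edges[[i]])]))
  }
  invisible(x)
}

#' Assign a value to a bin
#'
#' Bins are half-open `[l, h)`; the last bin is closed on the right.
#' Out-of-range values clamp to the first or last bin, so the map is total.
#'
#' @param value Numeric vector of feature values.
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return Integer bin indices in `1..(length(edges) - 1)`.
#' @export
assign_bin <- function(value, edges) {
  nb <- length(edges) - 1L
  idx <- findInterval(value, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), nb)
}

#' Histogram estimate of class-conditional bin probabilities
#'
#' @param features Training feature table.
#' @param spec A `binning_spec` built on the same data.
#' @return Object of class `"cond_feature_model"`: `probs[[feature]]` is a
#'   classes x bins matrix of P(B_i = b | C_k); plus `classes`, `method`
#'   and the `spec`.
#' @export
histogram_probs <- function(features, spec) {
  check_feature_table(features)
  classes <- sort(unique(features$label))
  fcols <- spec$features
  probs <- vector("list", length(fcols))
  for (i in seq_along(fcols)) {
    nb <- spec$n_bins[i]
    tab <- matrix(0, nrow = length(classes), ncol = nb,
                  dimnames = list(as.character(classes), NULL))
    for (k in seq_along(classes)) {
      v <- features[[fcols[i]]][features$label == classes[k]]
      if (length(v) == 0L) stop("class ", classes[k], " has no samples")
      bins <- assign_bin(v, spec$edges[[i]])
      tab[k, ] <- tabulate(bins, nbins = nb) / length(v)
    }
    probs[[i]] <- tab
  }
  structure(list(probs = probs, classes = classes, method = "histogram",
                 spec = spec, fits = NULL),
            class = "cond_feature_model")
}

#' Skew-normal estimate of class-conditional bin probabilities
#'
#' Fits a skew-normal distribution by maximum likelihood to each
#' (feature, class) sample and computes bin probabilities as CDF
#' differences `F(h) - F(l)`. Tail mass beyond the first and last edges is
#' absorbed into the extreme bins, so each row sums to 1 exactly.
#'
#' @inheritParams histogram_probs
#' @return A `"cond_feature_model"` with `method = "skew-normal"` and the
#'   per-(feature, class) fits in `fits`.
#' @export
skewnormal_probs <- function(features, spec) {
  check_feature_table(features)
  classes <- sort(unique(features$label))
  fcols <- spec$features
  probs <- vector("list", length(fcols))
  fits <- vector("list", length(fcols))
  for (i in seq_along(fcols)) {
    nb <- spec$n_bins[i]
    edges <- spec$edges[[i]]
    tab <- matrix(0, nrow = length(classes), ncol = nb,
                  dimnames = list(as.character(classes), NULL))
    fits[[i]] <- vector("list", length(classes))
    for (k in seq_along(classes)) {
      v <- features[[fcols[i]]][features$label == classes[k]]
      if (length(v) == 0L) stop("class ", classes[k], " has no samples")
      fit <- fit_skewnorm(v)
      fits[[i]][[k]] <- fit
      cdf <- pskewnorm(edges, fit$xi, fit$omega, fit$alpha)
      p <- diff(cdf)
      # absorb the tails so the row is an exact distribution
      p[1] <- p[1] + cdf[1]
      p[nb] <- p[nb] + (1 - cdf[nb + 1L])
      p[p < 0] <- 0
      tab[k, ] <- p / sum(p)
    }
    probs[[i]] <- tab
  }
  structure(list(probs = probs, classes = classes, method = "skew-normal",
                 spec = spec, fits = fits),
            class = "cond_feature_model")
}

#' @export
print.cond_feature_model <- function(x, ...) {
  cat("Class-conditional feature model (", x$method, ")\n", sep = "")
  cat("  ", length(x$probs), " features, ", length(x$classes),
      " classes\n", sep = "")
  invisible(x)
}
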