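#' BCI performance measures
#'
#' Confusion accounting with an "unclassified" column and the performance
#' measures used for SSVEP BCIs: accuracy on classified samples, mean
#' detection time (MDT), the standard Wolpaw information transfer rate
#' (ITR) and the mutual-information ITR. The Wolpaw formula is the special
#' case of the mutual information between predicted and true class under a
#' doubly symmetric channel; the mutual-information ITR drops that
#' assumption.
#'
#' @name metrics
NULL

#' Confusion table with reject column
#'
#' @param truth Vector of true class labels.
#' @param predicted Vector of predicted labels with `NA` for unclassified
#'   samples.
#' @param classes Class labels (defaults to sorted unique truth values).
#' @return Integer matrix of class `"confusion_table"`, rows = true class,
#'   columns = predicted classes plus `"unclassified"`.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  if (is.null(classes)) classes <- sort(unique(truth))
  pred <- factor(ifelse(is.na(predicted), "unclassified",
                        as.character(predicted)),
                 levels = c(as.character(classes), "unclassified"))
  tr <- factor(as.character(truth), levels = as.character(classes))
  tab <- table(tr, pred)
  structure(matrix(as.integer(tab), nrow = length(classes),
                   dimnames = list(as.character(classes),
                                   c(as.character(classes),
                                     "unclassified"))),
            class = "confusion_table")
}

#' Timing configuration for detection-time estimates
#'
#' @param w Window length in seconds.
#' @param s Step between consecutive feature extractions in seconds.
#' @param gaze Gaze-shift constant in seconds (0 by default; about 0.5 s
#'   when switching targets is modelled).
#' @return List of class `"timing_config"`.
#' @export
timing_config <- function(w = 1, s = 0.125, gaze = 0) {
  stopifnot(w > 0, s > 0, gaze >= 0)
  structure(list(w = w, s = s, gaze = gaze), class = "timing_config")
}

#' Wolpaw information transfer rate per prediction
#'
#' \deqn{ITR_s = \log_2 N + a \log_2 a + (1-a)\log_2\frac{1-a}{N-1}}
#' with the `0 log 0 = 0` convention at `a = 0` and `a = 1`. Negative for
#' accuracies below chance; returned unmodified.
#'
#' @param N Number of targets (>= 2).
#' @param a Accuracy in `[0, 1]`.
#' @return Bits per prediction.
#' @export
itr_wolpaw <- function(N, a) {
  stopifnot(N >= 2, a >= 0, a <= 1)
  term_a <- if (a > 0) a * log2(a) else 0
  term_e <- if (a < 1) (1 - a) * log2((1 - a) / (N - 1)) else 0
  log2(N) + term_a + term_e
}

#' Mean detection time
#'
#' `w + (1/p_classified - 1) * s + gaze`: the window length plus one step
#' per expected failed classification before a successful one (an
#' overlapping sliding window advances `s` seconds per attempt), plus the
#' optional gaze-shift constant.
#'
#' @param timing A [timing_config()].
#' @param p_classified Probability that a sample is classified, in (0, 1].
#' @return Seconds; `Inf` when `p_classified` is 0.
#' @export
mdt <- function(timing, p_classified) {
  stopifnot(inherits(timing, "timing_config"),
            p_classified >= 0, p_classified <= 1)
  if (p_classified == 0) return(Inf)
  timing$w + (1 / p_classified - 1) * timing$s + timing$gaze
}

#' Mutual information between predicted and true class
#'
#' Builds the joint p(P, C) and returns I(P;C) in bits (plug-in estimate
#' from counts). By default the unclassified column is excluded and the
#' remaining counts renormalised, so the value describes the information
#' carried by one emitted prediction; `include_unclassified = TRUE`
#' instead treats abstention as an (N+1)-th prediction outcome.
#'
#' @param table A `"confusion_table"`.
#' @param include_unclassified Logical, see above.
#' @return Bits per prediction.
#' @export
mi_from_confusion <- function(table, include_unclassified = FALSE) {
  stopifnot(inherits(table, "confusion_table"))
  counts <- unclass(table)
  if (!include_unclassified) {
    counts <- counts[, -ncol(counts), drop = FALSE]
  }
  total <- sum(counts)
  if (total == 0) stop("no classified samples: mutual information undefined")
  # rows = true class C, columns = predicted class P
  mutual_information(counts / total)
}

#' Performance report: accuracy, MDT, ITR and mutual-information ITR
#'
#' @param table A `"confusion_table"`.
#' @param timing A [timing_config()].
#' @return List of class `"performance_report"`: `accuracy` (on classified
#'   samples), `p_classified`, `mdt` (s), `itr` and `itr_mi` (bits/min),
#'   `i_pc` (bits/prediction), `n_predictions`, `n_samples`, `n_classes`.
#' @export
performance_report <- function(table, timing = timing_config()) {
  stopifnot(inherits(table, "confusion_table"))
  counts <- unclass(table)
  n_classes <- nrow(counts)
  total <- sum(counts)
  classified <- sum(counts[, -ncol(counts)])
  correct <- sum(diag(counts[, -ncol(counts), drop = FALSE]))
  p_classified <- if (total > 0) classified / total else 0
  a <- if (classified > 0) correct / classified else NA_real_
  det_time <- mdt(timing, p_classified)
  if (classified == 0 || !is.finite(det_time)) {
    i_pc <- 0
    itr <- 0
    itr_mi <- 0
  } else {
    i_pc <- mi_from_confusion(table)
    itr <- itr_wolpaw(n_classes, a) * 60 / det_time
    itr_mi <- i_pc * 60 / det_time
  }
  structure(list(accuracy = a, p_classified = p_classified,
                 mdt = det_time, itr = itr, itr_mi = itr_mi, i_pc = i_pc,
                 n_predictions = classified, n_samples = total,
                 n_classes = n_classes, confusion = table,
                 timing = timing),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("BCI performance report\n")
  cat(sprintf("  ITR_mi %.2f bits/min  ITR %.2f bits/min\n",
              x$itr_mi, x$itr))
  cat(sprintf("  accuracy %.3f  MDT %.3f s  predictions %d / %d samples\n",
              x$accuracy, x$mdt, x$n_predictions, x$n_samples))
  cat(sprintf("  I(P;C) %.4f bits per prediction\n", x$i_pc))
  invisible(x)
}

#' One-row data frame of a performance report (Table-style layout)
#'
#' @param report A `"performance_report"`.
#' @return `data.frame` with columns `itr_mi`, `itr`, `accuracy`, `mdt`,
#'   `n_predictions`.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "performance_report"))
  data.frame(itr_mi = report$itr_mi, itr = report$itr,
             accuracy = report$accuracy, mdt = report$mdt,
             n_predictions = report$n_predictions)
}
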