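#' Cross-validation and parameter scans
#'
#' Leave-one-trial-out cross-validation (folds are defined by trial id,
#' never by random shuffling, because sliding-window samples within a trial
#' are strongly dependent), a beta-grid scan of the bottleneck solution,
#' and a threshold scan for the neighbourhood classifier.
#'
#' @name evaluation
NULL

#' Leave-one-trial-out cross-validation plan
#'
#' @param features Feature table with a `trial` column.
#' @return List of class `"cv_plan"`; each fold holds `test_trials` (one
#'   trial) and `train_trials` (the rest).
#' @export
cv_plan <- function(features) {
  check_feature_table(features)
  trials <- sort(unique(features$trial))
  folds <- lapply(trials, function(tr) {
    list(test_trials = tr, train_trials = setdiff(trials, tr))
  })
  structure(list(folds = folds, trials = trials), class = "cv_plan")
}

#' Cross-validate the information-bottleneck classifier
#'
#' Trains one classifier per fold and pools the test confusion counts; the
#' pooled table feeds [performance_report()]. Per-fold reports are also
#' returned.
#'
#' @param features Feature table.
#' @param method,estimator,config,prior,tau,rule Passed to
#'   [fit_ib_classifier()].
#' @param classifier `"c1"` (point rule) or `"c2"` (neighbourhood vote).
#' @param n,t Classifier-2 parameters (ignored for `"c1"`).
#' @param timing A [timing_config()].
#' @return List of class `"cv_result"`: `pooled` (a
#'   `"performance_report"`), `per_fold` (list of reports), `confusion`
#'   (pooled table), `plan`.
#' @export
cross_validate <- function(features, method = "skew-normal",
                           estimator = "fd", config = ib_config(),
                           prior = "empirical", tau = 1e-6,
                           rule = "strict", classifier = c("c1", "c2"),
                           n = 1L, t = NULL,
                           timing = timing_config()) {
  classifier <- match.arg(classifier)
  check_feature_table(features)
  plan <- cv_plan(features)
  if (length(plan$folds) < 2L) stop("need at least 2 trials per class")
  classes <- sort(unique(features$label))
  fcols <- feature_columns(features)
  pooled_counts <- NULL
  per_fold <- vector("list", length(plan$folds))
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    train <- features[features$trial %in% fold$train_trials, , drop = FALSE]
    test <- features[features$trial %in% fold$test_trials, , drop = FALSE]
    if (!all(classes %in% train$label)) {
      stop("class missing from training fold ", i)
    }
    clf <- fit_ib_classifier(train, method = method, estimator = estimator,
                             config = config, prior = prior, tau = tau,
                             rule = rule)
    vals <- as.matrix(test[, fcols, drop = FALSE])
    pred <- if (classifier == "c1") predict_c1(clf, vals)
            else predict_c2(clf, vals, n = n, t = t)
    tab <- confusion_table(test$label, pred, classes = classes)
    per_fold[[i]] <- performance_report(tab, timing)
    pooled_counts <- if (is.null(pooled_counts)) unclass(tab)
                     else pooled_counts + unclass(tab)
  }
  pooled_tab <- structure(pooled_counts, class = "confusion_table")
  structure(list(pooled = performance_report(pooled_tab, timing),
                 per_fold = per_fold, confusion = pooled_tab,
                 plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", length(x$per_fold), " folds)\n", sep = "")
  cat("Pooled:\n")
  print(x$pooled)
  invisible(x)
}

#' Scan the information bottleneck over a beta grid
#'
#' One multi-restart solve per beta; the grid defaults to
#' `{10, 20, ..., 150}`. Restart seeds are derived from `config$seed` so
#' each beta sees independent initialisations.
#'
#' @param joint A `"joint_xc"`.
#' @param alpha Objective interpolation parameter.
#' @param betas Numeric grid of beta values.
#' @param config Base [ib_config()] (its `beta`/`alpha` are overridden).
#' @return `data.frame` with one row per beta: `beta`, `H_P`,
#'   `H_P_given_X`, `I_PX`, `I_PC`, `objective`, `n_occupied`.
#' @export
scan_beta <- function(joint, alpha = 1, betas = seq(10, 150, by = 10),
                      config = ib_config()) {
  rows <- lapply(seq_along(betas), function(i) {
    cfg <- ib_config(alpha = alpha, beta = betas[i],
                     n_clusters = config$n_clusters,
                     max_iter = config$max_iter, tol = config$tol,
                     restarts = config$restarts,
                     seed = config$seed + i, pmin = config$pmin)
    sol <- solve_generalized_ib(joint, cfg)
    data.frame(beta = betas[i], H_P = sol$H_P,
               H_P_given_X = sol$H_P_given_X, I_PX = sol$I_PX,
               I_PC = sol$I_PC, objective = sol$objective,
               n_occupied = length(sol$occupied_clusters))
  })
  do.call(rbind, rows)
}

#' Scan the Classifier-2 vote threshold
#'
#' For each neighbourhood radius `n`, evaluates the neighbourhood
#' classifier over every threshold in the valid range and reports the
#' performance measures. Vote counts are computed once per radius, so the
#' scan costs one neighbourhood pass per `n` regardless of how many
#' thresholds are evaluated.
#'
#' @param clf A fitted `"ib_classifier"`.
#' @param features Test feature table.
#' @param n_values Neighbourhood radii to scan.
#' @param timing A [timing_config()].
#' @return `data.frame` with one row per (n, t): `n`, `t`, `itr_mi`,
#'   `itr`, `accuracy`, `mdt`, `n_predictions`.
#' @export
scan_t <- function(clf, features, n_values = 1:4,
                   timing = timing_config()) {
  check_feature_table(features)
  fcols <- feature_columns(features)
  vals <- as.matrix(features[, fcols, drop = FALSE])
  classes <- clf$classes
  rows <- list()
  for (n in n_values) {
    counts <- c2_vote_counts(clf, vals, n)
    rng <- valid_t_range(n, length(clf$spec$edges))
    for (t in seq.int(rng$t_min, rng$t_max)) {
      reach <- counts >= t
      winner <- rep(NA_integer_, nrow(counts))
      hit <- rowSums(reach) == 1L
      winner[hit] <- max.col(reach, ties.method = "first")[hit]
      pred <- classes[winner]
      tab <- confusion_table(features$label, pred, classes = classes)
      rep_ <- performance_report(tab, timing)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(n = n, t = t), report_row(rep_))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
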