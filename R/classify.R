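#' End-to-end SSVEP classifiers with a reject option
#'
#' [fit_ib_classifier()] runs the full training path (binning, conditional
#' probability estimation, conditional-independence joint, information
#' bottleneck, cluster-to-class mapping). Prediction offers two rules:
#' Classifier 1 assigns the class whose cluster posterior q(p|x) is 1
#' (within tolerance `tau`), otherwise abstains; Classifier 2 additionally
#' requires at least `t` of the `(2n+1)^F` neighbouring bin vectors to be
#' classified the same way. Abstentions ("unclassified", coded `NA`) cost
#' detection time rather than errors.
#'
#' @name classify
NULL

#' Fit the information-bottleneck classifier
#'
#' @param features Training feature table (`trial`, `t`, `label`,
#'   `f1`..`fN`).
#' @param method Probability estimation: `"histogram"` or `"skew-normal"`.
#' @param estimator Bin-count estimator: `"fd"` or `"sturges"`.
#' @param config An [ib_config()]; `n_clusters` defaults to the number of
#'   classes.
#' @param prior Class prior: `"empirical"` (training frequencies),
#'   `"uniform"`, or a numeric vector.
#' @param tau Posterior tolerance for the "q(p|x) = 1" rule; soft
#'   (`alpha = 1`) encoders are near- but not exactly deterministic.
#' @param rule `"strict"` (posterior must reach `1 - tau`) or `"argmax"`
#'   (highest-posterior cluster always classifies when x is in support).
#' @return Object of class `"ib_classifier"`.
#' @export
fit_ib_classifier <- function(features,
                              method = c("skew-normal", "histogram"),
                              estimator = c("fd", "sturges"),
                              config = ib_config(),
                              prior = c("empirical", "uniform"),
                              tau = 1e-6,
                              rule = c("strict", "argmax")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  rule <- match.arg(rule)
  check_feature_table(features)
  classes <- sort(unique(features$label))
  if (length(classes) < 2L) stop("need at least 2 classes to train")

  spec <- build_binning(features, estimator)
  model <- if (method == "histogram") {
    histogram_probs(features, spec)
  } else {
    skewnormal_probs(features, spec)
  }
  if (is.numeric(prior)) {
    prior_vec <- prior
  } else {
    prior <- match.arg(prior)
    prior_vec <- if (prior == "uniform") {
      rep(1 / length(classes), length(classes))
    } else {
      as.numeric(table(factor(features$label, levels = classes))) /
        nrow(features)
    }
  }
  joint <- build_joint(model, prior = prior_vec, pmin = config$pmin)
  solution <- solve_generalized_ib(joint, config)

  clf <- structure(list(spec = spec, model = model, joint = joint,
                        solution = solution, classes = classes,
                        indexer = joint$indexer, tau = tau, rule = rule,
                        mapping = NULL, cluster_of_x = NULL),
                   class = "ib_classifier")
  clf$cluster_of_x <- cluster_lookup(clf)
  clf$mapping <- map_clusters(solution, clf, features)
  clf
}

## Cluster decision per bin cell: integer vector over all cells; NA where
## the cell is outside x_support or the strict rule rejects.
cluster_lookup <- function(clf) {
  sol <- clf$solution
  n_cells <- clf$indexer$n_cells
  out <- rep(NA_integer_, n_cells)
  enc <- sol$encoder
  best <- max.col(enc, ties.method = "first")
  top <- enc[cbind(seq_len(nrow(enc)), best)]
  keep <- if (clf$rule == "argmax") rep(TRUE, nrow(enc)) else
    top >= 1 - clf$tau
  out[sol$x_support[keep]] <- best[keep]
  out
}

#' Map IB clusters to class labels
#'
#' Cluster identities are arbitrary, so every injective map from occupied
#' clusters to classes is scored by training accuracy (over classified
#' samples) and the best is kept; ties break to the lexicographically
#' smallest mapping.
#'
#' @param solution An `"ib_solution"`.
#' @param clf The partially built `"ib_classifier"` (for the bin lookup).
#' @param features Training feature table.
#' @return Integer vector over clusters: `mapping[p]` is the class index of
#'   cluster `p` (NA for unoccupied clusters).
#' @export
map_clusters <- function(solution, clf, features) {
  occ <- solution$occupied_clusters
  n_classes <- length(clf$classes)
  if (length(occ) > n_classes) {
    stop("more occupied clusters than classes; cannot map injectively")
  }
  fcols <- feature_columns(features)
  xs <- sample_to_x(as.matrix(features[, fcols, drop = FALSE]), clf$spec,
                    clf$indexer)
  cl <- clf$cluster_of_x[xs]
  truth <- match(features$label, clf$classes)
  keep <- !is.na(cl)
  cl <- cl[keep]
  truth <- truth[keep]

  n_clusters <- ncol(solution$encoder)
  mapping <- rep(NA_integer_, n_clusters)
  if (length(cl) == 0L) {
    # nothing classified on the training set: arbitrary lexicographic map
    mapping[occ] <- seq_along(occ)
    return(mapping)
  }
  # candidate class tuples for the occupied clusters: all injective maps
  perms <- injective_maps(length(occ), n_classes)
  best_acc <- -1
  best_map <- NULL
  for (r in seq_len(nrow(perms))) {
    assign <- perms[r, ]
    acc <- mean(assign[match(cl, occ)] == truth)
    if (acc > best_acc + 1e-15) {
      best_acc <- acc
      best_map <- assign
    }
  }
  mapping[occ] <- best_map
  mapping
}

## All injective maps of k slots into n classes, in lexicographic row order.
injective_maps <- function(k, n) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grids <- as.matrix(expand.grid(rep(list(seq_len(n)), k),
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(grids) <- NULL
  keep <- apply(grids, 1L, function(z) !anyDuplicated(z))
  m <- grids[keep, , drop = FALSE]
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Classifier 1: point rule with reject option
#'
#' Maps the sample to its bin vector; if the cell was filtered out of the
#' support, or no cluster posterior reaches `1 - tau` (strict rule), the
#' sample is left unclassified (`NA`).
#'
#' @param clf An `"ib_classifier"`.
#' @param values Feature vector, or matrix with one row per sample.
#' @return Vector of class labels with `NA` for unclassified samples.
#' @export
predict_c1 <- function(clf, values) {
  stopifnot(inherits(clf, "ib_classifier"))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (ncol(values) != length(clf$spec$edges)) {
    stop("feature dimension mismatch: expected ", length(clf$spec$edges))
  }
  xs <- sample_to_x(values, clf$spec, clf$indexer)
  cl <- clf$cluster_of_x[xs]
  clf$classes[clf$mapping[cl]]
}

#' Valid vote-threshold range for Classifier 2
#'
#' With neighbourhood radius `n` over `n_features` features there are
#' `(2n+1)^n_features` neighbouring bin vectors; the threshold must exceed
#' half of them (so at most one class can win) and can at most require all
#' of them.
#'
#' @param n Neighbourhood radius (>= 0).
#' @param n_features Number of features.
#' @return List with `t_min` and `t_max` (inclusive bounds).
#' @export
valid_t_range <- function(n, n_features = 3L) {
  stopifnot(n >= 0, n_features >= 1)
  t_max <- (2 * n + 1)^n_features
  list(t_min = floor(t_max / 2) + 1L, t_max = t_max)
}

#' Classifier 2: neighbourhood vote with reject option
#'
#' For each class, counts the offset tuples `s in {-n..n}^F` whose shifted
#' bin vector is classified into that class by the point rule; offsets
#' leaving the bin grid (or landing on filtered cells) vote for no class.
#' The sample is assigned to the class whose count reaches the threshold
#' `t`, and left unclassified otherwise. For `t > (2n+1)^F / 2` at most one
#' class can reach the threshold.
#'
#' @inheritParams predict_c1
#' @param n Neighbourhood radius in bins.
#' @param t Vote threshold; see [valid_t_range()].
#' @return Vector of class labels with `NA` for unclassified samples.
#' @export
predict_c2 <- function(clf, values, n = 1L, t = NULL) {
  stopifnot(inherits(clf, "ib_classifier"), n >= 0)
  rng <- valid_t_range(n, length(clf$spec$edges))
  if (is.null(t)) t <- rng$t_min
  if (t < rng$t_min || t > rng$t_max) {
    warning("t = ", t, " outside the valid range [", rng$t_min, ", ",
            rng$t_max, "]")
  }
  counts <- c2_vote_counts(clf, values, n)
  winners <- apply(counts, 1L, function(v) {
    hit <- which(v >= t)
    if (length(hit) > 1L) {
      stop("ambiguous vote: two classes reached the threshold; ",
           "t is below the majority bound")
    }
    if (length(hit) == 1L) hit else NA_integer_
  })
  clf$classes[winners]
}

## Per-sample per-class neighbourhood vote counts (samples x classes).
## Shared by predict_c2 and scan_t (counts do not depend on t).
c2_vote_counts <- function(clf, values, n) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  n_feat <- length(clf$spec$edges)
  if (ncol(values) != n_feat) {
    stop("feature dimension mismatch: expected ", n_feat)
  }
  nb <- clf$indexer$n_bins
  offsets <- as.matrix(expand.grid(rep(list(seq.int(-n, n)), n_feat),
                                   KEEP.OUT.ATTRS = FALSE))
  bins <- matrix(0L, nrow = nrow(values), ncol = n_feat)
  for (i in seq_len(n_feat)) {
    bins[, i] <- assign_bin(values[, i], clf$spec$edges[[i]])
  }
  class_of_x <- clf$mapping[clf$cluster_of_x]  # class index per cell or NA
  n_classes <- length(clf$classes)
  counts <- matrix(0L, nrow = nrow(values), ncol = n_classes)
  for (s in seq_len(nrow(values))) {
    shifted <- sweep(offsets, 2L, bins[s, ], "+")
    ok <- rep(TRUE, nrow(shifted))
    for (i in seq_len(n_feat)) {
      ok <- ok & shifted[, i] >= 1L & shifted[, i] <= nb[i]
    }
    if (!any(ok)) next
    xs <- x_encode(shifted[ok, , drop = FALSE], clf$indexer)
    cls <- class_of_x[xs]
    cls <- cls[!is.na(cls)]
    if (length(cls)) counts[s, ] <- tabulate(cls, nbins = n_classes)
  }
  counts
}

#' @export
print.ib_classifier <- function(x, ...) {
  cat("Information-bottleneck classifier\n")
  cat(sprintf("  %d classes, %s probabilities, %s bin estimator\n",
              length(x$classes), x$model$method, x$spec$estimator))
  cat(sprintf("  bins: %s (%d cells, %d in support)\n",
              paste(x$indexer$n_bins, collapse = "x"),
              x$indexer$n_cells, length(x$solution$x_support)))
  cat(sprintf("  alpha = %g, beta = %g, I(P;C) = %.4f bits\n",
              x$solution$config$alpha, x$solution$config$beta,
              x$solution$I_PC))
  invisible(x)
}
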