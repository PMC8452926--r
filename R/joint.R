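#' Joint distribution over the bin vector X and class C
#'
#' Per-feature conditional bin probabilities combine, under the assumption
#' that binned features are conditionally independent given the class, into
#' the joint p(x, c) = p(c) * prod_i P(B_i = b_i | C_c) that the
#' information-bottleneck solver consumes. The bin vector (b_1, ..., b_F)
#' is flattened to a single index by row-major mixed-radix encoding with
#' feature 1 most significant.
#'
#' @name joint_model
NULL

#' Mixed-radix indexer for bin vectors
#'
#' @param n_bins Integer vector of bins per feature.
#' @return Object of class `"x_indexer"` with the per-feature radices and
#'   total number of cells.
#' @export
x_indexer <- function(n_bins) {
  n_bins <- as.integer(n_bins)
  stopifnot(all(n_bins >= 1L))
  structure(list(n_bins = n_bins, n_cells = prod(n_bins)),
            class = "x_indexer")
}

#' Encode bin vectors to flat indices
#'
#' @param bins Integer vector (one bin per feature) or matrix with one row
#'   per sample.
#' @param indexer An `x_indexer`.
#' @return 1-based flat indices; bin vector `(1, ..., 1)` maps to 1 and the
#'   all-last vector to the cell count.
#' @export
x_encode <- function(bins, indexer) {
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = 1L)
  nb <- indexer$n_bins
  stopifnot(ncol(bins) == length(nb))
  idx <- rep(0, nrow(bins))
  for (i in seq_along(nb)) {
    idx <- idx * nb[i] + (bins[, i] - 1L)
  }
  as.integer(idx + 1L)
}

#' Decode flat indices back to bin vectors
#'
#' @param idx 1-based flat indices.
#' @inheritParams x_encode
#' @return Integer matrix, one row per index.
#' @export
x_decode <- function(idx, indexer) {
  nb <- indexer$n_bins
  out <- matrix(0L, nrow = length(idx), ncol = length(nb))
  rem <- as.integer(idx) - 1L
  for (i in rev(seq_along(nb))) {
    out[, i] <- rem %% nb[i] + 1L
    rem <- rem %/% nb[i]
  }
  out
}

#' Build the joint distribution p(x, c)
#'
#' @param model A `cond_feature_model`.
#' @param prior Class prior; `"empirical"` is supplied by callers that know
#'   training frequencies, or a numeric vector over classes. Default
#'   uniform.
#' @param pmin Support threshold: cells with marginal p(x) < `pmin` are
#'   excluded from `x_support` (samples landing there are unclassifiable).
#' @param max_cells Guard on the number of cells `prod(n_bins)`; the full
#'   Cartesian product is enumerated densely and grows exponentially with
#'   the number of classes/features.
#' @return Object of class `"joint_xc"`: `p_xc` (cells x classes matrix
#'   summing to 1), `x_support` (indices with p(x) >= pmin), `indexer`,
#'   `classes`, `prior`, `pmin`.
#' @export
build_joint <- function(model, prior = NULL, pmin = 1e-12,
                        max_cells = 1e6) {
  stopifnot(inherits(model, "cond_feature_model"))
  n_classes <- length(model$classes)
  if (is.null(prior)) prior <- rep(1 / n_classes, n_classes)
  validate_distribution(prior)
  stopifnot(length(prior) == n_classes)
  idx <- x_indexer(model$spec$n_bins)
  if (idx$n_cells > max_cells) {
    stop("bin grid has ", idx$n_cells, " cells, above the cap of ",
         max_cells, "; the cell count grows exponentially with the number ",
         "of features, use fewer bins or classes")
  }
  p_xc <- canonical_joint(model, prior, idx)
  p_x <- rowSums(p_xc)
  structure(list(p_xc = p_xc, x_support = which(p_x >= pmin),
                 indexer = idx, classes = model$classes,
                 prior = prior, pmin = pmin),
            class = "joint_xc")
}

## Dense joint in canonical row-major order: row r corresponds to
## x_decode(r); p_xc[r, k] = prior[k] * prod_i P(B_i = b_i | C_k).
canonical_joint <- function(model, prior, idx) {
  n_classes <- length(model$classes)
  p_xc <- matrix(rep(prior, each = idx$n_cells), nrow = idx$n_cells)
  bins <- x_decode(seq_len(idx$n_cells), idx)
  for (i in seq_along(model$probs)) {
    tab <- model$probs[[i]]
    for (k in seq_len(n_classes)) {
      p_xc[, k] <- p_xc[, k] * tab[k, bins[, i]]
    }
  }
  p_xc
}

#' Wrap a raw joint probability matrix as a `joint_xc`
#'
#' For joints that do not come from a feature model (tests, external
#' tables): rows index the flattened bin vector, columns the class.
#'
#' @param p_xc Non-negative matrix summing to 1 (cells x classes).
#' @param pmin Support threshold on the row marginal.
#' @param classes Optional class labels (default `1..ncol`).
#' @return A `"joint_xc"` over a one-feature indexer with `nrow(p_xc)`
#'   bins.
#' @export
joint_from_matrix <- function(p_xc, pmin = 1e-12, classes = NULL) {
  validate_joint(p_xc)
  if (is.null(classes)) classes <- seq_len(ncol(p_xc))
  structure(list(p_xc = p_xc, x_support = which(rowSums(p_xc) >= pmin),
                 indexer = x_indexer(nrow(p_xc)), classes = classes,
                 prior = colSums(p_xc), pmin = pmin),
            class = "joint_xc")
}

#' @export
print.joint_xc <- function(x, ...) {
  cat("Joint distribution over bin vector X and class C\n")
  cat(sprintf("  %d cells (%s bins), %d classes, support %d cells (pmin %g)\n",
              x$indexer$n_cells,
              paste(x$indexer$n_bins, collapse = "x"),
              length(x$classes), length(x$x_support), x$pmin))
  invisible(x)
}

#' Map a raw feature vector to its flat bin-vector index
#'
#' Applies `assign_bin` per feature then mixed-radix encodes. Clamping in
#' `assign_bin` makes the map total.
#'
#' @param values Numeric vector (one value per feature) or matrix with one
#'   row per sample.
#' @param spec A `binning_spec`.
#' @param indexer Matching `x_indexer`; built from `spec` if omitted.
#' @return Flat indices (1-based).
#' @export
sample_to_x <- function(values, spec, indexer = NULL) {
  if (is.null(indexer)) indexer <- x_indexer(spec$n_bins)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  stopifnot(ncol(values) == length(spec$edges))
  bins <- matrix(0L, nrow = nrow(values), ncol = ncol(values))
  for (i in seq_len(ncol(values))) {
    bins[, i] <- assign_bin(values[, i], spec$edges[[i]])
  }
  x_encode(bins, indexer)
}
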