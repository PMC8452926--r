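# Fixtures built in code; all randomness is seeded by the caller.

# Random joint over n_x cells and n_c classes, wrapped as a joint_xc.
rand_joint <- function(n_x, n_c, seed, pmin = 0) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n_x * n_c, shape = 1), nrow = n_x)
  m <- m / sum(m)
  joint_from_matrix(m, pmin = pmin)
}

# Joint where each class owns a disjoint block of cells (perfectly
# separable): I(X;C) = H(C).
separable_joint <- function(cells_per_class = 3L, n_c = 3L) {
  n_x <- cells_per_class * n_c
  m <- matrix(0, nrow = n_x, ncol = n_c)
  for (k in seq_len(n_c)) {
    rows <- (k - 1L) * cells_per_class + seq_len(cells_per_class)
    m[rows, k] <- 1 / (n_c * cells_per_class)
  }
  joint_from_matrix(m)
}

# Doubly symmetric confusion counts: diagonal accuracy a, errors spread
# uniformly, uniform true classes, `per_class` samples per class.
doubly_symmetric_table <- function(n_c, a, per_class) {
  diag_n <- round(a * per_class)
  off_n <- (per_class - diag_n) / (n_c - 1)
  stopifnot(off_n == round(off_n)) # keep counts integral
  counts <- matrix(off_n, n_c, n_c)
  diag(counts) <- diag_n
  counts <- cbind(counts, 0) # no unclassified samples
  structure(matrix(as.integer(counts), nrow = n_c,
                   dimnames = list(as.character(seq_len(n_c)),
                                   c(as.character(seq_len(n_c)),
                                     "unclassified"))),
            class = "confusion_table")
}

# Small, well-separated synthetic feature table.
easy_features <- function(seed = 1, delta = 10, n = 150, trials = 5) {
  generate_features(synthetic_config(delta = delta, samples_per_class = n,
                                     trials_per_class = trials,
                                     seed = seed))
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^f[0-9]+$", names(features)), drop = FALSE])
}

# Direct evaluation of the doubly-symmetric-channel information formula;
# used as the independent oracle for mutual-information code paths.
wolpaw_direct <- function(N, a) {
  xl <- function(p) if (p > 0) p * log2(p) else 0
  log2(N) + xl(a) + if (a < 1) (1 - a) * log2((1 - a) / (N - 1)) else 0
}
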