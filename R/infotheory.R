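#' Information-theoretic primitives
#'
#' All quantities are in bits (base-2 logarithms) and use the convention
#' 0 log2 0 = 0. Distributions are plain numeric vectors; joints are
#' matrices whose entries sum to 1.
#'
#' @name infotheory
NULL

## x * log2(x) with the 0 log 0 = 0 convention
xlog2x <- function(x) {
  out <- x
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

#' Validate a discrete probability distribution
#'
#' @param probs Numeric vector of probabilities.
#' @param tol Tolerance on the deviation of `sum(probs)` from 1.
#' @return `probs`, invisibly, if valid; otherwise an error is raised.
#' @keywords internal
validate_distribution <- function(probs, tol = 1e-8) {
  if (!is.numeric(probs) || length(probs) == 0L) {
    stop("invalid distribution: must be a non-empty numeric vector")
  }
  if (anyNA(probs)) stop("invalid distribution: contains NA")
  if (any(probs < 0)) stop("invalid distribution: negative entries")
  if (abs(sum(probs) - 1) > tol) {
    stop("invalid distribution: entries sum to ", format(sum(probs)),
         ", not 1")
  }
  invisible(probs)
}

validate_joint <- function(joint, tol = 1e-8) {
  if (!is.matrix(joint)) stop("invalid joint: must be a matrix")
  validate_distribution(as.numeric(joint), tol = tol)
  invisible(joint)
}

#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(Y) = -\sum_i P(y_i) \log_2 P(y_i)} with \eqn{0 \log_2 0 = 0}.
#'
#' @param probs Numeric vector of non-negative probabilities summing to 1.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' entropy(rep(0.25, 4)) # 2 bits
#' entropy(c(1, 0, 0))   # 0 bits
#' @export
entropy <- function(probs) {
  validate_distribution(probs)
  -sum(xlog2x(probs))
}

#' Conditional entropy H(Y | Z) from a joint distribution
#'
#' Computed as \eqn{H(Y, Z) - H(Z)}, where rows of `joint` index values of
#' Y and columns index values of Z.
#'
#' @param joint Matrix of joint probabilities p(y, z) summing to 1.
#' @return Conditional entropy in bits; lies in `[0, H(Y)]`.
#' @export
conditional_entropy <- function(joint) {
  validate_joint(joint)
  h_yz <- -sum(xlog2x(as.numeric(joint)))
  h_z <- -sum(xlog2x(colSums(joint)))
  max(h_yz - h_z, 0)
}

#' Mutual information I(Y; Z) from a joint distribution
#'
#' Computed as \eqn{H(Y) - H(Y | Z)}; symmetric in its arguments and
#' bounded by `min(H(Y), H(Z))`.
#'
#' @inheritParams conditional_entropy
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(joint) {
  validate_joint(joint)
  h_y <- -sum(xlog2x(rowSums(joint)))
  max(h_y - conditional_entropy(joint), 0)
}

## Natural-log KL divergence between rows of p and a single distribution q.
## p: matrix (rows are distributions), q: vector. Returns vector (one per row).
## Rows placing mass where q has none yield Inf.
kl_rows_nats <- function(p, q) {
  lq <- ifelse(q > 0, log(q), -Inf)
  out <- numeric(nrow(p))
  for (j in seq_along(q)) {
    pj <- p[, j]
    contrib <- numeric(length(pj))
    pos <- pj > 0
    contrib[pos] <- pj[pos] * (log(pj[pos]) - lq[j])
    out <- out + contrib
  }
  out
}
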