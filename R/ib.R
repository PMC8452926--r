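#' Generalized information bottleneck
#'
#' Given a joint distribution p(x, c), the information bottleneck finds a
#' (soft) clustering P of X that trades compression against the information
#' kept about the class C. The generalized objective
#' \deqn{H(P) - \alpha H(P|X) - \beta I(P;C)}
#' recovers the original bottleneck at `alpha = 1` (where
#' `H(P) - H(P|X) = I(P;X)`) and the deterministic bottleneck at
#' `alpha = 0`, whose optimal encoder is a function of X. Minimisation is
#' over encoders q(p|x) subject to the Markov chain C - X - P, by the
#' self-consistent fixed-point iteration: score each (x, p) as
#' `log q(p) - beta * KL(p(c|x) || q(c|p))`, set q(p|x) proportional to
#' `exp(score / alpha)` (hard argmax at `alpha = 0`, ties to the lowest
#' cluster index), then refresh q(p) and the decoder q(c|p).
#'
#' @name ib_core
NULL

#' Configuration for the information-bottleneck solver
#'
#' @param alpha Interpolation parameter in `[0, 1]`: 0 = deterministic IB,
#'   1 = original IB.
#' @param beta Positive trade-off weight on I(P;C).
#' @param n_clusters Number of values allowed for P (default: number of
#'   classes, set by the caller).
#' @param max_iter Maximum fixed-point iterations per restart.
#' @param tol Convergence threshold on the absolute objective change (bits).
#' @param restarts Number of random initialisations; the lowest-objective
#'   solution is returned.
#' @param seed Integer seed controlling the initialisations.
#' @param pmin Support threshold echoed to [build_joint()] by high-level
#'   callers.
#' @return List of class `"ib_config"`.
#' @export
ib_config <- function(alpha = 1, beta = 100, n_clusters = NULL,
                      max_iter = 1000L, tol = 1e-8, restarts = 20L,
                      seed = 1L, pmin = 1e-12) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta <= 0) stop("beta must be positive")
  if (!is.null(n_clusters) && n_clusters < 1) {
    stop("n_clusters must be at least 1")
  }
  if (tol <= 0) stop("tol must be positive")
  structure(list(alpha = alpha, beta = beta, n_clusters = n_clusters,
                 max_iter = as.integer(max_iter), tol = tol,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 pmin = pmin),
            class = "ib_config")
}

## Information quantities (bits) of an encoder against p(x) and p(c|x).
## Returns the pieces needed for the objective and the solution record.
ib_quantities <- function(encoder, p_x, p_c_given_x, prior_c) {
  q_p <- as.numeric(crossprod(encoder, p_x))          # q(p)
  h_p <- -sum(xlog2x(q_p))
  h_p_given_x <- -sum(p_x * rowSums(xlog2x(encoder)))
  # joint q(p, c) = sum_x p(x) q(p|x) p(c|x)
  q_pc <- crossprod(encoder, p_x * p_c_given_x)       # clusters x classes
  h_pc <- -sum(xlog2x(as.numeric(q_pc)))
  h_c <- -sum(xlog2x(prior_c))
  i_pc <- max(h_p + h_c - h_pc, 0)
  list(q_p = q_p, q_pc = q_pc, H_P = h_p, H_P_given_X = h_p_given_x,
       I_PX = max(h_p - h_p_given_x, 0), I_PC = i_pc)
}

ib_objective_value <- function(qt, alpha, beta) {
  qt$H_P - alpha * qt$H_P_given_X - beta * qt$I_PC
}

#' Evaluate the generalized IB objective of a solution
#'
#' Returns `H(P) - alpha * H(P|X) - beta * I(P;C)` in bits. At `alpha = 1`
#' this equals `I(P;X) - beta * I(P;C)`; at `alpha = 0` it is
#' `H(P) - beta * I(P;C)`.
#'
#' @param solution An `"ib_solution"`.
#' @param alpha,beta Objective parameters.
#' @return Objective value in bits.
#' @export
ib_objective <- function(solution, alpha, beta) {
  stopifnot(inherits(solution, "ib_solution"))
  solution$H_P - alpha * solution$H_P_given_X - beta * solution$I_PC
}

## One restart of the fixed-point iteration. Returns encoder + diagnostics.
ib_fixed_point <- function(encoder, p_x, p_c_given_x, prior_c,
                           alpha, beta, max_iter, tol) {
  n_clusters <- ncol(encoder)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    q_p <- as.numeric(crossprod(encoder, p_x))
    q_pc <- crossprod(encoder, p_x * p_c_given_x)
    # decoder rows for occupied clusters
    decoder <- q_pc
    occ <- q_p > 0
    decoder[occ, ] <- decoder[occ, , drop = FALSE] / q_p[occ]
    # score(x, p) = ln q(p) - beta * KL_nats(p(c|x) || q(c|p)); equals
    # ln(2) times the bracket [log2 q(p) - beta * KL_bits], so argmax and
    # exp(score/alpha) match the base-2 statement of the update
    score <- matrix(-Inf, nrow = nrow(encoder), ncol = n_clusters)
    for (p in which(occ)) {
      score[, p] <- log(q_p[p]) -
        beta * kl_rows_nats(p_c_given_x, decoder[p, ])
    }
    if (alpha == 0) {
      new_enc <- matrix(0, nrow = nrow(encoder), ncol = n_clusters)
      best <- apply(score, 1L, which.max)   # ties -> lowest index
      new_enc[cbind(seq_len(nrow(encoder)), best)] <- 1
    } else {
      # softmax with temperature alpha, row-wise, numerically stabilised
      z <- score / alpha
      zmax <- apply(z, 1L, max)
      w <- exp(z - zmax)
      w[!is.finite(w)] <- 0
      rs <- rowSums(w)
      # all-(-Inf) rows (x with no feasible cluster) -> keep previous row
      bad <- rs == 0 | !is.finite(zmax)
      w[bad, ] <- encoder[bad, , drop = FALSE]
      rs[bad] <- 1
      new_enc <- w / rowSums(w)
    }
    encoder <- new_enc
    qt <- ib_quantities(encoder, p_x, p_c_given_x, prior_c)
    obj <- ib_objective_value(qt, alpha, beta)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) && abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }
  list(encoder = encoder, qt = qt, objective = obj, trace = obj_trace,
       iterations = length(obj_trace))
}

#' Solve the generalized information bottleneck
#'
#' Runs the fixed-point iteration from `restarts` random initialisations
#' and returns the solution with the lowest objective. The joint is
#' restricted to `x_support` (cells with marginal at least `pmin`) and
#' renormalised; filtered cells carry no encoder row and are reported in
#' `dropped_x`.
#'
#' @param joint A `"joint_xc"` from [build_joint()].
#' @param config An [ib_config()].
#' @return Object of class `"ib_solution"`: `encoder` (support x clusters),
#'   `marginal` q(p), `decoder` q(c|p), `objective`, `H_P`, `H_P_given_X`,
#'   `I_PX`, `I_PC`, `I_XC` (of the solved joint), `occupied_clusters`,
#'   `x_support`, `dropped_x`, `config`, `trace` of the winning restart.
#' @export
solve_generalized_ib <- function(joint, config = ib_config()) {
  stopifnot(inherits(joint, "joint_xc"), inherits(config, "ib_config"))
  support <- joint$x_support
  if (length(support) == 0L) {
    stop("degenerate input: no bin cells above the pmin threshold")
  }
  n_classes <- length(joint$classes)
  n_clusters <- config$n_clusters
  if (is.null(n_clusters)) n_clusters <- n_classes
  if (n_clusters < 1L) stop("n_clusters must be at least 1")

  p_xc <- joint$p_xc[support, , drop = FALSE]
  p_xc <- p_xc / sum(p_xc)
  p_x <- rowSums(p_xc)
  p_c_given_x <- p_xc / p_x
  prior_c <- colSums(p_xc)
  i_xc <- mutual_information(p_xc)

  n_x <- length(support)
  best <- NULL
  set.seed(config$seed)
  for (r in seq_len(config$restarts)) {
    if (config$alpha == 0) {
      init <- matrix(0, nrow = n_x, ncol = n_clusters)
      init[cbind(seq_len(n_x),
                 sample.int(n_clusters, n_x, replace = TRUE))] <- 1
    } else {
      # symmetric Dirichlet(1) rows
      g <- matrix(stats::rgamma(n_x * n_clusters, shape = 1),
                  nrow = n_x)
      init <- g / rowSums(g)
    }
    run <- ib_fixed_point(init, p_x, p_c_given_x, prior_c,
                          config$alpha, config$beta,
                          config$max_iter, config$tol)
    if (is.null(best) || run$objective < best$objective) best <- run
  }

  qt <- best$qt
  occ <- which(qt$q_p > 0)
  decoder <- qt$q_pc
  decoder[occ, ] <- decoder[occ, , drop = FALSE] / qt$q_p[occ]
  structure(list(encoder = best$encoder, marginal = qt$q_p,
                 decoder = decoder, objective = best$objective,
                 H_P = qt$H_P, H_P_given_X = qt$H_P_given_X,
                 I_PX = qt$I_PX, I_PC = qt$I_PC, I_XC = i_xc,
                 occupied_clusters = occ,
                 x_support = support,
                 dropped_x = setdiff(seq_len(joint$indexer$n_cells),
                                     support),
                 n_classes = n_classes, classes = joint$classes,
                 config = config, trace = best$trace,
                 iterations = best$iterations),
            class = "ib_solution")
}

#' @export
print.ib_solution <- function(x, ...) {
  cat("Information-bottleneck solution\n")
  cat(sprintf("  alpha = %g, beta = %g, %d clusters (%d occupied)\n",
              x$config$alpha, x$config$beta, ncol(x$encoder),
              length(x$occupied_clusters)))
  cat(sprintf("  H(P) = %.4f  H(P|X) = %.4f  I(P;X) = %.4f  I(P;C) = %.4f bits\n",
              x$H_P, x$H_P_given_X, x$I_PX, x$I_PC))
  cat(sprintf("  objective = %.4f bits after %d iterations\n",
              x$objective, x$iterations))
  invisible(x)
}

#' Exhaustive deterministic-IB oracle
#'
#' Enumerates every deterministic encoder (map from support cells to
#' clusters) and returns the global minimiser of
#' `H(P) - beta * I(P;C)`. Intended as an independent check of the
#' iterative solver on small instances; guarded to
#' `n_clusters ^ |support| <= max_maps`.
#'
#' @inheritParams solve_generalized_ib
#' @param beta Positive trade-off parameter.
#' @param n_clusters Number of clusters.
#' @param max_maps Guard on the enumeration size.
#' @return An `"ib_solution"` with a deterministic encoder.
#' @export
exhaustive_dib_oracle <- function(joint, beta, n_clusters,
                                  max_maps = 600000) {
  stopifnot(inherits(joint, "joint_xc"), beta > 0, n_clusters >= 1)
  support <- joint$x_support
  n_x <- length(support)
  n_maps <- n_clusters^n_x
  if (n_maps > max_maps) {
    stop("instance too large for exhaustive enumeration: ", n_maps,
         " deterministic maps")
  }
  p_xc <- joint$p_xc[support, , drop = FALSE]
  p_xc <- p_xc / sum(p_xc)
  n_classes <- ncol(p_xc)
  prior_c <- colSums(p_xc)
  h_c <- -sum(xlog2x(prior_c))

  # all maps as an n_maps x n_x integer matrix, enumerated mixed-radix
  maps <- as.matrix(expand.grid(rep(list(seq_len(n_clusters)), n_x),
                                KEEP.OUT.ATTRS = FALSE))
  # q(p, c) per map, accumulated vectorised over maps
  q_pc <- matrix(0, nrow = n_maps, ncol = n_clusters * n_classes)
  for (x in seq_len(n_x)) {
    for (p in seq_len(n_clusters)) {
      hit <- maps[, x] == p
      if (!any(hit)) next
      for (cc in seq_len(n_classes)) {
        col <- (p - 1L) * n_classes + cc
        q_pc[hit, col] <- q_pc[hit, col] + p_xc[x, cc]
      }
    }
  }
  q_p <- sapply(seq_len(n_clusters), function(p) {
    rowSums(q_pc[, (p - 1L) * n_classes + seq_len(n_classes), drop = FALSE])
  })
  if (is.null(dim(q_p))) q_p <- matrix(q_p, nrow = n_maps)
  h_p <- -rowSums(matrix(xlog2x(as.numeric(q_p)), nrow = n_maps))
  h_pc <- -rowSums(matrix(xlog2x(as.numeric(q_pc)), nrow = n_maps))
  i_pc <- pmax(h_p + h_c - h_pc, 0)
  objective <- h_p - beta * i_pc
  best <- which.min(objective)

  encoder <- matrix(0, nrow = n_x, ncol = n_clusters)
  encoder[cbind(seq_len(n_x), maps[best, ])] <- 1
  p_x <- rowSums(p_xc)
  p_c_given_x <- p_xc / p_x
  qt <- ib_quantities(encoder, p_x, p_c_given_x, prior_c)
  occ <- which(qt$q_p > 0)
  decoder <- qt$q_pc
  decoder[occ, ] <- decoder[occ, , drop = FALSE] / qt$q_p[occ]
  structure(list(encoder = encoder, marginal = qt$q_p, decoder = decoder,
                 objective = objective[best],
                 H_P = qt$H_P, H_P_given_X = qt$H_P_given_X,
                 I_PX = qt$I_PX, I_PC = qt$I_PC,
                 I_XC = mutual_information(p_xc),
                 occupied_clusters = occ, x_support = support,
                 dropped_x = setdiff(seq_len(joint$indexer$n_cells),
                                     support),
                 n_classes = n_classes, classes = joint$classes,
                 config = ib_config(alpha = 0, beta = beta,
                                    n_clusters = n_clusters),
                 trace = objective[best], iterations = 1L,
                 all_objectives = objective),
            class = "ib_solution")
}
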