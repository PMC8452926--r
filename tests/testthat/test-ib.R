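test_that("uninformative joints collapse to a single cluster", {
  # p(c|x) identical for every x: nothing to preserve
  m <- matrix(rep(c(0.2, 0.3, 0.5), each = 4) / 4, nrow = 4)
  joint <- joint_from_matrix(m)
  sol <- solve_generalized_ib(joint, ib_config(alpha = 0, beta = 50,
                                               restarts = 10, seed = 1))
  expect_equal(length(sol$occupied_clusters), 1L)
  expect_equal(sol$I_PC, 0, tolerance = 1e-9)
  expect_equal(sol$H_P, 0, tolerance = 1e-9)
})

test_that("a lossless deterministic encoder is found when one exists", {
  joint <- separable_joint(cells_per_class = 2, n_c = 2)
  sol <- solve_generalized_ib(joint, ib_config(alpha = 0, beta = 10,
                                               n_clusters = 2,
                                               restarts = 20, seed = 2))
  expect_equal(sol$I_PC, mutual_information(joint$p_xc), tolerance = 1e-9)
  expect_equal(sol$H_P_given_X, 0)
})

test_that("best-of-restarts deterministic solver matches exhaustive enumeration", {
  matched <- 0L
  for (s in 1:20) {
    joint <- rand_joint(sample(4:10, 1), 3, seed = s)
    sol <- solve_generalized_ib(joint, ib_config(alpha = 0, beta = 100,
                                                 restarts = 50,
                                                 seed = s + 500))
    oracle <- exhaustive_dib_oracle(joint, beta = 100, n_clusters = 3)
    # the oracle is the global minimum over every deterministic encoder
    expect_gte(sol$objective, oracle$objective - 1e-9)
    expect_true(all(oracle$all_objectives >= oracle$objective))
    if (abs(sol$objective - oracle$objective) < 1e-9) matched <- matched + 1L
  }
  expect_gte(matched, 19L)
})

test_that("deterministic solutions are exactly hard; soft encoders stay on the simplex", {
  joint <- rand_joint(8, 3, seed = 3)
  sol0 <- solve_generalized_ib(joint, ib_config(alpha = 0, beta = 100,
                                                restarts = 10, seed = 4))
  expect_true(all(sol0$encoder %in% c(0, 1)))
  expect_identical(sol0$H_P_given_X, 0)
  sol1 <- solve_generalized_ib(joint, ib_config(alpha = 1, beta = 100,
                                                restarts = 10, seed = 4))
  expect_equal(rowSums(sol1$encoder), rep(1, 8), tolerance = 1e-9)
  expect_true(all(sol1$encoder >= 0))
})

test_that("the objective trace is non-increasing within a restart", {
  for (s in 1:5) {
    joint <- rand_joint(9, 3, seed = 20 + s)
    for (alpha in c(0, 1)) {
      sol <- solve_generalized_ib(joint, ib_config(alpha = alpha, beta = 30,
                                                   restarts = 1,
                                                   seed = 30 + s))
      expect_true(all(diff(sol$trace) <= 1e-9))
    }
  }
})

test_that("every solution respects the data processing inequality", {
  for (s in 1:10) {
    joint <- rand_joint(10, 3, seed = 40 + s)
    for (alpha in c(0, 0.5, 1)) {
      sol <- solve_generalized_ib(joint, ib_config(alpha = alpha,
                                                   beta = 100,
                                                   restarts = 5,
                                                   seed = 50 + s))
      expect_lte(sol$I_PC, mutual_information(joint$p_xc) + 1e-9)
    }
  }
})

test_that("alpha = 1 solutions on well-separated joints are near-deterministic", {
  joint <- separable_joint(cells_per_class = 3, n_c = 3)
  sol <- solve_generalized_ib(joint, ib_config(alpha = 1, beta = 100,
                                               restarts = 10, seed = 6))
  expect_lte(sol$H_P_given_X, 0.07)
})

test_that("objective identities hold at the alpha extremes", {
  joint <- rand_joint(8, 3, seed = 7)
  sol <- solve_generalized_ib(joint, ib_config(alpha = 1, beta = 40,
                                               restarts = 5, seed = 8))
  expect_equal(ib_objective(sol, 1, 40), sol$I_PX - 40 * sol$I_PC,
               tolerance = 1e-9)
  expect_equal(ib_objective(sol, 0, 40), sol$H_P - 40 * sol$I_PC,
               tolerance = 1e-12)
})

test_that("configuration and degenerate inputs error cleanly", {
  expect_error(ib_config(beta = 0), "beta")
  expect_error(ib_config(alpha = 2), "alpha")
  expect_error(ib_config(n_clusters = 0), "n_clusters")
  m <- matrix(c(0.5, 0.5), ncol = 2)
  joint <- joint_from_matrix(m, pmin = 2) # impossible threshold
  expect_error(solve_generalized_ib(joint, ib_config()), "degenerate")
  expect_error(exhaustive_dib_oracle(rand_joint(10, 3, 1), beta = 10,
                                     n_clusters = 3, max_maps = 100),
               "too large")
})

test_that("filtered cells are reported as unclassifiable", {
  m <- rbind(c(0.5, 0.4), c(0.05, 0.049), c(1e-15, 1e-16), c(0.001, 0))
  m <- m / sum(m)
  joint <- joint_from_matrix(m, pmin = 1e-9)
  sol <- solve_generalized_ib(joint, ib_config(alpha = 0, beta = 10,
                                               restarts = 5, seed = 9))
  expect_true(3L %in% sol$dropped_x)
  expect_equal(nrow(sol$encoder), length(sol$x_support))
})
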