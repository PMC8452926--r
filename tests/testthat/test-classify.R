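fit_easy <- function(seed = 1, ...) {
  feats <- easy_features(seed = seed)
  list(feats = feats,
       clf = fit_ib_classifier(feats, config = ib_config(restarts = 10,
                                                         seed = seed + 100),
                               ...))
}

test_that("training on well-separated data reaches near-perfect accuracy", {
  fe <- fit_easy(seed = 1)
  pred <- predict_c1(fe$clf, feature_matrix(fe$feats))
  acc <- mean(pred == fe$feats$label, na.rm = TRUE)
  expect_gte(acc, 0.99)
  expect_gte(mean(!is.na(pred)), 0.9)
})

test_that("shuffled labels leave almost no class information", {
  feats <- easy_features(seed = 2)
  set.seed(99)
  feats$label <- sample(feats$label)
  clf <- fit_ib_classifier(feats, config = ib_config(restarts = 10,
                                                     seed = 3))
  expect_lte(clf$solution$I_PC, 0.05)
})

test_that("refitting with the same seed reproduces the classifier", {
  fe1 <- fit_easy(seed = 4)
  fe2 <- fit_easy(seed = 4)
  expect_identical(fe1$clf$solution$encoder, fe2$clf$solution$encoder)
  expect_identical(fe1$clf$mapping, fe2$clf$mapping)
})

test_that("the cluster mapping maximises training accuracy over injective maps", {
  fe <- fit_easy(seed = 5)
  clf <- fe$clf
  feats <- fe$feats
  xs <- sample_to_x(feature_matrix(feats), clf$spec, clf$indexer)
  cl <- clf$cluster_of_x[xs]
  truth <- match(feats$label, clf$classes)
  keep <- !is.na(cl)
  occ <- clf$solution$occupied_clusters
  # brute force over all injective maps of occupied clusters to classes
  accs <- apply(as.matrix(expand.grid(1:3, 1:3, 1:3)), 1, function(assign) {
    if (anyDuplicated(assign[seq_along(occ)])) return(-1)
    full <- rep(NA_integer_, ncol(clf$solution$encoder))
    full[occ] <- assign[seq_along(occ)]
    mean(full[cl[keep]] == truth[keep])
  })
  chosen <- mean(clf$mapping[cl[keep]] == truth[keep])
  expect_equal(chosen, max(accs), tolerance = 1e-12)
})

test_that("point-rule prediction rejects filtered and ambiguous cells", {
  fe <- fit_easy(seed = 6)
  clf <- fe$clf
  # a cell outside the support is unclassified
  dropped <- clf$solution$dropped_x
  if (length(dropped) > 0) {
    expect_true(is.na(clf$mapping[clf$cluster_of_x[dropped[1]]]))
  }
  # soft encoder row below 1 - tau is rejected under the strict rule
  clf_strict <- clf
  clf_strict$tau <- 1e-12
  enc <- clf$solution$encoder
  soft_rows <- which(apply(enc, 1, max) < 1 - 1e-12)
  if (length(soft_rows) > 0) {
    lookup <- ibbci:::cluster_lookup(clf_strict)
    expect_true(all(is.na(lookup[clf$solution$x_support[soft_rows]])))
  }
  expect_error(predict_c1(clf, matrix(0, 1, 5)), "dimension")
})

test_that("vote-threshold range matches the neighbourhood count", {
  r <- valid_t_range(4, 3)
  expect_equal(r$t_min, 365L)
  expect_equal(r$t_max, 729L)
  expect_true(600 >= r$t_min && 600 <= r$t_max)
  r0 <- valid_t_range(0, 3)
  expect_equal(c(r0$t_min, r0$t_max), c(1L, 1L))
  r1 <- valid_t_range(1, 3)
  expect_equal(c(r1$t_min, r1$t_max), c(14L, 27L))
})

test_that("the neighbourhood rule at n = 0, t = 1 reproduces the point rule", {
  fe <- fit_easy(seed = 7)
  clf <- fe$clf
  # exhaustive sweep over every bin vector of the trained model
  grid <- x_decode(seq_len(clf$indexer$n_cells), clf$indexer)
  # convert bin vectors to representative feature values (bin midpoints)
  mids <- lapply(clf$spec$edges, function(e) (e[-1] + e[-length(e)]) / 2)
  vals <- sapply(seq_len(ncol(grid)), function(i) mids[[i]][grid[, i]])
  p1 <- predict_c1(clf, vals)
  p2 <- predict_c2(clf, vals, n = 0, t = 1)
  expect_identical(p1, p2)
})

test_that("raising the vote threshold weakly shrinks the classified set", {
  cfgn <- synthetic_config(delta = 1.5, samples_per_class = 200, seed = 8)
  feats <- generate_features(cfgn)
  clf <- fit_ib_classifier(feats, config = ib_config(restarts = 10,
                                                     seed = 9))
  vals <- feature_matrix(feats)
  prev <- NULL
  for (t in c(14, 18, 22, 27)) {
    pred <- predict_c2(clf, vals, n = 1, t = t)
    classified <- which(!is.na(pred))
    if (!is.null(prev)) expect_true(all(classified %in% prev))
    prev <- classified
  }
})

test_that("the majority bound forbids two winners", {
  # with t above half the neighbourhood size, predict_c2 never raises the
  # ambiguity error over an exhaustive sweep of cells
  fe <- fit_easy(seed = 10)
  clf <- fe$clf
  mids <- lapply(clf$spec$edges, function(e) (e[-1] + e[-length(e)]) / 2)
  grid <- x_decode(seq_len(clf$indexer$n_cells), clf$indexer)
  vals <- sapply(seq_len(ncol(grid)), function(i) mids[[i]][grid[, i]])
  expect_silent(predict_c2(clf, vals, n = 1, t = 14))
})

test_that("the argmax rule classifies whenever the cell is in support", {
  feats <- easy_features(seed = 11)
  clf <- fit_ib_classifier(feats, config = ib_config(alpha = 1, restarts = 5,
                                                     seed = 12),
                           rule = "argmax")
  pred <- predict_c1(clf, feature_matrix(feats))
  xs <- sample_to_x(feature_matrix(feats), clf$spec, clf$indexer)
  in_support <- xs %in% clf$solution$x_support
  mapped <- !is.na(clf$mapping[clf$cluster_of_x[xs]])
  expect_equal(!is.na(pred), in_support & mapped)
})
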