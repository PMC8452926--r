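#' Reading and writing the package's text formats
#'
#' Feature tables are delimited text with header
#' `trial,t,label,f1,...,fN`. EEG segments are delimited text with a
#' `# fs=<Hz>` header line followed by one row per channel. Trained
#' classifiers and bottleneck solutions serialise to JSON.
#'
#' @name io
NULL

#' Write / read a feature table
#'
#' @param features Feature table `data.frame`.
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path, sep = ",") {
  check_feature_table(features)
  utils::write.table(features, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, sep = ",") {
  out <- utils::read.table(path, header = TRUE, sep = sep)
  check_feature_table(out)
  out
}

#' Write / read multichannel EEG as delimited text
#'
#' @param signal An `"eeg_signal"`.
#' @param path File path.
#' @return `read_eeg_text` returns an `"eeg_signal"`.
#' @export
write_eeg_text <- function(signal, path) {
  stopifnot(inherits(signal, "eeg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fs=", signal$fs), con)
  utils::write.table(signal$samples, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_text
#' @export
read_eeg_text <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# fs=", header)) stop("missing '# fs=' header line")
  fs <- as.numeric(sub("^# fs=", "", header))
  mat <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  dimnames(mat) <- NULL
  structure(list(samples = mat, fs = fs, duration = ncol(mat) / fs),
            class = "eeg_signal")
}

#' Serialise a bottleneck solution to JSON
#'
#' Encoder and decoder are written as nested arrays with the configuration
#' echoed; deterministic given the solver seed.
#'
#' @param solution An `"ib_solution"`.
#' @param path File path.
#' @export
write_ib_solution <- function(solution, path) {
  stopifnot(inherits(solution, "ib_solution"))
  payload <- list(
    encoder = unclass(solution$encoder),
    marginal = solution$marginal,
    decoder = unclass(solution$decoder),
    objective = solution$objective,
    H_P = solution$H_P, H_P_given_X = solution$H_P_given_X,
    I_PX = solution$I_PX, I_PC = solution$I_PC, I_XC = solution$I_XC,
    occupied_clusters = solution$occupied_clusters,
    x_support = solution$x_support,
    classes = solution$classes,
    config = unclass(solution$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise / restore a trained classifier
#'
#' The full model (bin edges, conditional probabilities, encoder, cluster
#' mapping, reject parameters) round-trips through a single JSON document.
#'
#' @param clf An `"ib_classifier"`.
#' @param path File path.
#' @return `read_classifier` returns the restored `"ib_classifier"`.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "ib_classifier"))
  cfg <- unclass(clf$solution$config)
  if (is.null(cfg$n_clusters)) cfg$n_clusters <- ncol(clf$solution$encoder)
  payload <- list(
    classes = clf$classes,
    tau = clf$tau,
    rule = clf$rule,
    mapping = clf$mapping,
    spec = list(edges = clf$spec$edges, n_bins = clf$spec$n_bins,
                estimator = clf$spec$estimator,
                features = clf$spec$features),
    model = list(method = clf$model$method,
                 probs = lapply(clf$model$probs, unclass)),
    prior = clf$joint$prior,
    pmin = clf$joint$pmin,
    solution = list(encoder = unclass(clf$solution$encoder),
                    marginal = clf$solution$marginal,
                    decoder = unclass(clf$solution$decoder),
                    objective = clf$solution$objective,
                    H_P = clf$solution$H_P,
                    H_P_given_X = clf$solution$H_P_given_X,
                    I_PX = clf$solution$I_PX, I_PC = clf$solution$I_PC,
                    I_XC = clf$solution$I_XC,
                    occupied_clusters = clf$solution$occupied_clusters,
                    x_support = clf$solution$x_support,
                    config = cfg)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## nested JSON array (list of row lists) -> numeric matrix
json_matrix <- function(x) {
  do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  p$classes <- unlist(p$classes)
  spec <- structure(list(edges = lapply(p$spec$edges,
                                        function(e) as.numeric(unlist(e))),
                         n_bins = as.integer(unlist(p$spec$n_bins)),
                         estimator = p$spec$estimator,
                         features = unlist(p$spec$features)),
                    class = "binning_spec")
  probs <- lapply(p$model$probs, function(m) {
    out <- json_matrix(m)
    rownames(out) <- as.character(p$classes)
    out
  })
  model <- structure(list(probs = probs,
                          classes = p$classes, method = p$model$method,
                          spec = spec, fits = NULL),
                     class = "cond_feature_model")
  idx <- x_indexer(spec$n_bins)
  cl <- p$solution$config
  cfg <- ib_config(alpha = cl$alpha, beta = cl$beta,
                   n_clusters = cl$n_clusters, max_iter = cl$max_iter,
                   tol = cl$tol, restarts = cl$restarts, seed = cl$seed,
                   pmin = cl$pmin)
  sol <- structure(list(encoder = json_matrix(p$solution$encoder),
                        marginal = as.numeric(unlist(p$solution$marginal)),
                        decoder = json_matrix(p$solution$decoder),
                        objective = p$solution$objective,
                        H_P = p$solution$H_P,
                        H_P_given_X = p$solution$H_P_given_X,
                        I_PX = p$solution$I_PX, I_PC = p$solution$I_PC,
                        I_XC = p$solution$I_XC,
                        occupied_clusters =
                          as.integer(unlist(p$solution$occupied_clusters)),
                        x_support = as.integer(unlist(p$solution$x_support)),
                        dropped_x = setdiff(
                          seq_len(idx$n_cells),
                          as.integer(unlist(p$solution$x_support))),
                        n_classes = length(p$classes),
                        classes = p$classes, config = cfg,
                        trace = NA_real_, iterations = NA_integer_),
                   class = "ib_solution")
  joint <- build_joint(model, prior = as.numeric(unlist(p$prior)),
                       pmin = p$pmin)
  mapping <- vapply(p$mapping, function(m) {
    if (is.null(m)) NA_integer_ else as.integer(m)
  }, integer(1))
  clf <- structure(list(spec = spec, model = model, joint = joint,
                        solution = sol, classes = p$classes,
                        indexer = idx, tau = p$tau, rule = p$rule,
                        mapping = mapping,
                        cluster_of_x = NULL),
                   class = "ib_classifier")
  clf$cluster_of_x <- cluster_lookup(clf)
  clf
}
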