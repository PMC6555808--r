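# Learned sleep-wake classifiers.
#
# Classical models (logistic regression, linear SVM, perceptron, extra
# trees) consume a sliding-window feature matrix; sequence models (small
# CNN / LSTM reference stacks, see nets.R) consume fixed-width windows of
# raw counts. Hyperparameters are chosen by k-fold cross-validation
# maximizing accuracy, then the winning configuration is refit on all data.

#' Build a window dataset for sequence models
#'
#' The window for epoch `t` covers epochs
#' `[t - floor(width/2), t + ceiling(width/2) - 1]`, zero-padded outside the
#' series, so there is exactly one window per epoch.
#'
#' @param counts Numeric vector of activity counts.
#' @param width Window width in epochs (20, 50 or 100 are the conventional
#'   choices).
#' @return Object of class `window_dataset` with fields `width`, `windows`
#'   (matrix, one row per epoch) and `alignment`.
#' @export
make_window_dataset <- function(counts, width) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    abort_validation("empty count sequence")
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width < 1)
    abort_validation("width must be a positive integer")
  width <- as.integer(width)
  own_missing <- is.na(counts)
  x <- ifelse(own_missing, 0, counts)
  before <- width %/% 2L
  after <- width - before - 1L
  W <- .window_mat(x, before, after)
  structure(list(width = width, windows = W,
                 alignment = seq_along(counts) - 1L,
                 own_missing = own_missing),
            class = "window_dataset")
}

.default_grids <- list(
  logistic_regression = list(lambda = c(1e-4, 1e-2, 1e-1)),
  linear_svm = list(cost = c(0.1, 1, 10)),
  perceptron = list(n_iter = c(5L, 25L)),
  extra_trees = list(num_trees = c(50L), mtry_frac = c(0.1, 0.35)),
  cnn = list(filters = c(4L), lr = c(0.1)),
  lstm = list(hidden = c(6L), lr = c(0.05))
)

.known_algorithms <- names(.default_grids)
.window_algorithms <- c("cnn", "lstm")

.as_input_matrix <- function(inputs) {
  if (inherits(inputs, "window_dataset")) inputs$windows
  else as.matrix(inputs)
}

.input_contract <- function(inputs) {
  if (inherits(inputs, "window_dataset"))
    list(type = "window", width = inputs$width)
  else
    list(type = "features", columns = colnames(inputs))
}

# Fold assignment. Subject-level folds (by `groups`) are the default to
# avoid within-subject leakage; without groups, contiguous epoch blocks are
# used.
.make_folds <- function(n, folds, groups = NULL) {
  if (!is.null(groups)) {
    ug <- unique(groups)
    gf <- sample(rep_len(seq_len(folds), length(ug)))
    gf[match(groups, ug)]
  } else {
    cut(seq_len(n), breaks = folds, labels = FALSE)  # contiguous blocks
  }
}

.fit_one <- function(algorithm, X, y, hyper, seed) {
  with_seed(seed, switch(
    algorithm,
    logistic_regression = {
      fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = hyper$lambda)
      list(kind = "glmnet", fit = fit, lambda = hyper$lambda)
    },
    linear_svm = {
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                        cost = hyper$cost, scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    perceptron = fit_perceptron(X, y, n_iter = hyper$n_iter),
    extra_trees = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(.y ~ ., data = df,
                            num.trees = hyper$num_trees,
                            mtry = max(1L, floor(hyper$mtry_frac * ncol(X))),
                            splitrule = "extratrees",
                            seed = seed, num.threads = 1L)
      list(kind = "ranger", fit = fit)
    },
    cnn = fit_cnn(X, y, filters = hyper$filters, lr = hyper$lr, seed = seed),
    lstm = fit_lstm(X, y, hidden = hyper$hidden, lr = hyper$lr, seed = seed),
    abort_config("unknown algorithm '%s'", algorithm)))
}

.predict_one <- function(model, X) {
  switch(model$kind,
         glmnet = as.integer(stats::predict(model$fit, X, s = model$lambda,
                                            type = "response") > 0.5),
         svm = as.integer(as.character(stats::predict(model$fit, X))),
         perceptron = predict_perceptron(model, X),
         ranger = {
           df <- as.data.frame(X)
           names(df) <- paste0("f", seq_len(ncol(X)))
           as.integer(as.character(
             stats::predict(model$fit, df, num.threads = 1L)$predictions))
         },
         cnn = predict_cnn(model, X),
         lstm = predict_lstm(model, X),
         abort_config("unknown fitted model kind '%s'", model$kind))
}

#' Train a sleep-wake classifier
#'
#' Performs a grid search over `search_space` by k-fold cross-validation
#' maximizing epoch accuracy, then refits the winning configuration on all
#' data. Fully reproducible given `seed`.
#'
#' @param inputs A feature matrix from [extract_features()] or a
#'   `window_dataset` from [make_window_dataset()] (required for `"cnn"` and
#'   `"lstm"`).
#' @param labels Aligned binary hypnogram; missing-label epochs are excluded
#'   from training.
#' @param algorithm One of `"logistic_regression"`, `"linear_svm"`,
#'   `"perceptron"`, `"extra_trees"`, `"cnn"`, `"lstm"`.
#' @param search_space Named list of hyperparameter value vectors; defaults
#'   to a small built-in grid per algorithm.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer training seed.
#' @param groups Optional per-epoch subject ids; when given, CV folds are
#'   formed at the subject level (the default protocol) rather than by
#'   contiguous epoch blocks.
#' @return Object of class `trained_model`.
#' @export
train_classifier <- function(inputs, labels, algorithm,
                             search_space = NULL, folds = 5L, seed = 1L,
                             groups = NULL) {
  if (!algorithm %in% .known_algorithms)
    abort_config("unknown algorithm '%s' (known: %s)", algorithm,
                 paste(.known_algorithms, collapse = ", "))
  if (algorithm %in% .window_algorithms &&
      !inherits(inputs, "window_dataset"))
    abort_validation("algorithm '%s' requires a window_dataset input",
                     algorithm)
  X <- .as_input_matrix(inputs)
  labels <- as_hypnogram(labels)
  if (nrow(X) != length(labels))
    abort_validation("inputs and labels are not aligned")
  keep <- !is.na(labels)
  if (!is.null(groups)) {
    if (length(groups) != length(labels))
      abort_validation("groups and labels are not aligned")
    groups <- groups[keep]
  }
  X <- X[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) < 2L)
    abort_validation("labels contain a single class; nothing to learn")

  search_space <- search_space %||% .default_grids[[algorithm]]
  if (!is.list(search_space) || length(search_space) == 0L ||
      any(lengths(search_space) == 0L))
    abort_config("empty hyperparameter grid")
  grid <- expand.grid(search_space, stringsAsFactors = FALSE)

  fold_id <- with_seed(seed, .make_folds(nrow(X), folds, groups))
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, , drop = FALSE])
    correct <- 0L
    total <- 0L
    for (k in sort(unique(fold_id))) {
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2L) next
      m <- .fit_one(algorithm, X[tr, , drop = FALSE], y[tr], hyper,
                    seed = seed + k)
      p <- .predict_one(m, X[!tr, , drop = FALSE])
      correct <- correct + sum(p == y[!tr], na.rm = TRUE)
      total <- total + sum(!is.na(p))
    }
    cv_acc[g] <- if (total > 0) correct / total else NA_real_
  }
  best <- which.max(cv_acc)
  hyper <- as.list(grid[best, , drop = FALSE])
  fit <- .fit_one(algorithm, X, y, hyper, seed = seed)

  structure(list(algorithm = algorithm, fit = fit, hyper = hyper,
                 cv_accuracy = cv_acc[best], grid = grid, cv_grid = cv_acc,
                 seed = as.integer(seed),
                 contract = .input_contract(inputs)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  hp <- paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  cat(sprintf("<trained_model> %s (%s); CV accuracy %.3f; input: %s\n",
              x$algorithm, hp, x$cv_accuracy, x$contract$type))
  invisible(x)
}

#' Predict epoch labels with a trained classifier
#'
#' @param model A `trained_model`.
#' @param inputs Inputs matching the model's contract (same feature schema
#'   columns, or same window width). Epochs whose own count was missing get
#'   a missing prediction.
#' @return Binary hypnogram aligned to the input epochs.
#' @export
predict_epochs <- function(model, inputs) {
  if (!inherits(model, "trained_model"))
    abort_validation("model must be a trained_model")
  contract <- .input_contract(inputs)
  if (!identical(contract$type, model$contract$type))
    abort_validation("input type '%s' does not match the model's '%s'",
                     contract$type, model$contract$type)
  if (contract$type == "window" &&
      contract$width != model$contract$width)
    abort_validation("window width %d does not match the model's width %d",
                     contract$width, model$contract$width)
  if (contract$type == "features" &&
      !identical(contract$columns, model$contract$columns))
    abort_validation("feature columns do not match the model's schema")
  X <- .as_input_matrix(inputs)
  pred <- .predict_one(model$fit, X)
  miss <- if (inherits(inputs, "window_dataset")) inputs$own_missing
          else attr(inputs, "own_missing")
  if (!is.null(miss)) pred[miss] <- NA_integer_
  as_hypnogram(pred)
}

#' Save / load a trained model with its manifest
#'
#' Models are serialized with `saveRDS`; the manifest (algorithm, chosen
#' hyperparameters, seed, input contract) is embedded in the object.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model"))
    abort_validation("file does not contain a trained_model")
  m
}
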