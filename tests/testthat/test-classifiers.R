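test_that("window datasets center and zero-pad as specified", {
  wd <- make_window_dataset(c(1, 2, 3), 3)
  expect_equal(wd$windows,
               rbind(c(0, 1, 2), c(1, 2, 3), c(2, 3, 0)))
  w1 <- make_window_dataset(c(4, 7, 1), 1)
  expect_equal(as.numeric(w1$windows), c(4, 7, 1))
  w20 <- make_window_dataset(abs(rnorm(55)), 20)
  expect_equal(dim(w20$windows), c(55L, 20L))
  expect_error(make_window_dataset(1:5, 0),
               class = "actisleep_validation_error")
})

make_separable <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- ifelse(y == 1L, -1, 1) * stats::runif(n, 0.5, 2)
  X <- cbind(x1, matrix(stats::rnorm(3 * n), n, 3))
  colnames(X) <- paste0("f", 1:4)
  list(X = X, y = y)
}

test_that("classical models fit a separable toy problem perfectly", {
  d <- make_separable(80)
  for (alg in c("logistic_regression", "linear_svm", "perceptron",
                "extra_trees")) {
    m <- train_classifier(d$X, d$y, alg, folds = 4, seed = 2)
    p <- predict_epochs(m, d$X)
    expect_equal(mean(p == d$y), 1, info = alg)
    expect_length(p, nrow(d$X))
  }
})

test_that("training is deterministic given the seed", {
  d <- make_separable(60, seed = 3)
  m1 <- train_classifier(d$X, d$y, "logistic_regression", folds = 3,
                         seed = 11)
  m2 <- train_classifier(d$X, d$y, "logistic_regression", folds = 3,
                         seed = 11)
  expect_identical(m1$hyper, m2$hyper)
  expect_identical(m1$cv_grid, m2$cv_grid)
  expect_identical(predict_epochs(m1, d$X), predict_epochs(m2, d$X))
})

test_that("input contracts are enforced and missing inputs give missing predictions", {
  d <- make_separable(60)
  expect_error(train_classifier(d$X, rep(1L, 60), "linear_svm"),
               class = "actisleep_validation_error")
  expect_error(train_classifier(d$X, d$y, "nope"),
               class = "actisleep_config_error")
  expect_error(train_classifier(d$X, d$y, "linear_svm",
                                search_space = list()),
               class = "actisleep_config_error")
  expect_error(train_classifier(d$X, d$y, "cnn"),
               class = "actisleep_validation_error")

  counts <- abs(stats::rnorm(120, 40, 40))
  wd100 <- make_window_dataset(counts, 100)
  wd20 <- make_window_dataset(counts, 20)
  y <- rep(c(0L, 1L), 60)
  m <- train_classifier(wd20, y, "cnn", folds = 2, seed = 4,
                        search_space = list(filters = 2L, lr = 0.1))
  expect_error(predict_epochs(m, wd100),
               class = "actisleep_validation_error")

  counts_na <- counts
  counts_na[7] <- NA
  f <- extract_features(counts_na)
  fm <- train_classifier(extract_features(counts), y, "perceptron",
                         folds = 2, seed = 1,
                         search_space = list(n_iter = 5L))
  p <- predict_epochs(fm, f)
  expect_true(is.na(p[7]))
  expect_false(anyNA(p[-7]))
})

test_that("missing labels are excluded and single-class labels rejected", {
  d <- make_separable(60)
  y <- d$y
  y[1:10] <- NA
  m <- train_classifier(d$X, y, "perceptron", folds = 3, seed = 1)
  expect_s3_class(m, "trained_model")
})

test_that("network gradients match finite differences", {
  set.seed(9)
  n <- 6L; W <- 8L
  X <- matrix(stats::rnorm(n * W), n, W)
  y <- rep(c(0, 1), 3)

  # CNN
  L <- 3L; FF <- 2L; P <- W - L + 1L
  Xe <- actisleep:::.conv_embed(X, L)
  par <- list(Wf = matrix(stats::rnorm(L * FF, sd = 0.5), L, FF),
              bf = stats::rnorm(FF, sd = 0.2),
              v = stats::rnorm(FF, sd = 0.5), c = 0.1)
  lg <- actisleep:::.cnn_loss_grad(par, Xe, y, n, P)
  num_grad <- function(loss_fn, par, eps = 1e-6) {
    g <- par
    for (nm in names(par)) {
      gv <- par[[nm]]
      for (i in seq_along(gv)) {
        up <- par; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
        gv[i] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      }
      g[[nm]] <- gv
    }
    g
  }
  ng <- num_grad(function(p)
    actisleep:::.cnn_loss_grad(p, Xe, y, n, P)$loss, par)
  for (nm in names(par))
    expect_equal(as.numeric(lg$grad[[nm]]), as.numeric(ng[[nm]]),
                 tolerance = 1e-5, info = paste("cnn", nm))

  # LSTM
  H <- 3L
  parl <- list(wx = stats::rnorm(4 * H, sd = 0.4),
               Wh = matrix(stats::rnorm(4 * H * H, sd = 0.3), H, 4 * H),
               b = stats::rnorm(4 * H, sd = 0.2),
               v = stats::rnorm(H, sd = 0.5), c = -0.2)
  lgl <- actisleep:::.lstm_loss_grad(parl, X, y)
  ngl <- num_grad(function(p)
    actisleep:::.lstm_loss_grad(p, X, y)$loss, parl)
  for (nm in names(parl))
    expect_equal(as.numeric(lgl$grad[[nm]]), as.numeric(ngl[[nm]]),
                 tolerance = 1e-5, info = paste("lstm", nm))
})

test_that("sequence models learn a separable count pattern", {
  set.seed(12)
  n <- 240L
  y <- rep(c(0L, 1L), each = n / 2)
  counts <- ifelse(y == 1L, stats::rgamma(n, 1, scale = 3),
                   stats::rgamma(n, 2, scale = 120))
  ord <- sample.int(n)
  y <- y[ord]; counts <- counts[ord]
  wd <- make_window_dataset(counts, 20)
  majority <- max(mean(y), 1 - mean(y))
  for (alg in c("cnn", "lstm")) {
    m <- train_classifier(wd, y, alg, folds = 2, seed = 5)
    acc <- mean(predict_epochs(m, wd) == y)
    expect_gt(acc, majority)
  }
})

test_that("models roundtrip through serialization", {
  d <- make_separable(50)
  m <- train_classifier(d$X, d$y, "perceptron", folds = 2, seed = 8,
                        search_space = list(n_iter = 5L))
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_model(m, tmp)
  m2 <- read_model(tmp)
  expect_identical(predict_epochs(m2, d$X), predict_epochs(m, d$X))
  expect_equal(m2$algorithm, "perceptron")
})
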