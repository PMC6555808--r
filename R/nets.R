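# Native reference models: an averaged perceptron on feature vectors and
# two intentionally small sequence networks on raw-count windows (a 1-D
# convolutional stack and an LSTM with a final per-epoch decision). The
# networks are trained full-batch with Adam on binary cross-entropy;
# analytic gradients are checked against finite differences in the test
# suite. Inputs are log1p-transformed and standardized with statistics
# stored in the fitted model.

.standardizer <- function(X) {
  xs <- log1p(X)
  mu <- mean(xs)
  sdv <- stats::sd(as.numeric(xs))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  list(mu = mu, sd = sdv)
}

.standardize <- function(X, st) (log1p(X) - st$mu) / st$sd

.sigmoid <- function(x) 1 / (1 + exp(-x))

.bce <- function(q, y) {
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  -mean(y * log(q) + (1 - y) * log(1 - q))
}

# Adam step over a flat named list of arrays.
.adam_init <- function(par) list(m = lapply(par, function(p) p * 0),
                                 v = lapply(par, function(p) p * 0), t = 0)

.adam_step <- function(par, grad, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(par)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grad[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}

# ---- averaged perceptron ---------------------------------------------------

fit_perceptron <- function(X, y, n_iter = 25L) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yy <- ifelse(y == 1L, 1, -1)
  w <- numeric(ncol(X)); b <- 0
  wa <- w; ba <- 0; steps <- 0
  ord <- sample.int(nrow(Xs))  # fixed by the caller's seed
  for (it in seq_len(n_iter)) {
    for (i in ord) {
      if (yy[i] * (sum(w * Xs[i, ]) + b) <= 0) {
        w <- w + yy[i] * Xs[i, ]
        b <- b + yy[i]
      }
      wa <- wa + w; ba <- ba + b; steps <- steps + 1
    }
  }
  list(kind = "perceptron", w = wa / steps, b = ba / steps,
       center = ctr, scale = scl)
}

predict_perceptron <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  as.integer(as.numeric(Xs %*% model$w) + model$b > 0)
}

# ---- 1-D CNN ---------------------------------------------------------------

# Embedded window rows for the convolution: row (i-1)*P + p holds
# X[i, p:(p+L-1)].
.conv_embed <- function(X, L) {
  W <- ncol(X); P <- W - L + 1L; n <- nrow(X)
  idx <- outer(seq_len(P), 0:(L - 1L), `+`)           # P x L of column ids
  Xe <- matrix(0, n * P, L)
  for (l in seq_len(L))
    Xe[, l] <- as.numeric(t(X[, idx[, l], drop = FALSE]))  # p fastest
  Xe
}

.cnn_loss_grad <- function(par, Xe, y, n, P) {
  FF <- ncol(par$Wf)
  Z <- Xe %*% par$Wf + matrix(par$bf, nrow(Xe), FF, byrow = TRUE)
  A <- pmax(Z, 0)
  pool <- matrix(0, n, FF)
  for (f in seq_len(FF))
    pool[, f] <- colMeans(matrix(A[, f], nrow = P))
  u <- as.numeric(pool %*% par$v) + par$c
  q <- .sigmoid(u)
  loss <- .bce(q, y)

  du <- (q - y) / n
  dv <- as.numeric(crossprod(pool, du))
  dc <- sum(du)
  dpool <- outer(du, par$v)
  dA <- dpool[rep(seq_len(n), each = P), , drop = FALSE] / P
  dZ <- dA * (Z > 0)
  list(loss = loss,
       grad = list(Wf = crossprod(Xe, dZ), bf = colSums(dZ),
                   v = dv, c = dc),
       prob = q)
}

fit_cnn <- function(X, y, filters = 4L, filter_len = 5L, lr = 0.1,
                    iters = 150L, seed = 1L) {
  st <- .standardizer(X)
  Xs <- .standardize(X, st)
  L <- min(filter_len, ncol(Xs))
  P <- ncol(Xs) - L + 1L
  n <- nrow(Xs)
  Xe <- .conv_embed(Xs, L)
  par <- with_seed(seed, list(
    Wf = matrix(stats::rnorm(L * filters, sd = 0.3), L, filters),
    bf = numeric(filters),
    v = stats::rnorm(filters, sd = 0.3),
    c = 0))
  ad <- .adam_init(par)
  for (it in seq_len(iters)) {
    lg <- .cnn_loss_grad(par, Xe, y, n, P)
    upd <- .adam_step(par, lg$grad, ad, lr)
    par <- upd$par; ad <- upd$state
  }
  list(kind = "cnn", par = par, filter_len = L, standardizer = st)
}

predict_cnn <- function(model, X) {
  Xs <- .standardize(X, model$standardizer)
  L <- model$filter_len
  P <- ncol(Xs) - L + 1L
  Xe <- .conv_embed(Xs, L)
  q <- .cnn_loss_grad(model$par, Xe, rep(0, nrow(Xs)), nrow(Xs), P)$prob
  as.integer(q > 0.5)
}

# ---- LSTM ------------------------------------------------------------------

.lstm_forward <- function(par, Xs) {
  n <- nrow(Xs); W <- ncol(Xs); H <- length(par$v)
  Hs <- matrix(0, n, H); C <- matrix(0, n, H)
  cache <- vector("list", W)
  for (t in seq_len(W)) {
    Z <- outer(Xs[, t], par$wx) + Hs %*% par$Wh +
      matrix(par$b, n, 4L * H, byrow = TRUE)
    gi <- .sigmoid(Z[, seq_len(H), drop = FALSE])
    gf <- .sigmoid(Z[, H + seq_len(H), drop = FALSE])
    go <- .sigmoid(Z[, 2L * H + seq_len(H), drop = FALSE])
    gg <- tanh(Z[, 3L * H + seq_len(H), drop = FALSE])
    Cprev <- C
    Hprev <- Hs
    C <- gf * Cprev + gi * gg
    tC <- tanh(C)
    Hs <- go * tC
    cache[[t]] <- list(gi = gi, gf = gf, go = go, gg = gg,
                       Cprev = Cprev, Hprev = Hprev, tC = tC)
  }
  list(Hs = Hs, cache = cache)
}

.lstm_loss_grad <- function(par, Xs, y) {
  n <- nrow(Xs); W <- ncol(Xs); H <- length(par$v)
  fw <- .lstm_forward(par, Xs)
  u <- as.numeric(fw$Hs %*% par$v) + par$c
  q <- .sigmoid(u)
  loss <- .bce(q, y)

  du <- (q - y) / n
  g <- list(wx = numeric(4L * H), Wh = matrix(0, H, 4L * H),
            b = numeric(4L * H), v = as.numeric(crossprod(fw$Hs, du)),
            c = sum(du))
  dH <- outer(du, par$v)
  dC <- matrix(0, n, H)
  for (t in rev(seq_len(W))) {
    cc <- fw$cache[[t]]
    do <- dH * cc$tC
    dC <- dC + dH * cc$go * (1 - cc$tC^2)
    di <- dC * cc$gg
    dg <- dC * cc$gi
    df <- dC * cc$Cprev
    dCnext <- dC * cc$gf
    dZ <- cbind(di * cc$gi * (1 - cc$gi),
                df * cc$gf * (1 - cc$gf),
                do * cc$go * (1 - cc$go),
                dg * (1 - cc$gg^2))
    g$wx <- g$wx + as.numeric(crossprod(dZ, Xs[, t]))
    g$Wh <- g$Wh + crossprod(cc$Hprev, dZ)
    g$b <- g$b + colSums(dZ)
    dH <- dZ %*% t(par$Wh)
    dC <- dCnext
  }
  list(loss = loss, grad = g, prob = q)
}

fit_lstm <- function(X, y, hidden = 6L, lr = 0.05, iters = 80L, seed = 1L) {
  st <- .standardizer(X)
  Xs <- .standardize(X, st)
  H <- hidden
  par <- with_seed(seed, {
    b <- numeric(4L * H)
    b[H + seq_len(H)] <- 1  # forget-gate bias
    list(wx = stats::rnorm(4L * H, sd = 0.3),
         Wh = matrix(stats::rnorm(4L * H * H, sd = 0.3 / sqrt(H)), H, 4L * H),
         b = b,
         v = stats::rnorm(H, sd = 0.3),
         c = 0)
  })
  ad <- .adam_init(par)
  for (it in seq_len(iters)) {
    lg <- .lstm_loss_grad(par, Xs, y)
    upd <- .adam_step(par, lg$grad, ad, lr)
    par <- upd$par; ad <- upd$state
  }
  list(kind = "lstm", par = par, standardizer = st)
}

predict_lstm <- function(model, X) {
  Xs <- .standardize(X, model$standardizer)
  fw <- .lstm_forward(model$par, Xs)
  q <- .sigmoid(as.numeric(fw$Hs %*% model$par$v) + model$par$c)
  as.integer(q > 0.5)
}
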