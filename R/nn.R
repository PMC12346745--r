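## Internal neural-network primitives.  Layout conventions:
##   - time-series activations: array (time, channels, batch)
##   - dense activations: matrix (batch, units)
##   - conv weights: im2col matrix (kernel*channels_in, filters)
## Convolution fwd/bwd is compiled (src/conv1d.cpp); everything else is
## vectorized R.  Parameters live in a flat named list ("conv1.W", ...).

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## ---- dense -----------------------------------------------------------

dense_fw <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

dense_bw <- function(X, W, dZ) {
  list(dX = dZ %*% t(W), dW = crossprod(X, dZ), db = colSums(dZ))
}

## ---- max pooling (size 2, stride 2, floor) ---------------------------

maxpool_fw <- function(X) {
  t_out <- dim(X)[1] %/% 2L
  A <- X[2L * seq_len(t_out) - 1L, , , drop = FALSE]
  B <- X[2L * seq_len(t_out), , , drop = FALSE]
  mask <- A >= B
  list(Y = pmax(A, B), mask = mask, t_in = dim(X)[1])
}

maxpool_bw <- function(cache, dY) {
  t_out <- dim(dY)[1]
  dX <- array(0, c(cache$t_in, dim(dY)[2], dim(dY)[3]))
  dX[2L * seq_len(t_out) - 1L, , ] <- dY * cache$mask
  dX[2L * seq_len(t_out), , ] <- dY * !cache$mask
  dX
}

## ---- batch normalization (per channel over time x batch) -------------

bn_fw <- function(X, gamma, beta, run, training, momentum = 0.9, eps = 1e-3) {
  d <- dim(X)
  Xm <- matrix(aperm(X, c(1L, 3L, 2L)), ncol = d[2])
  if (training) {
    mu <- colMeans(Xm)
    v <- pmax(colMeans(Xm^2) - mu^2, 0)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2L, mu, "-"), 2L, inv_std, "*")
  Ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  Y <- aperm(array(Ym, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
  list(Y = Y, xhat = xhat, inv_std = inv_std, run = run, dims = d)
}

bn_bw <- function(cache, gamma, dY) {
  d <- cache$dims
  dYm <- matrix(aperm(dY, c(1L, 3L, 2L)), ncol = d[2])
  m <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dXm <- sweep(
    dxhat - sweep(cache$xhat, 2L, s2 / m, "*") -
      matrix(s1 / m, m, d[2], byrow = TRUE),
    2L, cache$inv_std, "*")
  list(dX = aperm(array(dXm, c(d[1], d[3], d[2])), c(1L, 3L, 2L)),
       dgamma = dgamma, dbeta = dbeta)
}

## ---- dropout (inverted) ----------------------------------------------

dropout_mask <- function(dims, rate) {
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

## ---- softmax / cross-entropy -----------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

cross_entropy <- function(P, Y1hot) {
  -mean(log(pmax(rowSums(P * Y1hot), 1e-12)))
}

## ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
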