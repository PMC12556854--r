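# Low-level network primitives: dense, 1-D convolution (valid, via
# im2col), max pooling, LSTM (BPTT), inverted dropout, and the Nadam
# update. The convolution, LSTM and optimizer hot paths run in compiled
# kernels (src/nn_kernels.cpp); the *R variants below are the pure-R
# reference implementations used in parity tests. All forward functions
# return a cache consumed by the matching backward function; batch is
# always the first array dimension.

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

nnDenseFwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(Y = Y, X = X)
}

nnDenseBwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

nnReluFwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  list(Y = Y, mask = X > 0)
}

nnReluBwd <- function(dY, cache) dY * cache$mask

nnDropoutFwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- array((runif(length(X)) >= p) / (1 - p), dim = dim(X) %||% length(X))
  list(Y = X * mask, mask = mask)
}

nnDropoutBwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# X: array (B, L, C); W: (k*C, F) with rows ordered offset-major
# (offset 1 channels 1..C, offset 2 channels 1..C, ...); valid padding.
nnConv1dFwd <- function(X, W, b, k) {
  out <- .cppConv1dFwd(X, W, as.numeric(b), as.integer(k))
  list(Y = array(out$Y, dim = c(out$B, out$P, ncol(W))), X = X, k = k)
}

nnConv1dBwd <- function(dY, cache, W) {
  d <- dim(dY)
  out <- .cppConv1dBwd(cache$X, W, matrix(dY, d[1] * d[2], d[3]),
                       as.integer(cache$k))
  list(dX = out$dX, dW = out$dW, db = as.numeric(out$db))
}

# Pure-R reference for the convolution kernel.
nnConv1dFwdR <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  P <- L - k + 1L
  Xcol <- array(0, dim = c(B, P, k * C))
  for (j in seq_len(k))
    Xcol[, , ((j - 1L) * C + 1L):(j * C)] <- X[, j:(j + P - 1L), , drop = FALSE]
  M <- matrix(Xcol, B * P, k * C)
  Y <- M %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(Y = array(Y, dim = c(B, P, ncol(W))), M = M,
       dims = c(B = B, L = L, C = C, P = P, k = k))
}

nnConv1dBwdR <- function(dY, cache, W) {
  dm <- cache$dims
  Fn <- ncol(W)
  dYm <- matrix(dY, dm["B"] * dm["P"], Fn)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dXcol <- array(dM, dim = unname(c(dm["B"], dm["P"], dm["k"] * dm["C"])))
  dX <- array(0, dim = unname(c(dm["B"], dm["L"], dm["C"])))
  for (j in seq_len(dm["k"])) {
    cols <- ((j - 1L) * dm["C"] + 1L):(j * dm["C"])
    dX[, j:(j + dm["P"] - 1L), ] <-
      dX[, j:(j + dm["P"] - 1L), , drop = FALSE] + dXcol[, , cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# Non-overlapping max pooling of size 2 along the position axis; an odd
# trailing position is dropped. Ties take the earlier position.
nnMaxPool2Fwd <- function(X) {
  d <- dim(X); P2 <- d[2] %/% 2L
  a <- X[, seq(1L, 2L * P2, by = 2L), , drop = FALSE]
  b <- X[, seq(2L, 2L * P2, by = 2L), , drop = FALSE]
  mask <- a >= b
  Y <- a * mask + b * !mask
  list(Y = Y, mask = mask, in_dim = d)
}

nnMaxPool2Bwd <- function(dY, cache) {
  d <- cache$in_dim; P2 <- dim(dY)[2]
  dX <- array(0, dim = d)
  dX[, seq(1L, 2L * P2, by = 2L), ] <- dY * cache$mask
  dX[, seq(2L, 2L * P2, by = 2L), ] <- dY * !cache$mask
  dX
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# xs: list of T matrices (B x D). Gate column order: input, forget,
# cell, output. Hidden states are returned per timestep; the cache is
# the compiled kernel's stacked gate matrices.
nnLstmFwd <- function(xs, Wx, Wh, b) {
  Tn <- length(xs); B <- nrow(xs[[1]])
  xcat <- do.call(rbind, xs)
  out <- .cppLstmFwd(xcat, Wx, Wh, as.numeric(b), as.integer(Tn),
                     as.integer(B))
  H <- out$H
  hs <- lapply(seq_len(Tn), function(t)
    out$hs[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  list(hs = hs, cpp = out, xcat = xcat, H = H, B = B, Tn = Tn)
}

# dhs: list of T matrices (B x H) of external gradients on each hidden
# state (zero matrices where unused).
nnLstmBwd <- function(dhs, fwd, Wx, Wh) {
  out <- .cppLstmBwd(do.call(rbind, dhs), fwd$xcat, Wx, Wh,
                     fwd$cpp$hs, fwd$cpp$I, fwd$cpp$F, fwd$cpp$G,
                     fwd$cpp$O, fwd$cpp$TC, fwd$cpp$CP, fwd$cpp$HP,
                     as.integer(fwd$Tn), as.integer(fwd$B))
  B <- fwd$B
  dxs <- lapply(seq_len(fwd$Tn), function(t)
    out$dxcat[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  list(dxs = dxs, dWx = out$dWx, dWh = out$dWh, db = as.numeric(out$db))
}

# Pure-R reference for the LSTM kernel.
nnLstmFwdR <- function(xs, Wx, Wh, b) {
  Tn <- length(xs); B <- nrow(xs[[1]]); H <- ncol(Wh) %/% 4L
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  hs <- vector("list", Tn); cache <- vector("list", Tn)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    z <- xs[[t]] %*% Wx + h %*% Wh + bmat
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * c_ + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_, tc = tc,
                       h_prev = h, x = xs[[t]])
    h <- o * tc; c_ <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache, H = H)
}

nnLstmBwdR <- function(dhs, fwd, Wx, Wh) {
  Tn <- length(dhs); H <- fwd$H
  B <- nrow(dhs[[Tn]])
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dh_rec <- matrix(0, B, H); dc <- matrix(0, B, H)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dh <- dhs[[t]] + dh_rec
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dxs[[t]] <- dZ %*% t(Wx)
    dh_rec <- dZ %*% t(Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# Nadam (Adam with Nesterov momentum), with decoupled L2 weight decay
# applied to weight matrices (parameter names not ending in "_b").
# The update runs on a single flattened parameter vector; the index map
# built here relists parameters afterwards.
nadamInit <- function(params) {
  sizes <- vapply(params, length, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  n <- sum(sizes)
  decay_mask <- rep(!grepl("_b$", names(params)), times = sizes)
  list(m = numeric(n), v = numeric(n), t = 0L,
       starts = starts, ends = ends, decay_mask = decay_mask,
       dims = lapply(params, function(p) dim(p)))
}

nadamStep <- function(params, grads, state, lr, beta1, beta2,
                      weight_decay = 0, eps = 1e-7) {
  state$t <- state$t + 1L
  up <- .cppNadam(unlist(params, use.names = FALSE),
                  unlist(grads, use.names = FALSE),
                  state$m, state$v, as.integer(state$decay_mask),
                  state$t, lr, beta1, beta2, weight_decay, eps)
  state$m <- as.numeric(up$m)
  state$v <- as.numeric(up$v)
  theta <- as.numeric(up$theta)
  for (i in seq_along(params)) {
    v <- theta[state$starts[i]:state$ends[i]]
    if (!is.null(state$dims[[i]])) dim(v) <- state$dims[[i]]
    params[[i]] <- v
  }
  list(params = params, state = state)
}
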