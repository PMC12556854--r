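#' Configuration of the four-branch Tm regressor
#'
#' Optimiser hyperparameters follow the published calibration: Nadam
#' (Adam with Nesterov momentum) with learning rate 1.55e-4, momentum
#' decay rates beta1 = 0.995 and beta2 = 0.9915, decoupled L2 weight
#' decay lambda = 4e-5, and mean-squared-error loss. Branch widths are
#' conventions of this package (the performance, not the weights, is
#' what is reproduced) and every one is overridable here.
#'
#' @param conv_filters,conv_kernel,pool_size,conv_dropout,conv_dense
#'   one-hot branch: two convolution blocks (filters, kernel, max-pool
#'   size, dropout), then flatten and two dense layers.
#' @param lstm_units,kmer_dense k-mer branch: two bidirectional LSTM
#'   layers then three ReLU dense layers.
#' @param cond_dense cation branch: two ReLU dense layers.
#' @param ph_dense,ph_dropout pH branch: two ReLU dense layers, each
#'   followed by dropout.
#' @param head_dense,head_dropout merge head: two ReLU dense layers, a
#'   dropout layer, then the single linear output unit.
#' @param learning_rate,beta1,beta2,weight_decay,epsilon Nadam settings.
#' @param epochs,batch_size,patience training length, mini-batch size,
#'   and early-stopping patience (in epochs, on validation MSE).
#' @param normalization `"standardize"` (per-element standardisation of
#'   each branch input with training-split statistics) or `"none"`.
#' @param rng_seed integer seed governing initialisation, shuffling and
#'   dropout.
#' @return a classed list (`ModelConfig`).
#' @export
modelConfig <- function(conv_filters = c(32L, 64L), conv_kernel = 5L,
                        pool_size = 2L, conv_dropout = 0.2,
                        conv_dense = c(64L, 32L),
                        lstm_units = c(32L, 16L),
                        kmer_dense = c(32L, 16L, 8L),
                        cond_dense = c(16L, 8L),
                        ph_dense = c(8L, 4L), ph_dropout = 0.2,
                        head_dense = c(64L, 32L), head_dropout = 0.2,
                        learning_rate = 1.55e-4, beta1 = 0.995,
                        beta2 = 0.9915, weight_decay = 4e-5,
                        epsilon = 1e-7,
                        epochs = 200L, batch_size = 32L, patience = 20L,
                        normalization = c("standardize", "none"),
                        rng_seed = 1L) {
  normalization <- match.arg(normalization)
  cfg <- as.list(environment())
  stopifnot(cfg$learning_rate > 0, cfg$beta1 > 0, cfg$beta1 < 1,
            cfg$beta2 > 0, cfg$beta2 < 1, cfg$weight_decay >= 0,
            cfg$conv_dropout >= 0, cfg$conv_dropout < 1,
            cfg$ph_dropout >= 0, cfg$ph_dropout < 1,
            cfg$head_dropout >= 0, cfg$head_dropout < 1,
            length(cfg$conv_filters) == 2L, length(cfg$conv_dense) == 2L,
            length(cfg$lstm_units) == 2L, length(cfg$kmer_dense) == 3L,
            length(cfg$cond_dense) == 2L, length(cfg$ph_dense) == 2L,
            length(cfg$head_dense) == 2L,
            all(c(cfg$conv_filters, cfg$conv_dense, cfg$lstm_units,
                  cfg$kmer_dense, cfg$cond_dense, cfg$ph_dense,
                  cfg$head_dense) >= 1),
            cfg$epochs >= 1, cfg$batch_size >= 1, cfg$patience >= 0)
  structure(cfg, class = "ModelConfig")
}

# sequence-branch position counts after each conv/pool stage
.convGeometry <- function(config) {
  k <- config$conv_kernel
  p1 <- 100L - k + 1L
  if (p1 < 1L)
    .stopf("one-hot branch: kernel %d exceeds the 100-nt window", k)
  q1 <- p1 %/% config$pool_size
  p2 <- q1 - k + 1L
  if (p2 < 1L)
    .stopf("one-hot branch: pooling reduces length below kernel size (%d < %d)",
           q1, k)
  q2 <- p2 %/% config$pool_size
  if (q2 < 1L) .stopf("one-hot branch: second pooling empties the feature map")
  list(p1 = p1, q1 = q1, p2 = p2, q2 = q2,
       flat = q2 * config$conv_filters[2])
}

.lstmInit <- function(D, H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias at 1: standard stable start
  list(Wx = .glorot(D, 4L * H), Wh = .glorot(H, 4L * H), b = b)
}

#' Build an untrained Tm regressor
#'
#' Instantiates all network parameters (Glorot-uniform, seeded by
#' `config$rng_seed`, so two builds with the same seed are identical)
#' and validates that the configured geometry is consistent.
#'
#' @param config a [modelConfig()].
#' @return an untrained [TmRegressor-class].
#' @export
buildRegressor <- function(config = modelConfig()) {
  stopifnot(inherits(config, "ModelConfig") || is.list(config))
  geo <- .convGeometry(config)
  k <- config$conv_kernel
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  cd <- config$conv_dense; lu <- config$lstm_units; kd <- config$kmer_dense
  nd <- config$cond_dense; pd <- config$ph_dense; hd <- config$head_dense
  set.seed(config$rng_seed)
  p <- list()
  p$conv1_W <- .glorot(k * 4L, f1); p$conv1_b <- numeric(f1)
  p$conv2_W <- .glorot(k * f1, f2); p$conv2_b <- numeric(f2)
  p$cnn_fc1_W <- .glorot(geo$flat, cd[1]); p$cnn_fc1_b <- numeric(cd[1])
  p$cnn_fc2_W <- .glorot(cd[1], cd[2]); p$cnn_fc2_b <- numeric(cd[2])
  l1f <- .lstmInit(20L, lu[1]); l1b <- .lstmInit(20L, lu[1])
  l2f <- .lstmInit(2L * lu[1], lu[2]); l2b <- .lstmInit(2L * lu[1], lu[2])
  p$lstm1f_Wx <- l1f$Wx; p$lstm1f_Wh <- l1f$Wh; p$lstm1f_b <- l1f$b
  p$lstm1b_Wx <- l1b$Wx; p$lstm1b_Wh <- l1b$Wh; p$lstm1b_b <- l1b$b
  p$lstm2f_Wx <- l2f$Wx; p$lstm2f_Wh <- l2f$Wh; p$lstm2f_b <- l2f$b
  p$lstm2b_Wx <- l2b$Wx; p$lstm2b_Wh <- l2b$Wh; p$lstm2b_b <- l2b$b
  p$km_fc1_W <- .glorot(2L * lu[2], kd[1]); p$km_fc1_b <- numeric(kd[1])
  p$km_fc2_W <- .glorot(kd[1], kd[2]); p$km_fc2_b <- numeric(kd[2])
  p$km_fc3_W <- .glorot(kd[2], kd[3]); p$km_fc3_b <- numeric(kd[3])
  p$cond_fc1_W <- .glorot(3L, nd[1]); p$cond_fc1_b <- numeric(nd[1])
  p$cond_fc2_W <- .glorot(nd[1], nd[2]); p$cond_fc2_b <- numeric(nd[2])
  p$ph_fc1_W <- .glorot(1L, pd[1]); p$ph_fc1_b <- numeric(pd[1])
  p$ph_fc2_W <- .glorot(pd[1], pd[2]); p$ph_fc2_b <- numeric(pd[2])
  concat <- cd[2] + kd[3] + nd[2] + pd[2]
  p$head_fc1_W <- .glorot(concat, hd[1]); p$head_fc1_b <- numeric(hd[1])
  p$head_fc2_W <- .glorot(hd[1], hd[2]); p$head_fc2_b <- numeric(hd[2])
  p$out_W <- .glorot(hd[2], 1L); p$out_b <- numeric(1L)
  new("TmRegressor", params = p, config = unclass(config), trained = FALSE)
}

.identityNorm <- function(dims) {
  D <- prod(dims)
  list(mu = numeric(D), inv = rep(1, D))
}

.fitNormStats <- function(enc, config) {
  one <- function(X) {
    B <- dim(X)[1]
    Xm <- matrix(X, B, prod(dim(X)[-1]))
    mu <- colMeans(Xm)
    sdv <- sqrt(pmax(colMeans(Xm^2) - mu^2, 0))
    inv <- ifelse(sdv < 1e-8, 0, 1 / sdv)
    list(mu = mu, inv = inv)
  }
  if (config$normalization == "none") {
    list(onehot = .identityNorm(c(100, 4)), kmer = .identityNorm(c(17, 20)),
         cond = .identityNorm(3), ph = .identityNorm(1))
  } else {
    list(onehot = one(enc$onehot), kmer = one(enc$kmer),
         cond = one(enc$cond), ph = one(enc$ph))
  }
}

.normFwd <- function(X, st) {
  B <- dim(X)[1]
  D <- length(st$mu)
  Xm <- matrix(X, B, D)
  Z <- (Xm - matrix(st$mu, B, D, byrow = TRUE)) *
    matrix(st$inv, B, D, byrow = TRUE)
  array(Z, dim = dim(X))
}

.normBwd <- function(dZ, st) {
  B <- dim(dZ)[1]
  D <- length(st$mu)
  array(matrix(dZ, B, D) * matrix(st$inv, B, D, byrow = TRUE), dim = dim(dZ))
}

# Full forward pass. inputs: list from encodeRecords(). Returns the
# predicted Tm vector and (if keep_cache) everything backward needs.
.modelForward <- function(params, normStats, inputs, config, training,
                          keep_cache = FALSE) {
  p <- params
  B <- inputs$n
  Tn <- 17L
  cc <- list()

  # branch 1: one-hot sequence
  z1 <- .normFwd(inputs$onehot, normStats$onehot)
  c1 <- nnConv1dFwd(z1, p$conv1_W, p$conv1_b, config$conv_kernel)
  r1 <- nnReluFwd(c1$Y)
  pl1 <- nnMaxPool2Fwd(r1$Y)
  dr1 <- nnDropoutFwd(pl1$Y, config$conv_dropout, training)
  c2 <- nnConv1dFwd(dr1$Y, p$conv2_W, p$conv2_b, config$conv_kernel)
  r2 <- nnReluFwd(c2$Y)
  pl2 <- nnMaxPool2Fwd(r2$Y)
  dr2 <- nnDropoutFwd(pl2$Y, config$conv_dropout, training)
  flat_dim <- prod(dim(dr2$Y)[-1])
  fl <- matrix(dr2$Y, B, flat_dim)
  cf1 <- nnDenseFwd(fl, p$cnn_fc1_W, p$cnn_fc1_b)
  cr1 <- nnReluFwd(cf1$Y)
  cf2 <- nnDenseFwd(cr1$Y, p$cnn_fc2_W, p$cnn_fc2_b)
  cnn_out <- cf2$Y

  # branch 2: k-mer matrix as 17 timesteps of 20 features
  zk <- .normFwd(inputs$kmer, normStats$kmer)
  xs <- lapply(seq_len(Tn), function(t) matrix(zk[, t, ], nrow = B))
  l1f <- nnLstmFwd(xs, p$lstm1f_Wx, p$lstm1f_Wh, p$lstm1f_b)
  l1b <- nnLstmFwd(rev(xs), p$lstm1b_Wx, p$lstm1b_Wh, p$lstm1b_b)
  ys <- lapply(seq_len(Tn), function(t) cbind(l1f$hs[[t]], l1b$hs[[Tn + 1L - t]]))
  l2f <- nnLstmFwd(ys, p$lstm2f_Wx, p$lstm2f_Wh, p$lstm2f_b)
  l2b <- nnLstmFwd(rev(ys), p$lstm2b_Wx, p$lstm2b_Wh, p$lstm2b_b)
  lstm_out <- cbind(l2f$hs[[Tn]], l2b$hs[[Tn]])
  kf1 <- nnDenseFwd(lstm_out, p$km_fc1_W, p$km_fc1_b)
  kr1 <- nnReluFwd(kf1$Y)
  kf2 <- nnDenseFwd(kr1$Y, p$km_fc2_W, p$km_fc2_b)
  kr2 <- nnReluFwd(kf2$Y)
  kf3 <- nnDenseFwd(kr2$Y, p$km_fc3_W, p$km_fc3_b)
  kr3 <- nnReluFwd(kf3$Y)
  km_out <- kr3$Y

  # branch 3: cation concentrations
  zc <- .normFwd(inputs$cond, normStats$cond)
  sf1 <- nnDenseFwd(zc, p$cond_fc1_W, p$cond_fc1_b)
  sr1 <- nnReluFwd(sf1$Y)
  sf2 <- nnDenseFwd(sr1$Y, p$cond_fc2_W, p$cond_fc2_b)
  sr2 <- nnReluFwd(sf2$Y)
  cond_out <- sr2$Y

  # branch 4: pH
  zp <- .normFwd(inputs$ph, normStats$ph)
  pf1 <- nnDenseFwd(zp, p$ph_fc1_W, p$ph_fc1_b)
  pr1 <- nnReluFwd(pf1$Y)
  pdr1 <- nnDropoutFwd(pr1$Y, config$ph_dropout, training)
  pf2 <- nnDenseFwd(pdr1$Y, p$ph_fc2_W, p$ph_fc2_b)
  pr2 <- nnReluFwd(pf2$Y)
  pdr2 <- nnDropoutFwd(pr2$Y, config$ph_dropout, training)
  ph_out <- pdr2$Y

  # merge head
  concat <- cbind(cnn_out, km_out, cond_out, ph_out)
  hf1 <- nnDenseFwd(concat, p$head_fc1_W, p$head_fc1_b)
  hr1 <- nnReluFwd(hf1$Y)
  hf2 <- nnDenseFwd(hr1$Y, p$head_fc2_W, p$head_fc2_b)
  hr2 <- nnReluFwd(hf2$Y)
  hdr <- nnDropoutFwd(hr2$Y, config$head_dropout, training)
  out <- nnDenseFwd(hdr$Y, p$out_W, p$out_b)
  yhat <- as.numeric(out$Y)

  if (!keep_cache) return(list(yhat = yhat))
  cc <- list(c1 = c1, r1 = r1, pl1 = pl1, dr1 = dr1, c2 = c2, r2 = r2,
             pl2 = pl2, dr2 = dr2, fl_dim = dim(dr2$Y), cf1 = cf1, cr1 = cr1,
             cf2 = cf2, xs = xs, l1f = l1f, l1b = l1b, ys = ys, l2f = l2f,
             l2b = l2b, kf1 = kf1, kr1 = kr1, kf2 = kf2, kr2 = kr2, kf3 = kf3,
             kr3 = kr3, sf1 = sf1, sr1 = sr1, sf2 = sf2, sr2 = sr2,
             pf1 = pf1, pr1 = pr1, pdr1 = pdr1, pf2 = pf2, pr2 = pr2,
             pdr2 = pdr2, hf1 = hf1, hr1 = hr1, hf2 = hf2, hr2 = hr2,
             hdr = hdr, out = out, B = B, Tn = Tn,
             widths = c(ncol(cnn_out), ncol(km_out), ncol(cond_out),
                        ncol(ph_out)))
  list(yhat = yhat, cache = cc)
}

.modelBackward <- function(params, cache, dyhat, config) {
  p <- params; cc <- cache
  g <- list()
  Tn <- cc$Tn
  dY <- matrix(dyhat, ncol = 1L)

  bo <- nnDenseBwd(dY, cc$out, p$out_W)
  g$out_W <- bo$dW; g$out_b <- bo$db
  d <- nnDropoutBwd(bo$dX, cc$hdr)
  d <- nnReluBwd(d, cc$hr2)
  b2 <- nnDenseBwd(d, cc$hf2, p$head_fc2_W)
  g$head_fc2_W <- b2$dW; g$head_fc2_b <- b2$db
  d <- nnReluBwd(b2$dX, cc$hr1)
  b1 <- nnDenseBwd(d, cc$hf1, p$head_fc1_W)
  g$head_fc1_W <- b1$dW; g$head_fc1_b <- b1$db
  w <- cc$widths
  dcnn <- b1$dX[, seq_len(w[1]), drop = FALSE]
  dkm <- b1$dX[, w[1] + seq_len(w[2]), drop = FALSE]
  dcond <- b1$dX[, w[1] + w[2] + seq_len(w[3]), drop = FALSE]
  dph <- b1$dX[, w[1] + w[2] + w[3] + seq_len(w[4]), drop = FALSE]

  # branch 1
  bc2 <- nnDenseBwd(dcnn, cc$cf2, p$cnn_fc2_W)
  g$cnn_fc2_W <- bc2$dW; g$cnn_fc2_b <- bc2$db
  d <- nnReluBwd(bc2$dX, cc$cr1)
  bc1 <- nnDenseBwd(d, cc$cf1, p$cnn_fc1_W)
  g$cnn_fc1_W <- bc1$dW; g$cnn_fc1_b <- bc1$db
  dflat <- array(bc1$dX, dim = cc$fl_dim)
  d <- nnDropoutBwd(dflat, cc$dr2)
  d <- nnMaxPool2Bwd(d, cc$pl2)
  d <- nnReluBwd(d, cc$r2)
  bcv2 <- nnConv1dBwd(d, cc$c2, p$conv2_W)
  g$conv2_W <- bcv2$dW; g$conv2_b <- bcv2$db
  d <- nnDropoutBwd(bcv2$dX, cc$dr1)
  d <- nnMaxPool2Bwd(d, cc$pl1)
  d <- nnReluBwd(d, cc$r1)
  bcv1 <- nnConv1dBwd(d, cc$c1, p$conv1_W)
  g$conv1_W <- bcv1$dW; g$conv1_b <- bcv1$db

  # branch 2
  d <- nnReluBwd(dkm, cc$kr3)
  bk3 <- nnDenseBwd(d, cc$kf3, p$km_fc3_W)
  g$km_fc3_W <- bk3$dW; g$km_fc3_b <- bk3$db
  d <- nnReluBwd(bk3$dX, cc$kr2)
  bk2 <- nnDenseBwd(d, cc$kf2, p$km_fc2_W)
  g$km_fc2_W <- bk2$dW; g$km_fc2_b <- bk2$db
  d <- nnReluBwd(bk2$dX, cc$kr1)
  bk1 <- nnDenseBwd(d, cc$kf1, p$km_fc1_W)
  g$km_fc1_W <- bk1$dW; g$km_fc1_b <- bk1$db
  H2 <- ncol(cc$l2f$hs[[1]])
  B <- cc$B
  zeroH2 <- matrix(0, B, H2)
  dh2f <- rep(list(zeroH2), Tn); dh2f[[Tn]] <- bk1$dX[, seq_len(H2), drop = FALSE]
  dh2b <- rep(list(zeroH2), Tn); dh2b[[Tn]] <- bk1$dX[, H2 + seq_len(H2), drop = FALSE]
  bl2f <- nnLstmBwd(dh2f, cc$l2f, p$lstm2f_Wx, p$lstm2f_Wh)
  bl2b <- nnLstmBwd(dh2b, cc$l2b, p$lstm2b_Wx, p$lstm2b_Wh)
  g$lstm2f_Wx <- bl2f$dWx; g$lstm2f_Wh <- bl2f$dWh; g$lstm2f_b <- bl2f$db
  g$lstm2b_Wx <- bl2b$dWx; g$lstm2b_Wh <- bl2b$dWh; g$lstm2b_b <- bl2b$db
  dys <- lapply(seq_len(Tn), function(t) bl2f$dxs[[t]] + bl2b$dxs[[Tn + 1L - t]])
  H1 <- ncol(cc$l1f$hs[[1]])
  dh1f <- lapply(seq_len(Tn), function(t) dys[[t]][, seq_len(H1), drop = FALSE])
  dh1b <- lapply(seq_len(Tn),
                 function(s) dys[[Tn + 1L - s]][, H1 + seq_len(H1), drop = FALSE])
  bl1f <- nnLstmBwd(dh1f, cc$l1f, p$lstm1f_Wx, p$lstm1f_Wh)
  bl1b <- nnLstmBwd(dh1b, cc$l1b, p$lstm1b_Wx, p$lstm1b_Wh)
  g$lstm1f_Wx <- bl1f$dWx; g$lstm1f_Wh <- bl1f$dWh; g$lstm1f_b <- bl1f$db
  g$lstm1b_Wx <- bl1b$dWx; g$lstm1b_Wh <- bl1b$dWh; g$lstm1b_b <- bl1b$db

  # branch 3
  d <- nnReluBwd(dcond, cc$sr2)
  bs2 <- nnDenseBwd(d, cc$sf2, p$cond_fc2_W)
  g$cond_fc2_W <- bs2$dW; g$cond_fc2_b <- bs2$db
  d <- nnReluBwd(bs2$dX, cc$sr1)
  bs1 <- nnDenseBwd(d, cc$sf1, p$cond_fc1_W)
  g$cond_fc1_W <- bs1$dW; g$cond_fc1_b <- bs1$db

  # branch 4
  d <- nnDropoutBwd(dph, cc$pdr2)
  d <- nnReluBwd(d, cc$pr2)
  bp2 <- nnDenseBwd(d, cc$pf2, p$ph_fc2_W)
  g$ph_fc2_W <- bp2$dW; g$ph_fc2_b <- bp2$db
  d <- nnDropoutBwd(bp2$dX, cc$pdr1)
  d <- nnReluBwd(d, cc$pr1)
  bp1 <- nnDenseBwd(d, cc$pf1, p$ph_fc1_W)
  g$ph_fc1_W <- bp1$dW; g$ph_fc1_b <- bp1$db

  g[names(params)]
}

# MSE loss + gradients for one mini-batch (used by the trainer and by
# the finite-difference gradient checks).
.modelLossGrad <- function(params, normStats, inputs, y, config,
                           training = FALSE) {
  fw <- .modelForward(params, normStats, inputs, config, training,
                      keep_cache = TRUE)
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dyhat <- 2 * resid / length(y)
  grads <- .modelBackward(params, fw$cache, dyhat, config)
  list(loss = loss, grads = grads, yhat = fw$yhat)
}

.sliceInputs <- function(enc, idx) {
  list(onehot = enc$onehot[idx, , , drop = FALSE],
       kmer = enc$kmer[idx, , , drop = FALSE],
       cond = enc$cond[idx, , drop = FALSE],
       ph = enc$ph[idx, , drop = FALSE],
       n = length(idx))
}

# coerce a (possibly JSON-restored) config into the exact types the
# compiled kernels expect
.asCppConfig <- function(config) {
  ints <- c("conv_filters", "conv_kernel", "pool_size", "conv_dense",
            "lstm_units", "kmer_dense", "cond_dense", "ph_dense",
            "head_dense", "epochs", "batch_size", "patience")
  for (nm in ints) config[[nm]] <- as.integer(config[[nm]])
  dbls <- c("conv_dropout", "ph_dropout", "head_dropout", "learning_rate",
            "beta1", "beta2", "weight_decay", "epsilon")
  for (nm in dbls) config[[nm]] <- as.numeric(config[[nm]])
  config
}

#' Train a Tm regressor
#'
#' Fits the condition scalers and input-standardisation statistics on
#' the training data only, then minimises the mean squared error with
#' Nadam over seeded shuffled mini-batches. When a validation set is
#' supplied its MSE is monitored each epoch; training stops after
#' `patience` epochs without improvement and the best-validation
#' parameters are restored. A non-finite loss aborts with a diagnostic.
#'
#' @param x an untrained [TmRegressor-class] from [buildRegressor()], or
#'   a [modelConfig()] (a model is then built from it).
#' @param data a [G4Dataset-class] of training records.
#' @param validation optional [G4Dataset-class] monitored for early
#'   stopping.
#' @param verbose print per-epoch losses.
#' @return a trained [TmRegressor-class] with its history filled in.
#' @export
trainRegressor <- function(x, data, validation = NULL, verbose = FALSE) {
  model <- if (is(x, "TmRegressor")) x else buildRegressor(x)
  config <- model@config
  stopifnot(is(data, "G4Dataset"), length(data) >= 2L)
  scalers <- fitScalers(data)
  enc <- encodeRecords(data, scalers)
  y <- g4Records(data)$tm_celsius
  normStats <- .fitNormStats(enc, config)
  has_val <- !is.null(validation)
  if (has_val) {
    stopifnot(is(validation, "G4Dataset"), length(validation) >= 1L)
    venc <- suppressWarnings(encodeRecords(validation, scalers, clip = TRUE))
    vy <- g4Records(validation)$tm_celsius
  }

  cpp_cfg <- .asCppConfig(config)
  val_inputs <- if (has_val)
    list(onehot = venc$onehot, kmer = venc$kmer, cond = venc$cond,
         ph = venc$ph, y = vy) else NULL
  set.seed(deriveSeed(config$rng_seed, 2L))
  res <- .cppTrainLoop(model@params, enc$onehot, enc$kmer, enc$cond, enc$ph,
                       y, normStats, cpp_cfg, val_inputs,
                       cpp_cfg$epochs, cpp_cfg$batch_size, cpp_cfg$patience,
                       if (verbose) 25L else 0L)
  history <- data.frame(epoch = seq_len(res$epochs_run),
                        train_mse = res$train_mse[seq_len(res$epochs_run)],
                        val_mse = res$val_mse[seq_len(res$epochs_run)])
  if (verbose)
    message(sprintf("trained %d epoch(s); final train MSE %.4f%s",
                    res$epochs_run, history$train_mse[res$epochs_run],
                    if (has_val) sprintf(" (best val %.4f at epoch %d)",
                                         min(history$val_mse),
                                         res$best_epoch) else ""))
  model@params <- res$params
  model@scalers <- scalers
  model@normStats <- normStats
  model@history <- history
  model@trained <- TRUE
  model
}

.asQueryFrame <- function(newdata) {
  nd <- as.data.frame(newdata)
  need <- c("sequence", .cation_names, "ph")
  missing <- setdiff(need, names(nd))
  if (length(missing))
    .stopf("query table missing column(s): %s", paste(missing, collapse = ", "))
  nd
}

#' Predict melting temperatures with a trained regressor
#'
#' Applies the scalers and normalisation statistics stored at fit time
#' (never refits them); condition values outside the training range are
#' clipped to the scaled unit interval with a warning. Prediction is
#' deterministic (dropout off) and batching-invariant.
#'
#' @param object a trained [TmRegressor-class].
#' @param newdata data.frame with columns `sequence`, `conc_k`,
#'   `conc_na`, `conc_li_nh4`, `ph`.
#' @param chunk_size rows encoded and forwarded per chunk (memory
#'   bound).
#' @param ... ignored.
#' @return numeric vector of predicted Tm in degC.
#' @export
setMethod("predict", "TmRegressor",
  function(object, newdata, chunk_size = 512L, ...) {
    if (!object@trained) .stopf("model is not trained")
    nd <- .asQueryFrame(newdata)
    n <- nrow(nd)
    out <- numeric(n)
    cpp_cfg <- .asCppConfig(object@config)
    for (s in seq(1L, n, by = chunk_size)) {
      idx <- s:min(s + chunk_size - 1L, n)
      enc <- encodeRecords(nd[idx, , drop = FALSE], object@scalers,
                           clip = TRUE)
      out[idx] <- .cppModelForward(object@params, enc$onehot, enc$kmer,
                                   enc$cond, enc$ph, object@normStats,
                                   cpp_cfg)
    }
    out
  })

#' Convenience wrapper: predict Tm for sequences under one condition
#'
#' @param model a trained [TmRegressor-class] or [TmEnsemble-class].
#' @param sequences character vector of A/C/G/T sequences.
#' @param condition an [ionicCondition()] (or preset name).
#' @param ph pH, default 7.
#' @return for a regressor, numeric Tm vector; for an ensemble, the
#'   data.frame from the ensemble predict method.
#' @export
predictTm <- function(model, sequences, condition = "normal", ph = 7) {
  cond <- if (is.character(condition)) conditionPreset(condition) else condition
  qd <- data.frame(sequence = sequences, conc_k = cond$conc_k,
                   conc_na = cond$conc_na, conc_li_nh4 = cond$conc_li_nh4,
                   ph = ph, stringsAsFactors = FALSE)
  predict(model, qd)
}

.configHash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  h <- 2166136261
  for (v in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), v)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.serializeArrays <- function(lst) {
  lapply(lst, function(a) list(dim = as.integer(dim(a) %||% length(a)),
                               data = as.numeric(a)))
}

.deserializeArrays <- function(lst) {
  lapply(lst, function(e) {
    d <- as.integer(unlist(e$dim))
    x <- as.numeric(unlist(e$data))
    if (length(d) > 1L) array(x, dim = d) else x
  })
}

#' Persist / restore a trained regressor
#'
#' The artifact is a directory of plain-text files: `config.json`,
#' `scalers.json`, `norm_stats.json`, `weights.json` (full-precision)
#' and `history.tsv`, plus a manifest carrying a hash of the
#' configuration. Loading refuses to proceed without the scalers or the
#' config, and warns if the stored config hash does not match the
#' weights it accompanies.
#'
#' @param model a trained [TmRegressor-class].
#' @param dir artifact directory (created if needed).
#' @return `saveRegressor`: `dir`, invisibly; `loadRegressor`: a
#'   [TmRegressor-class].
#' @export
saveRegressor <- function(model, dir) {
  stopifnot(is(model, "TmRegressor"), model@trained)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA)
  wj(model@config, "config.json")
  wj(list(mins = as.list(model@scalers@mins),
          maxs = as.list(model@scalers@maxs)), "scalers.json")
  wj(.serializeArrays(unlist(model@normStats, recursive = FALSE)),
     "norm_stats.json")
  wj(.serializeArrays(model@params), "weights.json")
  wj(list(config_hash = .configHash(model@config),
          package = "g4melt",
          version = as.character(utils::packageVersion("g4melt"))),
     "manifest.json")
  utils::write.table(model@history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname saveRegressor
#' @export
loadRegressor <- function(dir) {
  need <- c("config.json", "scalers.json", "weights.json", "norm_stats.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      .stopf("model artifact incomplete: missing %s", f)
  rj <- function(f) jsonlite::read_json(file.path(dir, f),
                                        simplifyVector = FALSE)
  config <- lapply(rj("config.json"), function(x)
    if (is.list(x)) unlist(x) else x)
  sc <- rj("scalers.json")
  scalers <- new("FeatureScalers",
                 mins = unlist(sc$mins)[c(.cation_names, "ph")],
                 maxs = unlist(sc$maxs)[c(.cation_names, "ph")])
  flatNorm <- .deserializeArrays(rj("norm_stats.json"))
  normStats <- list(
    onehot = list(mu = flatNorm[["onehot.mu"]], inv = flatNorm[["onehot.inv"]]),
    kmer = list(mu = flatNorm[["kmer.mu"]], inv = flatNorm[["kmer.inv"]]),
    cond = list(mu = flatNorm[["cond.mu"]], inv = flatNorm[["cond.inv"]]),
    ph = list(mu = flatNorm[["ph.mu"]], inv = flatNorm[["ph.inv"]]))
  params <- .deserializeArrays(rj("weights.json"))
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf)
    if (!identical(manifest$config_hash, .configHash(config)))
      .warnf("model artifact config hash mismatch (weights may come from a different configuration)")
  }
  hist_f <- file.path(dir, "history.tsv")
  history <- if (file.exists(hist_f))
    utils::read.delim(hist_f) else data.frame()
  new("TmRegressor", params = params, config = config, scalers = scalers,
      normStats = normStats, history = history, trained = TRUE)
}
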