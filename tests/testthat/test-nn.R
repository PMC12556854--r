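# Analytic gradients of the full four-branch graph are checked against
# central finite differences at a jittered parameter point (jittering
# moves units off the exact ReLU kinks that zero-initialised biases and
# zero-padded inputs would otherwise sit on).
test_that("backpropagation matches finite-difference gradients", {
  cfg <- modelConfig(conv_filters = c(3L, 4L), conv_kernel = 3L,
                     conv_dense = c(5L, 4L), lstm_units = c(3L, 2L),
                     kmer_dense = c(4L, 3L, 2L), cond_dense = c(3L, 2L),
                     ph_dense = c(2L, 2L), head_dense = c(4L, 3L),
                     conv_dropout = 0, ph_dropout = 0, head_dropout = 0,
                     rng_seed = 42L)
  mod <- buildRegressor(cfg)
  set.seed(11)
  mod@params <- lapply(mod@params, function(p)
    p + array(runif(length(p), -0.25, 0.25), dim = dim(p) %||% length(p)))
  ds <- generateG4Records(synthConfig(n_records = 5, rng_seed = 3))
  sc <- fitScalers(ds)
  enc <- encodeRecords(ds, sc)
  y <- g4Records(ds)$tm_celsius
  ns <- g4melt:::.fitNormStats(enc, cfg)
  lg <- g4melt:::.modelLossGrad(mod@params, ns, enc, y, cfg,
                                training = FALSE)
  set.seed(99)
  eps <- 1e-5
  for (nm in names(mod@params)) {
    p <- mod@params[[nm]]
    for (i in sample(length(p), min(3L, length(p)))) {
      pp <- mod@params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- mod@params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (g4melt:::.modelLossGrad(pp, ns, enc, y, cfg, FALSE)$loss -
              g4melt:::.modelLossGrad(pm, ns, enc, y, cfg, FALSE)$loss) /
        (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("builds are seeded: same seed identical, different seeds differ", {
  cfg <- tinyModelConfig(rng_seed = 17L)
  m1 <- buildRegressor(cfg)
  m2 <- buildRegressor(cfg)
  expect_identical(m1@params, m2@params)
  cfg2 <- tinyModelConfig(rng_seed = 18L)
  m3 <- buildRegressor(cfg2)
  expect_false(identical(m1@params$conv1_W, m3@params$conv1_W))
})

test_that("forward pass emits one finite real per record", {
  cfg <- tinyModelConfig()
  mod <- buildRegressor(cfg)
  ds <- generateG4Records(synthConfig(n_records = 9, rng_seed = 4))
  enc <- encodeRecords(ds, fitScalers(ds))
  ns <- g4melt:::.fitNormStats(enc, cfg)
  out <- g4melt:::.modelForward(mod@params, ns, enc, cfg, training = FALSE)
  expect_length(out$yhat, 9L)
  expect_true(all(is.finite(out$yhat)))
})

test_that("inconsistent geometry is a build error naming the branch", {
  expect_error(buildRegressor(modelConfig(conv_kernel = 60L)),
               "one-hot branch")
})

test_that("LSTM backward matches finite differences in isolation", {
  set.seed(77)
  B <- 3L; Tn <- 4L; D <- 5L; H <- 3L
  xs <- lapply(seq_len(Tn), function(t) matrix(rnorm(B * D), B, D))
  Wx <- matrix(rnorm(D * 4 * H, sd = 0.3), D, 4 * H)
  Wh <- matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H)
  b <- rnorm(4 * H, sd = 0.2)
  loss_of <- function(Wx, Wh, b) {
    fw <- g4melt:::nnLstmFwd(xs, Wx, Wh, b)
    sum(fw$hs[[Tn]]^2)
  }
  fw <- g4melt:::nnLstmFwd(xs, Wx, Wh, b)
  dhs <- rep(list(matrix(0, B, H)), Tn)
  dhs[[Tn]] <- 2 * fw$hs[[Tn]]
  bw <- g4melt:::nnLstmBwd(dhs, fw, Wx, Wh)
  eps <- 1e-6
  for (probe in 1:8) {
    i <- sample(length(Wx), 1)
    Wp <- Wx; Wp[i] <- Wp[i] + eps
    Wm <- Wx; Wm[i] <- Wm[i] - eps
    num <- (loss_of(Wp, Wh, b) - loss_of(Wm, Wh, b)) / (2 * eps)
    expect_equal(bw$dWx[i], num, tolerance = 1e-5)
    j <- sample(length(Wh), 1)
    Wp <- Wh; Wp[j] <- Wp[j] + eps
    Wm <- Wh; Wm[j] <- Wm[j] - eps
    num <- (loss_of(Wx, Wp, b) - loss_of(Wx, Wm, b)) / (2 * eps)
    expect_equal(bw$dWh[j], num, tolerance = 1e-5)
  }
})

test_that("compiled kernels agree with the pure-R reference implementations", {
  set.seed(123)
  B <- 4L; L <- 20L; C <- 3L; Fn <- 5L; k <- 4L
  X <- array(rnorm(B * L * C), dim = c(B, L, C))
  W <- matrix(rnorm(k * C * Fn, sd = 0.3), k * C, Fn)
  b <- rnorm(Fn, sd = 0.1)
  f_cpp <- g4melt:::nnConv1dFwd(X, W, b, k)
  f_r <- g4melt:::nnConv1dFwdR(X, W, b, k)
  expect_equal(f_cpp$Y, f_r$Y, tolerance = 1e-12)
  dY <- array(rnorm(length(f_r$Y)), dim = dim(f_r$Y))
  b_cpp <- g4melt:::nnConv1dBwd(dY, f_cpp, W)
  b_r <- g4melt:::nnConv1dBwdR(dY, f_r, W)
  expect_equal(b_cpp$dX, b_r$dX, tolerance = 1e-12)
  expect_equal(b_cpp$dW, b_r$dW, tolerance = 1e-12)
  expect_equal(b_cpp$db, unname(b_r$db), tolerance = 1e-12)

  Tn <- 6L; D <- 7L; H <- 4L
  xs <- lapply(seq_len(Tn), function(t) matrix(rnorm(B * D), B, D))
  Wx <- matrix(rnorm(D * 4 * H, sd = 0.3), D, 4 * H)
  Wh <- matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H)
  bb <- rnorm(4 * H, sd = 0.1)
  l_cpp <- g4melt:::nnLstmFwd(xs, Wx, Wh, bb)
  l_r <- g4melt:::nnLstmFwdR(xs, Wx, Wh, bb)
  for (t in seq_len(Tn))
    expect_equal(l_cpp$hs[[t]], l_r$hs[[t]], tolerance = 1e-12)
  dhs <- lapply(seq_len(Tn), function(t) matrix(rnorm(B * H), B, H))
  g_cpp <- g4melt:::nnLstmBwd(dhs, l_cpp, Wx, Wh)
  g_r <- g4melt:::nnLstmBwdR(dhs, l_r, Wx, Wh)
  expect_equal(g_cpp$dWx, g_r$dWx, tolerance = 1e-12)
  expect_equal(g_cpp$dWh, g_r$dWh, tolerance = 1e-12)
  expect_equal(g_cpp$db, unname(g_r$db), tolerance = 1e-12)
  for (t in seq_len(Tn))
    expect_equal(g_cpp$dxs[[t]], g_r$dxs[[t]], tolerance = 1e-12)
})
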