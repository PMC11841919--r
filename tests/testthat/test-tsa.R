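# scalar reference recurrence for one LSTM step (gate order i, f, o, g)
ref_lstm_step <- function(x, h, c, W, U, b) {
  u <- length(h)
  hn <- numeric(u); cn <- numeric(u)
  sig <- function(z) 1 / (1 + exp(-z))
  for (j in seq_len(u)) {
    zi <- sum(W[j, ] * x) + sum(U[j, ] * h) + b[j]
    zf <- sum(W[u + j, ] * x) + sum(U[u + j, ] * h) + b[u + j]
    zo <- sum(W[2 * u + j, ] * x) + sum(U[2 * u + j, ] * h) + b[2 * u + j]
    zg <- sum(W[3 * u + j, ] * x) + sum(U[3 * u + j, ] * h) + b[3 * u + j]
    cn[j] <- sig(zf) * c[j] + sig(zi) * tanh(zg)
    hn[j] <- sig(zo) * tanh(cn[j])
  }
  list(h = hn, c = cn)
}

test_that("lstm_step matches a scalar-by-scalar reference recurrence", {
  set.seed(10)
  for (rep in 1:5) {
    d <- sample(1:4, 1); u <- sample(1:5, 1)
    w <- list(W = matrix(rnorm(4 * u * d), 4 * u, d),
              U = matrix(rnorm(4 * u * u), 4 * u, u),
              b = matrix(rnorm(4 * u), 4 * u, 1))
    x <- rnorm(d); h <- rnorm(u); cc <- rnorm(u)
    got <- lstm_step(x, h, cc, w)
    ref <- ref_lstm_step(x, h, cc, w$W, w$U, as.vector(w$b))
    expect_equal(as.vector(got$h), ref$h, tolerance = 1e-10)
    expect_equal(as.vector(got$c), ref$c, tolerance = 1e-10)
  }
})

test_that("lstm_step degenerates correctly and stays bounded", {
  u <- 3; d <- 2
  w0 <- list(W = matrix(0, 4 * u, d), U = matrix(0, 4 * u, u),
             b = matrix(0, 4 * u, 1))
  st <- lstm_step(rnorm(d), rnorm(u), rep(0, u), w0)
  expect_equal(as.vector(st$h), rep(0, u))  # gates 0.5, candidate 0
  expect_equal(as.vector(st$c), rep(0, u))
  set.seed(11)
  w <- list(W = matrix(rnorm(4 * u * d, 0, 3), 4 * u, d),
            U = matrix(rnorm(4 * u * u, 0, 3), 4 * u, u),
            b = matrix(rnorm(4 * u), 4 * u, 1))
  st <- lstm_step(rnorm(d, 0, 5), rnorm(u), rnorm(u, 0, 5), w)
  expect_true(all(abs(st$h) < 1))
  expect_error(lstm_step(rnorm(3), rnorm(u), rnorm(u), w0), "shapes")
})

test_that("input attention is a softmax over drivers", {
  tau <- 5; s <- 3
  params <- list(ve = matrix(rnorm(tau), tau, 1),
                 We = matrix(rnorm(tau * 2 * s), tau, 2 * s),
                 Ue = matrix(rnorm(tau * tau), tau, tau))
  h <- rnorm(s); cc <- rnorm(s)
  # singleton: alpha = 1
  expect_equal(input_attention(matrix(rnorm(tau), 1, tau), h, cc, params), 1)
  # identical windows: symmetry gives 0.5 / 0.5
  w <- matrix(rnorm(tau), 1, tau)
  expect_equal(input_attention(rbind(w, w), h, cc, params), c(0.5, 0.5))
  # random instance equals an exp-normalize loop oracle
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    X <- matrix(rnorm(n * tau), n, tau)
    a <- input_attention(X, h, cc, params)
    logit <- vapply(seq_len(n), function(k) {
      sum(params$ve * tanh(params$We %*% c(h, cc) + params$Ue %*% X[k, ]))
    }, numeric(1))
    expect_equal(a, exp(logit) / sum(exp(logit)), tolerance = 1e-12)
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
})

test_that("temporal attention is a softmax over encoder steps", {
  tau <- 6; s <- 4; p <- 3
  params <- list(vd = matrix(rnorm(s), s, 1),
                 Wd = matrix(rnorm(s * 2 * p), s, 2 * p),
                 Ud = matrix(rnorm(s * s), s, s))
  d <- rnorm(p); cd <- rnorm(p)
  # identical encoder states: uniform weights
  H_same <- matrix(rep(rnorm(s), tau), s, tau)
  expect_equal(temporal_attention(d, cd, H_same, params), rep(1 / tau, tau))
  # single step: beta = 1
  expect_equal(temporal_attention(d, cd, matrix(rnorm(s), s, 1), params), 1)
  # random instance vs loop-softmax oracle
  set.seed(13)
  H <- matrix(rnorm(s * tau), s, tau)
  b <- temporal_attention(d, cd, H, params)
  logit <- vapply(seq_len(tau), function(i) {
    sum(params$vd * tanh(params$Wd %*% c(d, cd) + params$Ud %*% H[, i]))
  }, numeric(1))
  expect_equal(b, exp(logit) / sum(exp(logit)), tolerance = 1e-12)
})

test_that("the context vector is the beta-weighted sum of encoder states", {
  set.seed(14)
  s <- 4; tau <- 5
  H <- matrix(rnorm(s * tau), s, tau)
  onehot <- rep(0, tau); onehot[3] <- 1
  expect_equal(context_vector(onehot, H), H[, 3])
  expect_equal(context_vector(rep(1 / tau, tau), H), rowMeans(H))
  b <- runif(tau); b <- b / sum(b)
  acc <- rep(0, s)
  for (i in seq_len(tau)) acc <- acc + b[i] * H[, i]
  expect_equal(context_vector(b, H), acc, tolerance = 1e-12)
  expect_error(context_vector(b[-1], H), "equal")
})

test_that("encode/decode traces normalize and zero readout yields the bias", {
  fx <- fix_tsa()
  smp <- fix_sample(fx$ds, 2)
  es <- encode(smp, fx$handle)
  expect_equal(dim(es$H), c(fx$cfg$s, fx$cfg$tau))
  expect_equal(colSums(es$alphas), rep(1, fx$cfg$tau), tolerance = 1e-6)
  dc <- decode(smp, es$H, fx$handle)
  expect_equal(colSums(dc$betas), rep(1, fx$cfg$tau - 1L), tolerance = 1e-6)

  h0 <- fx$handle
  h0$params$out_W[] <- 0
  h0$params$out_b[] <- 1.25
  dc0 <- decode(smp, encode(smp, h0)$H, h0)
  expect_equal(dc0$pred, 1.25)
})

test_that("batched forward equals the per-sample sequential path", {
  fx <- fix_tsa()
  idx <- 1:6
  batch <- tsaforecast:::ds_take(fx$ds, idx)
  out <- fx$handle$forward(fx$handle$params, batch, rate = 0)
  seq_pred <- vapply(idx, function(i) {
    smp <- fix_sample(fx$ds, i)
    decode(smp, encode(smp, fx$handle)$H, fx$handle)$pred
  }, numeric(1))
  expect_equal(as.vector(tsaforecast:::nval(out$pred)), seq_pred,
               tolerance = 1e-6)
})

test_that("a single driver degenerates to alpha = 1 everywhere", {
  fx <- fix_tsa(n = 1L)
  smp <- fix_sample(fx$ds, 1)
  es <- encode(smp, fx$handle)
  expect_equal(as.vector(es$alphas), rep(1, fx$cfg$tau))
})

test_that("training is seed-reproducible and respects early stopping", {
  fx <- fix_tsa(T_ = 40L)
  cfg <- tsa_config(n = 3, tau = 4, s = 3, p = 3, lr = 0.01, dropout = 0.2,
                    batch_size = 16, max_epochs = 30, patience = 5, seed = 99)
  sp <- split_windows(fx$ds, test = 6, val = 6)
  f1 <- train_model(build_tsa(cfg), fx$ds, sp)
  f2 <- train_model(build_tsa(cfg), fx$ds, sp)
  expect_identical(f1$history, f2$history)          # bitwise-identical
  expect_identical(f1$params, f2$params)
  ran <- nrow(f1$history)
  expect_lte(ran, cfg$max_epochs)
  expect_lte(ran - f1$best_epoch, cfg$patience)     # never past best + patience
  # predictions return to the original scale
  pred <- predict(f1, fx$ds, samples = sp$test)
  expect_length(pred, 6L)
  expect_true(all(is.finite(pred)))
})

test_that("analytic gradients match finite differences on a tiny model", {
  fx <- fix_tsa(n = 2L, tau = 3L, s = 3L, p = 3L, T_ = 20L, seed = 31L)
  # standardize so the loss is O(1), as in training
  sp <- split_windows(fx$ds, test = 4, val = 4)
  std <- tsaforecast:::ds_standardize(fx$ds, tsaforecast:::ds_scaler(fx$ds, sp$train))
  batch <- tsaforecast:::ds_take(std, 1:5)
  expect_lt(gradient_check(fx$handle, batch), 1e-4)
})

test_that("gradients vanish at the readout bias for a zero-loss sample and scale linearly", {
  fx <- fix_tsa(n = 2L, tau = 3L, s = 2L, p = 2L, T_ = 15L, seed = 8L)
  batch <- tsaforecast:::ds_take(fx$ds, 1:3)
  params <- fx$handle$params
  ad_grad <- tsaforecast:::ad_grad
  ad_mse <- tsaforecast:::ad_mse
  # force prediction == label: target set to the model's own output
  out <- fx$handle$forward(params, batch, rate = 0)$pred
  g0 <- ad_grad(params, function(pn) {
    ad_mse(fx$handle$forward(pn, batch, rate = 0)$pred, out)
  })
  expect_equal(g0$grads$out_b[1, 1], 0)
  # doubling the loss doubles every gradient
  target <- matrix(batch$labels, nrow = 1)
  g1 <- ad_grad(params, function(pn) {
    ad_mse(fx$handle$forward(pn, batch, rate = 0)$pred, target)
  })
  g2 <- ad_grad(params, function(pn) {
    tsaforecast:::ad_scale(
      ad_mse(fx$handle$forward(pn, batch, rate = 0)$pred, target), 2)
  })
  for (nm in names(g1$grads)) {
    expect_equal(g2$grads[[nm]], 2 * g1$grads[[nm]], tolerance = 1e-10)
  }
})

test_that("checkpoints reload bit-exactly", {
  fx <- fix_tsa(T_ = 30L)
  cfg <- tsa_config(n = 3, tau = 4, s = 2, p = 2, lr = 0.01, batch_size = 8,
                    max_epochs = 3, patience = 3, seed = 5)
  sp <- split_windows(fx$ds, test = 5, val = 5)
  fit <- train_model(build_tsa(cfg), fx$ds, sp)
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  re <- load_checkpoint(path)
  expect_identical(re$params, fit$params)
  expect_equal(predict(re, fx$ds, samples = sp$test),
               predict(fit, fx$ds, samples = sp$test))
})
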