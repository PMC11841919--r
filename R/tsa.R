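#' TSA-LSTM configuration
#'
#' Hyperparameters of the two-stage-attention LSTM and its training
#' protocol. Defaults follow the reference protocol: hidden sizes 128,
#' dropout 0.2, learning rate 0.001, minibatch 128, up to 1000 epochs with
#' early stopping after 20 non-improving epochs.
#'
#' @param n Number of driving series.
#' @param tau Window length (encoder steps per prediction).
#' @param s Encoder hidden size.
#' @param p Decoder hidden size.
#' @param dropout Dropout rate applied to recurrent hidden states during
#'   training.
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs past the best validation
#'   loss).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param optimizer \code{"adam"} (default) or plain \code{"sgd"}.
#' @return A list of class \code{tsa_config}.
#' @export
tsa_config <- function(n, tau, s = 128L, p = 128L, dropout = 0.2, lr = 0.001,
                       batch_size = 128L, max_epochs = 1000L, patience = 20L,
                       seed = 1L, optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  cfg <- list(
    n = as.integer(n), tau = as.integer(tau), s = as.integer(s),
    p = as.integer(p), dropout = dropout, lr = lr,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), seed = as.integer(seed),
    optimizer = optimizer
  )
  stopifnot(cfg$n >= 1L, cfg$tau >= 1L, cfg$s >= 1L, cfg$p >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "tsa_config"
  cfg
}

# parameter blocks; shapes follow the attention equations:
#   v_e in R^tau, W_e in R^(tau x 2s), U_e in R^(tau x tau)
#   v_d in R^s,   W_d in R^(s x 2p),   U_d in R^(s x s)
init_tsa_params <- function(cfg) {
  n <- cfg$n; tau <- cfg$tau; s <- cfg$s; p <- cfg$p
  c(
    lstm_params(n, s, "enc"),
    list(
      ve = init_mat(tau, 1L, tau),
      We = init_mat(tau, 2L * s, 2L * s),
      Ue = init_mat(tau, tau, tau)
    ),
    lstm_params(1L, p, "dec"),
    list(
      vd = init_mat(s, 1L, s),
      Wd = init_mat(s, 2L * p, 2L * p),
      Ud = init_mat(s, s, s),
      fus_w = init_mat(1L, 1L + s, 1L + s),
      fus_b = matrix(0, 1L, 1L),
      out_W = init_mat(1L, p + s, p + s),
      out_b = matrix(0, 1L, 1L)
    )
  )
}

# inverted dropout mask
drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

mask_mul <- function(x, m) if (is.null(m)) x else ad_mul(x, m)

# slice helpers tolerating B = 1
win_matrix <- function(windows, a, tau) matrix(windows[a, , ], nrow = tau)
step_matrix <- function(windows, t, n) matrix(windows[, t, ], nrow = n)

# Batched TSA-LSTM forward pass.
# batch: list(windows = n x tau x B array, past = (tau-1) x B matrix).
# params may be plain matrices or tape nodes. Returns pred (1 x B) plus,
# when trace = TRUE, numeric attention traces.
forward_tsa <- function(params, batch, cfg, rate = 0, trace = FALSE) {
  n <- cfg$n; tau <- cfg$tau; s <- cfg$s; p <- cfg$p
  B <- dim(batch$windows)[3]
  win_list <- lapply(seq_len(n), function(a) win_matrix(batch$windows, a, tau))
  m_enc <- drop_mask(s, B, rate)
  m_dec <- drop_mask(p, B, rate)

  h <- matrix(0, s, B); cc <- matrix(0, s, B)
  H <- vector("list", tau)
  alphas <- if (trace) array(NA_real_, c(n, tau, B)) else NULL
  for (t in seq_len(tau)) {
    al <- input_attention_op(win_list, h, cc, params$ve, params$We, params$Ue)
    if (trace) for (a in seq_len(n)) alphas[a, t, ] <- nval(al[[a]])
    amat <- Reduce(ad_rbind, al)
    xhat <- ad_mul(step_matrix(batch$windows, t, n), amat)
    st <- lstm_step_op(xhat, h, cc, params$enc_W, params$enc_U, params$enc_b)
    h <- mask_mul(st$h, m_enc)
    cc <- st$c
    H[[t]] <- h
  }

  d <- matrix(0, p, B); cd <- matrix(0, p, B)
  chat <- matrix(0, s, B)
  betas <- if (trace && tau > 1L) array(NA_real_, c(tau, tau - 1L, B)) else NULL
  if (tau > 1L) {
    for (t in 2:tau) {
      bl <- temporal_attention_op(d, cd, H, params$vd, params$Wd, params$Ud)
      if (trace) for (i in seq_len(tau)) betas[i, t - 1L, ] <- nval(bl[[i]])
      chat_new <- context_vector_op(bl, H)
      ylag <- matrix(batch$past[t - 1L, ], nrow = 1L)
      ytilde <- ad_add(ad_matmul(params$fus_w, ad_rbind(ylag, chat)), params$fus_b)
      st <- lstm_step_op(ytilde, d, cd, params$dec_W, params$dec_U, params$dec_b)
      d <- mask_mul(st$h, m_dec)
      cd <- st$c
      chat <- chat_new
    }
  }
  pred <- ad_add(ad_matmul(params$out_W, ad_rbind(d, chat)), params$out_b)
  list(pred = pred, alphas = alphas, betas = betas)
}

#' Build an (untrained) TSA-LSTM model handle
#'
#' The two-stage-attention LSTM: an LSTM encoder whose inputs are reweighted
#' per time step by input attention over the driving series, and an LSTM
#' decoder driven by past targets fused with temporal-attention context
#' vectors; the prediction is a linear readout of the final decoder state
#' and context vector.
#'
#' @param config A \code{\link{tsa_config}}.
#' @return A model handle (class \code{rnn_handle}) exposing the common
#'   train/predict contract; pass it to \code{\link{train_model}}.
#' @export
build_tsa <- function(config) {
  stopifnot(inherits(config, "tsa_config"))
  structure(
    list(
      name = "TSA-LSTM",
      config = config,
      init = function() init_tsa_params(config),
      forward = function(params, batch, rate = 0, trace = FALSE) {
        forward_tsa(params, batch, config, rate = rate, trace = trace)
      },
      params = NULL
    ),
    class = "rnn_handle"
  )
}

#' @export
print.rnn_handle <- function(x, ...) {
  cat(sprintf(
    "<rnn_handle> %s (tau = %d, n = %d)%s\n",
    x$name, x$config$tau, x$config$n,
    if (is.null(x$params)) " [untrained]" else " [trained]"
  ))
  invisible(x)
}

# one sample as a B = 1 batch
sample_batch <- function(sample) {
  w <- sample$windows
  if (length(dim(w)) == 2L) w <- array(w, c(dim(w), 1L))
  past <- sample$past
  if (is.null(past)) past <- matrix(0, 0L, 1L)
  if (!is.matrix(past)) past <- matrix(past, ncol = 1L)
  list(windows = w, past = past)
}

model_params <- function(model) {
  p <- model$params
  if (is.null(p)) stop("model has no parameters; train it or call $init()", call. = FALSE)
  p
}

#' Run the attention encoder on one sample
#'
#' Sequentially applies input attention and the encoder LSTM over the
#' window, starting from zero hidden and cell states.
#'
#' @param sample List with \code{windows} (n x tau driver windows) and
#'   optionally \code{past} (ignored here).
#' @param model A TSA-LSTM handle with parameters (train it first, or set
#'   \code{model$params <- model$init()}).
#' @return List with \code{H} (s x tau matrix of hidden states) and
#'   \code{alphas} (n x tau input-attention trace; columns sum to 1).
#' @export
encode <- function(sample, model) {
  enc_states(model_params(model), sample_batch(sample), model$config)
}

# encoder-only pass returning states + alpha trace (numeric)
enc_states <- function(params, batch, cfg) {
  n <- cfg$n; tau <- cfg$tau; s <- cfg$s
  B <- dim(batch$windows)[3]
  win_list <- lapply(seq_len(n), function(a) win_matrix(batch$windows, a, tau))
  h <- matrix(0, s, B); cc <- matrix(0, s, B)
  H <- matrix(0, s, tau)
  alphas <- matrix(0, n, tau)
  for (t in seq_len(tau)) {
    al <- input_attention_op(win_list, h, cc, params$ve, params$We, params$Ue)
    alphas[, t] <- vapply(al, function(x) nval(x)[1, 1], numeric(1))
    amat <- Reduce(ad_rbind, al)
    xhat <- ad_mul(step_matrix(batch$windows, t, n), amat)
    st <- lstm_step_op(xhat, h, cc, params$enc_W, params$enc_U, params$enc_b)
    h <- st$h; cc <- st$c
    H[, t] <- h[, 1]
  }
  list(H = H, alphas = alphas)
}

#' Run the attention decoder on one sample
#'
#' Starting from zero decoder state and context, alternates temporal
#' attention, context formation, target/context fusion and the decoder
#' LSTM, then applies the linear readout to the final decoder state and
#' context vector.
#'
#' @param sample List with \code{past}: the tau - 1 past target values.
#' @param H s x tau matrix of encoder hidden states (from
#'   \code{\link{encode}}).
#' @param model A TSA-LSTM handle with parameters.
#' @return List with \code{pred} (scalar) and \code{betas}
#'   (tau x (tau - 1) temporal-attention trace; columns sum to 1).
#' @export
decode <- function(sample, H, model) {
  params <- model_params(model)
  cfg <- model$config
  tau <- cfg$tau; s <- cfg$s; p <- cfg$p
  if (is.null(H)) stop("encoder states H are required", call. = FALSE)
  H <- as.matrix(H)
  Hl <- lapply(seq_len(tau), function(i) H[, i, drop = FALSE])
  past <- as.numeric(sample$past)
  d <- matrix(0, p, 1L); cd <- matrix(0, p, 1L); chat <- matrix(0, s, 1L)
  betas <- if (tau > 1L) matrix(0, tau, tau - 1L) else NULL
  if (tau > 1L) {
    for (t in 2:tau) {
      bl <- temporal_attention_op(d, cd, Hl, params$vd, params$Wd, params$Ud)
      betas[, t - 1L] <- vapply(bl, function(x) nval(x)[1, 1], numeric(1))
      chat_new <- context_vector_op(bl, Hl)
      ylag <- matrix(past[t - 1L], 1L, 1L)
      ytilde <- ad_add(ad_matmul(params$fus_w, ad_rbind(ylag, chat)), params$fus_b)
      st <- lstm_step_op(ytilde, d, cd, params$dec_W, params$dec_U, params$dec_b)
      d <- st$h; cd <- st$c; chat <- chat_new
    }
  }
  pred <- (nval(params$out_W) %*% rbind(nval(d), nval(chat)))[1, 1] +
    nval(params$out_b)[1, 1]
  list(pred = pred, betas = betas)
}
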