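# Recurrent cells and attention blocks. Internal `_op` functions are written
# against the autodiff operators, so they run on plain matrices (inference,
# unit tests) and on tape nodes (training) alike. Exported wrappers expose
# the per-sample numeric contract.

as_col <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

# uniform fan-in-scaled initialization
init_mat <- function(nr, nc, fan_in = nc) {
  lim <- 1 / sqrt(max(fan_in, 1))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# LSTM parameter block for input dimension d, hidden size u; the four gates
# (input, forget, output, candidate) are stacked row-wise in W, U, b
lstm_params <- function(d, u, prefix) {
  p <- list(
    W = init_mat(4L * u, d, d + u),
    U = init_mat(4L * u, u, d + u),
    b = matrix(0, 4L * u, 1L)
  )
  names(p) <- paste0(prefix, c("_W", "_U", "_b"))
  p
}

gru_params <- function(d, u, prefix) {
  p <- list(
    W = init_mat(3L * u, d, d + u),
    U = init_mat(3L * u, u, d + u),
    b = matrix(0, 3L * u, 1L)
  )
  names(p) <- paste0(prefix, c("_W", "_U", "_b"))
  p
}

# one LSTM step; weights = list(W, U, b); x (d x B), h/c (u x B)
lstm_step_op <- function(x, h_prev, c_prev, W, U, b) {
  u <- nrow(nval(h_prev))
  z <- ad_add(ad_add(ad_matmul(W, x), ad_matmul(U, h_prev)), b)
  i <- ad_sigmoid(ad_rows(z, 1L, u))
  f <- ad_sigmoid(ad_rows(z, u + 1L, 2L * u))
  o <- ad_sigmoid(ad_rows(z, 2L * u + 1L, 3L * u))
  g <- ad_tanh(ad_rows(z, 3L * u + 1L, 4L * u))
  c_new <- ad_add(ad_mul(f, c_prev), ad_mul(i, g))
  h_new <- ad_mul(o, ad_tanh(c_new))
  list(h = h_new, c = c_new)
}

# one GRU step; gates (update z, reset r, candidate) stacked in W, U, b;
# candidate uses the original form tanh(W_n x + U_n (r o h) + b_n)
gru_step_op <- function(x, h_prev, W, U, b) {
  u <- nrow(nval(h_prev))
  wx <- ad_matmul(W, x)
  z <- ad_sigmoid(ad_add(
    ad_add(ad_rows(wx, 1L, u), ad_matmul(ad_rows(U, 1L, u), h_prev)),
    ad_rows(b, 1L, u)
  ))
  r <- ad_sigmoid(ad_add(
    ad_add(ad_rows(wx, u + 1L, 2L * u),
           ad_matmul(ad_rows(U, u + 1L, 2L * u), h_prev)),
    ad_rows(b, u + 1L, 2L * u)
  ))
  n_ <- ad_tanh(ad_add(
    ad_add(ad_rows(wx, 2L * u + 1L, 3L * u),
           ad_matmul(ad_rows(U, 2L * u + 1L, 3L * u), ad_mul(r, h_prev))),
    ad_rows(b, 2L * u + 1L, 3L * u)
  ))
  # h = (1 - z) * h_prev + z * n
  ad_add(ad_sub(h_prev, ad_mul(z, h_prev)), ad_mul(z, n_))
}

# Input attention over drivers (softmax over series a = 1..n):
#   e^a = v_e' tanh(W_e [h; c] + U_e x^a),  alpha = softmax_a(e^a)
# `win_list`: per-driver full windows (tau x B). Returns list of 1 x B rows.
input_attention_op <- function(win_list, h_prev, c_prev, ve, We, Ue) {
  hc <- ad_rbind(h_prev, c_prev)
  base <- ad_matmul(We, hc)
  vT <- ad_t(ve)
  logits <- lapply(win_list, function(xa) {
    ad_matmul(vT, ad_tanh(ad_add(base, ad_matmul(Ue, xa))))
  })
  ad_softmax_list(logits)
}

# Temporal attention over encoder states (softmax over i = 1..tau):
#   l^i = v_d' tanh(W_d [d; c] + U_d h_i),  beta = softmax_i(l^i)
# `H`: list of tau encoder states (s x B). Returns list of 1 x B rows.
temporal_attention_op <- function(d_prev, cell_prev, H, vd, Wd, Ud) {
  dc <- ad_rbind(d_prev, cell_prev)
  base <- ad_matmul(Wd, dc)
  vT <- ad_t(vd)
  logits <- lapply(H, function(hi) {
    ad_matmul(vT, ad_tanh(ad_add(base, ad_matmul(Ud, hi))))
  })
  ad_softmax_list(logits)
}

# context vector c = sum_i beta_i h_i; beta as list of 1 x B rows
context_vector_op <- function(beta, H) {
  ad_sum_list(Map(function(b, h) ad_rowscale(h, b), beta, H))
}

#' Single LSTM cell step
#'
#' Standard gated formulation: sigmoid input/forget/output gates, tanh
#' candidate and output squashing,
#' \eqn{c_t = f \odot c_{t-1} + i \odot \tilde c}, \eqn{h_t = o \odot
#' \tanh(c_t)}.
#'
#' @param x Input vector (length d) or d x B matrix.
#' @param h_prev,c_prev Previous hidden/cell state, length u or u x B.
#' @param weights List with gate-stacked matrices \code{W} (4u x d),
#'   \code{U} (4u x u) and bias \code{b} (4u x 1); gate order input,
#'   forget, output, candidate.
#' @return List with matrices \code{h} and \code{c}.
#' @export
lstm_step <- function(x, h_prev, c_prev, weights) {
  x <- as_col(x); h_prev <- as_col(h_prev); c_prev <- as_col(c_prev)
  if (nrow(weights$W) != 4L * nrow(h_prev) || ncol(weights$W) != nrow(x) ||
      ncol(weights$U) != nrow(h_prev)) {
    stop("weight shapes inconsistent with inputs", call. = FALSE)
  }
  lstm_step_op(x, h_prev, c_prev, weights$W, weights$U, weights$b)
}

#' Input attention over driving series
#'
#' Stage-one attention: scores each driving series from the encoder's
#' previous hidden and cell state plus the series' full window, and
#' softmax-normalizes across series so the weights sum to one.
#'
#' @param driver_windows n x tau matrix: one row per driving series, the
#'   series' window of length tau.
#' @param h_prev,c_prev Encoder hidden/cell state (length s).
#' @param params List with \code{ve} (tau x 1), \code{We} (tau x 2s),
#'   \code{Ue} (tau x tau).
#' @return Numeric vector of n attention weights summing to 1.
#' @export
input_attention <- function(driver_windows, h_prev, c_prev, params) {
  driver_windows <- as.matrix(driver_windows)
  tau <- ncol(driver_windows)
  if (nrow(params$ve) != tau || ncol(params$Ue) != tau) {
    stop("attention parameter shapes inconsistent with the window", call. = FALSE)
  }
  wl <- lapply(seq_len(nrow(driver_windows)), function(a) {
    matrix(driver_windows[a, ], ncol = 1L)
  })
  al <- input_attention_op(wl, as_col(h_prev), as_col(c_prev),
                           params$ve, params$We, params$Ue)
  vapply(al, function(x) nval(x)[1, 1], numeric(1))
}

#' Temporal attention over encoder states
#'
#' Stage-two attention: scores every encoder hidden state from the decoder's
#' previous hidden and cell state, softmax-normalized across the tau encoder
#' steps.
#'
#' @param d_prev,cell_prev Decoder hidden/cell state (length p).
#' @param H s x tau matrix of encoder hidden states (one column per step).
#' @param params List with \code{vd} (s x 1), \code{Wd} (s x 2p),
#'   \code{Ud} (s x s).
#' @return Numeric vector of tau attention weights summing to 1.
#' @export
temporal_attention <- function(d_prev, cell_prev, H, params) {
  H <- as.matrix(H)
  Hl <- lapply(seq_len(ncol(H)), function(i) H[, i, drop = FALSE])
  bl <- temporal_attention_op(as_col(d_prev), as_col(cell_prev), Hl,
                              params$vd, params$Wd, params$Ud)
  vapply(bl, function(x) nval(x)[1, 1], numeric(1))
}

#' Context vector
#'
#' Weighted sum of the encoder hidden states under temporal-attention
#' weights: \eqn{\hat c = \sum_i \beta_i h_i}.
#'
#' @param beta Numeric vector of tau weights.
#' @param H s x tau matrix of encoder hidden states.
#' @return Numeric vector of length s.
#' @export
context_vector <- function(beta, H) {
  H <- as.matrix(H)
  if (length(beta) != ncol(H)) stop("length(beta) must equal ncol(H)", call. = FALSE)
  as.vector(H %*% matrix(beta, ncol = 1L))
}
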