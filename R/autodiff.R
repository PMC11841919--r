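# Minimal reverse-mode automatic differentiation on matrices.
#
# Every operator accepts either a plain numeric matrix (in which case it just
# computes the value) or an `adnode` recorded on a tape (in which case the
# result is a new node whose `back` closure propagates gradients to its
# parents). Forward code written against these operators therefore serves
# both as the inference path and the differentiable training path.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

is_node <- function(x) inherits(x, "adnode")

nval <- function(x) if (is_node(x)) x$val else x

node_tape <- function(...) {
  for (a in list(...)) if (is_node(a)) return(a$tp)
  NULL
}

new_node <- function(tp, val, parents = integer(), back = NULL) {
  id <- tp$n + 1L
  if (id > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$n <- id
  tp$nodes[[id]] <- list(val = val, parents = parents, back = back)
  structure(list(tp = tp, id = id, val = val), class = "adnode")
}

# leaf with gradient tracking (a trainable parameter)
ad_param <- function(tp, val) new_node(tp, val)

parent_ids <- function(...) {
  vapply(Filter(is_node, list(...)), function(x) x$id, integer(1))
}

# helper: build node when any input is a node, else return plain value
ad_emit <- function(val, back_builder, ...) {
  tp <- node_tape(...)
  if (is.null(tp)) return(val)
  args <- list(...)
  takes <- vapply(args, is_node, logical(1))
  back <- back_builder(takes)
  new_node(tp, val, parents = parent_ids(...), back = back)
}

ad_matmul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  val <- va %*% vb
  ad_emit(val, function(takes) {
    function(G) {
      out <- list()
      j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G %*% t(vb) }
      if (takes[2]) { j <- j + 1L; out[[j]] <- t(va) %*% G }
      out
    }
  }, a, b)
}

# elementwise add; `b` may be a one-column bias broadcast over columns of `a`
ad_add <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  bcast <- ncol(vb) == 1L && ncol(va) > 1L
  val <- if (bcast) va + as.vector(vb) else va + vb
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G }
      if (takes[2]) {
        j <- j + 1L
        out[[j]] <- if (bcast) matrix(rowSums(G), ncol = 1L) else G
      }
      out
    }
  }, a, b)
}

ad_sub <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  val <- va - vb
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G }
      if (takes[2]) { j <- j + 1L; out[[j]] <- -G }
      out
    }
  }, a, b)
}

# elementwise product (equal dims, or `b` a one-column vector broadcast)
ad_mul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  bcast <- ncol(vb) == 1L && ncol(va) > 1L
  val <- if (bcast) va * as.vector(vb) else va * vb
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) {
        j <- j + 1L
        out[[j]] <- if (bcast) G * as.vector(vb) else G * vb
      }
      if (takes[2]) {
        j <- j + 1L
        out[[j]] <- if (bcast) matrix(rowSums(G * va), ncol = 1L) else G * va
      }
      out
    }
  }, a, b)
}

# scale rows of `a` (r x B) by a 1 x B weight row
ad_rowscale <- function(a, w) {
  va <- nval(a); vw <- nval(w)
  wx <- matrix(as.vector(vw), nrow(va), ncol(va), byrow = TRUE)
  val <- va * wx
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G * wx }
      if (takes[2]) { j <- j + 1L; out[[j]] <- matrix(colSums(G * va), nrow = 1L) }
      out
    }
  }, a, w)
}

ad_tanh <- function(a) {
  val <- tanh(nval(a))
  ad_emit(val, function(takes) function(G) list(G * (1 - val^2)), a)
}

ad_sigmoid <- function(a) {
  val <- 1 / (1 + exp(-nval(a)))
  ad_emit(val, function(takes) function(G) list(G * val * (1 - val)), a)
}

ad_exp <- function(a) {
  val <- exp(nval(a))
  ad_emit(val, function(takes) function(G) list(G * val), a)
}

ad_div <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  val <- va / vb
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G / vb }
      if (takes[2]) { j <- j + 1L; out[[j]] <- -G * va / vb^2 }
      out
    }
  }, a, b)
}

ad_rbind <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  na <- nrow(va)
  val <- rbind(va, vb)
  ad_emit(val, function(takes) {
    function(G) {
      out <- list(); j <- 0L
      if (takes[1]) { j <- j + 1L; out[[j]] <- G[seq_len(na), , drop = FALSE] }
      if (takes[2]) { j <- j + 1L; out[[j]] <- G[-seq_len(na), , drop = FALSE] }
      out
    }
  }, a, b)
}

ad_rows <- function(a, from, to) {
  va <- nval(a)
  val <- va[from:to, , drop = FALSE]
  ad_emit(val, function(takes) {
    function(G) {
      Z <- matrix(0, nrow(va), ncol(va))
      Z[from:to, ] <- G
      list(Z)
    }
  }, a)
}

ad_t <- function(a) {
  val <- t(nval(a))
  ad_emit(val, function(takes) function(G) list(t(G)), a)
}

ad_scale <- function(a, k) {
  val <- nval(a) * k
  ad_emit(val, function(takes) function(G) list(G * k), a)
}

ad_sum_list <- function(lst) {
  vals <- lapply(lst, nval)
  val <- Reduce(`+`, vals)
  tp <- do.call(node_tape, lst)
  if (is.null(tp)) return(val)
  takes <- vapply(lst, is_node, logical(1))
  parents <- vapply(Filter(is_node, lst), function(x) x$id, integer(1))
  new_node(tp, val, parents = parents,
           back = function(G) rep(list(G), sum(takes)))
}

ad_sum <- function(a) {
  va <- nval(a)
  val <- matrix(sum(va), 1L, 1L)
  ad_emit(val, function(takes) {
    function(G) list(matrix(G[1], nrow(va), ncol(va)))
  }, a)
}

# mean squared error against a constant target
ad_mse <- function(pred, target) {
  d <- ad_sub(pred, target)
  ad_scale(ad_sum(ad_mul(d, d)), 1 / length(nval(pred)))
}

# softmax across a list of equal-shaped (1 x B) logit nodes; max-shifted for
# numerical stability (the shift is treated as a constant)
ad_softmax_list <- function(logits) {
  vals <- lapply(logits, nval)
  m <- Reduce(pmax, vals)
  exps <- lapply(logits, function(l) ad_exp(ad_sub(l, m)))
  total <- ad_sum_list(exps)
  lapply(exps, function(e) ad_div(e, total))
}

# Reverse sweep from `loss` (any node); returns gradients indexed by node id.
ad_backward <- function(loss) {
  stopifnot(is_node(loss))
  tp <- loss$tp
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- matrix(1, nrow(loss$val), ncol(loss$val))
  for (id in loss$id:1L) {
    G <- grads[[id]]
    if (is.null(G)) next
    node <- tp$nodes[[id]]
    if (!length(node$parents)) next
    pg <- node$back(G)
    for (j in seq_along(node$parents)) {
      pid <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  grads
}

# Gradients of `loss_fn(params)` w.r.t. every matrix in the named list
# `params`. `loss_fn` receives a named list of nodes and must return a node.
ad_grad <- function(params, loss_fn) {
  tp <- tape_new()
  pnodes <- lapply(params, function(p) ad_param(tp, p))
  loss <- loss_fn(pnodes)
  grads <- ad_backward(loss)
  out <- lapply(names(params), function(nm) {
    g <- grads[[pnodes[[nm]]$id]]
    if (is.null(g)) matrix(0, nrow(params[[nm]]), ncol(params[[nm]])) else g
  })
  names(out) <- names(params)
  list(loss = loss$val[1], grads = out)
}
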