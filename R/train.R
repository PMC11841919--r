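# Shared training machinery for the TSA-LSTM and every baseline handle:
# minibatch MSE training with Adam (or plain SGD), inverted dropout, and
# early stopping on validation loss.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

adam_new <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_update <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

# numeric forward over a sample index set, in chunks; returns standardized
# predictions
forward_predict <- function(handle, params, ds_std, idx, chunk = 512L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    batch <- ds_take(ds_std, sel)
    pred <- handle$forward(params, batch, rate = 0)$pred
    out[start:(start + length(sel) - 1L)] <- as.vector(nval(pred))
  }
  out
}

eval_loss <- function(handle, params, ds_std, idx) {
  if (!length(idx)) return(NA_real_)
  pred <- forward_predict(handle, params, ds_std, idx)
  mean((pred - ds_std$labels[idx])^2)
}

#' Train a recurrent forecasting model
#'
#' Shared training protocol for the TSA-LSTM and all baseline handles:
#' inputs and targets are standardized on the training split only, training
#' minimizes mean squared error by minibatch Adam (or plain SGD), dropout is
#' applied to recurrent hidden states, and training stops early when the
#' validation loss has not improved for \code{patience} epochs. The model
#' with the best validation loss is returned. Fully reproducible given the
#' config seed.
#'
#' @param handle A model handle from \code{\link{build_tsa}} or
#'   \code{\link{build_baseline}}.
#' @param dataset A \code{\link{make_windows}} dataset.
#' @param split A \code{\link{split_windows}} result; default: last 36
#'   labels test, preceding 36 validation, remainder training.
#' @return A \code{trained_model}: the handle plus fitted \code{params},
#'   per-epoch \code{history} (train/validation loss), the \code{scaler},
#'   the \code{split}, and \code{best_epoch}.
#' @export
train_model <- function(handle, dataset, split = NULL) {
  stopifnot(inherits(handle, "rnn_handle"), inherits(dataset, "windowed_dataset"))
  cfg <- handle$config
  if (is.null(split)) split <- split_windows(dataset)
  if (!length(split$train)) stop("empty training split", call. = FALSE)
  monitor <- if (length(split$val)) split$val else split$train

  with_seed(cfg$seed, {
    params <- handle$init()
    opt <- if (cfg$optimizer == "adam") adam_new(params) else NULL
    scaler <- ds_scaler(dataset, split$train)
    ds_std <- ds_standardize(dataset, scaler)

    best <- list(loss = Inf, params = params, epoch = 0L)
    hist_train <- numeric(0); hist_val <- numeric(0)
    n_train <- length(split$train)
    for (epoch in seq_len(cfg$max_epochs)) {
      order_ <- split$train[sample.int(n_train)]
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n_train, by = cfg$batch_size)) {
        sel <- order_[start:min(start + cfg$batch_size - 1L, n_train)]
        batch <- ds_take(ds_std, sel)
        target <- matrix(ds_std$labels[sel], nrow = 1L)
        res <- ad_grad(params, function(pn) {
          ad_mse(handle$forward(pn, batch, rate = cfg$dropout)$pred, target)
        })
        if (!is.finite(res$loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d (model %s); try a lower learning rate",
            epoch, handle$name
          ), call. = FALSE)
        }
        if (cfg$optimizer == "adam") {
          upd <- adam_update(params, res$grads, opt, cfg$lr)
          params <- upd$params; opt <- upd$state
        } else {
          params <- sgd_update(params, res$grads, cfg$lr)
        }
        epoch_loss <- epoch_loss + res$loss
        nb <- nb + 1L
      }
      hist_train[epoch] <- epoch_loss / nb
      vloss <- eval_loss(handle, params, ds_std, monitor)
      hist_val[epoch] <- vloss
      if (vloss < best$loss) {
        best <- list(loss = vloss, params = params, epoch = epoch)
      }
      if (epoch - best$epoch >= cfg$patience) break
    }

    out <- handle
    out$params <- best$params
    out$history <- data.frame(
      epoch = seq_along(hist_train),
      train_loss = hist_train,
      val_loss = hist_val
    )
    out$best_epoch <- best$epoch
    out$scaler <- scaler
    out$split <- split
    class(out) <- c("trained_model", "rnn_handle")
    out
  })
}

#' Predict from a trained model
#'
#' @param object A \code{trained_model}.
#' @param dataset A \code{\link{make_windows}} dataset built with the same
#'   window length and driver count the model was trained on.
#' @param samples Integer indices of the samples to predict (default: all).
#' @param ... Unused.
#' @return Numeric predictions on the original (unstandardized) scale.
#' @export
predict.trained_model <- function(object, dataset, samples = NULL, ...) {
  if (is.null(samples)) samples <- seq_len(dataset$n_samples)
  ds_std <- ds_standardize(dataset, object$scaler)
  pred <- forward_predict(object, object$params, ds_std, samples)
  pred * object$scaler$sd_y + object$scaler$mu_y
}

#' Attention traces of a trained TSA-LSTM
#'
#' @param model A trained TSA-LSTM model.
#' @param dataset The windowed dataset to trace.
#' @param samples Sample indices (default: all).
#' @return List with \code{alphas} (n x tau x S input-attention weights)
#'   and \code{betas} (tau x (tau - 1) x S temporal-attention weights).
#' @export
attention_trace <- function(model, dataset, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(dataset$n_samples)
  ds_std <- ds_standardize(dataset, model$scaler)
  batch <- ds_take(ds_std, samples)
  out <- model$forward(model$params, batch, rate = 0, trace = TRUE)
  list(alphas = out$alphas, betas = out$betas)
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradients of the minibatch MSE with central finite
#' differences for every parameter entry. Intended for small models
#' (hidden sizes <= 8).
#'
#' @param handle A model handle; parameters are initialized if absent.
#' @param batch A batch as produced by \code{ds_take} (or a single sample
#'   via its windows/past fields) together with \code{labels}.
#' @param eps Finite-difference step.
#' @return Maximum relative deviation over all parameter entries, where the
#'   relative deviation is \eqn{|g_a - g_n| / \max(|g_a| + |g_n|, f)} with a
#'   floor \eqn{f} of \eqn{10^{-4}} times the largest analytic gradient
#'   magnitude (near-zero entries are otherwise dominated by
#'   finite-difference round-off).
#' @export
gradient_check <- function(handle, batch, eps = 1e-5) {
  params <- if (is.null(handle$params)) handle$init() else handle$params
  target <- matrix(batch$labels, nrow = 1L)
  loss_fn <- function(pn) ad_mse(handle$forward(pn, batch, rate = 0)$pred, target)
  analytic <- ad_grad(params, loss_fn)$grads
  num_loss <- function(p) nval(loss_fn(p))[1, 1]
  gmax <- max(vapply(analytic, function(g) max(abs(g)), numeric(1)), 1e-8)
  floor_ <- 1e-4 * gmax
  worst <- 0
  for (nm in names(params)) {
    P <- params[[nm]]
    for (k in seq_along(P)) {
      pp <- params; pp[[nm]][k] <- P[k] + eps
      lp <- num_loss(pp)
      pp[[nm]][k] <- P[k] - eps
      lm <- num_loss(pp)
      gn <- (lp - lm) / (2 * eps)
      ga <- analytic[[nm]][k]
      dev <- abs(ga - gn) / max(abs(ga) + abs(gn), floor_)
      if (dev > worst) worst <- dev
    }
  }
  worst
}
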