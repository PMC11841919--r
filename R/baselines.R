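# The nine recurrent comparison architectures under the same train/predict
# contract as the TSA-LSTM: plain and bidirectional GRU/LSTM readers of the
# joint (drivers, lagged target) sequence, sequence-to-sequence
# encoder-decoder variants (encoder reads drivers, decoder reads past
# targets), and a seq2seq LSTM with stage-one input attention.

#' Names of the baseline architectures
#'
#' @return Character vector of the nine supported baseline names.
#' @export
baseline_names <- function() {
  c("GRU", "BiGRU", "Seq2SeqGRU", "Seq2SeqBiGRU",
    "LSTM", "BiLSTM", "Seq2SeqLSTM", "Seq2SeqBiLSTM",
    "Seq2SeqLSTM+InputAttention")
}

# lagged-target input row for plain models: zero at t = 1 (no earlier target
# inside the window), past targets afterwards
ylag_row <- function(past, t, B) {
  if (t == 1L) matrix(0, 1L, B) else matrix(past[t - 1L, ], nrow = 1L)
}

run_lstm_chain <- function(inputs, u, W, U, b, mask = NULL) {
  B <- ncol(nval(inputs[[1]]))
  h <- matrix(0, u, B); cc <- matrix(0, u, B)
  for (x in inputs) {
    st <- lstm_step_op(x, h, cc, W, U, b)
    h <- mask_mul(st$h, mask); cc <- st$c
  }
  list(h = h, c = cc)
}

run_gru_chain <- function(inputs, u, W, U, b, mask = NULL) {
  B <- ncol(nval(inputs[[1]]))
  h <- matrix(0, u, B)
  for (x in inputs) h <- mask_mul(gru_step_op(x, h, W, U, b), mask)
  h
}

forward_plain <- function(params, batch, cfg, cell, bidir, rate = 0) {
  n <- cfg$n; tau <- cfg$tau; u <- cfg$s
  B <- dim(batch$windows)[3]
  inputs <- lapply(seq_len(tau), function(t) {
    rbind(step_matrix(batch$windows, t, n), ylag_row(batch$past, t, B))
  })
  mask <- drop_mask(u, B, rate)
  state <- if (cell == "lstm") {
    run_lstm_chain(inputs, u, params$f_W, params$f_U, params$f_b, mask)$h
  } else {
    run_gru_chain(inputs, u, params$f_W, params$f_U, params$f_b, mask)
  }
  if (bidir) {
    mask_b <- drop_mask(u, B, rate)
    rev_in <- rev(inputs)
    back <- if (cell == "lstm") {
      run_lstm_chain(rev_in, u, params$b_W, params$b_U, params$b_b, mask_b)$h
    } else {
      run_gru_chain(rev_in, u, params$b_W, params$b_U, params$b_b, mask_b)
    }
    state <- ad_rbind(state, back)
  }
  list(pred = ad_add(ad_matmul(params$out_W, state), params$out_b))
}

forward_seq2seq <- function(params, batch, cfg, cell, bidir, inattn, rate = 0) {
  n <- cfg$n; tau <- cfg$tau; u <- cfg$s
  B <- dim(batch$windows)[3]
  mask <- drop_mask(u, B, rate)

  if (inattn) {
    # stage-one attention on the encoder inputs (LSTM encoder only)
    win_list <- lapply(seq_len(n), function(a) win_matrix(batch$windows, a, tau))
    h <- matrix(0, u, B); cc <- matrix(0, u, B)
    for (t in seq_len(tau)) {
      al <- input_attention_op(win_list, h, cc, params$ve, params$We, params$Ue)
      amat <- Reduce(ad_rbind, al)
      xhat <- ad_mul(step_matrix(batch$windows, t, n), amat)
      st <- lstm_step_op(xhat, h, cc, params$f_W, params$f_U, params$f_b)
      h <- mask_mul(st$h, mask); cc <- st$c
    }
    enc_h <- h; enc_c <- cc
  } else {
    inputs <- lapply(seq_len(tau), function(t) step_matrix(batch$windows, t, n))
    if (cell == "lstm") {
      st <- run_lstm_chain(inputs, u, params$f_W, params$f_U, params$f_b, mask)
      enc_h <- st$h; enc_c <- st$c
    } else {
      enc_h <- run_gru_chain(inputs, u, params$f_W, params$f_U, params$f_b, mask)
      enc_c <- NULL
    }
    if (bidir) {
      mask_b <- drop_mask(u, B, rate)
      if (cell == "lstm") {
        st <- run_lstm_chain(rev(inputs), u, params$b_W, params$b_U, params$b_b, mask_b)
        enc_h <- ad_rbind(enc_h, st$h); enc_c <- ad_rbind(enc_c, st$c)
      } else {
        hb <- run_gru_chain(rev(inputs), u, params$b_W, params$b_U, params$b_b, mask_b)
        enc_h <- ad_rbind(enc_h, hb)
      }
    }
  }

  ud <- if (bidir) 2L * u else u  # decoder matches the encoder output width
  mask_d <- drop_mask(ud, B, rate)
  d <- enc_h
  cd <- if (cell == "lstm") enc_c else NULL
  if (tau > 1L) {
    for (t in seq_len(tau - 1L)) {
      yin <- matrix(batch$past[t, ], nrow = 1L)
      if (cell == "lstm") {
        st <- lstm_step_op(yin, d, cd, params$d_W, params$d_U, params$d_b)
        d <- mask_mul(st$h, mask_d); cd <- st$c
      } else {
        d <- mask_mul(gru_step_op(yin, d, params$d_W, params$d_U, params$d_b), mask_d)
      }
    }
  }
  list(pred = ad_add(ad_matmul(params$out_W, d), params$out_b))
}

init_baseline_params <- function(name, cfg) {
  n <- cfg$n; tau <- cfg$tau; u <- cfg$s
  din <- n + 1L
  switch(name,
    "GRU" = c(gru_params(din, u, "f"),
              list(out_W = init_mat(1L, u), out_b = matrix(0, 1L, 1L))),
    "BiGRU" = c(gru_params(din, u, "f"), gru_params(din, u, "b"),
                list(out_W = init_mat(1L, 2L * u), out_b = matrix(0, 1L, 1L))),
    "LSTM" = c(lstm_params(din, u, "f"),
               list(out_W = init_mat(1L, u), out_b = matrix(0, 1L, 1L))),
    "BiLSTM" = c(lstm_params(din, u, "f"), lstm_params(din, u, "b"),
                 list(out_W = init_mat(1L, 2L * u), out_b = matrix(0, 1L, 1L))),
    "Seq2SeqGRU" = c(gru_params(n, u, "f"), gru_params(1L, u, "d"),
                     list(out_W = init_mat(1L, u), out_b = matrix(0, 1L, 1L))),
    "Seq2SeqBiGRU" = c(gru_params(n, u, "f"), gru_params(n, u, "b"),
                       gru_params(1L, 2L * u, "d"),
                       list(out_W = init_mat(1L, 2L * u), out_b = matrix(0, 1L, 1L))),
    "Seq2SeqLSTM" = c(lstm_params(n, u, "f"), lstm_params(1L, u, "d"),
                      list(out_W = init_mat(1L, u), out_b = matrix(0, 1L, 1L))),
    "Seq2SeqBiLSTM" = c(lstm_params(n, u, "f"), lstm_params(n, u, "b"),
                        lstm_params(1L, 2L * u, "d"),
                        list(out_W = init_mat(1L, 2L * u), out_b = matrix(0, 1L, 1L))),
    "Seq2SeqLSTM+InputAttention" = c(
      lstm_params(n, u, "f"),
      list(ve = init_mat(tau, 1L, tau), We = init_mat(tau, 2L * u, 2L * u),
           Ue = init_mat(tau, tau, tau)),
      lstm_params(1L, u, "d"),
      list(out_W = init_mat(1L, u), out_b = matrix(0, 1L, 1L))
    ),
    stop("unknown baseline architecture: ", name, call. = FALSE)
  )
}

#' Build a baseline recurrent model handle
#'
#' Constructs one of the nine comparison architectures under the same
#' train/predict contract as the TSA-LSTM. Plain (optionally bidirectional)
#' GRU/LSTM models read the drivers and the lagged target jointly;
#' sequence-to-sequence variants encode the driver windows and decode the
#' past target sequence; the \code{"Seq2SeqLSTM+InputAttention"} variant
#' adds stage-one input attention to the encoder.
#'
#' @param name One of \code{\link{baseline_names}()}.
#' @param config A \code{\link{tsa_config}}; \code{s} is used as the hidden
#'   size (\code{units}) of every layer.
#' @return An \code{rnn_handle} for \code{\link{train_model}}.
#' @export
build_baseline <- function(name, config) {
  if (!name %in% baseline_names()) {
    stop("unknown baseline architecture: ", name, call. = FALSE)
  }
  stopifnot(inherits(config, "tsa_config"))
  cell <- if (grepl("GRU", name)) "gru" else "lstm"
  bidir <- grepl("Bi", name)
  seq2seq <- grepl("Seq2Seq", name)
  inattn <- grepl("InputAttention", name)
  forward <- if (seq2seq) {
    function(params, batch, rate = 0, trace = FALSE) {
      forward_seq2seq(params, batch, config, cell, bidir, inattn, rate)
    }
  } else {
    function(params, batch, rate = 0, trace = FALSE) {
      forward_plain(params, batch, config, cell, bidir, rate)
    }
  }
  structure(
    list(
      name = name,
      config = config,
      init = function() init_baseline_params(name, config),
      forward = forward,
      params = NULL
    ),
    class = "rnn_handle"
  )
}

build_model <- function(name, config) {
  if (name == "TSA-LSTM") build_tsa(config) else build_baseline(name, config)
}

#' Repeated-run benchmark of forecasting models
#'
#' Trains every requested architecture \code{repeats} times (per-repeat seed
#' = master seed + repeat index), evaluates each run on the test split, and
#' ranks the models by mean accuracy (ties broken by lower mean error
#' percentage, then by name). Runs whose training diverges (non-finite
#' loss) are recorded as failures and excluded from the means.
#'
#' @param models Character vector of model names (\code{baseline_names()}
#'   and/or \code{"TSA-LSTM"}), or \code{"all"} for the nine baselines plus
#'   the TSA-LSTM.
#' @param dataset A \code{\link{make_windows}} dataset.
#' @param config A \code{\link{tsa_config}} shared by all models (its seed
#'   field is overridden per repeat).
#' @param split Optional \code{\link{split_windows}} result.
#' @param repeats Training repetitions per model (default 10).
#' @param seed Master seed.
#' @return An object of class \code{benchmark_result}: \code{table} (one
#'   row per model: mean accuracy, mean error percentage, mean training
#'   seconds, failures, rank) and \code{metrics} (per model, the list of
#'   per-repeat \code{metric_set}s).
#' @export
run_benchmark <- function(models, dataset, config, split = NULL,
                          repeats = 10L, seed = 1L) {
  if (identical(models, "all")) models <- c(baseline_names(), "TSA-LSTM")
  stopifnot(length(models) >= 1L, inherits(dataset, "windowed_dataset"))
  if (is.null(split)) split <- split_windows(dataset)
  repeats <- as.integer(repeats)
  metrics <- stats::setNames(vector("list", length(models)), models)
  tab <- data.frame(
    model = models, mean_accuracy = NA_real_, mean_error_pct = NA_real_,
    mean_seconds = NA_real_, failures = 0L, stringsAsFactors = FALSE
  )
  y_train <- dataset$labels[split$train]
  y_test <- dataset$labels[split$test]
  for (mi in seq_along(models)) {
    runs <- list()
    secs <- numeric(0)
    fails <- 0L
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- as.integer(seed + r)
      handle <- build_model(models[mi], cfg)
      t0 <- proc.time()[["elapsed"]]
      fit <- tryCatch(train_model(handle, dataset, split), error = function(e) e)
      dt <- proc.time()[["elapsed"]] - t0
      if (inherits(fit, "error")) {
        fails <- fails + 1L
        next
      }
      pred <- predict(fit, dataset, samples = split$test)
      runs[[length(runs) + 1L]] <-
        compute_metrics(y_test, pred, training = y_train)
      secs <- c(secs, dt)
    }
    metrics[[mi]] <- runs
    tab$failures[mi] <- fails
    if (length(runs)) {
      tab$mean_accuracy[mi] <- mean(vapply(runs, `[[`, numeric(1), "accuracy"))
      tab$mean_error_pct[mi] <- mean(vapply(runs, `[[`, numeric(1), "error_pct"))
      tab$mean_seconds[mi] <- mean(secs)
    }
  }
  ord <- order(-tab$mean_accuracy, tab$mean_error_pct, tab$model,
               na.last = TRUE)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  structure(
    list(table = tab[order(tab$rank), ], metrics = metrics,
         repeats = repeats, seed = seed),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d repeats, master seed %d\n",
              x$repeats, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}
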