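#' Optimizer and training configuration
#'
#' Adam hyperparameters and training-loop settings for gradient
#' prediction models. The loss is mean absolute error on the normalized
#' gradient samples. Mini-batches are groups of whole waveform
#' sequences; `batch_size` counts sequences per batch.
#'
#' @param learning_rate peak Adam step size.
#' @param batch_size sequences per mini-batch.
#' @param weight_decay L2 penalty added to gradients.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs training epochs.
#' @param schedule learning-rate schedule: `"cosine"` decays from
#'   `learning_rate` to `min_lr` over the run (suits short
#'   sequence-batched training), `"constant"` holds it fixed.
#' @param min_lr floor of the cosine schedule.
#' @param ema decay of the exponential moving average of the weights
#'   (Polyak averaging); the averaged weights are returned as the
#'   trained model, damping the dither of sign-based gradient steps.
#'   `0` disables averaging.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 4e-3, batch_size = 2,
                            weight_decay = 9e-8, beta1 = 0.9,
                            beta2 = 1 - 1e-6, epochs = 30,
                            schedule = c("cosine", "constant"),
                            min_lr = 5e-5, ema = 0.995, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            ema >= 0, ema < 1)
  schedule <- match.arg(schedule)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), schedule = schedule,
                 min_lr = min_lr, ema = ema, seed = as.integer(seed)),
            class = "training_config")
}

.tree_axpy <- function(a, x, b, y) {
  # a*x + b*y over matching parameter trees
  if (is.list(x)) {
    for (nm in seq_along(x)) x[[nm]] <- .tree_axpy(a, x[[nm]], b, y[[nm]])
    return(x)
  }
  a * x + b * y
}

#' Build a windowed training dataset from nominal/measured pairs
#'
#' Normalizes each pair by its nominal amplitude: channel 1 is the
#' nominal waveform scaled to \[-1, 1\], channel 2 the constant
#' `abs(amp_scale) / a_sys` (the gradient chain is odd-symmetric, so
#' the scale's sign cancels under the signed normalization), and the
#' target the measured waveform under the
#' same normalization. Conceptually the dataset holds one sliding causal
#' window of length `window` per time point per waveform (stride 1, left
#' zero-padding, windows never crossing waveform boundaries); windows
#' are materialized on demand by [get_window()] while training operates
#' on the equivalent full sequences.
#'
#' @param pairs list of `list(nominal=, measured=)` waveform pairs (as
#'   from a simulated library), sharing axis and raster.
#' @param window window length `T` in samples.
#' @param a_sys reference amplitude (mT/m) for channel 2.
#' @return a `window_dataset`.
#' @export
build_windows <- function(pairs, window = 48L, a_sys = 770) {
  if (!length(pairs)) stop("empty pair list")
  axis <- pairs[[1]]$nominal$axis
  dt <- pairs[[1]]$nominal$dt
  seqs <- lapply(pairs, function(p) {
    w <- p$nominal
    if (w$axis != axis || w$dt != dt)
      stop("all pairs must share axis and raster time")
    a <- w$amp_scale
    an <- if (a == 0) 1 else a
    list(x = rbind(w$samples / an,
                   rep(abs(a) / a_sys, length(w$samples))),
         y = p$measured$samples / an, amp = a, n = length(w$samples))
  })
  structure(list(sequences = seqs, window = as.integer(window),
                 a_sys = a_sys, axis = axis, dt = dt,
                 n_windows = sum(vapply(seqs, `[[`, 0, "n"))),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> axis=%s %d waveforms, %d windows (T=%d)\n",
              x$axis, length(x$sequences), x$n_windows, x$window))
  invisible(x)
}

#' Materialize one training window
#'
#' @param ds a `window_dataset`.
#' @param seq_i waveform index.
#' @param t time index within the waveform (the window's final sample).
#' @param window window length override.
#' @return `list(window = T x 2 matrix, target = scalar)`.
#' @export
get_window <- function(ds, seq_i, t, window = ds$window) {
  s <- ds$sequences[[seq_i]]
  lo <- t - window + 1L
  idx <- lo:t
  ok <- idx >= 1L
  w <- matrix(0, window, 2L)
  w[ok, ] <- t(s$x[, idx[ok], drop = FALSE])
  list(window = w, target = s$y[t])
}

# ---- Adam on the nested parameter tree ---------------------------------

# parameter and gradient trees share leaf names, so a single recursive
# walk updates any architecture

.adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"), t = 0L)
}

.tree_adam <- function(p, g, m, v, lr_t, b1, b2, eps, wd) {
  if (is.list(p)) {
    for (nm in if (is.null(names(p))) seq_along(p) else names(p)) {
      r <- .tree_adam(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr_t, b1, b2,
                      eps, wd)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  gr <- g + wd * p
  m <- b1 * m + (1 - b1) * gr
  v <- b2 * v + (1 - b2) * gr^2
  list(p = p - lr_t * m / (sqrt(v) + eps), m = m, v = v)
}

.adam_step <- function(params, grads, st, tcfg, eps = 1e-8) {
  st$t <- st$t + 1L
  lr_t <- tcfg$learning_rate *
    sqrt(1 - tcfg$beta2^st$t) / (1 - tcfg$beta1^st$t)
  r <- .tree_adam(params, grads, st$m, st$v, lr_t, tcfg$beta1,
                  tcfg$beta2, eps, tcfg$weight_decay)
  st$m <- r$m; st$v <- r$v
  list(params = r$p, st = st)
}

# concatenate a list of sequences along time with `gap` zero columns
# between them (and in front), returning input, target, and index sets
.assemble_batch <- function(seqs, gap) {
  lens <- vapply(seqs, `[[`, 0, "n")
  total <- sum(lens) + gap * length(seqs)
  X <- matrix(0, 2, total)
  y <- numeric(total)
  valid <- logical(total)
  pos <- 0L
  for (s in seqs) {
    pos <- pos + gap
    idx <- pos + seq_len(s$n)
    X[, idx] <- s$x
    y[idx] <- s$y
    valid[idx] <- TRUE
    pos <- pos + s$n
  }
  list(X = X, y = y, valid = valid, gap_idx = which(!valid))
}

#' Train a gradient prediction model
#'
#' Adam optimization of the mean-absolute-error loss over shuffled
#' mini-batches of waveform sequences for `tcfg$epochs` epochs.
#' Reproducible given `tcfg$seed` (which drives shuffling and dropout).
#' Training fails with an error naming the epoch if the loss becomes
#' non-finite.
#'
#' @param model an untrained (or previously trained) `tcn_model` or
#'   `lstm_model`.
#' @param dataset a [build_windows()] dataset.
#' @param tcfg a [training_config()].
#' @param verbose print per-epoch loss?
#' @return the trained model, with `loss_trace` (one mean training loss
#'   per epoch) and `axis` filled in.
#' @export
train_model <- function(model, dataset, tcfg = training_config(),
                        verbose = FALSE) {
  if (!inherits(dataset, "window_dataset")) stop("need a window_dataset")
  if (!length(dataset$sequences)) stop("empty dataset")
  seqs <- dataset$sequences
  is_tcn <- inherits(model, "tcn_model")
  gap <- if (is_tcn)
    (model$config$kernel_size - 1L) * 2L^(model$config$n_blocks - 1L)
  else 0L
  params <- model$params
  st <- .adam_init(params)
  ema_p <- if (tcfg$ema > 0) params else NULL
  trace <- numeric(tcfg$epochs)
  base_lr <- tcfg$learning_rate
  .with_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      if (tcfg$schedule == "cosine")
        tcfg$learning_rate <- tcfg$min_lr + (base_lr - tcfg$min_lr) *
          0.5 * (1 + cos(pi * (ep - 1) / max(1, tcfg$epochs - 1)))
      ord <- sample.int(length(seqs))
      tot_loss <- 0; tot_n <- 0
      for (b in seq(1, length(ord), by = tcfg$batch_size)) {
        take <- ord[b:min(b + tcfg$batch_size - 1L, length(ord))]
        if (is_tcn) {
          ba <- .assemble_batch(seqs[take], gap)
          mtmp <- model; mtmp$params <- params
          fw <- .tcn_fwd(mtmp, ba$X, gap_idx = ba$gap_idx, train = TRUE)
          r <- fw$yhat[1, ] - ba$y
          nval <- sum(ba$valid)
          loss <- sum(abs(r[ba$valid])) / nval
          dy <- matrix(0, 1, length(r))
          dy[1, ba$valid] <- sign(r[ba$valid]) / nval
          grads <- .tcn_bwd(mtmp, fw, dy, gap_idx = ba$gap_idx)
        } else {
          mtmp <- model; mtmp$params <- params
          fb <- .lstm_fwd_bwd(mtmp, seqs[take])
          loss <- fb$loss; grads <- fb$grads; nval <- fb$n
        }
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       ep))
        u <- .adam_step(params, grads, st, tcfg)
        params <- u$params; st <- u$st
        if (!is.null(ema_p))
          ema_p <- .tree_axpy(tcfg$ema, ema_p, 1 - tcfg$ema, params)
        tot_loss <- tot_loss + loss * nval; tot_n <- tot_n + nval
      }
      trace[ep] <- tot_loss / tot_n
      if (verbose)
        message(sprintf("epoch %3d  mae %.3e", ep, trace[ep]))
    }
  })
  model$params <- if (!is.null(ema_p)) ema_p else params
  model$loss_trace <- trace
  model$axis <- dataset$axis
  model$a_sys <- dataset$a_sys
  model
}

#' Predict the played-out waveform for a nominal input
#'
#' Full-sequence causal application of a trained model: the input is
#' normalized exactly as in training (channel 1 by the waveform's
#' signed `amp_scale`, channel 2 the constant `abs(amp_scale) / a_sys`),
#' the network
#' produces one sample per time point, and the output is denormalized by
#' `amp_scale`. Identical to per-window sliding inference whenever the
#' sliding window covers the model's receptive field.
#'
#' @param model a trained `grad_model`.
#' @param nominal a `gradient_waveform` on the model's axis.
#' @param a_sys reference amplitude; defaults to the value used in
#'   training.
#' @return a `gradient_waveform` of predicted played-out samples.
#' @export
predict_waveform <- function(model, nominal, a_sys = NULL) {
  if (is.null(a_sys))
    a_sys <- if (!is.null(model$a_sys)) model$a_sys else model$config$a_sys
  if (!is.na(model$axis) && model$axis != nominal$axis)
    stop(sprintf("model was trained for axis '%s', waveform is '%s'",
                 model$axis, nominal$axis))
  a <- nominal$amp_scale
  an <- if (a == 0) 1 else a
  X <- rbind(nominal$samples / an,
             rep(abs(a) / a_sys, length(nominal$samples)))
  yh <- if (inherits(model, "tcn_model")) .tcn_apply(model, X)
        else .lstm_apply(model, X)
  gradient_waveform(yh * an, nominal$dt, axis = nominal$axis,
                    amp_scale = NULL, label = nominal$label)
}

#' Sliding-window inference (reference path)
#'
#' Applies the model to one causal window per time point and keeps the
#' final output of each window — the window-by-window definition of
#' inference. Windows near the waveform start contain only the
#' available past samples; the zeros before the waveform are supplied
#' by the network's causal padding, exactly as in full-sequence
#' application (an explicit zero column is not equivalent, because the
#' convolution biases make deep-layer activations non-zero there).
#' Equal to [predict_waveform()] whenever
#' `window >= receptive_field(model)`; used as the reference in
#' equivalence checks.
#'
#' @inheritParams predict_waveform
#' @param window window length in samples.
#' @return a `gradient_waveform`.
#' @export
predict_waveform_windowed <- function(model, nominal, window = NULL,
                                      a_sys = NULL) {
  if (is.null(a_sys))
    a_sys <- if (!is.null(model$a_sys)) model$a_sys else model$config$a_sys
  if (is.null(window)) window <- receptive_field(model)
  a <- nominal$amp_scale
  an <- if (a == 0) 1 else a
  n <- length(nominal$samples)
  x1 <- nominal$samples / an
  x2 <- rep(abs(a) / a_sys, n)
  out <- numeric(n)
  for (t in seq_len(n)) {
    idx <- max(1L, t - window + 1L):t
    Xw <- rbind(x1[idx], x2[idx])
    yh <- if (inherits(model, "tcn_model")) .tcn_apply(model, Xw)
          else .lstm_apply(model, Xw)
    out[t] <- yh[length(idx)]
  }
  gradient_waveform(out * an, nominal$dt, axis = nominal$axis,
                    amp_scale = NULL, label = nominal$label)
}
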