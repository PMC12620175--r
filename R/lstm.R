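#' Build an untrained LSTM gradient model
#'
#' Recurrent baseline consuming the same normalized `[T, 2]` inputs as
#' the TCN: stacked LSTM layers followed by a linear head mapping the
#' hidden state at each time point to one predicted gradient sample.
#'
#' @param n_layers number of stacked LSTM layers (>= 1).
#' @param hidden hidden-state size per layer.
#' @param seed weight-initialization seed.
#' @param in_channels input channels.
#' @param a_sys reference amplitude for channel-2 normalization.
#' @return an `lstm_model` (also `grad_model`).
#' @export
build_lstm <- function(n_layers = 2, hidden = 96, seed = 1L,
                       in_channels = 2L, a_sys = 770) {
  stopifnot(n_layers >= 1, hidden >= 1)
  H <- as.integer(hidden)
  params <- .with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      cin <- if (l == 1) in_channels else H
      s <- 1 / sqrt(H)
      list(W = matrix(stats::runif(4 * H * (cin + H), -s, s), 4 * H),
           b = stats::runif(4 * H, -s, s))
    })
    s <- 1 / sqrt(H)
    list(layers = layers,
         head = list(W = matrix(stats::runif(H, -s, s), 1),
                     b = stats::runif(1, -s, s)))
  })
  cfg <- list(n_layers = as.integer(n_layers), hidden = H,
              a_sys = a_sys, dropout = 0)
  structure(list(arch = "lstm", axis = NA_character_, config = cfg,
                 params = params, loss_trace = NULL, seed = seed),
            class = c("lstm_model", "grad_model"))
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> axis=%s layers=%d hidden=%d%s\n", x$axis,
              x$config$n_layers, x$config$hidden,
              if (is.null(x$loss_trace)) " (untrained)" else ""))
  invisible(x)
}

.sigm <- function(x) 1 / (1 + exp(-x))

# forward one sequence (2 x T); returns per-step caches when `keep`
.lstm_seq_fwd <- function(model, X, keep = FALSE) {
  p <- model$params
  H <- model$config$hidden
  L <- model$config$n_layers
  Tn <- ncol(X)
  h <- lapply(seq_len(L), function(l) numeric(H))
  cc <- lapply(seq_len(L), function(l) numeric(H))
  yhat <- numeric(Tn)
  cache <- if (keep) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xin <- X[, t]
    st <- if (keep) vector("list", L) else NULL
    for (l in seq_len(L)) {
      z <- p$layers[[l]]$W %*% c(xin, h[[l]]) + p$layers[[l]]$b
      i <- .sigm(z[1:H]); f <- .sigm(z[H + 1:H])
      g <- tanh(z[2 * H + 1:H]); o <- .sigm(z[3 * H + 1:H])
      c_new <- f * cc[[l]] + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      if (keep)
        st[[l]] <- list(xin = xin, h_prev = h[[l]], c_prev = cc[[l]],
                        i = i, f = f, g = g, o = o, tc = tc)
      cc[[l]] <- c_new
      h[[l]] <- h_new
      xin <- h_new
    }
    yhat[t] <- sum(p$head$W * h[[L]]) + p$head$b
    if (keep) cache[[t]] <- st
  }
  list(yhat = yhat, cache = cache)
}

# MAE loss + full BPTT gradients over a list of sequences
.lstm_fwd_bwd <- function(model, seqs) {
  p <- model$params
  H <- model$config$hidden
  L <- model$config$n_layers
  zero <- rapply(p, function(x) x * 0, how = "replace")
  grads <- zero
  tot <- 0; n <- sum(vapply(seqs, `[[`, 0, "n"))
  for (s in seqs) {
    fw <- .lstm_seq_fwd(model, s$x, keep = TRUE)
    r <- fw$yhat - s$y
    tot <- tot + sum(abs(r))
    dy <- sign(r) / n
    Tn <- s$n
    dh <- lapply(seq_len(L), function(l) numeric(H))
    dc <- lapply(seq_len(L), function(l) numeric(H))
    for (t in rev(seq_len(Tn))) {
      st <- fw$cache[[t]]
      grads$head$W <- grads$head$W + dy[t] * st[[L]]$o * st[[L]]$tc
      grads$head$b <- grads$head$b + dy[t]
      dh[[L]] <- dh[[L]] + dy[t] * p$head$W[1, ]
      dx_up <- NULL
      for (l in rev(seq_len(L))) {
        ca <- st[[l]]
        dhl <- dh[[l]]
        if (!is.null(dx_up)) dhl <- dhl + dx_up
        do <- dhl * ca$tc * ca$o * (1 - ca$o)
        dcl <- dc[[l]] + dhl * ca$o * (1 - ca$tc^2)
        di <- dcl * ca$g * ca$i * (1 - ca$i)
        df <- dcl * ca$c_prev * ca$f * (1 - ca$f)
        dg <- dcl * ca$i * (1 - ca$g^2)
        dz <- c(di, df, dg, do)
        inp <- c(ca$xin, ca$h_prev)
        grads$layers[[l]]$W <- grads$layers[[l]]$W + outer(dz, inp)
        grads$layers[[l]]$b <- grads$layers[[l]]$b + dz
        dinp <- crossprod(p$layers[[l]]$W, dz)[, 1]
        cin <- length(ca$xin)
        dx_up <- dinp[seq_len(cin)]
        dh[[l]] <- dinp[cin + seq_len(H)]
        dc[[l]] <- dcl * ca$f
      }
      dx_up <- NULL
    }
  }
  list(loss = tot / n, grads = grads, n = n)
}

.lstm_apply <- function(model, X) .lstm_seq_fwd(model, X)$yhat
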