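#' Temporal convolutional network configuration
#'
#' Architecture hyperparameters for the causal dilated-convolution
#' gradient predictor: `n_blocks` residual blocks, block `i` using
#' dilation `2^(i-1)`, each block holding two causal convolutions of
#' kernel size `kernel_size` (with weight normalization, GELU activation
#' and dropout after each) plus a kernel-1 bypass convolution. A final
#' linear layer maps the features at each time index to one predicted
#' gradient sample.
#'
#' @param n_blocks number of residual blocks (>= 1).
#' @param kernel_size causal convolution kernel size (samples, >= 2).
#' @param channels feature channels per convolution layer.
#' @param window training-window length `T` (samples) used when building
#'   windowed datasets.
#' @param dropout dropout probability in \[0, 1).
#' @param a_sys system reference amplitude (mT/m) used to normalize the
#'   amplitude input channel.
#' @param residual_output when `TRUE` (default) the network output is
#'   the nominal input channel plus the final linear layer's value, so
#'   the convolutional stack models the (small) gradient distortion
#'   rather than reproducing the full waveform. An untrained network is
#'   then already close to the identity map, which conditions short
#'   training runs; see the methods vignette.
#' @return a `tcn_config` list.
#' @export
tcn_config <- function(n_blocks = 5, kernel_size = 16, channels = 16,
                       window = 48, dropout = 0.2, a_sys = 770,
                       residual_output = TRUE) {
  stopifnot(n_blocks >= 1, kernel_size >= 2, window >= 1,
            dropout >= 0, dropout < 1, channels >= 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 kernel_size = as.integer(kernel_size),
                 channels = as.integer(channels),
                 window = as.integer(window), dropout = dropout,
                 a_sys = a_sys,
                 residual_output = isTRUE(residual_output)),
            class = "tcn_config")
}

#' Receptive field of a TCN
#'
#' Closed form `1 + 2 (k - 1) (2^n_blocks - 1)`: each of the two
#' convolutions in block `i` looks back `(k - 1) 2^(i-1)` samples.
#' @param x a `tcn_config` or `tcn_model`.
#' @return receptive field in samples.
#' @export
receptive_field <- function(x) {
  cfg <- if (inherits(x, "tcn_config")) x else x$config
  1L + 2L * (cfg$kernel_size - 1L) * (2L^cfg$n_blocks - 1L)
}

# uniform init like a standard 1D conv layer; weight-norm scale g set to
# the row norms so the effective initial weights equal V
.conv_init <- function(c_out, c_in, k) {
  s <- 1 / sqrt(c_in * k)
  V <- matrix(stats::runif(c_out * c_in * k, -s, s), c_out, c_in * k)
  list(V = V, g = sqrt(rowSums(V^2)), b = stats::runif(c_out, -s, s))
}

# identity init for a k=1 (bypass/head) conv: each output channel copies
# one input channel. Together with zero-scaled second convolutions this
# makes the untrained network exactly the identity map on channel 1
# (the nominal waveform), which conditions short training runs (see the
# methods vignette).
.conv_init_identity <- function(c_out, c_in) {
  V <- matrix(0, c_out, c_in)
  for (r in seq_len(c_out)) V[r, (r - 1) %% c_in + 1] <- 1
  list(V = V, g = rep(1, c_out), b = numeric(c_out))
}

# residual-branch output conv: standard random direction V but the
# weight-norm scale g shrunk, so each block starts close to (but not
# exactly at) its bypass and gradients still reach the first convolution
.conv_init_scaled <- function(c_out, c_in, k, scale = 0.5) {
  p <- .conv_init(c_out, c_in, k)
  p$g <- scale * p$g
  p$b <- numeric(c_out)
  p
}

#' Build an untrained TCN gradient model
#'
#' @param config a [tcn_config()].
#' @param seed integer seed for weight initialization.
#' @param in_channels input channels (2: normalized waveform and
#'   normalized amplitude).
#' @return a `tcn_model` (also `grad_model`).
#' @export
build_tcn <- function(config = tcn_config(), seed = 1L, in_channels = 2L) {
  C <- config$channels; k <- config$kernel_size
  params <- .with_seed(seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(i) {
      cin <- if (i == 1) in_channels else C
      list(conv1 = .conv_init(C, cin, k),
           conv2 = .conv_init(C, C, k),
           bypass = .conv_init(C, cin, 1))
    })
    head <- .conv_init(1L, C, 1)
    if (config$residual_output) {
      # zero head scale: the untrained model is exactly the identity
      # map on the nominal channel; the head's weight-norm direction is
      # random and its scale grows with training
      head$g <- 0 * head$g
      head$b <- 0 * head$b
    }
    list(blocks = blocks, head = head)
  })
  structure(list(arch = "tcn", axis = NA_character_, config = config,
                 params = params, loss_trace = NULL, seed = seed),
            class = c("tcn_model", "grad_model"))
}

#' @export
print.tcn_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(lapply(rapply(x$params, length, how = "list"), unlist)))
  cat(sprintf(
    "<tcn_model> axis=%s blocks=%d k=%d channels=%d RF=%d params=%d%s\n",
    x$axis, cfg$n_blocks, cfg$kernel_size, cfg$channels,
    receptive_field(x), np,
    if (is.null(x$loss_trace)) " (untrained)" else ""))
  invisible(x)
}

# ---- conv primitives on a C x T layout ---------------------------------
# heavy lifting (dilated causal convolution, GELU) is compiled; see
# src/tcn_ops.cpp. The weight-norm reparameterization W = g * V/||V||
# stays in R (cheap row operations).

.conv_fwd <- function(p, X, k, d) {
  nv <- sqrt(rowSums(p$V^2))
  W <- p$V * (p$g / nv)
  list(Y = tcn_conv_fwd(W, p$b, X, k, d), W = W, nv = nv, X = X)
}

.conv_bwd <- function(p, fw, dY, k, d, c_in) {
  r <- tcn_conv_bwd(fw$W, fw$X, dY, k, d)
  gn <- p$g / fw$nv
  dv_dot <- rowSums(r$dW * p$V)
  # gradient leaves share the parameter names so optimizers can walk the
  # two trees in lockstep
  list(V = r$dW * gn - p$V * (gn * dv_dot / fw$nv^2),
       g = dv_dot / fw$nv, b = as.numeric(r$db), dX = r$dX)
}

.gelu <- function(x) x * stats::pnorm(x)

# ---- full-sequence forward/backward ------------------------------------

# X: 2 x T input; gap_idx: columns that emulate per-layer zero padding
# between concatenated sequences (always zeroed after each layer output).
.tcn_fwd <- function(model, X, gap_idx = integer(0), train = FALSE) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  keep <- 1 - cfg$dropout
  x <- X
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    d <- 2L^(i - 1L)
    bl <- p$blocks[[i]]
    c1 <- .conv_fwd(bl$conv1, x, k, d)
    g1f <- tcn_gelu_fwd(c1$Y)
    phi1 <- g1f$Phi
    h1 <- g1f$H
    m1 <- NULL
    if (train && cfg$dropout > 0) {
      m1 <- (matrix(stats::runif(length(h1)), nrow(h1)) < keep) / keep
      h1 <- h1 * m1
    }
    if (length(gap_idx)) h1[, gap_idx] <- 0
    c2 <- .conv_fwd(bl$conv2, h1, k, d)
    g2f <- tcn_gelu_fwd(c2$Y)
    phi2 <- g2f$Phi
    h2 <- g2f$H
    m2 <- NULL
    if (train && cfg$dropout > 0) {
      m2 <- (matrix(stats::runif(length(h2)), nrow(h2)) < keep) / keep
      h2 <- h2 * m2
    }
    by <- .conv_fwd(bl$bypass, x, 1L, 1L)
    out <- h2 + by$Y
    if (length(gap_idx)) out[, gap_idx] <- 0
    caches[[i]] <- list(x = x, c1 = c1, phi1 = phi1, h1 = h1, m1 = m1,
                        c2 = c2, phi2 = phi2, m2 = m2, by = by)
    x <- out
  }
  hd <- .conv_fwd(p$head, x, 1L, 1L)
  yhat <- if (cfg$residual_output) hd$Y + X[1, , drop = FALSE] else hd$Y
  list(yhat = yhat, caches = caches, head = hd, feat = x)
}

.tcn_bwd <- function(model, fw, dyhat, gap_idx = integer(0)) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  C <- cfg$channels
  ghead <- .conv_bwd(p$head, fw$head, dyhat, 1L, 1L, C)
  dx <- ghead$dX
  gblocks <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    d <- 2L^(i - 1L)
    bl <- p$blocks[[i]]
    ca <- fw$caches[[i]]
    cin <- nrow(ca$x)
    if (length(gap_idx)) dx[, gap_idx] <- 0
    gby <- .conv_bwd(bl$bypass, ca$by, dx, 1L, 1L, cin)
    dh2 <- dx
    if (!is.null(ca$m2)) dh2 <- dh2 * ca$m2
    da2 <- tcn_gelu_bwd(ca$c2$Y, ca$phi2, dh2)
    g2 <- .conv_bwd(bl$conv2, ca$c2, da2, k, d, C)
    dh1 <- g2$dX
    if (length(gap_idx)) dh1[, gap_idx] <- 0
    if (!is.null(ca$m1)) dh1 <- dh1 * ca$m1
    da1 <- tcn_gelu_bwd(ca$c1$Y, ca$phi1, dh1)
    g1 <- .conv_bwd(bl$conv1, ca$c1, da1, k, d, cin)
    dx <- g1$dX + gby$dX
    gblocks[[i]] <- list(conv1 = g1[c("V", "g", "b")],
                         conv2 = g2[c("V", "g", "b")],
                         bypass = gby[c("V", "g", "b")])
  }
  list(blocks = gblocks, head = ghead[c("V", "g", "b")])
}

# single-sequence inference on a 2 x T matrix (dropout off)
.tcn_apply <- function(model, X) {
  .tcn_fwd(model, X, train = FALSE)$yhat[1, ]
}
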