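#' Estimate a gradient impulse response function (GIRF)
#'
#' Frequency-domain least-squares estimate of the linear transfer
#' function H(f) of the gradient chain from nominal/measured waveform
#' pairs:
#' \deqn{H(f) = \frac{\sum_n \overline{I_n(f)}\, O_n(f)}
#'                   {\sum_n |I_n(f)|^2 + \lambda \max_f \sum_n |I_n(f)|^2}}
#' where \eqn{I_n, O_n} are the discrete Fourier transforms of the n-th
#' nominal input and measured output, zero-padded to `fft_length`
#' (linear, not circular, convolution). All training pairs are pooled
#' into one estimate per axis. Since inputs and outputs are real, H is
#' conjugate-symmetric and the impulse response is real.
#'
#' @param pairs list of `list(nominal=, measured=)` `gradient_waveform`
#'   pairs sharing axis and raster time.
#' @param lambda relative Tikhonov regularization (dimensionless).
#' @param fft_length FFT length; defaults to the next power of two of at
#'   least twice the longest waveform. Must be at least twice the
#'   longest training waveform.
#' @return an object of class `girf_model` with the complex transfer
#'   function on the FFT frequency grid.
#' @export
estimate_girf <- function(pairs, lambda = 1e-9, fft_length = NULL) {
  if (!length(pairs)) stop("need at least one waveform pair")
  dt <- pairs[[1]]$nominal$dt
  axis <- pairs[[1]]$nominal$axis
  maxlen <- max(vapply(pairs, function(p)
    max(length(p$nominal$samples), length(p$measured$samples)), 0L))
  if (is.null(fft_length))
    fft_length <- 2L^ceiling(log2(2L * maxlen))
  fft_length <- as.integer(fft_length)
  if (fft_length < 2L * maxlen)
    stop("fft_length must be at least twice the longest waveform")
  num <- complex(fft_length)
  den <- numeric(fft_length)
  for (p in pairs) {
    if (p$nominal$dt != dt || p$nominal$axis != axis)
      stop("all pairs must share raster time and axis")
    if (length(p$nominal$samples) > length(p$measured$samples))
      stop("measured waveform shorter than nominal")
    In <- stats::fft(c(p$nominal$samples,
                       numeric(fft_length - length(p$nominal$samples))))
    On <- stats::fft(c(p$measured$samples,
                       numeric(fft_length - length(p$measured$samples))))
    num <- num + Conj(In) * On
    den <- den + Mod(In)^2
  }
  if (max(den) == 0) stop("zero-energy input set")
  H <- num / (den + lambda * max(den))
  freq <- (seq_len(fft_length) - 1) / (fft_length * dt)
  freq[freq >= 1 / (2 * dt)] <- freq[freq >= 1 / (2 * dt)] - 1 / dt
  structure(list(axis = axis, transfer_function = H, freq = freq,
                 fft_length = fft_length, lambda = lambda, dt = dt),
            class = "girf_model")
}

#' @export
print.girf_model <- function(x, ...) {
  cat(sprintf("<girf_model> axis=%s fft_length=%d lambda=%.1e dt=%.3g us\n",
              x$axis, x$fft_length, x$lambda, x$dt * 1e6))
  invisible(x)
}

#' Predict a played-out waveform with a GIRF
#'
#' Frequency-domain application: the nominal waveform is zero-padded to
#' the model's FFT length, multiplied by H(f), inverse-transformed, and
#' truncated to the input length. Linear in the input.
#'
#' @param girf a `girf_model`.
#' @param nominal a `gradient_waveform` with the model's raster time.
#' @return a `gradient_waveform` of predicted samples.
#' @export
predict_with_girf <- function(girf, nominal) {
  if (!isTRUE(all.equal(nominal$dt, girf$dt)))
    stop("waveform raster time does not match the GIRF")
  n <- length(nominal$samples)
  if (n > girf$fft_length)
    stop("waveform longer than the GIRF fft_length")
  X <- stats::fft(c(nominal$samples, numeric(girf$fft_length - n)))
  y <- Re(stats::fft(girf$transfer_function * X,
                     inverse = TRUE)) / girf$fft_length
  gradient_waveform(y[seq_len(n)], nominal$dt, axis = nominal$axis,
                    amp_scale = NULL, label = nominal$label)
}

#' Time-domain impulse response of a GIRF
#'
#' @param girf a `girf_model`.
#' @return real impulse response (length `fft_length`); the imaginary
#'   residue is checked to be negligible.
#' @export
girf_impulse_response <- function(girf) {
  h <- stats::fft(girf$transfer_function, inverse = TRUE) /
    girf$fft_length
  if (max(abs(Im(h))) > 1e-8 * max(abs(Re(h))))
    warning("impulse response has a non-negligible imaginary part")
  Re(h)
}
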