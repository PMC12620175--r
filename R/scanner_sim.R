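#' Synthetic nonlinear gradient-system model
#'
#' A stand-in for a physical gradient chain, used to produce "measured"
#' waveforms from nominal ones. Its distortion stages reproduce, with
#' deliberately simple functional forms, the phenomenology documented for
#' real gradient amplifiers: a band-limited, delayed linear core with
#' exponential eddy-current terms; dead-zone (zero-crossing / crossover)
#' distortion; amplitude-dependent gain and delay (weaker, later response
#' at low drive amplitude); hard slew-rate limiting; and additive
#' measurement noise. The functional forms are synthetic fixtures, not
#' measurements of any scanner.
#'
#' With `deadzone`, `gain_slope`, `delay_slope` zero, `slew_limit = Inf`
#' and `noise_sigma = 0`, the system is exactly linear time-invariant.
#'
#' @param group_delay linear-stage group delay (s).
#' @param lowpass_cutoff one-pole low-pass cutoff (Hz); must be below
#'   Nyquist for the raster in use.
#' @param eddy_terms list of `c(coupling, time_constant_s)` pairs; each
#'   subtracts `coupling * (dG/dt convolved with exp(-t/tau))`.
#' @param deadzone crossover dead-zone half-width (mT/m, >= 0).
#' @param gain_slope amplitude-dependent gain slope `g_A`
#'   (gain `= 1 - g_A (1 - |A|/reference_amp)`).
#' @param delay_slope amplitude-dependent extra delay `tau_A` (s) at zero
#'   amplitude (extra delay `= tau_A (1 - |A|/reference_amp)`).
#' @param slew_limit output slew-rate limit (T/m/s).
#' @param noise_sigma additive Gaussian measurement noise sd (mT/m).
#' @param reference_amp system reference (maximum) amplitude `A_sys`
#'   (mT/m) at which the amplitude-dependent stage is the identity.
#' @param rng_seed integer seed controlling measurement noise.
#' @return an object of class `gradient_system`.
#' @export
gradient_system <- function(group_delay = 20e-6,
                            lowpass_cutoff = 20e3,
                            eddy_terms = list(c(0.003, 100e-6),
                                              c(0.001, 1e-3)),
                            deadzone = 2,
                            gain_slope = 0.05,
                            delay_slope = 16e-6,
                            slew_limit = 5274,
                            noise_sigma = 0.05,
                            reference_amp = 770,
                            rng_seed = 1L) {
  stopifnot(deadzone >= 0, noise_sigma >= 0, group_delay >= 0,
            slew_limit > 0, reference_amp > 0)
  for (et in eddy_terms)
    if (length(et) != 2 || et[2] <= 0)
      stop("each eddy term must be c(coupling, time_constant) with tau > 0")
  structure(list(group_delay = group_delay, lowpass_cutoff = lowpass_cutoff,
                 eddy_terms = eddy_terms, deadzone = deadzone,
                 gain_slope = gain_slope, delay_slope = delay_slope,
                 slew_limit = slew_limit, noise_sigma = noise_sigma,
                 reference_amp = reference_amp,
                 rng_seed = as.integer(rng_seed)),
            class = "gradient_system")
}

#' An exactly linear-time-invariant configuration of the simulator
#'
#' Convenience constructor zeroing every nonlinear stage (dead zone,
#' amplitude dependence, slew limiting) and the measurement noise, leaving
#' only the delayed band-limited linear core with eddy terms.
#' @param ... overrides passed to [gradient_system()].
#' @return a `gradient_system`.
#' @export
gradient_system_lti <- function(...) {
  args <- list(deadzone = 0, gain_slope = 0, delay_slope = 0,
               slew_limit = Inf, noise_sigma = 0)
  args[names(list(...))] <- list(...)
  do.call(gradient_system, args)
}

# causal fractional delay by linear interpolation between integer shifts;
# strictly causal for delay >= 0 (output n depends on inputs <= n)
.delay_samples <- function(x, d) {
  if (d == 0) return(x)
  n <- length(x)
  i <- floor(d)
  f <- d - i
  shift_int <- function(x, k) {
    if (k <= 0) return(x)
    if (k >= n) return(numeric(n))
    c(numeric(k), x[1:(n - k)])
  }
  a <- shift_int(x, i)
  if (f == 0) return(a)
  b <- shift_int(x, i + 1)
  (1 - f) * a + f * b
}

#' Linear stage of the gradient-system simulator
#'
#' One-pole low-pass filtering, pure group delay, and subtraction of
#' exponential eddy-current terms driven by the input slew. All three
#' operations are causal and linear, so superposition holds to numerical
#' precision.
#'
#' @param model a `gradient_system`.
#' @param w a `gradient_waveform`.
#' @return a `gradient_waveform` with the same raster and metadata.
#' @export
apply_linear_response <- function(model, w) {
  if (is.finite(model$lowpass_cutoff) &&
      model$lowpass_cutoff >= 1 / (2 * w$dt))
    stop("low-pass cutoff must be below the raster Nyquist frequency")
  x <- w$samples
  if (is.finite(model$lowpass_cutoff)) {
    # causal one-pole low-pass: y[n] = a y[n-1] + (1-a) x[n]
    a <- exp(-2 * pi * model$lowpass_cutoff * w$dt)
    y <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  } else y <- x
  y <- .delay_samples(y, model$group_delay / w$dt)
  # eddy terms: coupling * (diff(x) convolved with exp(-t/tau)), causal
  for (et in model$eddy_terms) {
    alpha <- exp(-w$dt / et[2])
    dx <- c(0, diff(x))
    e <- as.numeric(stats::filter(dx, alpha, method = "recursive"))
    y <- y - et[1] * .delay_samples(e, model$group_delay / w$dt)
  }
  gradient_waveform(y, w$dt, axis = w$axis, amp_scale = NULL, label = w$label)
}

#' Crossover (zero-crossing) distortion
#'
#' Pointwise dead zone `y = sign(x) * max(|x| - deadzone, 0)`: the output
#' stage does not conduct until the drive exceeds the dead-zone
#' half-width, producing the flat-spot artifacts seen at waveform zero
#' crossings in push-pull amplifiers. Odd in `x`; identity when
#' `deadzone = 0`.
#'
#' @inheritParams apply_linear_response
#' @return a `gradient_waveform`.
#' @export
apply_crossover_distortion <- function(model, w) {
  d <- model$deadzone
  y <- sign(w$samples) * pmax(abs(w$samples) - d, 0)
  gradient_waveform(y, w$dt, axis = w$axis, amp_scale = NULL, label = w$label)
}

#' Amplitude-dependent gain and delay
#'
#' Applies `gain(A) = 1 - g_A (1 - |A|/A_sys)` and an extra delay
#' `tau(A) = tau_A (1 - |A|/A_sys)` (fractional-sample, causal linear
#' interpolation), where `A = w$amp_scale` is the waveform's nominal
#' amplitude and `A_sys` the system reference amplitude. At `A = A_sys`
#' the stage is the identity; response weakens and lags as `|A|`
#' decreases, as observed on real amplifiers at low drive.
#'
#' @inheritParams apply_linear_response
#' @param amp nominal amplitude `A` used to evaluate the gain and delay
#'   laws (mT/m); defaults to the waveform's own `amp_scale`. Passed
#'   explicitly when the stage is applied to an already-distorted
#'   waveform whose peak no longer equals the nominal amplitude.
#' @return a `gradient_waveform`.
#' @export
apply_amplitude_dependence <- function(model, w, amp = w$amp_scale) {
  A <- abs(amp)
  if (A == 0) stop("waveform amp_scale must be non-zero")
  if (A > model$reference_amp)
    stop("waveform amplitude exceeds the system reference amplitude")
  rel <- 1 - A / model$reference_amp
  gain <- 1 - model$gain_slope * rel
  extra <- model$delay_slope * rel
  y <- gain * .delay_samples(w$samples, extra / w$dt)
  gradient_waveform(y, w$dt, axis = w$axis, amp_scale = NULL, label = w$label)
}

#' Hard slew-rate limiting
#'
#' Rate limiter `y[n] = y[n-1] + clip(x[n] - y[n-1], +-slew_limit*dt)`
#' with `y[0] = clip(x[0])` from zero. Waveforms already within the limit
#' pass through unchanged (fast path).
#'
#' @inheritParams apply_linear_response
#' @return a `gradient_waveform` whose numeric slew never exceeds the
#'   limit.
#' @export
apply_slew_limit <- function(model, w) {
  if (!is.finite(model$slew_limit)) return(w)
  x <- w$samples
  step <- model$slew_limit * w$dt * 1e3  # mT/m per sample
  if (max(abs(diff(x))) <= step && abs(x[1]) <= step) return(w)
  y <- numeric(length(x))
  prev <- 0
  for (n in seq_along(x)) {
    d <- x[n] - prev
    prev <- prev + sign(d) * min(abs(d), step)
    y[n] <- prev
  }
  gradient_waveform(y, w$dt, axis = w$axis, amp_scale = NULL, label = w$label)
}

#' Simulate a gradient waveform measurement
#'
#' Full distortion chain: linear stage, amplitude-dependent gain/delay,
#' crossover distortion, slew limiting, then (optionally) additive
#' Gaussian measurement noise. Deterministic given the model's `rng_seed`
#' (combined with `noise_stream` so different waveforms in a library get
#' independent, reproducible noise).
#'
#' @inheritParams apply_linear_response
#' @param add_noise add measurement noise of sd `noise_sigma`?
#' @param noise_stream integer substream index for the noise RNG.
#' @param settle_pad post-waveform settling window (s): the measurement
#'   continues for this long after the nominal waveform ends, capturing
#'   eddy-current decay tails. The returned waveform is longer than the
#'   input by `round(settle_pad / dt)` samples.
#' @return a `gradient_waveform` ("measured").
#' @export
simulate_measurement <- function(model, w, add_noise = TRUE,
                                 noise_stream = 0L, settle_pad = 0) {
  if (settle_pad > 0) {
    npad <- round(settle_pad / w$dt)
    w <- gradient_waveform(c(w$samples, numeric(npad)), w$dt,
                           axis = w$axis, amp_scale = w$amp_scale,
                           label = w$label)
  }
  y <- apply_linear_response(model, w)
  if ((model$gain_slope != 0 || model$delay_slope != 0) &&
      w$amp_scale != 0)
    y <- apply_amplitude_dependence(model, y, amp = w$amp_scale)
  if (model$deadzone > 0) y <- apply_crossover_distortion(model, y)
  y <- apply_slew_limit(model, y)
  s <- y$samples
  if (add_noise && model$noise_sigma > 0) {
    rs <- (as.numeric(model$rng_seed) * 10007 +
             as.numeric(noise_stream)) %% 2147483647
    s <- s + .with_seed(rs, stats::rnorm(length(s), 0, model$noise_sigma))
  }
  gradient_waveform(s, w$dt, axis = w$axis, amp_scale = NULL, label = w$label)
}
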