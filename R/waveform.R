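#' Gradient waveform objects
#'
#' A `gradient_waveform` is a uniformly sampled single-axis gradient
#' amplitude time series. Amplitudes are stored in mT/m on a raster of
#' `dt` seconds. `amp_scale` is the signed peak nominal amplitude of the
#' waveform: `max(abs(samples)) == abs(amp_scale)` (up to floating point)
#' so that rescaling a waveform to a new amplitude is a pure
#' multiplication.
#'
#' @param samples numeric vector of gradient amplitudes (mT/m).
#' @param dt raster time in seconds (> 0).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param amp_scale signed peak nominal amplitude (mT/m). Defaults to the
#'   signed sample of largest magnitude.
#' @param label waveform class name.
#' @return an object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt, axis = "x", amp_scale = NULL,
                              label = "") {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("'samples' must be a numeric vector of length >= 2")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  axis <- match.arg(axis, c("x", "y", "z"))
  if (is.null(amp_scale)) {
    i <- which.max(abs(samples))
    amp_scale <- samples[i]
    if (abs(amp_scale) == 0) amp_scale <- 0
  }
  pk <- max(abs(samples))
  if (pk > 0 && abs(pk - abs(amp_scale)) > 1e-9 * max(pk, abs(amp_scale)))
    stop("max(abs(samples)) must equal abs(amp_scale) to 1e-9 relative")
  structure(list(samples = as.numeric(samples), dt = dt, axis = axis,
                 amp_scale = amp_scale, label = label),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> '%s' axis=%s n=%d dt=%.3g us amp=%.4g mT/m\n",
              x$label, x$axis, length(x$samples), x$dt * 1e6, x$amp_scale))
  invisible(x)
}

#' @export
length.gradient_waveform <- function(x) length(x$samples)

#' Time vector of a waveform (seconds, starting at 0)
#' @param w a `gradient_waveform`.
#' @return numeric vector of sample times.
#' @export
waveform_times <- function(w) (seq_along(w$samples) - 1) * w$dt

#' Maximum numeric slew rate of a waveform (T/m/s)
#'
#' First-difference estimate `max(abs(diff(samples)))/dt`, converted from
#' mT/m per second to T/m/s.
#' @param w a `gradient_waveform`.
#' @return slew rate in T/m/s.
#' @export
waveform_slew <- function(w) {
  max(abs(diff(w$samples))) / w$dt * 1e-3
}

#' Time integral of a gradient waveform (T s/m)
#'
#' Trapezoidal integration of the gradient amplitude; the gradient first
#' moment per unit gyromagnetic ratio.
#' @param w a `gradient_waveform`.
#' @return scalar area in T s/m.
#' @export
waveform_area <- function(w) {
  pracma::trapz(waveform_times(w), w$samples) * 1e-3
}

#' Trapezoidal gradient pulse
#'
#' Linear ramp up over `ramp_dur`, plateau at `plateau_amp` for
#' `plateau_dur`, linear ramp down. The implied slew rate is
#' `plateau_amp / ramp_dur`. With `plateau_dur = 0` the pulse degenerates
#' to a triangle.
#'
#' @param plateau_amp plateau amplitude (mT/m); may be negative or zero.
#' @param plateau_dur plateau duration (s, >= 0).
#' @param ramp_dur ramp duration (s, >= dt).
#' @param dt raster time (s).
#' @param axis gradient axis.
#' @return a `gradient_waveform` whose area is
#'   `plateau_amp * (plateau_dur + ramp_dur)`.
#' @export
make_trapezoid <- function(plateau_amp, plateau_dur, ramp_dur, dt = 4e-6,
                           axis = "x") {
  if (plateau_dur < 0 || ramp_dur < 0) stop("durations must be non-negative")
  if (ramp_dur < dt) stop("'ramp_dur' must be at least dt")
  n_r <- max(1L, round(ramp_dur / dt))
  n_p <- round(plateau_dur / dt)
  up <- plateau_amp * (0:n_r) / n_r
  plateau <- rep(plateau_amp, n_p)
  down <- plateau_amp * (n_r:0) / n_r
  s <- c(up, plateau, down[-1])
  gradient_waveform(s, dt, axis = axis, amp_scale = plateau_amp,
                    label = "trapezoid")
}

#' Alternating-sign triangle train
#'
#' `n_triangles` back-to-back triangles of peak `peak_amp` with
#' alternating sign; each triangle is an up ramp of `ramp_dur` followed by
#' a down ramp of `ramp_dur`. For even `n_triangles` the train has zero
#' mean.
#'
#' @param peak_amp triangle peak amplitude (mT/m).
#' @param n_triangles number of triangles (>= 1).
#' @param ramp_dur single-ramp duration (s, >= dt); slew is
#'   `peak_amp / ramp_dur`.
#' @inheritParams make_trapezoid
#' @return a `gradient_waveform`.
#' @export
make_triangle_train <- function(peak_amp, n_triangles, ramp_dur, dt = 4e-6,
                                axis = "x") {
  if (n_triangles < 1) stop("'n_triangles' must be >= 1")
  if (ramp_dur < dt) stop("'ramp_dur' must be at least dt")
  n_r <- max(1L, round(ramp_dur / dt))
  tri <- c((0:n_r) / n_r, (n_r - 1):0 / n_r)
  s <- numeric(0)
  for (m in seq_len(n_triangles)) {
    sgn <- if (m %% 2 == 1) 1 else -1
    seg <- sgn * peak_amp * tri
    s <- if (length(s)) c(s, seg[-1]) else seg
  }
  gradient_waveform(s, dt, axis = axis,
                    amp_scale = peak_amp, label = "triangle_train")
}

#' Slew-constrained linear chirp
#'
#' Linear frequency sweep from `f_start` to `f_end` over `duration`. The
#' envelope is `peak_amp` where feasible and is reduced where the local
#' slew of a full-amplitude tone would exceed `slew_limit`
#' (`envelope = slew_limit / (2 pi f)` in the fast part of the sweep).
#' Short linear tapers force the waveform to start and end at zero. After
#' construction the waveform is iteratively shrunk (if needed) until its
#' numeric slew is within `slew_limit`.
#'
#' @param f_start,f_end sweep frequencies (Hz), `0 <= f_start < f_end`,
#'   `f_end` below Nyquist `1/(2 dt)`.
#' @param duration sweep duration (s), excluding any hold.
#' @param peak_amp requested peak amplitude (mT/m).
#' @param slew_limit slew limit (T/m/s).
#' @inheritParams make_trapezoid
#' @param taper_dur duration of the linear end tapers (s).
#' @param hold_dur optional constant-frequency hold at `f_start`
#'   prepended to the sweep (s); a hold of at least one period lets the
#'   chirp carry its full peak amplitude in the slow section before the
#'   envelope clamp engages.
#' @return a `gradient_waveform`; `samples[1] == 0`.
#' @export
make_chirp <- function(f_start, f_end, duration, peak_amp, slew_limit,
                       dt = 4e-6, axis = "x", taper_dur = 3e-4,
                       hold_dur = 0) {
  if (f_start < 0 || f_end <= f_start) stop("need 0 <= f_start < f_end")
  if (duration <= 0) stop("'duration' must be positive")
  if (f_end >= 1 / (2 * dt))
    stop("'f_end' must be below the Nyquist frequency 1/(2 dt)")
  n <- round((duration + hold_dur) / dt)
  t <- (0:(n - 1)) * dt
  ts <- pmax(t - hold_dur, 0)                    # time within the sweep
  finst <- f_start + (f_end - f_start) * ts / duration
  phase <- 2 * pi * (f_start * t +
                     (f_end - f_start) * ts^2 / (2 * duration))
  # the slew of A(t) sin(phi) has a carrier term A*2*pi*f and an envelope
  # term A'; for an envelope of the form A = c/f under a linear sweep of
  # rate r both are captured by the closed form
  # A(f) = S / sqrt((r/f)^2 + (2 pi f)^2), clamped at the requested peak
  margin <- 0.94 * slew_limit * 1e3
  r_eff <- ifelse(t >= hold_dur, (f_end - f_start) / duration, 0)
  f_safe <- pmax(finst, 1)
  env <- pmin(abs(peak_amp),
              margin / sqrt((r_eff / f_safe)^2 + (2 * pi * f_safe)^2))
  # the sine itself starts at zero; only the end needs a taper, and a
  # raised cosine keeps the taper's own slew contribution smooth
  tl <- pmin(1, (max(t) - t) / taper_dur)
  taper <- 0.5 * (1 - cos(pi * tl))
  s <- sign(peak_amp + (peak_amp == 0)) * env * sin(phase) * taper
  if (peak_amp == 0) s <- numeric(n)
  # numeric safety: local envelope reduction where the finite-difference
  # slew still exceeds the limit; with the margins above this never
  # reaches the full-amplitude slow section, so rescaling the chirp to
  # its design peak keeps it slew-feasible
  if (any(s != 0)) {
    for (i in 1:200) {
      viol <- which(abs(diff(s)) / dt * 1e-3 > slew_limit)
      if (!length(viol)) break
      idx <- unique(pmin(pmax(rep(viol, each = 17) + (-8:8), 1), n))
      s[idx] <- s[idx] * 0.97
    }
  }
  gradient_waveform(s, dt, axis = axis, label = "chirp")
}

#' Multisine waveform
#'
#' Sum of sinusoids `sum_j amps[j] * sin(2 pi freqs[j] t)`, rescaled so
#' the peak equals `max(abs(amps))`, with short linear end tapers so the
#' waveform starts and ends at zero. Exact cancellations (or all-zero
#' `amps`) yield the zero waveform.
#'
#' @param freqs tone frequencies (Hz), all below Nyquist.
#' @param amps tone amplitudes (mT/m), same length as `freqs`.
#' @param duration waveform duration (s).
#' @inheritParams make_chirp
#' @return a `gradient_waveform`.
#' @export
make_multisine <- function(freqs, amps, duration, dt = 4e-6, axis = "x",
                           taper_dur = 2.5e-4) {
  if (length(freqs) == 0) stop("'freqs' must be non-empty")
  if (length(freqs) != length(amps))
    stop("'freqs' and 'amps' must have equal length")
  if (any(freqs >= 1 / (2 * dt))) stop("all frequencies must be below Nyquist")
  n <- round(duration / dt)
  t <- (0:(n - 1)) * dt
  s <- numeric(n)
  for (j in seq_along(freqs)) s <- s + amps[j] * sin(2 * pi * freqs[j] * t)
  pk <- max(abs(s))
  if (pk > 0) {
    s <- s * (max(abs(amps)) / pk)
    tl <- pmin(1, (max(t) - t) / taper_dur)
    s <- s * 0.5 * (1 - cos(pi * tl))
  }
  gradient_waveform(s, dt, axis = axis, label = "multisine")
}

#' Append trailing zeros to a waveform
#'
#' Extends a waveform with a zero-amplitude settling window, e.g. to
#' match a measurement that continued past the end of the nominal
#' waveform.
#' @param w a `gradient_waveform`.
#' @param pad_dur settling window duration (s).
#' @return a `gradient_waveform` longer by `round(pad_dur / dt)` samples.
#' @export
pad_waveform <- function(w, pad_dur) {
  npad <- round(pad_dur / w$dt)
  if (npad <= 0) return(w)
  gradient_waveform(c(w$samples, numeric(npad)), w$dt, axis = w$axis,
                    amp_scale = w$amp_scale, label = w$label)
}

#' Rescale a waveform to a set of nominal amplitudes
#'
#' Each output waveform is `w` multiplied by `a / w$amp_scale` so that its
#' `amp_scale` equals the requested amplitude `a`; the shape (and
#' duration) is unchanged. Amplitudes above `max_amp` trigger a warning
#' (the system would clip), not an error.
#'
#' @param w a `gradient_waveform` with non-zero `amp_scale`.
#' @param amplitudes numeric vector of requested signed amplitudes (mT/m),
#'   all non-zero.
#' @param max_amp system maximum gradient amplitude (mT/m).
#' @return a list of `gradient_waveform`s, one per amplitude.
#' @export
scale_to_amplitudes <- function(w, amplitudes, max_amp = 770) {
  if (any(amplitudes == 0)) stop("'amplitudes' must be non-zero")
  if (w$amp_scale == 0) stop("cannot rescale an all-zero waveform")
  if (any(abs(amplitudes) > max_amp))
    warning("requested amplitude exceeds the system maximum of ",
            max_amp, " mT/m")
  lapply(amplitudes, function(a) {
    gradient_waveform(w$samples * (a / w$amp_scale), w$dt, axis = w$axis,
                      amp_scale = a, label = w$label)
  })
}
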