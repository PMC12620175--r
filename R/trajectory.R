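#' k-space trajectory from gradient waveforms
#'
#' Cumulative trapezoidal integration of per-axis gradient waveforms:
#' `k(t) = gamma_bar * integral_0^t G(tau) dtau`, in cycles/m, starting
#' from `k = 0`.
#'
#' @param gx,gy `gradient_waveform`s of equal length and raster (gy may
#'   be omitted for a 1D trajectory).
#' @param gamma_bar gyromagnetic ratio over 2 pi (Hz/T); default 1H.
#' @param k_max design maximum k-space radius (cycles/m) used for
#'   normalized error metrics; defaults to the trajectory's own maximum
#'   radius.
#' @param t_echo echo-center time (s) subtracted from the time vector
#'   (off-resonance phase is referenced to the echo in spin-echo
#'   acquisitions).
#' @return an object of class `ktrajectory` with fields `kx`, `ky`
#'   (cycles/m), `times` (s, echo-referenced), `k_max`, `dt`.
#' @export
integrate_gradients <- function(gx, gy = NULL, gamma_bar = .GAMMA_BAR,
                                k_max = NULL, t_echo = 0) {
  if (!is.null(gy)) {
    if (length(gx$samples) != length(gy$samples))
      stop("axis waveforms must have equal length")
    if (gx$dt != gy$dt) stop("axis waveforms must share dt")
  }
  tt <- waveform_times(gx)
  kx <- gamma_bar * pracma::cumtrapz(tt, gx$samples * 1e-3)[, 1]
  ky <- if (is.null(gy)) numeric(length(kx))
        else gamma_bar * pracma::cumtrapz(tt, gy$samples * 1e-3)[, 1]
  if (is.null(k_max)) k_max <- max(sqrt(kx^2 + ky^2))
  structure(list(kx = kx, ky = ky, times = tt - t_echo, k_max = k_max,
                 dt = gx$dt, normalized = FALSE),
            class = "ktrajectory")
}

#' Integrate all shots of a readout
#'
#' @param shots a [shot_set] or a list of `list(gx=, gy=)` waveform
#'   pairs.
#' @param gamma_bar gyromagnetic ratio over 2 pi (Hz/T).
#' @param k_max design `k_max` override; for a `shot_set` the design
#'   value is used so all shots share one normalization.
#' @return list of `ktrajectory`, one per shot.
#' @export
integrate_shots <- function(shots, gamma_bar = .GAMMA_BAR, k_max = NULL) {
  if (inherits(shots, "shot_set")) {
    km <- if (is.null(k_max)) shots$k_max else k_max
    t_echo <- (shots$echo_index - 1) * shots$dt
    lapply(shots$shots, function(s)
      integrate_gradients(s$gx, s$gy, gamma_bar, k_max = km,
                          t_echo = t_echo))
  } else {
    lapply(shots, function(s)
      integrate_gradients(s$gx, s$gy, gamma_bar, k_max = k_max))
  }
}

#' Restrict a trajectory to a sample window
#'
#' Keeps the samples in `range` (inclusive indices), e.g. a `shot_set`'s
#' `core_range` — the acquisition window of the readout, excluding
#' prephaser and ramp segments during which no data are collected.
#' @param tr a `ktrajectory`.
#' @param range length-2 integer vector of first/last sample.
#' @return a `ktrajectory` over the window.
#' @export
traj_window <- function(tr, range) {
  idx <- seq.int(range[1], range[2])
  structure(list(kx = tr$kx[idx], ky = tr$ky[idx],
                 times = tr$times[idx], k_max = tr$k_max, dt = tr$dt,
                 normalized = tr$normalized), class = "ktrajectory")
}

#' Normalized root-mean-square waveform error
#'
#' `sqrt(mean((pred - meas)^2)) / amp`: the RMS sample error normalized
#' by the nominal peak amplitude, the convention used for comparing
#' predicted and measured gradient waveforms across amplitudes.
#'
#' @param pred,meas `gradient_waveform`s of equal length.
#' @param amp normalization amplitude (mT/m); defaults to the larger
#'   `abs(amp_scale)` of the two waveforms (for a prediction/measurement
#'   pair, the nominal peak amplitude). Must be non-zero.
#' @return dimensionless NRMSE; symmetric in `pred` and `meas`.
#' @export
waveform_nrmse <- function(pred, meas, amp = NULL) {
  if (length(pred$samples) != length(meas$samples))
    stop("waveforms must have equal length")
  if (is.null(amp)) amp <- max(abs(pred$amp_scale), abs(meas$amp_scale))
  if (amp == 0) stop("normalization amplitude must be non-zero")
  sqrt(mean((pred$samples - meas$samples)^2)) / abs(amp)
}

#' Trajectory root-mean-square error
#'
#' RMS of the per-sample Euclidean 2D k-space error between two
#' trajectories; with `normalize = TRUE` the result is divided by the
#' reference `k_max`, giving error in normalized k-space units.
#'
#' @param pred,ref `ktrajectory` objects of equal length.
#' @param normalize divide by `ref$k_max`?
#' @return dimensionless (normalized) or cycles/m RMSE.
#' @export
trajectory_rmse <- function(pred, ref, normalize = TRUE) {
  if (length(pred$kx) != length(ref$kx)) stop("trajectory length mismatch")
  e <- sqrt(mean((pred$kx - ref$kx)^2 + (pred$ky - ref$ky)^2))
  if (normalize) e / ref$k_max else e
}
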