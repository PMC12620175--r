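#' Multi-shot readout gradient sets
#'
#' A `shot_set` holds one x- and one y-axis [gradient_waveform] per shot,
#' all sharing raster time and length, plus the design metadata needed to
#' interpret the integrated trajectory (design `k_max`, index of the echo
#' center, index range of the analytic readout core between the
#' ramp/prephaser segments).
#'
#' @name shot_set
NULL

.shot_set <- function(shots, dt, k_max, fov, resolution, echo_index,
                      core_range, type, extra = list()) {
  n <- length(shots[[1]]$gx$samples)
  structure(c(list(shots = shots, n_shots = length(shots), dt = dt,
                   readout_duration = n * dt, k_max = k_max, fov = fov,
                   resolution = resolution, echo_index = echo_index,
                   core_range = core_range, type = type), extra),
            class = "shot_set")
}

#' @export
print.shot_set <- function(x, ...) {
  cat(sprintf("<shot_set> %s: %d shots, %d samples (%.2f ms), k_max=%.1f /m\n",
              x$type, x$n_shots, round(x$readout_duration / x$dt),
              x$readout_duration * 1e3, x$k_max))
  invisible(x)
}

# shortest trapezoid (or triangle) with a given gradient-time area,
# scaled so its *discrete trapezoidal* area is exact.
# area in T s/m, gmax mT/m, slew T/m/s
.trap_for_area <- function(area, gmax, slew, dt) {
  if (abs(area) < 1e-18) return(numeric(0))
  sgn <- sign(area)
  A <- abs(area)
  gmax_si <- gmax * 1e-3
  a_tri <- sqrt(A * slew)              # triangle peak if unconstrained
  if (a_tri <= gmax_si) {
    r <- a_tri / slew
    p <- 0
  } else {
    r <- gmax_si / slew
    p <- A / gmax_si - r
  }
  n_r <- max(1L, ceiling(r / dt))
  n_p <- max(0L, ceiling(p / dt))
  shape <- c((0:n_r) / n_r, rep(1, n_p), ((n_r - 1):0) / n_r)
  raw_area <- pracma::trapz(seq_along(shape) - 1, shape) * dt  # per unit peak
  peak <- A / raw_area * 1e3                                   # mT/m
  # ceiling() on the ramp count keeps the realized slew within the limit
  sgn * peak * shape
}

# linear ramp from 0 towards g (exclusive of the endpoint sample),
# slew-limited; returns a 2-column matrix (x,y)
.ramp_to <- function(g, slew, dt) {
  gmag <- sqrt(sum(g^2)) * 1e-3
  n_r <- max(1L, ceiling(gmag / (0.95 * slew * dt)))
  j <- seq_len(n_r) - 1
  outer(j / n_r, g)
}

#' Multi-shot Archimedean spiral-in-out readout
#'
#' Each shot traverses an Archimedean spiral from the k-space edge inward
#' to the center (reaching `k = 0` at the echo) and back out, with shot
#' `m` rotated by `2 pi m / n_shots` (uniform) or by the golden angle.
#' The spiral-out half is `k(u) = k_max u [cos, sin](2 pi n_t u + phi)`
#' with `u` linear in time and the duration chosen (by bisection) as the
#' shortest for which both the gradient amplitude and the numeric slew
#' rate are within limits; the spiral-in half is its point reflection
#' through the origin, so the gradient is continuous at the center. The
#' number of turns per shot is `fov / (2 resolution) / n_shots`
#' (Nyquist-spaced interleaves). Slew-limited ramps join zero gradient to
#' the spiral ends; when `prephaser` is set, trapezoidal prephasers (and
#' a time-reversed rewinder) move k from the origin to the spiral-in
#' start and back, so the integrated trajectory starts and ends at
#' `k = 0` and passes through the center at the waveform midpoint.
#'
#' @param n_shots number of interleaved shots (>= 1).
#' @param fov field of view (m).
#' @param resolution spatial resolution (m, <= fov).
#' @param max_grad maximum gradient amplitude (mT/m).
#' @param slew_limit slew-rate limit (T/m/s).
#' @param dt raster time (s).
#' @param prephaser prepend/append trapezoids so k starts and ends at 0.
#' @param rotation inter-shot rotation rule.
#' @param max_duration refuse designs whose spiral half exceeds this (s).
#' @return a `shot_set`.
#' @export
make_spiral_inout <- function(n_shots, fov, resolution, max_grad = 300,
                              slew_limit = 5274, dt = 4e-6,
                              prephaser = TRUE,
                              rotation = c("uniform", "golden"),
                              max_duration = 0.05) {
  rotation <- match.arg(rotation)
  if (n_shots < 1) stop("'n_shots' must be >= 1")
  if (resolution > fov) stop("'resolution' must not exceed 'fov'")
  k_max <- 1 / (2 * resolution)
  n_t <- (fov / (2 * resolution)) / n_shots
  gb <- .GAMMA_BAR

  core_g <- function(Thalf, phi) {
    # gradient of the spiral-out half, analytic, sampled on the raster
    n <- max(2L, round(Thalf / dt))
    u <- (0:n) / n
    th <- 2 * pi * n_t * u + phi
    gx <- k_max / (n * dt) * (cos(th) - u * 2 * pi * n_t * sin(th)) / gb * 1e3
    gy <- k_max / (n * dt) * (sin(th) + u * 2 * pi * n_t * cos(th)) / gb * 1e3
    cbind(gx, gy)
  }
  feasible <- function(Thalf) {
    g <- core_g(Thalf, 0)
    gm <- max(sqrt(rowSums(g^2)))
    sl <- max(abs(diff(g[, 1])), abs(diff(g[, 2]))) / dt * 1e-3
    c(amp = gm <= 0.99 * max_grad, slew = sl <= 0.95 * slew_limit)
  }
  lo <- dt * 4; hi <- lo
  while (!all(feasible(hi))) {
    hi <- hi * 2
    if (hi > max_duration) {
      f <- feasible(hi / 2)
      lim <- if (!f["amp"]) "max_grad" else "slew_limit"
      stop(sprintf("spiral infeasible within max_duration: %s is limiting",
                   lim))
    }
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (all(feasible(mid))) hi <- mid else lo <- mid
  }
  Thalf <- hi

  golden <- pi * (3 - sqrt(5))
  phis <- if (rotation == "uniform") 2 * pi * (seq_len(n_shots) - 1) /
    n_shots else (seq_len(n_shots) - 1) * golden

  # assemble cores and ramps first; ramp lengths depend only on |g| so
  # every rotation shares them
  bodies <- vector("list", n_shots)
  pres <- vector("list", n_shots)
  core_start0 <- NA_integer_; core_len <- NA_integer_
  for (m in seq_len(n_shots)) {
    gout <- core_g(Thalf, phis[m])         # (n+1) x 2, spiral-out
    gin <- gout[nrow(gout):1, , drop = FALSE]
    core <- rbind(gin, gout[-1, , drop = FALSE])   # continuous at center
    ramp_in <- .ramp_to(core[1, ], slew_limit, dt)
    ramp_out <- .ramp_to(core[nrow(core), ], slew_limit, dt)
    ramp_out <- ramp_out[rev(seq_len(nrow(ramp_out))), , drop = FALSE]
    body <- rbind(ramp_in, core, ramp_out)
    core_start0 <- nrow(ramp_in) + 1L
    core_len <- nrow(core)
    if (prephaser) {
      # target k at the spiral-in start is the (rotated) k-space edge
      th_end <- 2 * pi * n_t + phis[m]
      k_edge <- -k_max * c(cos(th_end), sin(th_end))
      kk <- apply(body, 2, function(g)
        pracma::cumtrapz(seq_len(nrow(body)) - 1, g)[, 1]) *
        dt * 1e-3 * gb
      need <- (k_edge - kk[core_start0, ]) / gb    # T s/m per axis
      px <- .trap_for_area(need[1], max_grad, 0.95 * slew_limit, dt)
      py <- .trap_for_area(need[2], max_grad, 0.95 * slew_limit, dt)
      len <- max(length(px), length(py))
      pres[[m]] <- cbind(c(numeric(len - length(px)), px),
                         c(numeric(len - length(py)), py))
    }
    bodies[[m]] <- body
  }
  # pad every prephaser to a common length so all shots share timing
  plen <- if (prephaser) max(vapply(pres, nrow, 0L)) else 0L
  shots <- vector("list", n_shots)
  for (m in seq_len(n_shots)) {
    body <- bodies[[m]]
    if (prephaser) {
      pre <- rbind(matrix(0, plen - nrow(pres[[m]]), 2), pres[[m]])
      rew <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
      body <- rbind(pre, body, rew)
    }
    shots[[m]] <- list(
      gx = gradient_waveform(body[, 1], dt, axis = "x",
                             label = "spiral_inout"),
      gy = gradient_waveform(body[, 2], dt, axis = "y",
                             label = "spiral_inout"))
  }
  core_start <- plen + core_start0
  echo_index <- core_start + (core_len - 1L) / 2L
  core_range <- c(core_start, core_start + core_len - 1L)
  .shot_set(shots, dt, k_max, fov, resolution, echo_index, core_range,
            "spiral_inout",
            extra = list(n_turns = n_t, rotation = rotation,
                         spiral_half_duration = Thalf))
}

#' Multi-shot rosette readout
#'
#' Rosette trajectory
#' `k(t) = k_max sin(w1 t) [cos(w2 t + phi_m), sin(w2 t + phi_m)]` with
#' `w1 = pi n_petals / readout_duration` (so the readout closes at the
#' k-space center after `n_petals` petals) and the convention
#' `w2 / w1 = (n_petals - 1) / n_petals`; shot rotations `phi_m` are
#' uniform over `2 pi`. Gradients are the analytic time derivative.
#' Slew-limited ramps connect zero gradient to the analytic core, and
#' small area-compensation blips cancel the ramps' k-space area so the
#' integrated trajectory is exactly the analytic rosette over the core
#' (`k = 0` at the core start and end).
#'
#' @param n_shots number of shots (>= 1).
#' @param n_petals petals per shot (>= 2).
#' @param fov field of view (m).
#' @param resolution spatial resolution (m).
#' @param readout_duration duration of the analytic rosette core (s);
#'   must be an integer number of raster periods.
#' @param dt raster time (s).
#' @param max_grad,slew_limit limits used for the ramps/blips and
#'   feasibility check.
#' @param ramp_slew optional reduced slew budget for the lead-in/out
#'   ramps and compensation blips (T/m/s); used when the rosette shape
#'   will later be rescaled to a larger amplitude, so the ramps keep
#'   margin for the upscale.
#' @return a `shot_set`.
#' @export
make_rosette <- function(n_shots, n_petals, fov, resolution,
                         readout_duration, dt = 4e-6, max_grad = 770,
                         slew_limit = 5274, ramp_slew = slew_limit) {
  if (n_petals < 2) stop("'n_petals' must be >= 2")
  if (n_shots < 1) stop("'n_shots' must be >= 1")
  n <- readout_duration / dt
  if (abs(n - round(n)) > 1e-6)
    stop("'readout_duration' must be an integer number of raster periods")
  n <- round(n)
  k_max <- 1 / (2 * resolution)
  w1 <- pi * n_petals / readout_duration
  w2 <- w1 * (n_petals - 1) / n_petals
  gb <- .GAMMA_BAR
  t <- (0:n) * dt

  gmax_core <- k_max * (w1 + w2) / gb * 1e3      # mT/m bound on |g|
  if (gmax_core > max_grad)
    stop("rosette infeasible: max_grad is limiting")
  if (k_max * (w1 + w2)^2 / gb > slew_limit)     # T/m/s bound on |dg/dt|
    stop("rosette infeasible: slew_limit is limiting")

  shots <- vector("list", n_shots)
  for (m in seq_len(n_shots)) {
    phi <- 2 * pi * (m - 1) / n_shots
    s1 <- sin(w1 * t); c1 <- cos(w1 * t)
    s2 <- sin(w2 * t + phi); c2 <- cos(w2 * t + phi)
    gx <- k_max * (w1 * c1 * c2 - w2 * s1 * s2) / gb * 1e3
    gy <- k_max * (w1 * c1 * s2 + w2 * s1 * c2) / gb * 1e3
    core <- cbind(gx, gy)
    ramp_in <- .ramp_to(core[1, ], ramp_slew, dt)
    ramp_out <- .ramp_to(core[nrow(core), ], ramp_slew, dt)
    ramp_out <- ramp_out[rev(seq_len(nrow(ramp_out))), , drop = FALSE]
    body <- rbind(ramp_in, core, ramp_out)
    core_start <- nrow(ramp_in) + 1L

    # cancel the ramp areas with compensation blips so k(core start) = 0
    kk <- apply(body, 2, function(g)
      pracma::cumtrapz(seq_len(nrow(body)) - 1, g)[, 1]) * dt * 1e-3 * gb
    need_pre <- -kk[core_start, ] / gb
    px <- .trap_for_area(need_pre[1], max_grad, 0.95 * ramp_slew, dt)
    py <- .trap_for_area(need_pre[2], max_grad, 0.95 * ramp_slew, dt)
    lp <- max(length(px), length(py))
    if (lp > 0) {
      pre <- cbind(c(numeric(lp - length(px)), px),
                   c(numeric(lp - length(py)), py))
      body <- rbind(pre, body)
      core_start <- core_start + lp
    }
    ke <- apply(body, 2, function(g)
      pracma::cumtrapz(seq_len(nrow(body)) - 1, g)[, 1]) * dt * 1e-3 * gb
    need_post <- -ke[nrow(body), ] / gb
    qx <- .trap_for_area(need_post[1], max_grad, 0.95 * ramp_slew, dt)
    qy <- .trap_for_area(need_post[2], max_grad, 0.95 * ramp_slew, dt)
    lq <- max(length(qx), length(qy))
    if (lq > 0) {
      post <- cbind(c(qx, numeric(lq - length(qx))),
                    c(qy, numeric(lq - length(qy))))
      body <- rbind(body, post)
    }
    shots[[m]] <- list(
      gx = gradient_waveform(body[, 1], dt, axis = "x", label = "rosette"),
      gy = gradient_waveform(body[, 2], dt, axis = "y", label = "rosette"))
    if (m == 1) {
      echo_index <- core_start + n  # core end returns to k = 0
      core_range <- c(core_start, core_start + n)
    }
  }
  .shot_set(shots, dt, k_max, fov, resolution, echo_index, core_range,
            "rosette", extra = list(n_petals = n_petals, w1 = w1, w2 = w2))
}
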