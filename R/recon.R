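#' @name recon
#' @title Non-Cartesian acquisition simulation and gridding reconstruction
#'
#' @description
#' Forward simulation is an exact discrete Fourier summation over the
#' phantom's non-zero voxels,
#' `s(t) = sum_r rho(r) exp(-i 2 pi (k(t).r + df(r) t))`, with sample
#' times referenced to the spin echo. Reconstruction is adjoint gridding
#' with a Kaiser-Bessel kernel (width 6, 2x oversampling, Beatty beta),
#' density compensation by the Pipe-Menon fixed point, deapodization by
#' the kernel's analytic Fourier transform, and optional time-segmented
#' conjugate-phase off-resonance correction.
NULL

# ---- Kaiser-Bessel gridding engine -------------------------------------

.kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

.kb_kernel <- function(d, width, beta) {
  # d: distance in (oversampled) grid cells
  u <- 2 * d / width
  out <- numeric(length(d))
  ok <- abs(u) < 1
  out[ok] <- besselI(beta * sqrt(1 - u[ok]^2), 0) / besselI(beta, 0)
  out
}

# analytic FT of the KB kernel, for deapodization; x in cycles per grid
# cell
.kb_ft <- function(x, width, beta) {
  z <- sqrt(as.complex((pi * width * x)^2 - beta^2))
  w <- Re(ifelse(abs(z) < 1e-12, 1, sin(z) / z))
  w / max(w)
}

.fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

# flatten per-shot trajectories to sample vectors (cycles/m and s)
.flatten_traj <- function(trajs) {
  list(kx = unlist(lapply(trajs, `[[`, "kx")),
       ky = unlist(lapply(trajs, `[[`, "ky")),
       t = unlist(lapply(trajs, `[[`, "times")))
}

# scatter complex sample values onto the oversampled grid (adjoint
# interpolation); p are continuous grid coordinates (1-based center
# No/2+1)
.grid_adjoint <- function(val, px, py, No, width, beta) {
  hw <- width / 2
  re <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(No, No))
  im <- re
  fx <- floor(px); fy <- floor(py)
  for (dx in seq.int(-hw + 1, hw)) {
    cx <- fx + dx
    wx <- .kb_kernel(px - cx, width, beta)
    for (dy in seq.int(-hw + 1, hw)) {
      cy <- fy + dy
      wy <- .kb_kernel(py - cy, width, beta)
      w <- wx * wy
      ok <- cx >= 1 & cx <= No & cy >= 1 & cy <= No & w > 0
      if (!any(ok)) next
      re <- re + Matrix::sparseMatrix(i = cx[ok], j = cy[ok],
                                      x = w[ok] * Re(val[ok]),
                                      dims = c(No, No))
      im <- im + Matrix::sparseMatrix(i = cx[ok], j = cy[ok],
                                      x = w[ok] * Im(val[ok]),
                                      dims = c(No, No))
    }
  }
  as.matrix(re) + 1i * as.matrix(im)
}

# interpolate a k-space grid at sample locations (forward interpolation)
.degrid <- function(grid, px, py, No, width, beta) {
  hw <- width / 2
  out <- complex(length(px))
  fx <- floor(px); fy <- floor(py)
  for (dx in seq.int(-hw + 1, hw)) {
    cx <- fx + dx
    wx <- .kb_kernel(px - cx, width, beta)
    for (dy in seq.int(-hw + 1, hw)) {
      cy <- fy + dy
      wy <- .kb_kernel(py - cy, width, beta)
      w <- wx * wy
      ok <- cx >= 1 & cx <= No & cy >= 1 & cy <= No & w > 0
      if (!any(ok)) next
      out[ok] <- out[ok] + w[ok] * grid[cbind(cx[ok], cy[ok])]
    }
  }
  out
}

# ---- forward simulation ------------------------------------------------

#' Simulate a non-Cartesian acquisition of a digital phantom
#'
#' Exact discrete Fourier summation per k-space sample with per-sample
#' off-resonance phase accrual (`exp(-i 2 pi df(r) t)`, `t` referenced
#' to the echo center). Deterministic given `seed`.
#'
#' @param phantom a [make_phantom()] object (or any list with `image`
#'   and `fov`).
#' @param trajs list of `ktrajectory` (one per shot), e.g. from
#'   [integrate_shots()].
#' @param b0 optional [make_b0_map()] object.
#' @param noise_sigma complex Gaussian noise sd, relative to the DC
#'   signal magnitude.
#' @param seed RNG seed for the noise.
#' @param chunk samples per DFT chunk (memory/time tradeoff).
#' @return a `kspace_data`: list with per-shot complex `samples`,
#'   `trajs`, `fov`.
#' @export
simulate_acquisition <- function(phantom, trajs, b0 = NULL,
                                 noise_sigma = 0, seed = 1L,
                                 chunk = 1024L) {
  img <- phantom$image
  fov <- phantom$fov
  N <- nrow(img)
  k_nyq <- N / (2 * fov)
  kmax_samp <- max(vapply(trajs, function(tr) max(sqrt(tr$kx^2 + tr$ky^2)),
                          0))
  if (kmax_samp > 2 * k_nyq)
    stop("trajectory extends beyond twice the grid Nyquist extent")
  nz <- which(img != 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    return(structure(list(samples = lapply(trajs, function(tr)
      complex(length(tr$kx))), trajs = trajs, fov = fov,
      noise_sigma = noise_sigma), class = "kspace_data"))
  }
  xr <- (nz[, 1] - 1 - N / 2) * fov / N
  yr <- (nz[, 2] - 1 - N / 2) * fov / N
  rho <- img[nz]
  fr <- if (!is.null(b0)) b0$field[nz] else NULL
  dc <- sum(abs(rho))
  samples <- vector("list", length(trajs))
  for (s in seq_along(trajs)) {
    tr <- trajs[[s]]
    M <- length(tr$kx)
    out <- complex(M)
    for (a in seq(1, M, by = chunk)) {
      b <- min(a + chunk - 1, M)
      P <- outer(tr$kx[a:b], xr) + outer(tr$ky[a:b], yr)
      if (!is.null(fr)) P <- P + outer(tr$times[a:b], fr)
      out[a:b] <- exp(-2i * pi * P) %*% rho
    }
    samples[[s]] <- out
  }
  if (noise_sigma > 0) {
    samples <- .with_seed(seed, lapply(samples, function(v)
      v + dc * noise_sigma *
        (stats::rnorm(length(v)) + 1i * stats::rnorm(length(v))) /
        sqrt(2)))
  }
  structure(list(samples = samples, trajs = trajs, fov = fov,
                 noise_sigma = noise_sigma), class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d shots x %d samples, fov=%.3g m\n",
              length(x$samples), length(x$samples[[1]]), x$fov))
  invisible(x)
}

# ---- density compensation ----------------------------------------------

#' Density compensation weights
#'
#' `method = "pipe_menon"`: fixed-point iteration `w <- w / (C w)` where
#' `C` is convolution with the gridding kernel over the sample cloud
#' (evaluated by gridding followed by degridding). Converged when the
#' maximum relative change is below `tol`; a warning reports the
#' residual otherwise. `method = "analytic_radial"` returns weights
#' proportional to the local radial speed `|k| |dk/dt|` (exact for
#' radially symmetric trajectories).
#'
#' @param trajs list of `ktrajectory`.
#' @param fov field of view (m) of the target grid.
#' @param N target grid size.
#' @param method weighting method.
#' @param n_iter maximum Pipe-Menon iterations (>= 1).
#' @param os,width,beta gridding kernel parameters.
#' @param tol convergence tolerance on the max relative change.
#' @return numeric vector of positive weights, one per sample
#'   (concatenated over shots), normalized to mean 1.
#' @export
compute_dcf <- function(trajs, fov, N, method = c("pipe_menon",
                                                  "analytic_radial"),
                        n_iter = 10L, os = 2, width = 6,
                        beta = .kb_beta(width, os), tol = 1e-3) {
  method <- match.arg(method)
  fl <- .flatten_traj(trajs)
  if (method == "analytic_radial") {
    r <- sqrt(fl$kx^2 + fl$ky^2)
    sp <- sqrt(diff(c(fl$kx[1], fl$kx))^2 + diff(c(fl$ky[1], fl$ky))^2)
    w <- pmax(r * sp, 1e-8 * max(r * sp))
    return(w / mean(w))
  }
  if (n_iter < 1) stop("'n_iter' must be >= 1")
  No <- 2L * as.integer(ceiling((os * N + 2 * width) / 2))
  os_eff <- No / N
  px <- fl$kx * fov * os_eff + No / 2 + 1
  py <- fl$ky * fov * os_eff + No / 2 + 1
  w <- rep(1, length(px))
  for (it in seq_len(n_iter)) {
    g <- .grid_adjoint(as.complex(w), px, py, No, width, beta)
    cw <- Re(.degrid(g, px, py, No, width, beta))
    cw[cw <= 0] <- min(cw[cw > 0])
    w_new <- w / cw
    change <- max(abs(w_new - w) / pmax(w, 1e-12))
    w <- w_new
    if (change < tol) break
  }
  if (change >= tol)
    warning(sprintf(
      "Pipe-Menon did not converge in %d iterations (residual %.2e)",
      n_iter, change))
  w / mean(w)
}

# ---- reconstruction ----------------------------------------------------

#' Grid-based image reconstruction with off-resonance correction
#'
#' Adjoint Kaiser-Bessel gridding of density-compensated data with 2x
#' oversampling and deapodization. With a B0 map, the readout is split
#' into `n_segments` time windows with raised-cosine temporal
#' interpolation weights; each segment is gridded separately and
#' combined after conjugate-phase demodulation at its center time.
#'
#' @param data a `kspace_data`.
#' @param trajs trajectory estimates used for gridding (need not be the
#'   true trajectories — reconstructing with mismatched trajectories is
#'   how trajectory errors become image artifacts).
#' @param dcf density compensation weights from [compute_dcf()].
#' @param b0 optional [make_b0_map()]; `NULL` disables correction.
#' @param n_segments number of time segments (>= 1).
#' @param N output grid size.
#' @param os,width kernel parameters.
#' @param tag provenance label stored on the image.
#' @return a `recon_image`: complex `image` (N x N), `fov`, `tag`.
#' @export
reconstruct <- function(data, trajs, dcf, b0 = NULL, n_segments = 8L,
                        N = NULL, os = 2, width = 6,
                        tag = "recon") {
  if (n_segments < 1) stop("'n_segments' must be >= 1")
  fov <- data$fov
  if (is.null(N)) {
    N <- if (!is.null(b0)) nrow(b0$field) else
      2L * as.integer(round(max(vapply(trajs, function(tr) tr$k_max, 0)) *
                              fov))
  }
  N <- as.integer(N); if (N %% 2L) N <- N + 1L
  beta <- .kb_beta(width, os)
  # margin of one kernel width so edge samples keep their full support
  No <- 2L * as.integer(ceiling((os * N + 2 * width) / 2))
  os_eff <- No / N
  fl <- .flatten_traj(trajs)
  val <- unlist(data$samples) * dcf
  if (length(val) != length(fl$kx))
    stop("dcf/data/trajectory sample counts differ")
  px <- fl$kx * fov * os_eff + No / 2 + 1
  py <- fl$ky * fov * os_eff + No / 2 + 1

  grid_to_img <- function(v) {
    g <- .grid_adjoint(v, px, py, No, width, beta)
    im <- .fftshift2(stats::fft(.fftshift2(g), inverse = TRUE)) / No^2
    ctr <- (No - N) / 2 + seq_len(N)
    im[ctr, ctr]
  }

  if (is.null(b0)) {
    img <- grid_to_img(val)
  } else if (n_segments == 1L) {
    img <- grid_to_img(val) * exp(2i * pi * b0$field * mean(range(fl$t)))
  } else {
    # linear temporal interpolation hats: an exact partition of unity,
    # so the correction is inert when the field map is zero
    tt <- fl$t
    tl <- seq(min(tt), max(tt), length.out = n_segments)
    dseg <- tl[2] - tl[1]
    img <- 0
    for (l in seq_len(n_segments)) {
      a <- pmax(0, 1 - abs(tt - tl[l]) / dseg)
      if (!any(a > 0)) next
      img <- img + grid_to_img(val * a) * exp(2i * pi * b0$field * tl[l])
    }
  }
  # deapodization: divide by the kernel's image-domain response
  xs <- (seq_len(N) - 1 - N / 2) / No
  dea <- .kb_ft(xs, width, beta)
  img <- img / outer(dea, dea)
  structure(list(image = img, fov = fov, N = N, tag = tag),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> '%s' %dx%d fov=%.3g m, max |I| = %.3g\n",
              x$tag, x$N, x$N, x$fov, max(abs(x$image))))
  invisible(x)
}

#' Normalized image error
#'
#' `RMS(|img - ref|) / max(|ref|)` plus a signed percent difference map
#' of the magnitudes. Invariant to a joint global phase rotation.
#'
#' @param img,ref `recon_image`s (or complex/numeric matrices) on the
#'   same grid.
#' @return list with `nrmse` and `diff_map` (percent of max |ref|).
#' @export
image_error <- function(img, ref) {
  a <- if (inherits(img, "recon_image")) img$image else img
  b <- if (inherits(ref, "recon_image")) ref$image else ref
  if (!all(dim(a) == dim(b))) stop("image grids differ")
  mx <- max(abs(b))
  if (mx == 0) stop("reference image is identically zero")
  list(nrmse = sqrt(mean(abs(a - b)^2)) / mx,
       diff_map = (abs(a) - abs(b)) / mx * 100)
}
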