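#' Diffusion encoding protocol
#'
#' Builds the b-matrix for a set of unit gradient directions and
#' b-values. Row `i` is
#' `[b gx^2, b gy^2, b gz^2, 2b gx gy, 2b gx gz, 2b gy gz]` so that
#' `log(S_i/S0) = -B_i . d` with `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param b b-values (s/mm^2), scalar or length-n; `b = 0` rows encode
#'   non-diffusion-weighted measurements.
#' @return a `diffusion_protocol` with `directions`, `b_values`, `B`.
#' @export
make_bmatrix <- function(directions, b = 1000) {
  directions <- rbind(directions)
  if (ncol(directions) != 3) stop("'directions' must be n x 3")
  n <- nrow(directions)
  b <- rep_len(b, n)
  nz <- b > 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[nz] - 1) > 1e-9))
    stop("diffusion directions must be unit vectors")
  g <- directions
  B <- cbind(b * g[, 1]^2, b * g[, 2]^2, b * g[, 3]^2,
             2 * b * g[, 1] * g[, 2], 2 * b * g[, 1] * g[, 3],
             2 * b * g[, 2] * g[, 3])
  identifiable <- sum(nz) >= 6 && qr(B[nz, , drop = FALSE])$rank >= 6
  if (sum(nz) >= 6 && !identifiable)
    stop("b-matrix rank < 6 over non-zero-b rows: tensor unidentifiable")
  structure(list(directions = g, b_values = b, B = B,
                 identifiable = identifiable),
            class = "diffusion_protocol")
}

#' Classic six-direction dual-gradient scheme plus one b=0
#'
#' @param b diffusion weighting (s/mm^2).
#' @return a `diffusion_protocol` with 7 rows (1 at b = 0).
#' @export
default_dti_protocol <- function(b = 1000) {
  s <- 1 / sqrt(2)
  g <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1)) * s
  make_bmatrix(rbind(c(0, 0, 0), g), b = c(0, rep(b, 6)))
}

#' Diffusion tensor phantom
#'
#' A deterministic 2D tensor field: isotropic background
#' (`0.7e-3 mm^2/s`), a C-shaped anisotropic "tract" following the arc
#' tangentially (eigenvalues `(1.7, 0.3, 0.3)e-3`), a straight oblique
#' tract, and a fluid-like isotropic blob (`2.0e-3`). `S0` follows the
#' geometry; background outside the support is zero.
#'
#' @param N grid size.
#' @param fov field of view (m).
#' @return a `tensor_field` with per-voxel `d` (N x N x 6 array,
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `S0`, `mask`.
#' @export
make_tensor_phantom <- function(N = 96, fov = 0.03) {
  x <- ((seq_len(N) - 1) - N / 2) / N * 2
  X <- matrix(x, N, N); Y <- t(X)
  R <- sqrt(X^2 + Y^2)
  d <- array(0, c(N, N, 6))
  S0 <- matrix(0, N, N)
  disk <- R <= 0.85
  iso <- 0.7e-3
  for (j in 1:3) d[, , j][disk] <- iso
  S0[disk] <- 1
  # C-shaped tangential tract
  arc <- R >= 0.45 & R <= 0.62 & !(X > 0 & abs(Y) < 0.18)
  lam <- c(1.7e-3, 0.3e-3)
  th <- atan2(Y, X) + pi / 2     # tangent direction
  exy <- cbind(cos(th)[arc], sin(th)[arc])
  d[, , 1][arc] <- lam[1] * exy[, 1]^2 + lam[2] * exy[, 2]^2
  d[, , 2][arc] <- lam[1] * exy[, 2]^2 + lam[2] * exy[, 1]^2
  d[, , 3][arc] <- lam[2]
  d[, , 4][arc] <- (lam[1] - lam[2]) * exy[, 1] * exy[, 2]
  S0[arc] <- 0.9
  # straight oblique tract
  bar <- abs(X * 0.7071 + Y * 0.7071) < 0.07 & R < 0.4
  e <- c(0.7071, -0.7071)
  d[, , 1][bar] <- lam[1] * e[1]^2 + lam[2] * e[2]^2
  d[, , 2][bar] <- lam[1] * e[2]^2 + lam[2] * e[1]^2
  d[, , 3][bar] <- lam[2]
  d[, , 4][bar] <- (lam[1] - lam[2]) * e[1] * e[2]
  S0[bar] <- 0.9
  # fluid blob
  blob <- (X - 0.28)^2 + (Y - 0.45)^2 <= 0.12^2
  for (j in 1:3) d[, , j][blob] <- 2.0e-3
  d[, , 4][blob] <- 0
  S0[blob] <- 1.4
  structure(list(d = d, S0 = S0, mask = S0 > 0, N = as.integer(N),
                 fov = fov), class = "tensor_field")
}

#' Closed-form diffusion-weighted signals from a tensor field
#'
#' Mono-exponential tensor model `S_i = S0 exp(-B_i . d)` per voxel,
#' with optional Rician noise (magnitude of complex Gaussian
#' perturbation).
#'
#' @param tensors a `tensor_field`.
#' @param protocol a [make_bmatrix()] protocol.
#' @param noise_sigma noise sd relative to the maximum S0.
#' @param seed RNG seed for the noise.
#' @return N x N x n array of signals.
#' @export
simulate_dwi <- function(tensors, protocol, noise_sigma = 0, seed = 1L) {
  N <- tensors$N
  n <- nrow(protocol$B)
  dmat <- matrix(tensors$d, ncol = 6)
  S <- array(0, c(N, N, n))
  for (i in seq_len(n)) {
    att <- exp(-as.numeric(dmat %*% protocol$B[i, ]))
    S[, , i] <- tensors$S0 * matrix(att, N, N)
  }
  if (noise_sigma > 0) {
    sd0 <- noise_sigma * max(tensors$S0)
    S <- .with_seed(seed, {
      nr <- array(stats::rnorm(length(S), 0, sd0), dim(S))
      ni <- array(stats::rnorm(length(S), 0, sd0), dim(S))
      sqrt((S + nr)^2 + ni^2)
    })
  }
  S
}

#' Weighted linear least squares tensor fit
#'
#' Two-pass fit of the log-linearized model
#' `log S = log S0 - B . d`: ordinary least squares first, then weighted
#' least squares with weights equal to the squared signals predicted by
#' the first pass. Voxels with any non-positive signal (or outside
#' `mask`) are flagged and excluded rather than failing the fit.
#'
#' @param signals N x N x n signal array.
#' @param protocol a `diffusion_protocol`.
#' @param mask optional logical N x N matrix of voxels to fit.
#' @return a `tensor_field` with fitted `d`, `S0` and `mask` (fitted
#'   voxels).
#' @export
fit_wlls <- function(signals, protocol, mask = NULL) {
  dm <- dim(signals)
  N <- dm[1]; n <- dm[3]
  if (nrow(protocol$B) != n) stop("protocol/signal count mismatch")
  if (!isTRUE(protocol$identifiable))
    stop("protocol cannot identify the tensor (needs >= 6 independent non-zero-b directions)")
  S <- matrix(signals, ncol = n)
  ok <- rowSums(S <= 0) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  X <- cbind(1, -protocol$B)
  d <- matrix(0, nrow(S), 6)
  S0 <- numeric(nrow(S))
  idx <- which(ok)
  if (length(idx)) {
    Y <- log(S[idx, , drop = FALSE])
    # pass 1: OLS, shared design
    beta <- t(solve(crossprod(X), crossprod(X, t(Y))))
    # pass 2: per-voxel weights = predicted signal squared
    for (v in seq_along(idx)) {
      w <- exp(2 * as.numeric(X %*% beta[v, ]))
      Xw <- X * w
      beta[v, ] <- solve(crossprod(Xw, X), crossprod(Xw, Y[v, ]))
    }
    S0[idx] <- exp(beta[, 1])
    d[idx, ] <- beta[, -1]
  }
  structure(list(d = array(d, c(N, N, 6)), S0 = matrix(S0, N, N),
                 mask = matrix(ok, N, N), N = as.integer(N),
                 fov = attr(signals, "fov")), class = "tensor_field")
}

# analytic eigenvalues of symmetric 3x3 tensors, vectorized (descending)
.eig3_sym <- function(dmat) {
  a <- dmat[, 1]; b <- dmat[, 2]; c <- dmat[, 3]
  de <- dmat[, 4]; f <- dmat[, 5]; g <- dmat[, 6]
  p1 <- de^2 + f^2 + g^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  r <- numeric(length(a))
  nz <- p > 0
  if (any(nz)) {
    # r = det((D - qI)/p) / 2, clamped to [-1, 1]; only defined where
    # the deviatoric part is non-zero
    ps <- ifelse(nz, p, 1)
    aa <- (a - q) / ps; bb <- (b - q) / ps; cc <- (c - q) / ps
    dd <- de / ps; ff <- f / ps; gg <- g / ps
    detB <- aa * (bb * cc - gg^2) - dd * (dd * cc - gg * ff) +
      ff * (dd * gg - bb * ff)
    r[nz] <- pmin(pmax(detB[nz] / 2, -1), 1)
  }
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  cbind(l1, l2, l3)
}

#' Scalar diffusion maps from a tensor field
#'
#' Eigenvalue-based summaries: `MD = (l1+l2+l3)/3`,
#' `FA = sqrt(3/2) ||l - MD|| / ||l||` (0 for an all-zero tensor,
#' clamped to \[0, 1\]), `RD = (l2+l3)/2`, `AD = l1`. Eigenvalues are
#' clamped at zero before the metrics; the fraction of voxels with any
#' negative eigenvalue is reported as `negative_fraction` (a QC
#' number).
#'
#' @param tensors a `tensor_field`.
#' @return a `parameter_maps` object: `MD`, `FA`, `RD`, `AD` matrices
#'   (units of `d`), `mask`, `negative_fraction`.
#' @export
tensor_metrics <- function(tensors) {
  N <- tensors$N
  dmat <- matrix(tensors$d, ncol = 6)
  ev <- .eig3_sym(dmat)
  negfrac <- mean(rowSums(ev < 0)[as.vector(tensors$mask)] > 0)
  ev[ev < 0] <- 0
  md <- rowMeans(ev)
  nl <- sqrt(rowSums(ev^2))
  dev <- ev - md
  fa <- ifelse(nl > 0, sqrt(1.5 * rowSums(dev^2)) / nl, 0)
  fa <- pmin(pmax(fa, 0), 1)
  mk <- function(v) matrix(v, N, N)
  structure(list(MD = mk(md), FA = mk(fa), RD = mk((ev[, 2] + ev[, 3]) / 2),
                 AD = mk(ev[, 1]), mask = tensors$mask,
                 negative_fraction = negfrac, N = N),
            class = "parameter_maps")
}

#' Cross-reconstruction parameter correlation
#'
#' Pearson correlation of each scalar map between two reconstructions,
#' over voxels where both FA maps exceed `threshold` (and both masks
#' hold). Errors if fewer than 10 voxels survive.
#'
#' @param maps_a,maps_b `parameter_maps` on the same grid.
#' @param threshold FA threshold applied to both maps.
#' @return list with `r` (named correlations for MD/FA/RD/AD) and `n`
#'   (voxels used).
#' @export
parameter_correlation <- function(maps_a, maps_b, threshold = 0.05) {
  if (!all(dim(maps_a$FA) == dim(maps_b$FA))) stop("map grids differ")
  sel <- maps_a$mask & maps_b$mask & maps_a$FA > threshold &
    maps_b$FA > threshold
  if (sum(sel) < 10)
    stop("fewer than 10 voxels above the FA threshold")
  r <- vapply(c("MD", "FA", "RD", "AD"), function(p)
    stats::cor(maps_a[[p]][sel], maps_b[[p]][sel]), 0)
  list(r = r, n = sum(sel))
}
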