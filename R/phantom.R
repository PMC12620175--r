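#' Digital phantoms
#'
#' Deterministic analytic phantoms on an `N x N` grid. Kinds:
#' `"brick"` — a gel disk containing a rectangular plastic-brick
#' inclusion with a row of studs (low signal); `"brain_like"` — an
#' ellipse with ventricle-like hypointense lobes and a few focal
#' features; `"point"` — a single unit voxel at the grid center;
#' `"shepp_like"` — a small set of nested ellipses.
#'
#' @param kind phantom type.
#' @param N grid size (>= 32).
#' @param fov field of view (m).
#' @return a `digital_phantom`: list with `image` (N x N, real),
#'   `labels` (integer region mask), `fov`, `N`.
#' @export
make_phantom <- function(kind = c("brick", "brain_like", "point",
                                  "shepp_like"), N = 96, fov = 0.03) {
  kind <- match.arg(kind)
  if (N < 32) stop("'N' must be at least 32")
  x <- ((seq_len(N) - 1) - N / 2) / N * 2   # normalized [-1, 1)
  X <- matrix(x, N, N); Y <- t(X)
  img <- matrix(0, N, N)
  lab <- matrix(0L, N, N)
  ell <- function(cx, cy, rx, ry, ang = 0) {
    xr <- (X - cx) * cos(ang) + (Y - cy) * sin(ang)
    yr <- -(X - cx) * sin(ang) + (Y - cy) * cos(ang)
    (xr / rx)^2 + (yr / ry)^2 <= 1
  }
  if (kind == "point") {
    img[N / 2 + 1, N / 2 + 1] <- 1
    lab[N / 2 + 1, N / 2 + 1] <- 1L
  } else if (kind == "brick") {
    disk <- ell(0, 0, 0.84, 0.84)
    img[disk] <- 1; lab[disk] <- 1L
    brick <- abs(X - 0.05) < 0.46 & abs(Y + 0.08) < 0.24
    img[brick] <- 0.35; lab[brick] <- 2L
    for (cx in c(-0.25, -0.05, 0.15, 0.35)) {
      st <- ell(cx, 0.28, 0.055, 0.055)
      img[st] <- 0.55; lab[st] <- 3L
    }
  } else if (kind == "brain_like") {
    outer <- ell(0, 0, 0.82, 0.68, 0.1)
    img[outer] <- 1; lab[outer] <- 1L
    inner <- ell(0, 0, 0.72, 0.58, 0.1)
    img[inner] <- 0.82; lab[inner] <- 2L
    for (s in c(-1, 1)) {
      v <- ell(0.16 * s, -0.05, 0.10, 0.26, -0.25 * s)
      img[v] <- 0.35; lab[v] <- 3L
    }
    f1 <- ell(-0.38, 0.25, 0.09, 0.09); img[f1] <- 1.15; lab[f1] <- 4L
    f2 <- ell(0.35, -0.35, 0.07, 0.07); img[f2] <- 0.55; lab[f2] <- 4L
    f3 <- ell(0.32, 0.33, 0.06, 0.1); img[f3] <- 1.25; lab[f3] <- 4L
  } else { # shepp_like
    a <- ell(0, 0, 0.85, 0.7); img[a] <- 1; lab[a] <- 1L
    b <- ell(0, 0, 0.78, 0.62); img[b] <- 0.6; lab[b] <- 2L
    c1 <- ell(-0.25, 0, 0.14, 0.3, 0.3); img[c1] <- 0.25; lab[c1] <- 3L
    c2 <- ell(0.25, 0, 0.14, 0.3, -0.3); img[c2] <- 0.25; lab[c2] <- 3L
    d <- ell(0, 0.35, 0.1, 0.1); img[d] <- 1.2; lab[d] <- 4L
  }
  structure(list(image = img, labels = lab, fov = fov, N = as.integer(N),
                 kind = kind), class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %s %dx%d fov=%.3g m, %d non-zero voxels\n",
              x$kind, x$N, x$N, x$fov, sum(x$image != 0)))
  invisible(x)
}

#' Smooth off-resonance (B0) field map
#'
#' A deterministic smooth field: two Gaussian lobes plus a linear ramp,
#' rescaled so the maximum |off-resonance| equals `max_hz`. Emulates the
#' slowly varying susceptibility-induced B0 field of a phantom/brain at
#' a known level; not derived from data.
#'
#' @param N grid size.
#' @param fov field of view (m).
#' @param max_hz peak absolute off-resonance (Hz).
#' @return a `b0_map`: list with `field` (Hz, N x N), `fov`.
#' @export
make_b0_map <- function(N = 96, fov = 0.03, max_hz = 150) {
  x <- ((seq_len(N) - 1) - N / 2) / N * 2
  X <- matrix(x, N, N); Y <- t(X)
  f <- 1.1 * exp(-((X - 0.25)^2 + (Y - 0.2)^2) / 0.18) -
    0.8 * exp(-((X + 0.3)^2 + (Y + 0.25)^2) / 0.3) + 0.25 * Y
  f <- f / max(abs(f)) * max_hz
  structure(list(field = f, fov = fov, N = as.integer(N),
                 max_hz = max_hz), class = "b0_map")
}
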