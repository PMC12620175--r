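recon_fixture <- function() memo("reconfix", {
  sp <- make_spiral_inout(12, fov = 0.03, resolution = 6.25e-4,
                          max_grad = 200, slew_limit = 4800)
  trajs <- lapply(integrate_shots(sp), traj_window, sp$core_range)
  dcf <- suppressWarnings(compute_dcf(trajs, fov = 0.03, N = 48,
                                      n_iter = 20))
  list(sp = sp, trajs = trajs, dcf = dcf)
})

test_that("phantoms are deterministic with the advertised structure", {
  p1 <- make_phantom("brick", N = 48)
  p2 <- make_phantom("brick", N = 48)
  expect_identical(p1$image, p2$image)
  expect_equal(sum(make_phantom("point", N = 48)$image), 1)
  expect_true(any(p1$labels == 2L))           # brick inclusion present
  expect_lt(mean(p1$image[p1$labels == 2L]), 1)
  expect_error(make_phantom("cube", N = 48), "arg")
  expect_error(make_phantom("brick", N = 16), "at least 32")
  b0 <- make_b0_map(N = 48, max_hz = 150)
  expect_equal(max(abs(b0$field)), 150)
})

test_that("acquisition obeys basic Fourier facts", {
  fx <- recon_fixture()
  ph <- make_phantom("point", N = 48, fov = 0.03)
  dat <- simulate_acquisition(ph, fx$trajs)
  expect_equal(range(abs(unlist(dat$samples))), c(1, 1))
  zero <- ph; zero$image[] <- 0
  expect_true(all(unlist(simulate_acquisition(zero,
                                              fx$trajs)$samples) == 0))
  # Fourier shift theorem oracle, checked per sample
  sh <- ph; sh$image[] <- 0; sh$image[48 / 2 + 1 + 5, 48 / 2 + 1] <- 1
  dat2 <- simulate_acquisition(sh, fx$trajs)
  dx <- 5 * 0.03 / 48
  kx <- unlist(lapply(fx$trajs, `[[`, "kx"))
  expect_lt(max(abs(unlist(dat2$samples) -
                      unlist(dat$samples) * exp(-2i * pi * kx * dx))),
            1e-9)
  # trajectories beyond the oversampled grid extent are rejected
  big <- fx$trajs
  big[[1]]$kx <- big[[1]]$kx * 5
  expect_error(simulate_acquisition(ph, big), "Nyquist")
})

test_that("Pipe-Menon weights are a positive uniform-density fixed point", {
  N <- 20; fov <- 0.03
  g <- ((-(N / 2)):(N / 2 - 1)) / fov
  tr <- list(structure(list(kx = rep(g, each = N), ky = rep(g, N),
                            times = numeric(N^2), k_max = max(abs(g)),
                            dt = 4e-6, normalized = FALSE),
                       class = "ktrajectory"))
  w <- compute_dcf(tr, fov = fov, N = N, n_iter = 10)
  expect_true(all(w > 0))
  interior <- rep(abs(g) < 0.7 * max(abs(g)), each = N) &
    rep(abs(g) < 0.7 * max(abs(g)), N)
  expect_lt(stats::sd(w[interior]) / mean(w[interior]), 0.01)
  expect_error(compute_dcf(tr, fov = fov, N = N, n_iter = 0), "n_iter")
  # one fixed-point sweep is scale invariant: starting from 2w gives
  # the same result as starting from w
  No <- 2L * as.integer(ceiling((2 * N + 12) / 2))
  beta <- gradnet:::.kb_beta(6, 2)
  px <- tr[[1]]$kx * fov * (No / N) + No / 2 + 1
  py <- tr[[1]]$ky * fov * (No / N) + No / 2 + 1
  cw <- function(w0) {
    g <- gradnet:::.grid_adjoint(as.complex(w0), px, py, No, 6, beta)
    w0 / Re(gradnet:::.degrid(g, px, py, No, 6, beta))
  }
  expect_equal(cw(rep(1, N^2)), cw(rep(2, N^2)), tolerance = 1e-12)
})

test_that("the PSF of an exact recon peaks sharply at the point source", {
  fx <- recon_fixture()
  ph <- make_phantom("point", N = 48, fov = 0.03)
  dat <- simulate_acquisition(ph, fx$trajs)
  rec <- reconstruct(dat, fx$trajs, fx$dcf, N = 48)
  a <- abs(rec$image)
  pk <- which(a == max(a), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(25, 25))
  a[pk[1] + (-2:2), pk[2] + (-2:2)] <- 0
  expect_gt(max(abs(rec$image)) / max(a), 10)
})

test_that("trajectory errors degrade the image; the true path wins", {
  fx <- recon_fixture()
  ph <- make_phantom("brick", N = 48, fov = 0.03)
  sys <- gradient_system()
  t_echo <- (fx$sp$echo_index - 1) * fx$sp$dt
  trajm <- lapply(fx$sp$shots, function(s) {
    mx <- simulate_measurement(sys, s$gx, add_noise = FALSE)
    my <- simulate_measurement(sys, s$gy, add_noise = FALSE)
    traj_window(integrate_gradients(mx, my, k_max = fx$sp$k_max,
                                    t_echo = t_echo),
                fx$sp$core_range)
  })
  dat <- simulate_acquisition(ph, trajm)
  recT <- reconstruct(dat, trajm, fx$dcf, N = 48)
  recN <- reconstruct(dat, fx$trajs, fx$dcf, N = 48)
  nr <- function(r) {
    a <- abs(r$image) / max(abs(r$image))
    sqrt(mean((a - ph$image / max(ph$image))^2))
  }
  expect_lt(nr(recT), nr(recN))
})

test_that("time segmentation is inert without off-resonance", {
  fx <- recon_fixture()
  ph <- make_phantom("brick", N = 48, fov = 0.03)
  dat <- simulate_acquisition(ph, fx$trajs)
  b00 <- make_b0_map(N = 48, fov = 0.03)
  b00$field[] <- 0
  r1 <- reconstruct(dat, fx$trajs, fx$dcf, b0 = b00, n_segments = 1,
                    N = 48)
  r8 <- reconstruct(dat, fx$trajs, fx$dcf, b0 = b00, n_segments = 8,
                    N = 48)
  expect_lt(max(abs(r1$image - r8$image)) / max(abs(r1$image)), 1e-8)
  expect_error(reconstruct(dat, fx$trajs, fx$dcf, n_segments = 0,
                           N = 48), "n_segments")
})

test_that("off-resonance correction recovers the rosette image", {
  ro <- make_rosette(12, 5, 0.03, 6.25e-4, 5e-3)
  trajs <- lapply(integrate_shots(ro), traj_window, ro$core_range)
  dcf <- suppressWarnings(compute_dcf(trajs, fov = 0.03, N = 48,
                                      n_iter = 20))
  ph <- make_phantom("brick", N = 48, fov = 0.03)
  ref <- reconstruct(simulate_acquisition(ph, trajs), trajs, dcf,
                     N = 48)
  b0 <- make_b0_map(N = 48, fov = 0.03, max_hz = 150)
  datb <- simulate_acquisition(ph, trajs, b0 = b0)
  un <- reconstruct(datb, trajs, dcf, N = 48)
  co <- reconstruct(datb, trajs, dcf, b0 = b0, n_segments = 8, N = 48)
  expect_lt(image_error(co, ref)$nrmse, image_error(un, ref)$nrmse)
})

test_that("image error has its closed form and phase invariance", {
  set.seed(2)
  a <- matrix(complex(real = stats::rnorm(64), imaginary =
                        stats::rnorm(64)), 8)
  expect_equal(image_error(a, a)$nrmse, 0)
  expect_equal(image_error(a + 0.3, a)$nrmse, 0.3 / max(abs(a)))
  ph <- exp(1i * 1.1)
  expect_equal(image_error(ph * (a + 0.3), ph * a)$nrmse,
               image_error(a + 0.3, a)$nrmse, tolerance = 1e-12)
  expect_error(image_error(a, a * 0), "zero")
  expect_error(image_error(a[1:4, ], a), "differ")
})
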