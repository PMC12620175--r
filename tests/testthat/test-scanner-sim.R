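test_that("the linear stage is linear, causal, and delays exactly", {
  sys <- gradient_system_lti()
  w1 <- make_trapezoid(100, 4e-4, 1.2e-4)
  w2 <- make_multisine(c(500, 1500), c(80, 40),
                       length(w1$samples) * w1$dt)
  expect_true(all(apply_linear_response(sys, gradient_waveform(
    numeric(64) + c(0, rep(0, 62), 0), 4e-6))$samples == 0))
  # superposition to 1e-10 relative
  y1 <- apply_linear_response(sys, w1)$samples
  y2 <- apply_linear_response(sys, w2)$samples
  wc <- gradient_waveform(2.5 * w1$samples - 0.7 * w2$samples, w1$dt)
  yc <- apply_linear_response(sys, wc)$samples
  expect_lt(max(abs(yc - (2.5 * y1 - 0.7 * y2))),
            1e-10 * max(abs(yc)))
  # pure-delay configuration: output is the input shifted 5 samples
  dsys <- gradient_system(group_delay = 5 * 4e-6, lowpass_cutoff = Inf,
                          eddy_terms = list(), deadzone = 0,
                          gain_slope = 0, delay_slope = 0,
                          slew_limit = Inf, noise_sigma = 0)
  yd <- apply_linear_response(dsys, w1)$samples
  expect_equal(yd, c(numeric(5),
                     w1$samples[1:(length(w1$samples) - 5)]))
})

test_that("crossover distortion is an odd dead zone", {
  sys <- gradient_system(deadzone = 2)
  mk <- function(v) gradient_waveform(c(0, v, 0), 4e-6)
  expect_equal(apply_crossover_distortion(sys, mk(1))$samples[2], 0)
  expect_equal(apply_crossover_distortion(sys, mk(50))$samples[2], 48)
  set.seed(3)
  x <- stats::rnorm(200, 0, 10)
  w <- gradient_waveform(x, 4e-6)
  wm <- gradient_waveform(-x, 4e-6)
  expect_equal(apply_crossover_distortion(sys, wm)$samples,
               -apply_crossover_distortion(sys, w)$samples)
  id <- gradient_system(deadzone = 0)
  expect_equal(apply_crossover_distortion(id, w)$samples, x)
})

test_that("amplitude dependence weakens and delays low-amplitude pulses", {
  sys <- gradient_system(gain_slope = 0.05, delay_slope = 0)
  w <- make_trapezoid(385, 4e-4, 1.2e-4)  # A = A_sys/2
  y <- apply_amplitude_dependence(sys, w)
  expect_equal(max(y$samples) / max(w$samples), 1 - 0.05 * 0.5,
               tolerance = 1e-12)
  w7 <- make_trapezoid(770, 4e-4, 1.6e-4)
  expect_equal(apply_amplitude_dependence(sys, w7)$samples, w7$samples)
  expect_error(apply_amplitude_dependence(
    sys, gradient_waveform(c(0, 0, 0), 4e-6, amp_scale = 0)),
    "non-zero")
  # cross-correlation lag oracle: delay decreases monotonically in |A|
  dsys <- gradient_system(gain_slope = 0, delay_slope = 16e-6)
  ms <- make_multisine(c(800, 2100), c(500, 260), 2e-3)
  lags <- vapply(c(100, 300, 500, 700), function(A) {
    wa <- scale_to_amplitudes(ms, A)[[1]]
    ya <- apply_amplitude_dependence(dsys, wa)$samples
    cc <- vapply(0:8, function(l) sum(ya * gradnet:::.delay_samples(
      wa$samples, l)), 0)
    lag0 <- which.max(cc) - 1
    # parabolic refinement around the integer peak
    if (lag0 >= 1 && lag0 <= 7) {
      y3 <- cc[lag0:(lag0 + 2)]
      lag0 - 1 + (y3[1] - y3[3]) / (2 * (y3[1] - 2 * y3[2] + y3[3])) + 1
    } else lag0
  }, 0)
  expect_true(all(diff(lags) < 0))
})

test_that("the slew limiter clips exactly at the configured rate", {
  sys <- gradient_system(slew_limit = 1000)
  ok <- make_trapezoid(100, 4e-4, 2e-3)  # slew 50 << 1000
  expect_identical(apply_slew_limit(sys, ok)$samples, ok$samples)
  step <- gradient_waveform(c(0, rep(40, 60)), 4e-6)
  y <- apply_slew_limit(sys, step)$samples
  # closed-form ramp oracle: rises by slew*dt per sample until the step
  per <- 1000 * 4e-6 * 1e3
  expect_equal(y[1:10], pmin(per * (0:9), 40))
  expect_lte(max(abs(diff(y))) / 4e-6 * 1e-3, 1000 + 1e-9)
})

test_that("the measurement chain collapses, repeats, and adds noise", {
  lin <- gradient_system_lti()
  w <- make_trapezoid(300, 4e-4, 1.2e-4)
  expect_equal(simulate_measurement(lin, w, add_noise = FALSE)$samples,
               apply_linear_response(lin, w)$samples)
  sys <- gradient_system(rng_seed = 42)
  a <- simulate_measurement(sys, w, noise_stream = 3)
  b <- simulate_measurement(sys, w, noise_stream = 3)
  expect_identical(a$samples, b$samples)
  # Monte-Carlo estimate of the stated sigma on a long zero waveform
  z <- gradient_waveform(numeric(1e5), 4e-6)
  nz <- simulate_measurement(sys, z, add_noise = TRUE)$samples
  expect_equal(stats::sd(nz), 0.05, tolerance = 0.05)
  # settling window lengthens the measurement
  m <- simulate_measurement(sys, w, add_noise = FALSE,
                            settle_pad = 1e-3)
  expect_equal(length(m$samples), length(w$samples) + 250)
})

test_that("the simulator is causal and passive", {
  sys <- gradient_system()
  w <- make_multisine(c(600, 1700), c(400, 150), 2e-3)
  y0 <- simulate_measurement(sys, w, add_noise = FALSE)$samples
  # perturb a late, non-peak sample; earlier outputs must not change
  j <- round(length(w$samples) * 0.7)
  w2 <- w
  w2$samples[j] <- w2$samples[j] + 0.5
  y1 <- simulate_measurement(sys, gradient_waveform(
    w2$samples, w$dt, amp_scale = w$amp_scale), add_noise = FALSE)$samples
  expect_equal(y1[1:(j - 1)], y0[1:(j - 1)])
  expect_false(isTRUE(all.equal(y1[j:length(y1)], y0[j:length(y0)])))
  # energy: gain <= 1 stages keep the output near or below the input peak
  expect_lte(max(abs(y0)), 1.02 * max(abs(w$samples)))
})

test_that("the LTI limit satisfies scaling to numerical precision", {
  lti <- gradient_system_lti()
  w <- make_chirp(700, 3e3, 1.2e-3, 300, 4500)
  y <- simulate_measurement(lti, w, add_noise = FALSE)$samples
  w3 <- gradient_waveform(3 * w$samples, w$dt)
  y3 <- simulate_measurement(lti, w3, add_noise = FALSE)$samples
  expect_lt(max(abs(y3 - 3 * y)), 1e-10 * max(abs(y3)))
})
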