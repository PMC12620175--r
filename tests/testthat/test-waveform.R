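test_that("trapezoid geometry and area match the analytic form", {
  w <- make_trapezoid(100, 1e-3, 1e-4, dt = 4e-6)
  expect_equal(waveform_area(w), 1.1e-4, tolerance = 1e-9)
  expect_equal(w$samples[1], 0)
  expect_equal(utils::tail(w$samples, 1), 0)
  expect_equal(max(w$samples), 100)
  # zero plateau degenerates to a triangle of the requested peak
  tri <- make_trapezoid(250, 0, 2e-4, dt = 4e-6)
  expect_equal(max(abs(tri$samples)), 250)
  expect_equal(sum(tri$samples == 250), 1)
  # zero amplitude gives the zero waveform
  z <- make_trapezoid(0, 1e-3, 1e-4, dt = 4e-6)
  expect_true(all(z$samples == 0))
  expect_error(make_trapezoid(100, -1e-3, 1e-4), "non-negative")
  expect_error(make_trapezoid(100, 1e-3, 1e-6, dt = 4e-6), "at least dt")
})

test_that("triangle trains alternate sign with the designed slew", {
  tr <- make_triangle_train(300, 2, 2e-4, dt = 4e-6)
  expect_equal(sum(tr$samples), 0, tolerance = 1e-12)
  one <- make_triangle_train(300, 1, 2e-4, dt = 4e-6)
  expect_equal(max(abs(one$samples)), 300)
  # numeric slew equals peak/ramp_dur (finite-difference oracle)
  expect_equal(waveform_slew(tr), 300e-3 / 2e-4, tolerance = 1e-9)
  expect_error(make_triangle_train(300, 0, 2e-4), ">= 1")
})

test_that("chirps start at zero and respect the slew limit", {
  ch <- make_chirp(0, 15e3, 10e-3, 300, 5270, dt = 4e-6)
  expect_equal(ch$samples[1], 0)
  # finite-difference oracle over every sample
  expect_lte(waveform_slew(ch), 5270)
  expect_true(all(make_chirp(0, 5e3, 2e-3, 0, 5000)$samples == 0))
  expect_error(make_chirp(0, 2e5, 1e-3, 100, 5000, dt = 4e-6), "Nyquist")
  expect_error(make_chirp(5e3, 1e3, 1e-3, 100, 5000), "f_start")
})

test_that("multisine spectra and cancellations behave", {
  f0 <- 2e3
  ms <- make_multisine(f0, 100, 4e-3, dt = 4e-6, taper_dur = 1e-4)
  # discrete Fourier transform oracle: spectral peak at the tone
  sp <- Mod(stats::fft(ms$samples))
  n <- length(ms$samples)
  freqs <- (seq_len(n) - 1) / (n * ms$dt)
  half <- freqs < 1 / (2 * ms$dt)
  expect_equal(freqs[half][which.max(sp[half])], f0, tolerance = 0.05)
  # exact cancellation of two opposite tones
  z <- make_multisine(c(1e3, 1e3), c(50, -50), 1e-3)
  expect_true(all(z$samples == 0))
  expect_true(all(make_multisine(c(1e3), c(0), 1e-3)$samples == 0))
  expect_error(make_multisine(numeric(0), numeric(0), 1e-3), "non-empty")
  expect_error(make_multisine(c(1e3, 2e3), c(1), 1e-3), "equal length")
})

test_that("amplitude rescaling is exact, signed, and bounded", {
  w <- make_trapezoid(100, 4e-4, 1e-4)
  same <- scale_to_amplitudes(w, 100)[[1]]
  expect_equal(same$samples, w$samples)
  flip <- scale_to_amplitudes(w, -100)[[1]]
  expect_equal(flip$samples, -w$samples)
  amps <- seq(70, 700, length.out = 15)
  expect_equal(unique(round(diff(amps), 9)), 45)
  out <- scale_to_amplitudes(w, amps)
  expect_equal(vapply(out, function(x) max(abs(x$samples)), 0), amps)
  expect_error(scale_to_amplitudes(w, 0), "non-zero")
  expect_warning(scale_to_amplitudes(w, 900), "maximum")
})

test_that("waveform invariants are enforced by the constructor", {
  expect_error(gradient_waveform(c(0, 1, 2), 4e-6, amp_scale = 5),
               "amp_scale")
  expect_error(gradient_waveform(c(0, NA, 1), 4e-6), "finite")
  expect_error(gradient_waveform(c(0, 1), 0), "positive")
  expect_error(gradient_waveform(1, 4e-6), "length")
  w <- pad_waveform(make_trapezoid(100, 4e-4, 1e-4), 1e-3)
  expect_equal(length(w$samples),
               length(make_trapezoid(100, 4e-4, 1e-4)$samples) + 250)
})

test_that("every default-library waveform is physical", {
  lib <- full_library()
  rx <- library_subset(lib, axis = "x")$records
  starts <- vapply(rx, function(r) r$waveform$samples[1], 0)
  ends <- vapply(rx, function(r) utils::tail(r$waveform$samples, 1), 0)
  expect_true(all(starts == 0) && all(ends == 0))
  slews <- vapply(rx, function(r) waveform_slew(r$waveform), 0)
  expect_true(all(slews <= 0.95 * 5274))
  peaks <- vapply(rx, function(r) max(abs(r$waveform$samples)), 0)
  amps <- vapply(rx, function(r) abs(r$amplitude), 0)
  expect_equal(peaks, amps, tolerance = 1e-9)
})
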