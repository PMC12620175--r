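test_that("configuration hashes are canonical under key order", {
  a <- list(x = 1, y = list(b = 2, a = 3), z = "s")
  b <- list(z = "s", x = 1, y = list(a = 3, b = 2))
  expect_identical(gradnet:::.config_hash(a), gradnet:::.config_hash(b))
  expect_false(identical(gradnet:::.config_hash(a),
                         gradnet:::.config_hash(c(a, list(w = 1)))))
})

test_that("an identity gradient system makes all recon variants agree", {
  sys <- gradient_system(group_delay = 0, lowpass_cutoff = Inf,
                         eddy_terms = list(), deadzone = 0,
                         gain_slope = 0, delay_slope = 0,
                         slew_limit = Inf, noise_sigma = 0)
  # measurement is exactly the nominal waveform
  w <- make_trapezoid(300, 4e-4, 1.2e-4)
  expect_equal(simulate_measurement(sys, w)$samples, w$samples)
  sp <- make_spiral_inout(12, 0.03, 6.25e-4, max_grad = 200,
                          slew_limit = 4800)
  pairs <- list()
  for (m in 1:4) {
    sh <- sp$shots[[m]]
    pairs[[2 * m - 1]] <- list(nominal = sh$gx,
                               measured = simulate_measurement(sys,
                                                               sh$gx))
    gy <- sh$gy; gy$axis <- "x"
    pairs[[2 * m]] <- list(nominal = gy,
                           measured = simulate_measurement(sys, gy))
  }
  # broad spectral coverage plus negligible regularization keeps the
  # estimator exact on the identity system
  g <- estimate_girf(c(identity_pairs(), pairs), lambda = 1e-12)
  tcn <- train_model(build_tcn(tcn_config(channels = 6, dropout = 0),
                               seed = 4),
                     build_windows(pairs),
                     training_config(epochs = 2, seed = 9))
  # the TCN sees zero residual and stays at the identity map
  expect_equal(utils::tail(tcn$loss_trace, 1), 0)
  t_echo <- (sp$echo_index - 1) * sp$dt
  tr_of <- function(fun) lapply(sp$shots[1:6], function(sh) {
    gx <- fun(sh$gx)
    gy0 <- sh$gy; gy0$axis <- "x"
    gy <- fun(gy0)
    traj_window(integrate_gradients(gx, gy, k_max = sp$k_max,
                                    t_echo = t_echo), sp$core_range)
  })
  trajs <- list(measured = tr_of(function(w) simulate_measurement(sys,
                                                                  w)),
                nominal = tr_of(identity),
                girf = tr_of(function(w) predict_with_girf(g, w)),
                tcn = tr_of(function(w) predict_waveform(tcn, w)))
  ph <- make_phantom("brick", N = 48, fov = 0.03)
  dat <- simulate_acquisition(ph, trajs$measured)
  dcf <- suppressWarnings(compute_dcf(trajs$measured, fov = 0.03,
                                      N = 48, n_iter = 15))
  ref <- reconstruct(dat, trajs$measured, dcf, N = 48)
  for (v in c("nominal", "girf", "tcn")) {
    rec <- reconstruct(dat, trajs[[v]], dcf, N = 48)
    expect_lt(image_error(rec, ref)$nrmse, 1e-6)
  }
})

test_that("the waveform stage emits a complete report", {
  cfg <- default_experiment_config(seed = 5)
  cfg$axes <- "x"
  cfg$training$epochs <- 1
  rep <- run_experiment(cfg, stages = "waveforms", verbose = FALSE)
  expect_true(is.character(rep$config_hash))
  expect_named(rep$waveform_nrmse$x,
               c("nominal", "girf", "tcn", "final_train_loss"))
  expect_lt(rep$waveform_nrmse$x$girf, rep$waveform_nrmse$x$nominal)
})

test_that("TCN stays within a factor of five of the GIRF on an LTI system", {
  lib <- full_library()
  sim <- simulate_library(gradient_system_lti(), lib, add_noise = FALSE)
  tr <- gradnet:::.library_pairs(sim, "x", "train")
  g <- estimate_girf(tr)
  girf_nr <- mean_val_nrmse(sim, "x",
                            function(w) predict_with_girf(g, w))
  tcn <- train_model(build_tcn(tcn_config(channels = 8, dropout = 0),
                               seed = 12),
                     build_windows(tr),
                     training_config(epochs = 30, seed = 13))
  tcn_nr <- mean_val_nrmse(sim, "x",
                           function(w) predict_waveform(tcn, w))
  # the linear estimator is near-exact in its own regime; the network
  # only has to stay in its neighborhood, not beat it
  expect_lt(tcn_nr, 5 * girf_nr)
})
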