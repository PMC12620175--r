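test_that("configuration and receptive field follow the closed form", {
  cfg <- tcn_config()   # paper architecture: 5 blocks, k = 16
  expect_equal(receptive_field(cfg),
               1 + 2 * (16 - 1) * (2^5 - 1))
  expect_equal(receptive_field(tcn_config(n_blocks = 2,
                                          kernel_size = 3)), 13)
  expect_error(tcn_config(n_blocks = 0), "n_blocks")
  expect_error(tcn_config(dropout = 1), "dropout")
})

test_that("a perturbation probe reproduces the analytic receptive field", {
  m <- build_tcn(tcn_config(dropout = 0, residual_output = FALSE),
                 seed = 1)
  L <- 1200
  y0 <- gradnet:::.tcn_apply(m, matrix(0, 2, L))
  X <- matrix(0, 2, L); X[1, 1] <- 1
  y1 <- gradnet:::.tcn_apply(m, X)
  touched <- which(abs(y1 - y0) > 0)
  expect_equal(max(touched), receptive_field(m))
})

test_that("the network is causal and emits one scalar per time point", {
  m <- build_tcn(tcn_config(n_blocks = 3, kernel_size = 4, channels = 6,
                            dropout = 0), seed = 3)
  set.seed(9)
  X <- matrix(stats::rnorm(2 * 200), 2)
  y <- gradnet:::.tcn_apply(m, X)
  expect_equal(length(y), 200)
  X2 <- X
  X2[, 120] <- X2[, 120] + 1
  y2 <- gradnet:::.tcn_apply(m, X2)
  expect_equal(y2[1:119], y[1:119])
  expect_false(isTRUE(all.equal(y2[120:200], y[120:200])))
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  m <- build_tcn(tcn_config(n_blocks = 2, kernel_size = 3, channels = 4,
                            dropout = 0), seed = 7)
  Tn <- 30
  X <- matrix(stats::rnorm(2 * Tn), 2)
  y <- stats::rnorm(Tn)
  loss_fn <- function(params) {
    mm <- m; mm$params <- params
    mean(abs(gradnet:::.tcn_fwd(mm, X)$yhat[1, ] - y))
  }
  fw <- gradnet:::.tcn_fwd(m, X)
  r <- fw$yhat[1, ] - y
  an <- gradnet:::.tcn_bwd(m, fw, matrix(sign(r) / Tn, 1))
  eps <- 1e-6
  worst <- 0
  paths <- list(
    c(1, 1), c(2, 2),   # (block, conv index 1/2)
    "bypass", "head")
  pert <- function(set, idx, delta) {
    p <- m$params
    if (identical(set, "head")) p$head$V[idx] <- p$head$V[idx] + delta
    else if (identical(set, "bypass"))
      p$blocks[[2]]$bypass$V[idx] <- p$blocks[[2]]$bypass$V[idx] + delta
    else {
      nm <- paste0("conv", set[2])
      p$blocks[[set[1]]][[nm]]$V[idx] <-
        p$blocks[[set[1]]][[nm]]$V[idx] + delta
    }
    p
  }
  gan_of <- function(set) {
    if (identical(set, "head")) an$head$V
    else if (identical(set, "bypass")) an$blocks[[2]]$bypass$V
    else an$blocks[[set[1]]][[paste0("conv", set[2])]]$V
  }
  for (set in paths) {
    gan <- gan_of(set)
    for (idx in sample(length(gan), min(4, length(gan)))) {
      num <- (loss_fn(pert(set, idx, eps)) -
                loss_fn(pert(set, idx, -eps))) / (2 * eps)
      worst <- max(worst, abs(num - gan[idx]) /
                     max(abs(num), abs(gan[idx]), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("full-sequence inference equals sliding-window inference", {
  cfg <- tcn_config(n_blocks = 2, kernel_size = 4, channels = 6,
                    dropout = 0, residual_output = FALSE)
  m <- build_tcn(cfg, seed = 5)
  m$axis <- "x"
  m$a_sys <- 770
  w <- make_multisine(c(700, 2300), c(300, 140), 8e-4)
  full <- predict_waveform(m, w)
  # windows covering the receptive field reproduce the full pass
  win <- predict_waveform_windowed(m, w,
                                   window = receptive_field(cfg))
  expect_equal(win$samples, full$samples, tolerance = 1e-6)
})

test_that("an untrained residual-output network is the identity map", {
  m <- build_tcn(tcn_config(channels = 8, dropout = 0), seed = 2)
  m$axis <- "x"; m$a_sys <- 770
  w <- make_trapezoid(250, 4e-4, 1.2e-4)
  expect_equal(predict_waveform(m, w)$samples, w$samples,
               tolerance = 1e-12)
})

test_that("windowed datasets cover each waveform sample exactly once", {
  pairs <- identity_pairs()[1:4]
  ds <- build_windows(pairs, window = 48)
  lens <- vapply(pairs, function(p) length(p$nominal$samples), 0)
  expect_equal(ds$n_windows, sum(lens))
  # an all-zero waveform yields all-zero targets
  z <- gradient_waveform(numeric(100), 4e-6)
  dz <- build_windows(list(list(nominal = z, measured = z)))
  expect_true(all(dz$sequences[[1]]$y == 0))
  # left zero-padding at the waveform start, matching content later
  gw <- get_window(ds, 1, 3)
  expect_true(all(gw$window[1:45, ] == 0))
  expect_equal(gw$window[46:48, 1],
               pairs[[1]]$nominal$samples[1:3] /
                 pairs[[1]]$nominal$amp_scale)
  expect_equal(gw$target, pairs[[1]]$measured$samples[3] /
                 pairs[[1]]$nominal$amp_scale)
  expect_error(build_windows(list()), "empty")
})

test_that("the default simulated library yields 214 pairs per axis", {
  sim <- nonlinear_sim()
  for (ax in c("x", "y", "z")) {
    tr <- gradnet:::.library_pairs(sim, ax, "train")
    pv <- gradnet:::.library_pairs(sim, ax, "validation")
    expect_equal(length(tr), 11 * 15)
    expect_equal(length(pv), 7 * 7)
    expect_equal(length(unique(vapply(tr, function(p) p$nominal$label,
                                      ""))), 11)
    expect_equal(length(unique(vapply(pv, function(p) p$nominal$label,
                                      ""))), 7)
  }
  # train/validation shape sets are disjoint
  tr_lab <- unique(vapply(gradnet:::.library_pairs(sim, "x", "train"),
                          function(p) p$nominal$label, ""))
  pv_lab <- unique(vapply(gradnet:::.library_pairs(sim, "x",
                                                   "validation"),
                          function(p) p$nominal$label, ""))
  expect_length(intersect(tr_lab, pv_lab), 0)
})
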