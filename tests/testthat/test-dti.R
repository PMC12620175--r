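test_that("b-matrix rows follow the definition", {
  p <- make_bmatrix(rbind(c(1, 0, 0)), b = 1000)
  expect_equal(p$B[1, ], c(1000, 0, 0, 0, 0, 0))
  p2 <- make_bmatrix(rbind(c(1, 1, 0) / sqrt(2)), b = 1000)
  expect_equal(p2$B[1, ], c(500, 500, 0, 1000, 0, 0))
  pr <- default_dti_protocol()
  expect_equal(qr(pr$B[pr$b_values > 0, ])$rank, 6)
  expect_equal(pr$B[1, ], rep(0, 6))        # b = 0 row is all zero
  # six coplanar directions cannot identify the tensor
  cop <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2), c(0.6, 0.8, 0), c(0.8, -0.6, 0))
  expect_error(make_bmatrix(cop, b = 1000), "rank")
  expect_error(make_bmatrix(rbind(c(2, 0, 0)), b = 1000), "unit")
})

test_that("closed-form signals obey the tensor model", {
  tf <- structure(list(
    d = array(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0), c(1, 1, 6)),
    S0 = matrix(2, 1, 1), mask = matrix(TRUE, 1, 1), N = 1L),
    class = "tensor_field")
  pz <- make_bmatrix(rbind(c(0, 0, 0), c(1, 0, 0)), b = c(0, 1000))
  S <- simulate_dwi(tf, pz)
  expect_equal(S[1, 1, 1], 2)                     # b = 0 gives S0
  expect_equal(S[1, 1, 2] / S[1, 1, 1], exp(-1.7))
  # isotropic tensors attenuate identically in every direction
  iso <- tf; iso$d[1, 1, ] <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  Si <- simulate_dwi(iso, default_dti_protocol())
  expect_equal(max(Si[1, 1, -1]) - min(Si[1, 1, -1]), 0,
               tolerance = 1e-15)
})

test_that("WLLS recovers tensors exactly from noiseless signals", {
  tp <- make_tensor_phantom(N = 48)
  pr <- default_dti_protocol()
  S <- simulate_dwi(tp, pr)
  fit <- fit_wlls(S, pr, mask = tp$mask)
  sel <- as.vector(tp$mask)
  d_err <- abs(matrix(fit$d, ncol = 6)[sel, ] -
                 matrix(tp$d, ncol = 6)[sel, ])
  expect_lt(max(d_err) / 1.7e-3, 1e-3)     # well under 0.1% relative
  # isotropic voxels come back with vanishing off-diagonals
  iso <- which(sel & abs(matrix(tp$d, ncol = 6)[, 4]) == 0 &
                 matrix(tp$d, ncol = 6)[, 1] > 0)
  expect_lt(max(abs(matrix(fit$d, ncol = 6)[iso, 4:6])), 1e-12)
  # a voxel with a non-positive signal is flagged, not fatal
  S2 <- S
  S2[10, 10, 3] <- 0
  fit2 <- fit_wlls(S2, pr, mask = tp$mask)
  expect_false(fit2$mask[10, 10])
  expect_true(fit2$mask[12, 12])
})

test_that("WLLS equals OLS under uniform signals", {
  pr <- default_dti_protocol()
  S <- array(rep(3, 1 * 1 * 7), c(1, 1, 7))
  fit <- fit_wlls(S, pr)
  expect_equal(fit$S0[1, 1], 3, tolerance = 1e-12)
  expect_lt(max(abs(fit$d)), 1e-15)
})

test_that("analytic 3x3 eigenvalues match base eigen()", {
  set.seed(7)
  dmat <- matrix(stats::rnorm(6 * 50, 0, 1e-3), ncol = 6)
  ev <- gradnet:::.eig3_sym(dmat)
  for (i in 1:50) {
    D <- matrix(c(dmat[i, 1], dmat[i, 4], dmat[i, 5],
                  dmat[i, 4], dmat[i, 2], dmat[i, 6],
                  dmat[i, 5], dmat[i, 6], dmat[i, 3]), 3)
    expect_equal(unname(ev[i, ]), sort(eigen(D, symmetric = TRUE,
                                     only.values = TRUE)$values,
                               decreasing = TRUE), tolerance = 1e-9)
  }
})

test_that("scalar maps evaluate the eigenvalue formulas", {
  mk <- function(v) structure(list(
    d = array(v, c(1, 1, 6)), S0 = matrix(1, 1, 1),
    mask = matrix(TRUE, 1, 1), N = 1L), class = "tensor_field")
  iso <- tensor_metrics(mk(c(1e-3, 1e-3, 1e-3, 0, 0, 0)))
  expect_equal(iso$MD[1, 1], 1e-3)
  expect_equal(iso$FA[1, 1], 0)
  expect_equal(iso$RD[1, 1], 1e-3)
  expect_equal(iso$AD[1, 1], 1e-3)
  ani <- tensor_metrics(mk(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)))
  expect_equal(ani$MD[1, 1], 0.76667e-3, tolerance = 1e-4)
  expect_equal(ani$AD[1, 1], 1.7e-3)
  expect_equal(ani$RD[1, 1], 0.3e-3)
  expect_equal(ani$FA[1, 1], 0.799, tolerance = 1e-3)
  stick <- tensor_metrics(mk(c(1, 0, 0, 0, 0, 0)))
  expect_equal(stick$FA[1, 1], 1)
  zero <- tensor_metrics(mk(rep(0, 6)))
  expect_equal(zero$FA[1, 1], 0)
})

test_that("parameter correlations behave like Pearson's r", {
  tp <- make_tensor_phantom(N = 48)
  maps <- tensor_metrics(tp)
  self <- parameter_correlation(maps, maps)
  expect_equal(unname(self$r), rep(1, 4))
  # permutation null: shuffled maps decorrelate
  sh <- maps
  set.seed(3)
  sel <- maps$mask & maps$FA > 0.05
  for (p in c("MD", "FA", "RD", "AD"))
    sh[[p]][sel] <- sample(sh[[p]][sel])
  rs <- parameter_correlation(sh, maps)
  expect_lt(max(abs(rs$r)), 3 / sqrt(rs$n) + 0.05)
  # invariant to a joint affine rescaling
  aff <- maps
  for (p in c("MD", "RD", "AD")) aff[[p]] <- 2 * aff[[p]] + 1e-4
  ra <- parameter_correlation(aff, maps)
  expect_equal(unname(ra$r[c("MD", "RD", "AD")]), rep(1, 3),
               tolerance = 1e-9)
  few <- maps
  few$mask[] <- FALSE
  few$mask[1:3, 1] <- TRUE
  expect_error(parameter_correlation(few, few), "10 voxels")
})
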