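test_that("fast connectivity encodes tuning similarity", {
  d <- c(0.6, 0.8)
  D <- decoder_set(cbind(d, d, c(0.8, -0.6), -d))
  Om <- fast_connectivity(D)
  expect_equal(Om[1, 2], -1)   # identical decoders inhibit
  expect_equal(Om[1, 3], 0)    # orthogonal decoders unconnected
  expect_equal(Om[1, 4], 1)    # antipodal decoders excite
  expect_equal(diag(Om), rep(-1, 4))
  expect_error(fast_connectivity(D, F = diag(3)), "N x M")
})

test_that("a quiescent network stays exactly at rest", {
  D <- random_unit_decoders(2, 8, seed = 1)
  n <- 1001
  sig <- sbx_signal(seq(0, 0.1, by = 1e-4), matrix(0, 2, n), matrix(0, 2, n))
  res <- simulate_network(D, network_params(), sig)
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$V == 0))
  expect_true(all(res$xhat == 0))
})

test_that("a spike resets the voltage to threshold minus the jump", {
  # single neuron, constant drive above threshold
  D <- decoder_set(matrix(c(1, 0), 2, 1))
  sig <- ramped_slow_noise_signal(2, duration = 1, dt = 1e-4, seed = 2,
                                  x0 = c(0.9, 0), eta_x = 0.05)
  res <- simulate_network(D, network_params(), sig)
  expect_gt(nrow(res$spikes), 5)
  idx <- round(res$spikes$time_s / 1e-4) + 1
  # the recorded grid point includes up to one step of drive past the exact
  # crossing, so the reset sits within a drive increment of T - 1
  expect_true(all(res$V[1, idx] >= -0.5 - 1e-9))
  expect_lt(max(abs(res$V[1, idx] - (0.5 - 1))), 0.01)
})

test_that("noiseless voltages equal the decoder-projected readout error", {
  tr <- run_polygon_trial()
  res <- tr$result
  r_oracle <- filter_spikes(res$spikes, 50, res$times, N = 21)
  expect_equal(r_oracle, res$r, tolerance = 1e-12)
  xhat_oracle <- decode(tr$fixture$decoders, r_oracle)
  V_oracle <- crossprod(unclass(tr$fixture$decoders),
                        tr$signal$x - xhat_oracle)
  expect_lt(max(abs(V_oracle - res$V)), 1e-8)
  expect_lt(subspace_residual(res$V, tr$fixture$decoders), 1e-9)
})

test_that("the readout error stays inside the closed box", {
  # box wide enough that a unit spike jump lands strictly inside (T > 1/2),
  # so no chained crossings occur during the refractory period
  fx <- make_fixture("polygon21")
  p <- network_params(threshold = 0.7)
  sig <- ramped_slow_noise_signal(2, duration = 1.5, dt = 1e-4, seed = 7,
                                  x0 = c(0.95, -0.55), eta_x = 0.05)
  res <- simulate_network(fx$decoders, p, sig)
  expect_gt(nrow(res$spikes), 20)
  err <- sqrt(colSums((sig$x - res$xhat)^2))
  expect_lt(max(err), max_box_radius(fx$decoders, 0.7) + 1e-6)
})

test_that("refractoriness enforces the minimum interspike interval", {
  D <- random_unit_decoders(2, 6, seed = 3)
  sig <- ramped_slow_noise_signal(2, duration = 1, dt = 1e-4, seed = 4,
                                  x0 = c(1.2, 0.3))
  res <- simulate_network(D, network_params(tau_ref = 2e-3, sigma_V = 0.2),
                          sig, seed = 5)
  isis <- unlist(tapply(res$spikes$time_s, res$spikes$neuron,
                        function(t) diff(sort(t))))
  expect_gte(min(isis), 2e-3 - 1e-9)
})

test_that("identical seed and config give bit-identical spike trains", {
  D <- random_unit_decoders(3, 12, seed = 6)
  sig <- ramped_slow_noise_signal(3, duration = 0.8, dt = 1e-4, seed = 7)
  p <- network_params(sigma_V = 0.3)
  a <- simulate_network(D, p, sig, seed = 8)
  b <- simulate_network(D, p, sig, seed = 8)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$V, b$V)
})

test_that("halving dt barely changes the trial error of a noiseless trial", {
  fx <- make_fixture("polygon21")
  E <- sapply(c(1e-4, 5e-5), function(dt) {
    sig <- ramped_slow_noise_signal(2, duration = 1, dt = dt, seed = 9,
                                    x0 = c(0.3, 0.1), eta_x = 0.1)
    res <- simulate_network(fx$decoders, fx$params, sig)
    error_E(sig$x, res$xhat, res$times)
  })
  expect_lt(abs(E[2] - E[1]) / E[1], 0.05)
})

test_that("voltages stay in the decoder row space only without noise", {
  D <- random_unit_decoders(2, 10, seed = 10)
  sig <- ramped_slow_noise_signal(2, duration = 0.6, dt = 1e-4, seed = 11)
  clean <- simulate_network(D, network_params(), sig)
  expect_lt(subspace_residual(clean$V, D), 1e-9)
  noisy <- simulate_network(D, network_params(sigma_V = 0.3), sig, seed = 12)
  expect_gt(subspace_residual(noisy$V, D), 1e-3)
})

test_that("slow networks with A = 0 reduce exactly to the autoencoder", {
  fx <- make_fixture("polygon21")
  sig <- circular_signal(1, 2 * pi, duration = 1, dt = 1e-4)
  p0 <- fx$params; p0$A <- matrix(0, 2, 2)
  a <- simulate_network(fx$decoders, fx$params, sig)
  b <- simulate_slow_network(fx$decoders, p0, command_from_signal(sig, 50))
  expect_identical(a$spikes, b$spikes)
  expect_equal(a$V, b$V, tolerance = 1e-12)
})

test_that("a rotational slow matrix generates a 2 Hz readout oscillation", {
  fx <- make_fixture("slow_oscillator")
  dt <- 1e-4
  times <- seq(0, 3, by = dt)
  cvals <- matrix(0, 2, length(times))
  cvals[1, times < 0.05] <- 60   # brief kick (lambda = 10 here)
  cmd <- sbx_signal(times, cvals, matrix(0, 2, length(times)))
  res <- simulate_slow_network(fx$decoders, fx$params, cmd, seed = 5)
  keep <- res$times >= 0.5 & res$times <= 2.5
  xh <- res$xhat[1, keep]
  spec <- Mod(stats::fft(xh - mean(xh)))[2:(floor(sum(keep) / 2))]
  fgrid <- (seq_along(spec)) / (sum(keep) * dt)
  f_dom <- fgrid[which.max(spec)]
  expect_lt(abs(f_dom - 2) / 2, 0.1)
  # the oscillation is sustained, not a decaying transient
  amp <- sqrt(colSums(res$xhat^2))
  expect_gt(amp[which.min(abs(res$times - 2.5))], 1)
})

test_that("the slow-connectivity rescaling factor is unity at T = 1/2", {
  # (<|Dr|> + T - 1/2) / <|Dr|> with T = 1/2 is 1 for any readout norm
  xhat <- matrix(rnorm(20), 2)
  cr <- correct_sphere(xhat, 0.5, method = "average")
  expect_equal(cr$scale_trace, 1)
  expect_equal(cr$xhat_corrected, xhat)
})

test_that("divergence is reported with its timestep", {
  D <- decoder_set(matrix(c(1, 0), 2, 1))
  n <- 101
  x <- matrix(NA_real_, 2, n)
  x[, 1:50] <- 0; x[, 51:n] <- Inf
  sig <- sbx_signal(seq(0, 0.01, by = 1e-4), x, matrix(0, 2, n))
  expect_error(simulate_network(D, network_params(), sig), "diverged")
})
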