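test_that("killing neurons removes faces; empty kills are the identity", {
  fx <- make_fixture("polygon21")
  same <- kill_neurons(fx$decoders, fx$params, integer(0))
  expect_identical(same$decoders, fx$decoders)
  red <- kill_neurons(fx$decoders, fx$params, c(1, 5))
  expect_equal(ncol(red$decoders), 19)
  expect_error(kill_neurons(fx$decoders, fx$params, 1:21), "empty network")
})

test_that("opening the square box lets the error escape toward the dead face", {
  fx <- make_fixture("square4")
  sig <- ramped_slow_noise_signal(2, duration = 1.5, dt = 1e-4, seed = 4,
                                  x0 = c(1, 0), eta_x = 0.1)
  closed <- simulate_network(fx$decoders, fx$params, sig)
  open <- simulate_network(fx$decoders, fx$params, sig,
                           perturbations = list(perturbation("kill",
                                                             targets = 1L)))
  E_closed <- error_E(sig$x, closed$xhat, closed$times)
  E_open <- error_E(sig$x, open$xhat, open$times)
  expect_gt(E_open, 3 * E_closed)
})

test_that("injected currents match their threshold-shift equivalent exactly", {
  dec <- random_unit_decoders(2, 20, seed = 11)
  p <- network_params(sigma_V = 0.2)
  sig <- ramped_slow_noise_signal(2, duration = 0.5, dt = 1e-4, seed = 12)
  nsteps <- length(sig$times) - 1
  Pcur <- matrix(0, 20, nsteps)
  w <- c(round(0.2 / 1e-4) + 1, round(0.4 / 1e-4))
  Pcur[3, w[1]:w[2]] <- 8
  with_cur <- simulate_network(dec, p, sig, seed = 55,
                               perturbations = list(inject_current(3, 8,
                                                                   c(0.2, 0.4))))
  with_shift <- simulate_network(dec, p, sig, seed = 55,
                                 perturbations = list(perturbation(
                                   "threshold_shift",
                                   magnitude = equivalent_threshold_shift(
                                     Pcur, 50, 1e-4))))
  expect_identical(with_cur$spikes, with_shift$spikes)
  expect_gt(nrow(with_cur$spikes), 50)
  # a constant current at steady state shifts the threshold by -p/lambda
  sh <- equivalent_threshold_shift(matrix(8, 1, 5000), 50, 1e-4)
  expect_equal(sh[1, 5001], -8 / 50, tolerance = 0.01)
  # zero current: trajectories unchanged
  base <- simulate_network(dec, p, sig, seed = 55)
  null <- simulate_network(dec, p, sig, seed = 55,
                           perturbations = list(inject_current(3, 0,
                                                               c(0.2, 0.4))))
  expect_identical(base$spikes, null$spikes)
})

test_that("a mistuned reset pulls the next spike forward and decays with the leak", {
  fx <- make_fixture("polygon21")
  Om <- fast_connectivity(fx$decoders)
  sig <- ramped_slow_noise_signal(2, duration = 1.5, dt = 1e-4, seed = 14,
                                  x0 = c(0.9, 0), eta_x = 0.05)
  base <- simulate_network(fx$decoders, fx$params, sig)
  busiest <- as.integer(names(which.max(table(base$spikes$neuron))))
  up <- simulate_network(fx$decoders, fx$params, sig,
                         perturbations = list(perturbation(
                           "reset_mistune", targets = busiest,
                           magnitude = 0.3)))
  t_base <- base$spikes$time_s[base$spikes$neuron == busiest]
  t_up <- up$spikes$time_s[up$spikes$neuron == busiest]
  first <- t_base[1]
  # identical up to the first spike of the mistuned neuron, earlier afterwards
  expect_equal(t_up[1], first)
  expect_lt(t_up[2], t_base[2])
  # delta = 0 is the identity
  expect_identical(mistune_resets(Om, 1:3, 0), Om)
  expect_warning(mistune_resets(Om, 1, 1.5), "runaway")
  # the effective inward shift of the face decays with the leak time constant:
  # closed form of the reset offset under exp(-lambda t)
  delta <- 0.3; lam <- 50
  tgrid <- seq(0, 0.1, by = 1e-3)
  shift <- delta * exp(-lam * tgrid)
  expect_equal(shift[1], delta)
  expect_lt(shift[length(shift)], delta * 1e-2)
})

test_that("synaptic mistuning scales off-diagonals within the stated band", {
  Om <- fast_connectivity(random_unit_decoders(3, 30, seed = 15))
  expect_identical(mistune_synapses(Om, 0), Om)
  d <- 0.4
  Om2 <- mistune_synapses(Om, d, seed = 16)
  expect_equal(diag(Om2), diag(Om))
  off <- row(Om) != col(Om) & Om != 0
  fac <- Om2[off] / Om[off]
  expect_true(all(fac >= 1 - d - 1e-12 & fac <= 1 / (1 - d) + 1e-12))
  # distribution matches (1 - d)^U(-1,1) by a two-sample test
  set.seed(17)
  direct <- (1 - d)^runif(sum(off), -1, 1)
  expect_gt(suppressWarnings(stats::ks.test(fac, direct)$p.value), 0.01)
})

test_that("widening scales the box exactly and calms a noisy network", {
  p <- network_params(threshold = 0.5)
  expect_identical(widen_box(p, 1), p)
  expect_equal(widen_box(p, 2)$threshold, 1)
  dec <- random_unit_decoders(2, 40, seed = 18)
  cs1 <- box_cross_section(dec, 0.5, u = c(1, 0), v = c(0, 1), n_angles = 36)
  cs2 <- box_cross_section(dec, 0.5 * 1.7, u = c(1, 0), v = c(0, 1),
                           n_angles = 36)
  expect_equal(cs2$radii, 1.7 * cs1$radii, tolerance = 1e-12)
  sig <- ramped_slow_noise_signal(2, duration = 1, dt = 1e-4, seed = 19,
                                  x0 = c(1.5, 0.5))
  counts <- sapply(c(1, 1.5, 2), function(f)
    simulate_network(dec, network_params(sigma_V = 0.4), sig, seed = 20,
                     record_V = FALSE,
                     perturbations = if (f > 1)
                       list(perturbation("widen_box", magnitude = f))
                     else list())$total_spikes)
  expect_true(all(diff(counts) < 0))
})

test_that("pruning removes the largest excitatory pairs symmetrically", {
  Om <- fast_connectivity(random_unit_decoders(2, 12, seed = 21))
  expect_identical(prune_excitatory(Om, 0), Om)
  Om2 <- prune_excitatory(Om, 3)
  removed <- which(Om > 0 & Om2 == 0 & upper.tri(Om), arr.ind = TRUE)
  expect_equal(nrow(removed), 3)
  expect_true(all(Om2 == t(Om2)))
  kept_pos <- Om2[upper.tri(Om2)][Om2[upper.tri(Om2)] > 0]
  expect_true(all(kept_pos <= min(Om[upper.tri(Om)][Om[upper.tri(Om)] > 0][
    order(Om[upper.tri(Om)][Om[upper.tri(Om)] > 0],
          decreasing = TRUE)[1:3]])))
  # square box: the only positive couplings are the two antipodal pairs
  Oms <- fast_connectivity(polygon_decoders(4))
  expect_warning(none <- prune_excitatory(Oms, 10), "clamping")
  expect_true(all(none[upper.tri(none)] <= 0))
  # pruning antipodal excitation lowers the spike count of a delayed network
  fx <- make_fixture("delayed_2d_r50")
  sig <- ramped_slow_noise_signal(2, duration = 1, dt = 1e-4, seed = 22)
  Omd <- fast_connectivity(fx$decoders)
  full <- simulate_network(fx$decoders, fx$params, sig, seed = 23,
                           record_V = FALSE, max_total_spikes = 2e4)
  pruned <- simulate_network(fx$decoders, fx$params, sig, seed = 23,
                             record_V = FALSE, max_total_spikes = 2e4,
                             Omega = prune_excitatory(Omd,
                               sum(upper.tri(Omd) & Omd > 0)))
  expect_lt(pruned$total_spikes, full$total_spikes)
})

test_that("windowed voltage noise perturbs only inside its window", {
  dec <- random_unit_decoders(2, 10, seed = 24)
  sig <- ramped_slow_noise_signal(2, duration = 1, dt = 1e-4, seed = 25)
  base <- simulate_network(dec, network_params(), sig, seed = 26)
  pert <- simulate_network(dec, network_params(), sig, seed = 26,
                           perturbations = list(perturbation(
                             "voltage_noise", magnitude = 0.5,
                             window = c(0.6, 1))))
  pre <- base$spikes$time_s <= 0.6
  expect_identical(base$spikes[pre, ], pert$spikes[pert$spikes$time_s <= 0.6, ])
  expect_false(identical(base$spikes, pert$spikes))
})

test_that("perturbation records validate their fields", {
  expect_error(perturbation("nonsense"), "arg")
  expect_error(perturbation("current", window = c(0.5, 0.2)), "window")
  p <- perturbation("kill", targets = c(1, 2), window = c(0.1, 0.2))
  expect_s3_class(p, "perturbation")
})
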