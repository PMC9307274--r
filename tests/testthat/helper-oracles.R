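# Independent oracles used across the suite. These deliberately avoid the
# closed-form code paths they are checked against.

# border distance along one ray by bisection on the feasibility predicate
# D^T (rho w) <= T
ray_radius_bisect <- function(D, Tv, w, hi = 1e3, tol = 1e-10) {
  feasible <- function(rho) all(crossprod(D, rho * w) <= Tv + 1e-15)
  if (feasible(hi)) return(Inf)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exponential filtering of a spike list by direct summation (quadratic,
# reference implementation for small cases)
filter_spikes_naive <- function(spikes, lambda, times, N) {
  r <- matrix(0, N, length(times))
  for (s in seq_len(nrow(spikes))) {
    k <- spikes$neuron[s]; ts <- spikes$time_s[s]
    on <- times >= ts - 1e-12
    r[k, on] <- r[k, on] + exp(-lambda * (times[on] - ts))
  }
  r
}

# a short deterministic trial on a fixture, shared by several tests
run_polygon_trial <- function(duration = 1, dt = 1e-4, x0 = c(0.8, -0.4),
                              eta_x = 0.1, seed = 7) {
  fx <- make_fixture("polygon21")
  sig <- ramped_slow_noise_signal(2, duration = duration, dt = dt,
                                  seed = seed, x0 = x0, eta_x = eta_x)
  res <- simulate_network(fx$decoders, fx$params, sig)
  list(fixture = fx, signal = sig, result = res)
}
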