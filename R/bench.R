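#' Benchmark configuration
#'
#' Describes a battery of paired perturbed/unperturbed trials: network size
#' via `(M, rho)` with `N = rho * M`, the network parameters, the input-signal
#' family, the perturbation under test, and a master seed from which every
#' per-trial seed is derived deterministically.
#'
#' @param M signal dimensionality.
#' @param rho redundancy; the network has `N = rho * M` neurons.
#' @param n_trials number of trial pairs (>= 20 for the published protocol,
#'   smaller batteries are allowed for quick checks).
#' @param duration trial duration in seconds (default 2).
#' @param dt time step in seconds (default 1e-4).
#' @param params a [network_params()]. The default uses the calibrated
#'   benchmarking noise [default_sigma_V()].
#' @param signal list describing the input family: either
#'   `list(kind = "ramped", sigma_x = 1, eta_x = 0.5, x0 = NULL)` or
#'   `list(kind = "circular", a = 1, omega = 2 * pi)`.
#' @param perturbation a [perturbation()] or list of them (`NULL` = none).
#' @param decoders `"random"` (a fresh decoder draw per trial) or a fixed
#'   [decoder_set()] used for every trial.
#' @param master_seed integer master seed.
#' @param exclude transient exclusion for error averages, seconds.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(M, rho, n_trials = 20, duration = 2, dt = 1e-4,
                             params = network_params(sigma_V = default_sigma_V()),
                             signal = list(kind = "ramped", sigma_x = 1,
                                           eta_x = 0.5, x0 = NULL),
                             perturbation = NULL, decoders = "random",
                             master_seed = 1L, exclude = 0.5) {
  if (n_trials < 1) stop("'n_trials' must be at least 1")
  N <- as.integer(round(rho * M))
  if (N < 1) stop("rho * M must give at least one neuron")
  structure(list(M = as.integer(M), rho = rho, N = N,
                 n_trials = as.integer(n_trials), duration = duration,
                 dt = dt, params = params, signal = signal,
                 perturbation = perturbation, decoders = decoders,
                 master_seed = as.integer(master_seed), exclude = exclude),
            class = "benchmark_config")
}

#' Default benchmarking voltage noise
#'
#' The voltage-noise scale used by [benchmark_config()], calibrated once so
#' that baseline random networks produce low median firing rates and
#' interspike-interval CVs near one (Poisson-like irregularity) at moderate
#' redundancy; see the package vignette.
#'
#' @return The noise scale (per sqrt(s)).
#' @export
default_sigma_V <- function() 0.05

#' Deterministic per-trial seed derivation
#'
#' Hashes `(master seed, trial index, stream)` into a positive integer below
#' 2^31, so that the whole benchmark is a pure function of the master seed.
#' The `stream` separates decoder, signal and noise randomness; perturbed and
#' reference arms share all three streams.
#'
#' @param master master seed.
#' @param trial trial index.
#' @param stream small integer labelling the random stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, trial, stream = 0L) {
  h <- (as.numeric(master) * 7919 + as.numeric(trial) * 104729 +
          as.numeric(stream) * 7907 + 12345) %% 2147483629
  as.integer(h) + 1L
}

trial_inputs <- function(config, trial) {
  dseed <- derive_seed(config$master_seed, trial, 1L)
  sseed <- derive_seed(config$master_seed, trial, 2L)
  vseed <- derive_seed(config$master_seed, trial, 3L)
  decoders <- if (inherits(config$decoders, "decoder_set")) config$decoders
  else random_unit_decoders(config$M, config$N, seed = dseed)
  sig <- config$signal
  signal <- switch(sig$kind,
    ramped = ramped_slow_noise_signal(config$M,
                                      sigma_x = sig$sigma_x %||% 1,
                                      eta_x = sig$eta_x %||% 0.5,
                                      duration = config$duration,
                                      dt = config$dt, seed = sseed,
                                      x0 = sig$x0 %||% NULL),
    circular = circular_signal(a = sig$a %||% 1, omega = sig$omega %||% (2 * pi),
                               duration = config$duration, dt = config$dt),
    stop(sprintf("unknown signal kind '%s'", sig$kind)))
  list(decoders = decoders, signal = signal, noise_seed = vseed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one paired perturbed/unperturbed trial
#'
#' Draws one decoder set, one input signal and one noise stream (all derived
#' from the master seed and the trial index, shared by both arms), simulates
#' the reference and the perturbed network, and computes the relative
#' performance `P`.
#'
#' @param config a [benchmark_config()].
#' @param trial trial index (1-based).
#' @param max_total_spikes optional early-stopping spike budget per arm.
#' @return A `trial_outcome` for the perturbed arm with `P` filled in and the
#'   reference outcome attached as `$reference`; on simulation divergence a
#'   list with `failed = TRUE` and the error message.
#' @export
paired_trial <- function(config, trial, max_total_spikes = Inf) {
  inp <- trial_inputs(config, trial)
  out <- tryCatch({
    ref <- simulate_network(inp$decoders, config$params, inp$signal,
                            seed = inp$noise_seed, record_V = FALSE,
                            max_total_spikes = max_total_spikes)
    pert <- simulate_network(inp$decoders, config$params, inp$signal,
                             seed = inp$noise_seed,
                             perturbations = config$perturbation %||% list(),
                             record_V = FALSE,
                             max_total_spikes = max_total_spikes)
    ref_out <- trial_outcome(ref, exclude = config$exclude)
    pert_out <- trial_outcome(pert, E_ref = ref_out$E,
                              reference_count = ref$total_spikes,
                              exclude = config$exclude)
    pert_out$reference <- ref_out
    pert_out
  }, error = function(e) list(failed = TRUE, message = conditionMessage(e),
                              trial = trial))
  out
}

#' Run a full battery of paired trials
#'
#' @param config a [benchmark_config()].
#' @param max_total_spikes optional per-arm spike budget.
#' @return A list with `trials` (the per-trial outcomes), a tidy `table`
#'   (one row per trial: `trial`, `P`, `E_pert`, `E_ref`, `E_dead`,
#'   `median_rate_pert`, `median_rate_ref`, `pingpong`, `failed`), and
#'   `n_failed`.
#' @export
run_paired_trials <- function(config, max_total_spikes = Inf) {
  outs <- lapply(seq_len(config$n_trials), function(i)
    paired_trial(config, i, max_total_spikes = max_total_spikes))
  rows <- lapply(seq_along(outs), function(i) {
    o <- outs[[i]]
    if (isTRUE(o$failed))
      return(data.frame(trial = i, P = NA_real_, E_pert = NA_real_,
                        E_ref = NA_real_, E_dead = NA_real_,
                        median_rate_pert = NA_real_, median_rate_ref = NA_real_,
                        pingpong = NA, failed = TRUE))
    data.frame(trial = i, P = o$P, E_pert = o$E, E_ref = o$reference$E,
               E_dead = o$E_dead, median_rate_pert = median(o$rates),
               median_rate_ref = median(o$reference$rates),
               pingpong = o$pingpong, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(trials = outs, table = tab, n_failed = sum(tab$failed))
}

#' Robustness-asymmetry battery
#'
#' Quantifies the published asymmetry between inhibitory and excitatory
#' perturbations on a random 2-D network: (a) killing one neuron leaves the
#' relative performance near 1; (b) strongly inhibiting half the population
#' leaves performance high because the spared neurons compensate; (c) the
#' spared neurons' firing rates rise under (b); (d) an excitatory current
#' into the single neuron best tuned to the stimulus moves the time-averaged,
#' sphere-corrected readout by much more than the unperturbed trial-to-trial
#' bias. Every trial draws fresh decoders, a fresh operating point of fixed
#' norm `signal_norm` in a random direction, and a fresh noise stream shared
#' by all arms.
#'
#' @param n_trials number of trials (the protocol asks for >= 20).
#' @param M,rho network shape (defaults M = 2, rho = 10).
#' @param threshold box threshold; the default 1 keeps the unit spike jumps
#'   well inside the box so that excitatory shrinkage is not masked by
#'   opposite-face crossings.
#' @param sigma_V voltage noise.
#' @param lambda leak rate (1/s).
#' @param signal_norm norm of the operating point `x0` (direction random).
#' @param exc_frac,inh_frac perturbation currents as fractions of
#'   `threshold * lambda` (the current that shifts a threshold by that
#'   fraction of `T` at steady state).
#' @param duration,dt trial grid.
#' @param seed master seed.
#' @return A list with the per-trial vectors `P_kill`, `P_inhibit`,
#'   `rate_rise` (mean rate change of the spared half, Hz), `shift`
#'   (perturbed-minus-reference readout displacement), `ref_bias`
#'   (unperturbed readout bias), and the summary scalars `median_P_kill`,
#'   `median_P_inhibit`, `median_rate_rise`, `median_shift`,
#'   `bias_sd` (`sd(ref_bias)`).
#' @export
robustness_battery <- function(n_trials = 20, M = 2, rho = 10, threshold = 1,
                               sigma_V = default_sigma_V(), lambda = 50,
                               signal_norm = 2.5, exc_frac = 0.75,
                               inh_frac = -1, duration = 2, dt = 1e-4,
                               seed = 1L) {
  N <- as.integer(round(M * rho))
  p <- network_params(lambda = lambda, threshold = threshold,
                      sigma_V = sigma_V)
  win <- c(0.5, duration)
  avg_corr <- function(res) {
    keep <- res$times >= 0.5
    rowMeans(correct_sphere(res$xhat, threshold)$xhat_corrected[, keep,
                                                                drop = FALSE])
  }
  P_kill <- P_inh <- rate_up <- shift <- ref_bias <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    dec <- random_unit_decoders(M, N, seed = derive_seed(seed, tr, 1L))
    old <- set_local_seed(derive_seed(seed, tr, 4L))
    u <- rnorm(M)
    restore_seed(old)
    x0 <- signal_norm * u / sqrt(sum(u^2))
    sig <- ramped_slow_noise_signal(M, duration = duration, dt = dt,
                                    seed = derive_seed(seed, tr, 2L), x0 = x0)
    vseed <- derive_seed(seed, tr, 3L)
    target <- which.max(crossprod(unclass(dec), x0))
    ref <- simulate_network(dec, p, sig, seed = vseed, record_V = FALSE)
    keep <- ref$times >= 0.5
    E_ref <- error_E(sig$x, correct_sphere(ref$xhat, threshold)$xhat_corrected,
                     ref$times)
    E_dead <- dead_error(sig$x, sig$times)
    ref_bias[tr] <- sqrt(sum((avg_corr(ref) -
                                rowMeans(sig$x[, keep, drop = FALSE]))^2))
    k1 <- simulate_network(dec, p, sig, seed = vseed, record_V = FALSE,
                           perturbations = list(perturbation("kill",
                                                             targets = 1L)))
    P_kill[tr] <- performance_P(
      error_E(sig$x, correct_sphere(k1$xhat, threshold)$xhat_corrected,
              k1$times), E_ref, E_dead)
    half <- seq_len(N %/% 2)
    inh <- simulate_network(dec, p, sig, seed = vseed, record_V = FALSE,
                            perturbations = list(inject_current(
                              half, inh_frac * threshold * lambda, win)))
    P_inh[tr] <- performance_P(
      error_E(sig$x, correct_sphere(inh$xhat, threshold)$xhat_corrected,
              inh$times), E_ref, E_dead)
    dur <- ref$times[length(ref$times)]
    rate_up[tr] <- mean(firing_rates(inh$spikes, N, dur)[-half]) -
      mean(firing_rates(ref$spikes, N, dur)[-half])
    exc <- simulate_network(dec, p, sig, seed = vseed, record_V = FALSE,
                            perturbations = list(inject_current(
                              target, exc_frac * threshold * lambda, win)),
                            max_total_spikes = 1e5)
    shift[tr] <- sqrt(sum((avg_corr(exc) - avg_corr(ref))^2))
  }
  list(P_kill = P_kill, P_inhibit = P_inh, rate_rise = rate_up,
       shift = shift, ref_bias = ref_bias,
       median_P_kill = median(P_kill), median_P_inhibit = median(P_inh),
       median_rate_rise = median(rate_up), median_shift = median(shift),
       bias_sd = sd(ref_bias))
}

#' Redundancy x dimensionality sweep of baseline networks
#'
#' Simulates `n_trials` unperturbed trials per `(M, rho)` cell and collects
#' the dimensionality-independent pooled component error together with firing
#' rates and CVs.
#'
#' @param M_values vector of signal dimensionalities.
#' @param rho_values vector of redundancies.
#' @param config_template a [benchmark_config()] whose `M`/`rho` are
#'   overridden per cell (its `n_trials`, parameters, signal and master seed
#'   are reused).
#' @return A list with `trials` (tidy data frame: one row per cell x trial
#'   with `M`, `rho`, `trial`, `pooled_error_median`, `rate_median`,
#'   `cv_median`, `pingpong`, `failed`) and `summary` (one row per cell with
#'   distributions pooled across trials: the median of all per-component
#'   error samples, the median per-neuron rate over all neurons
#'   (`rate_median`) and over neurons that fired at least once
#'   (`rate_median_active`), the median CV over neurons with at least three
#'   spikes, and counts of ping-pong and failed trials). Failed cells are
#'   reported in the table, never dropped.
#' @export
sweep_redundancy <- function(M_values, rho_values, config_template) {
  rows <- list()
  cells <- list()
  for (M in M_values) for (rho in rho_values) {
    cfg <- config_template
    cfg$M <- as.integer(M); cfg$rho <- rho
    cfg$N <- as.integer(round(rho * M))
    pool <- list(errs = c(), rates = c(), cvs = c(), pp = 0L, failed = 0L)
    for (trial in seq_len(cfg$n_trials)) {
      inp <- trial_inputs(cfg, trial)
      row <- tryCatch({
        res <- simulate_network(inp$decoders, cfg$params, inp$signal,
                                seed = inp$noise_seed, record_V = FALSE,
                                max_total_spikes = 1e6)
        o <- trial_outcome(res, exclude = cfg$exclude)
        pool$errs <- c(pool$errs, o$pooled_errors)
        pool$rates <- c(pool$rates, o$rates)
        pool$cvs <- c(pool$cvs, o$cvs)
        pool$pp <- pool$pp + o$pingpong
        data.frame(M = M, rho = rho, trial = trial,
                   pooled_error_median = median(o$pooled_errors),
                   rate_median = median(o$rates),
                   cv_median = median(o$cvs, na.rm = TRUE),
                   pingpong = o$pingpong, failed = FALSE)
      }, error = function(e)
        data.frame(M = M, rho = rho, trial = trial,
                   pooled_error_median = NA_real_, rate_median = NA_real_,
                   cv_median = NA_real_, pingpong = NA, failed = TRUE))
      pool$failed <- pool$failed + row$failed
      rows[[length(rows) + 1L]] <- row
    }
    cells[[length(cells) + 1L]] <- data.frame(
      M = M, rho = rho,
      pooled_error_median = median(pool$errs),
      rate_median = median(pool$rates),
      rate_median_active = median(pool$rates[pool$rates > 0]),
      cv_median = median(pool$cvs, na.rm = TRUE),
      n_pingpong = pool$pp, n_failed = pool$failed)
  }
  list(trials = do.call(rbind, rows), summary = do.call(rbind, cells))
}

#' Iteratively tune a delayed network away from ping-pong
#'
#' Searches the smallest box-widening factor (grid `1 + k * step`) or the
#' smallest number of pruned excitatory pairs (grid `k * step`, rounded) such
#' that no trial in a battery of seeds triggers [detect_pingpong()] against
#' the analytic healthy spike count. Trials should be at least 2 s long to
#' avoid false-negative reports.
#'
#' @param config a [benchmark_config()]; its `params$delay` is overridden by
#'   `delay`.
#' @param mode `"widen"` or `"prune"`.
#' @param delay synaptic delay in seconds (>= 0).
#' @param step grid step: widening-factor increment (default 0.25) or pruned
#'   pairs per iteration (default `N^2/40`, rounded up, a coarse grid over
#'   the order-`N^2/2` candidate pairs).
#' @param max_iter maximum grid points tried.
#' @param n_battery number of trial seeds in the battery (default
#'   `min(config$n_trials, 5)`).
#' @param c_pp ping-pong multiplier passed to [detect_pingpong()].
#' @return A list with `mode`, `value` (the minimal factor or pruned-pair
#'   count; `NA` when `max_iter` is exhausted), `iterations`, and
#'   `diagnostics` (per-iteration spike counts and flags).
#' @export
tune_to_avoid_pingpong <- function(config, mode = c("widen", "prune"), delay,
                                   step = NULL, max_iter = 20,
                                   n_battery = NULL, c_pp = 5) {
  mode <- match.arg(mode)
  if (delay < 0) stop("'delay' must be non-negative")
  if (config$duration < 2)
    warning("trials shorter than 2 s risk false-negative ping-pong reports")
  if (is.null(n_battery)) n_battery <- min(config$n_trials, 5L)
  if (is.null(step)) step <- if (mode == "widen") 0.25
                             else ceiling(config$N^2 / 40)
  cfg <- config
  cfg$params$delay <- delay
  diag_rows <- list()
  for (k in 0:(max_iter - 1)) {
    value <- if (mode == "widen") 1 + k * step else as.integer(round(k * step))
    clean <- TRUE
    for (trial in seq_len(n_battery)) {
      inp <- trial_inputs(cfg, trial)
      refc <- expected_spike_count(inp$signal, cfg$params$lambda)
      perts <- list()
      if (mode == "widen" && value > 1)
        perts <- list(perturbation("widen_box", magnitude = value))
      Om <- fast_connectivity(inp$decoders, cfg$params$F)
      if (mode == "prune" && value > 0) Om <- prune_excitatory(Om, value)
      res <- simulate_network(inp$decoders, cfg$params, inp$signal,
                              seed = inp$noise_seed, perturbations = perts,
                              Omega = Om, record_V = FALSE,
                              max_total_spikes = c_pp * refc + 100)
      pp <- detect_pingpong(res, refc, c_pp = c_pp)
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(iteration = k + 1L, value = value, trial = trial,
                   total_spikes = res$total_spikes, reference = refc,
                   pingpong = pp)
      if (pp) { clean <- FALSE; break }
    }
    if (clean)
      return(list(mode = mode, value = value, iterations = k + 1L,
                  diagnostics = do.call(rbind, diag_rows)))
  }
  list(mode = mode, value = NA_real_, iterations = max_iter,
       diagnostics = do.call(rbind, diag_rows))
}
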