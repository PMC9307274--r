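#' Network parameters
#'
#' Collects all scalar and matrix parameters of the coordinated spike-coding
#' network. Units are seconds throughout.
#'
#' @param lambda inverse time constant of the voltage leak and readout decay,
#'   1/s. Default 50 (a 20 ms time constant).
#' @param threshold spiking threshold(s) `T`: scalar or per-neuron vector.
#'   Default 0.5, the smallest box for unit-norm decoders.
#' @param tau_ref refractory period in seconds (default 2 ms). During the
#'   refractory period spikes are omitted; the voltage keeps integrating.
#' @param sigma_V voltage-noise scale (per sqrt(s)): each step adds independent
#'   per-neuron Gaussian increments of sd `sigma_V * sqrt(dt)`.
#' @param delay synaptic delay theta in seconds (>= 0). Lateral recurrence and
#'   the decoder readout are delayed; self-resets stay instantaneous.
#' @param A optional M x M slow-dynamics matrix (1/s); when present the slow
#'   recurrent connectivity \eqn{D^\top (A + \lambda I) D} makes the readout
#'   approximate \eqn{\dot x = A x + c(t)}.
#' @param F optional N x M face matrix with unit-norm rows; defaults to
#'   `t(D)`, i.e. jumps orthogonal to the faces.
#' @param slow_scale scalar applied to the slow recurrent connectivity (the
#'   sphere-correction factor when the readout is rescaled); default 1.
#' @param max_substeps cap on threshold crossings resolved within one time
#'   step; defaults to `10 * N` at simulation time. Exceeding it sets the
#'   `substep_overflow` flag (the ping-pong hook), it is not an error.
#' @return An object of class `network_params` (a list).
#' @export
network_params <- function(lambda = 50, threshold = 0.5, tau_ref = 2e-3,
                           sigma_V = 0, delay = 0, A = NULL, F = NULL,
                           slow_scale = 1, max_substeps = NULL) {
  if (lambda <= 0) stop("'lambda' must be positive")
  if (tau_ref < 0 || sigma_V < 0 || delay < 0)
    stop("'tau_ref', 'sigma_V' and 'delay' must be non-negative")
  if (any(threshold <= 0)) stop("thresholds must be positive")
  if (!is.null(F)) {
    F <- as.matrix(F)
    if (any(abs(sqrt(rowSums(F^2)) - 1) > 1e-12))
      stop("rows of 'F' must have unit norm")
  }
  structure(list(lambda = lambda, threshold = threshold, tau_ref = tau_ref,
                 sigma_V = sigma_V, delay = delay, A = A, F = F,
                 slow_scale = slow_scale, max_substeps = max_substeps),
            class = "network_params")
}

#' Fast recurrent connectivity
#'
#' \eqn{\Omega = -F D}, with the face matrix `F` defaulting to `t(D)` so that
#' \eqn{\Omega = -D^\top D}: similarly tuned neurons inhibit each other,
#' orthogonal neurons are unconnected, antipodal neurons excite each other.
#' The diagonal entries are the self-reset weights.
#'
#' @param decoders a [decoder_set()].
#' @param F optional N x M face matrix (unit-norm rows).
#' @return The N x N connectivity matrix.
#' @export
fast_connectivity <- function(decoders, F = NULL) {
  D <- unclass(decoders)
  if (is.null(F)) F <- t(D)
  F <- as.matrix(F)
  if (ncol(F) != nrow(D) || nrow(F) != ncol(D))
    stop("'F' must be N x M with dimensions matching the decoder set")
  -F %*% D
}

# thresholds as a full-length vector
threshold_vector <- function(params, N) rep_len(params$threshold, N)

#' Simulate a coordinated spike-coding network
#'
#' Integrates the leaky integrate-and-fire dynamics
#' \eqn{\dot V = -\lambda V + F(\lambda x + \dot x) - F D s(t) + \sigma_V \eta(t)}
#' on the signal's time grid. Voltages and filtered spike trains decay by
#' `exp(-lambda dt)` per step and the feedforward drive enters as the
#' exponentially consistent increment `F (x[n+1] - exp(-lambda dt) x[n])`, so
#' that in the noiseless undelayed case the identity
#' \eqn{V = F(x - \hat x)} holds to machine precision. Within a step,
#' threshold crossings are resolved one neuron at a time in order of
#' decreasing violation (ties to the lowest index); with a positive delay the
#' lateral recurrence and the readout are delivered at the first grid point at
#' or after `t_spike + delay`, at the end of that step, while self-resets are
#' instantaneous.
#'
#' @param decoders a [decoder_set()].
#' @param params a [network_params()].
#' @param signal an [sbx_signal()] (its grid defines `dt`).
#' @param seed optional integer seed controlling the voltage noise.
#' @param perturbations list of [perturbation()] records applied to this run.
#' @param Omega optional explicit fast connectivity, overriding
#'   `fast_connectivity(decoders, params$F)` (used for synaptic perturbations).
#' @param V0 initial voltages; defaults to `F x(0)`, the projection of the
#'   initial readout error (the readout starts at zero).
#' @param record_V record the voltage traces (default `TRUE`; turn off to save
#'   memory in sweeps).
#' @param max_total_spikes optional early-stopping cap on the total spike
#'   count; when exceeded the result is flagged `truncated` (used by the
#'   ping-pong tuner). Default `Inf`.
#' @return An object of class `sim_result`: list with `spikes` (data frame
#'   `time_s`, `neuron`), `V` (N x steps+1 or NULL), `r` (filtered spike
#'   trains, delayed when `delay > 0`), `xhat` (M x steps+1 readout `D r`),
#'   `times`, `substep_overflow`, `truncated`, `event_log` (spikes resolved
#'   per step), `total_spikes`, plus the `decoders`, `params` and `signal`
#'   used.
#' @export
simulate_network <- function(decoders, params = network_params(), signal,
                             seed = NULL, perturbations = list(),
                             Omega = NULL, V0 = NULL, record_V = TRUE,
                             max_total_spikes = Inf) {
  drive <- drive_increments(signal, params$lambda)
  run_core(decoders, params, signal, drive, Wslow = NULL, seed = seed,
           perturbations = perturbations, Omega = Omega, V0 = V0,
           record_V = record_V, max_total_spikes = max_total_spikes)
}

#' Simulate a network with slow recurrent connections
#'
#' Adds the slow recurrent current
#' \eqn{D^\top (A + \lambda I) D\, r(t)} (optionally rescaled by
#' `params$slow_scale`) to the fast dynamics, so that the readout approximates
#' the dynamical system \eqn{\dot x = A x + c(t)} driven by the command
#' `command`.
#'
#' @inheritParams simulate_network
#' @param command an [sbx_signal()] holding the command \eqn{c(t)} (M rows).
#'   Commands built with [command_from_signal()] carry their generating
#'   trajectory and reuse the exact drive increment, so with `A = 0` the
#'   result is identical to [simulate_network()] on that trajectory.
#' @return A `sim_result`, as [simulate_network()].
#' @export
simulate_slow_network <- function(decoders, params, command, seed = NULL,
                                  perturbations = list(), Omega = NULL,
                                  V0 = NULL, record_V = TRUE,
                                  max_total_spikes = Inf) {
  if (is.null(params$A)) stop("'params$A' must be set for a slow network")
  M <- nrow(decoders)
  A <- as.matrix(params$A)
  stopifnot(all(dim(A) == M))
  D <- unclass(decoders)
  F <- if (is.null(params$F)) t(D) else params$F
  ref <- attr(command, "trajectory")
  # For a raw command the slow connectivity is F (A + lambda I) D and the
  # feedforward is the command itself. A command built from a reference
  # trajectory already carries lambda*x + xdot in its drive, so the lambda*I
  # part of the slow recurrence is supplied by the input and omitted from the
  # weights; with A = 0 this reduces exactly to the autoencoder dynamics.
  if (!is.null(ref)) {
    Wslow <- params$slow_scale * (F %*% A %*% D)
    drive <- drive_increments(ref, params$lambda)
  } else {
    Wslow <- params$slow_scale *
      (F %*% (A + params$lambda * diag(M)) %*% D)
    drive <- command_increments(command, params$lambda)
  }
  if (all(Wslow == 0)) Wslow <- NULL
  # the latent state starts at x(0) (0 for a raw command), the readout at 0
  if (is.null(V0)) V0 <- if (!is.null(ref)) drop(F %*% ref$x[, 1])
                         else numeric(ncol(D))
  run_core(decoders, params, command, drive, Wslow = Wslow, seed = seed,
           perturbations = perturbations, Omega = Omega, V0 = V0,
           record_V = record_V, max_total_spikes = max_total_spikes)
}

#' Build the command signal equivalent to tracking a reference trajectory
#'
#' For the autoencoder, tracking `x(t)` is the special case `A = 0`,
#' `c(t) = lambda x(t) + xdot(t)` of the slow-network dynamics. The returned
#' command carries the reference trajectory so that
#' [simulate_slow_network()] reproduces [simulate_network()] exactly.
#'
#' @param signal an [sbx_signal()].
#' @param lambda leak rate (1/s).
#' @return An [sbx_signal()] holding `c(t)`, with the reference attached.
#' @export
command_from_signal <- function(signal, lambda) {
  cmd <- sbx_signal(signal$times, lambda * signal$x + signal$xdot,
                    central_diff(lambda * signal$x + signal$xdot, signal$dt))
  attr(cmd, "trajectory") <- signal
  cmd
}

# Exponentially consistent drive increments B[, n] = x[, n+1] - e^{-l dt} x[, n]
drive_increments <- function(signal, lambda) {
  n <- ncol(signal$x)
  dec <- exp(-lambda * signal$dt)
  signal$x[, 2:n, drop = FALSE] - dec * signal$x[, 1:(n - 1), drop = FALSE]
}

# Drive increments from a raw command: exponentially weighted trapezoid of
# int e^{-lambda(t_{n+1}-s)} c(s) ds over each step.
command_increments <- function(command, lambda) {
  n <- ncol(command$x)
  dt <- command$dt
  dec <- exp(-lambda * dt)
  (dt / 2) * (dec * command$x[, 1:(n - 1), drop = FALSE] +
                command$x[, 2:n, drop = FALSE])
}

# Shared core runner: assembles schedules from perturbation records and calls
# the compiled integrator.
run_core <- function(decoders, params, signal, drive, Wslow, seed,
                     perturbations, Omega, V0, record_V, max_total_spikes) {
  D <- unclass(decoders)
  M <- nrow(D); N <- ncol(D)
  nsteps <- ncol(drive)
  dt <- signal$dt
  if (is.null(Omega)) Omega <- fast_connectivity(decoders, params$F)
  F <- if (is.null(params$F)) t(D) else params$F

  sched <- build_schedules(perturbations, decoders, params, Omega, nsteps, dt)
  if (!is.null(sched$kill_idx)) {
    keep <- setdiff(seq_len(N), sched$kill_idx)
    if (!length(keep)) stop("empty network: cannot kill all neurons")
    return(run_core(decoder_set(D[, keep, drop = FALSE]),
                    subset_params(params, keep, N), signal, drive,
                    Wslow = if (is.null(Wslow)) NULL
                            else Wslow[keep, keep, drop = FALSE],
                    seed = seed, perturbations = sched$rest,
                    Omega = Omega[keep, keep, drop = FALSE],
                    V0 = if (is.null(V0)) NULL else V0[keep],
                    record_V = record_V, max_total_spikes = max_total_spikes))
  }
  Omega <- sched$Omega
  Tv <- threshold_vector(params, N)
  # voltages encode the projected initial error F (x(0) - xhat(0)), with
  # xhat(0) = 0
  if (is.null(V0)) V0 <- drop(F %*% signal$x[, 1])
  max_sub <- if (is.null(params$max_substeps)) 10L * N else params$max_substeps
  delay <- if (!is.null(sched$delay_override)) sched$delay_override else params$delay
  delay_steps <- if (delay > 0) as.integer(ceiling(delay / dt - 1e-9)) else 0L

  Fdrive <- F %*% drive
  empty <- matrix(numeric(0), 0, 0)
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  raw <- .sim_core(Fdrive, Omega,
                   if (is.null(sched$Omega2)) empty else sched$Omega2,
                   sched$om2_start, sched$om2_end,
                   if (is.null(Wslow)) empty else Wslow,
                   Tv,
                   if (is.null(sched$Tshift)) empty else sched$Tshift,
                   if (is.null(sched$Pcur)) empty else sched$Pcur,
                   sched$sigma_t,
                   params$lambda, dt, params$tau_ref, delay_steps,
                   as.integer(max_sub), max_total_spikes,
                   V0, numeric(N), isTRUE(record_V))
  if (raw$diverged)
    stop(sprintf("simulation diverged (non-finite voltage) at step %d",
                 raw$diverged_step))
  keep_n <- raw$completed_steps + 1L
  r <- raw$r[, seq_len(keep_n), drop = FALSE]
  structure(list(
    spikes = data.frame(time_s = raw$spike_times, neuron = raw$spike_ids),
    V = if (isTRUE(record_V)) raw$V[, seq_len(keep_n), drop = FALSE] else NULL,
    r = r,
    xhat = D %*% r,
    times = signal$times[seq_len(keep_n)],
    substep_overflow = raw$substep_overflow,
    truncated = raw$truncated,
    event_log = raw$spikes_per_step,
    total_spikes = raw$total_spikes,
    decoders = decoders, params = params, signal = signal
  ), class = "sim_result")
}

subset_params <- function(params, keep, N) {
  p <- params
  Tv <- rep_len(p$threshold, N)
  p$threshold <- Tv[keep]
  if (!is.null(p$F)) p$F <- p$F[keep, , drop = FALSE]
  p
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> N = %d neurons, %d spikes over %.3g s%s%s\n",
              nrow(x$r), nrow(x$spikes),
              x$times[length(x$times)] - x$times[1],
              if (x$substep_overflow) " [substep overflow]" else "",
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}
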