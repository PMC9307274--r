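#' Coefficient of variation of interspike intervals
#'
#' `sd(ISI)/mean(ISI)` with the sample (n-1) standard deviation. Close to 1
#' for Poisson-like firing, close to 0 for clock-like firing.
#'
#' @param spike_times one neuron's spike times (needs >= 3 spikes, i.e. >= 2
#'   intervals).
#' @return The CV, or `NA_real_` (with no error) for fewer than 3 spikes so
#'   that such neurons can be excluded from pooling.
#' @export
isi_cv <- function(spike_times) {
  if (length(spike_times) < 3) return(NA_real_)
  isi <- diff(sort(spike_times))
  sd(isi) / mean(isi)
}

#' Per-neuron firing rates
#'
#' Total spike count divided by trial duration, for every neuron.
#'
#' @param spikes spike data frame (`time_s`, `neuron`).
#' @param N number of neurons.
#' @param duration trial duration in seconds.
#' @return A length-N vector of rates in Hz.
#' @export
firing_rates <- function(spikes, N, duration) {
  tabulate(spikes$neuron, nbins = N) / duration
}

#' Trial coding error
#'
#' The time average of the Euclidean distance
#' \eqn{E = \langle \|x(t) - \hat x(t)\|_2 \rangle_t}. The initial transient
#' (by default the first 0.5 s, covering the 400 ms input ramp) is excluded
#' from the average.
#'
#' @param x M x timesteps signal values.
#' @param xhat M x timesteps readout (raw or corrected).
#' @param times time grid; when given with `exclude`, samples with
#'   `t < exclude` are dropped.
#' @param exclude transient exclusion in seconds (default 0 when `times` is
#'   missing, 0.5 otherwise).
#' @return The scalar error `E` in signal units.
#' @export
error_E <- function(x, xhat, times = NULL, exclude = if (is.null(times)) 0 else 0.5) {
  n <- min(ncol(x), ncol(xhat))
  keep <- seq_len(n)
  if (!is.null(times) && exclude > 0) keep <- keep[times[keep] >= exclude]
  mean(sqrt(colSums((x[, keep, drop = FALSE] - xhat[, keep, drop = FALSE])^2)))
}

#' Dead-network error
#'
#' The error of a non-functional network with \eqn{\hat x \equiv 0}:
#' \eqn{E_{dead} = \langle \|x(t)\| \rangle_t}, with the same transient
#' exclusion as [error_E()].
#'
#' @inheritParams error_E
#' @return The scalar dead error.
#' @export
dead_error <- function(x, times = NULL, exclude = if (is.null(times)) 0 else 0.5) {
  error_E(x, matrix(0, nrow(x), ncol(x)), times = times, exclude = exclude)
}

#' Relative network performance
#'
#' \eqn{P = (E_{pert} - E_{dead}) / (E_{ref} - E_{dead})}: 1 for an
#' unperturbed network, 0 for a dead one.
#'
#' @param E_pert error of the perturbed trial.
#' @param E_ref error of the paired unperturbed trial.
#' @param E_dead dead-network error of the same signal.
#' @return The scalar performance `P`.
#' @export
performance_P <- function(E_pert, E_ref, E_dead) {
  if (abs(E_ref - E_dead) < 1e-300)
    stop("undefined performance: reference and dead errors coincide")
  (E_pert - E_dead) / (E_ref - E_dead)
}

#' Pooled per-component coding errors
#'
#' Pools the absolute errors of every individual signal component,
#' \eqn{|x_i - \hat x_i|}, across components and time, giving a
#' dimensionality-independent error distribution; the median is reported.
#'
#' @inheritParams error_E
#' @return A list with the pooled `samples` and their `median`.
#' @export
pooled_component_error <- function(x, xhat, times = NULL,
                                   exclude = if (is.null(times)) 0 else 0.5) {
  n <- min(ncol(x), ncol(xhat))
  keep <- seq_len(n)
  if (!is.null(times) && exclude > 0) keep <- keep[times[keep] >= exclude]
  samples <- as.vector(abs(x[, keep, drop = FALSE] - xhat[, keep, drop = FALSE]))
  list(samples = samples, median = median(samples))
}

#' Excitation-inhibition balance per neuron
#'
#' Splits the total synaptic input of neuron `j` over a trial into its
#' positive and negative parts:
#' \deqn{C_j^\pm = \int dt\, [\pm D_j^\top(\lambda x + \dot x)]_+ +
#'   \sum_{k \ne j} [\mp D_j^\top D_k]_+ n_k}
#' (feedforward integrated on the grid; each spike of neuron `k` contributes
#' its full recurrent increment at its delivery step), and reports
#' \eqn{b_j = (C_j^+ - C_j^-)/(C_j^+ + C_j^-) \in [-1, 1]}: 0 for perfect
#' balance, positive for net excitation, negative for net inhibition.
#'
#' @param decoders a [decoder_set()].
#' @param params a [network_params()] (for `lambda`).
#' @param signal the trial's [sbx_signal()].
#' @param spikes spike data frame of the trial.
#' @return A length-N vector of balances; `NA` where a neuron received no
#'   input at all.
#' @export
ei_balance <- function(decoders, params, signal, spikes) {
  D <- unclass(decoders)
  N <- ncol(D)
  ff <- crossprod(D, params$lambda * signal$x + signal$xdot)  # N x timesteps
  dt <- signal$dt
  Cp <- dt * rowSums(pmax(ff, 0))
  Cm <- dt * rowSums(pmax(-ff, 0))
  if (nrow(spikes)) {
    counts <- tabulate(spikes$neuron, nbins = N)
    W <- -crossprod(D)          # Omega: recurrent weight from k onto j
    diag(W) <- 0                # self-resets are not synaptic input here
    Cp <- Cp + pmax(W, 0) %*% counts
    Cm <- Cm + pmax(-W, 0) %*% counts
  }
  tot <- Cp + Cm
  b <- ifelse(tot > 0, (Cp - Cm) / tot, NA_real_)
  as.vector(b)
}

#' Detect runaway ("ping-pong") firing
#'
#' Flags a trial as ping-pong when the total spike count exceeds `c_pp` times
#' a reference count (from a paired unperturbed trial or an analytic
#' estimate), or when the sub-step cap overflowed or the simulation was
#' truncated by its spike budget.
#'
#' @param result a `sim_result`.
#' @param reference_count expected spike count of a healthy trial.
#' @param c_pp multiplier on the reference count (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
detect_pingpong <- function(result, reference_count, c_pp = 5) {
  isTRUE(result$substep_overflow) || isTRUE(result$truncated) ||
    result$total_spikes > c_pp * reference_count
}

#' Analytic spike-count estimate for a healthy trial
#'
#' In a tracking network every spike moves the readout by a unit jump, and the
#' readout must counteract its own leak \eqn{\lambda \|\hat x\|}, so a healthy
#' trial fires about \eqn{\lambda \int \|x(t)\|\, dt} spikes in total.
#'
#' @param signal an [sbx_signal()].
#' @param lambda leak rate (1/s).
#' @return The estimated network-wide spike count.
#' @export
expected_spike_count <- function(signal, lambda) {
  lambda * sum(sqrt(colSums(signal$x^2))) * signal$dt
}

#' Residual of the voltage outside the decoder subspace
#'
#' Noiseless coordinated dynamics confine the N-dimensional voltage vector to
#' the M-dimensional row space of \eqn{D^\top} (the voltage subspace whose
#' borders are the bounding box). This returns the maximum over time of the
#' norm of the component of `V` orthogonal to that subspace.
#'
#' @param V N x timesteps voltage traces.
#' @param decoders a [decoder_set()].
#' @return The scalar maximal residual norm.
#' @export
subspace_residual <- function(V, decoders) {
  Q <- qr.Q(qr(t(unclass(decoders))))        # orthonormal basis of span(D^T)
  resid <- V - Q %*% crossprod(Q, V)
  sqrt(max(colSums(resid^2)))
}

#' Summarize one trial
#'
#' Bundles the published per-trial metrics: coding error `E`, relative
#' performance `P` (when references are given), per-neuron rates, CVs and E-I
#' balances, the pooled component errors, and the ping-pong flag.
#'
#' @param result a `sim_result`.
#' @param E_ref,E_dead optional reference errors for `P`.
#' @param reference_count optional healthy spike count for ping-pong
#'   detection; defaults to [expected_spike_count()] of the trial's signal.
#' @param exclude transient exclusion in seconds for the error averages.
#' @return An object of class `trial_outcome` (a list).
#' @export
trial_outcome <- function(result, E_ref = NULL, E_dead = NULL,
                          reference_count = NULL, exclude = 0.5) {
  sig <- result$signal
  n <- length(result$times)
  x <- sig$x[, seq_len(n), drop = FALSE]
  E <- error_E(x, result$xhat, times = result$times, exclude = exclude)
  Ed <- if (is.null(E_dead)) dead_error(x, times = result$times,
                                        exclude = exclude) else E_dead
  P <- if (!is.null(E_ref)) performance_P(E, E_ref, Ed) else NA_real_
  N <- nrow(result$r)
  dur <- result$times[n] - result$times[1]
  rates <- firing_rates(result$spikes, N, dur)
  cvs <- vapply(seq_len(N), function(k)
    isi_cv(result$spikes$time_s[result$spikes$neuron == k]), numeric(1))
  bal <- ei_balance(result$decoders, result$params, sig, result$spikes)
  refc <- if (is.null(reference_count))
    expected_spike_count(sig, result$params$lambda) else reference_count
  structure(list(
    E = E, E_dead = Ed, P = P, rates = rates, cvs = cvs, balance = bal,
    pingpong = detect_pingpong(result, refc),
    pooled_errors = pooled_component_error(x, result$xhat,
                                           times = result$times,
                                           exclude = exclude)$samples,
    total_spikes = result$total_spikes
  ), class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf("<trial_outcome> E = %.4g, P = %s, median rate = %.3g Hz, median CV = %.3g%s\n",
              x$E, if (is.na(x$P)) "-" else sprintf("%.3g", x$P),
              median(x$rates), median(x$cvs, na.rm = TRUE),
              if (x$pingpong) " [ping-pong]" else ""))
  invisible(x)
}
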