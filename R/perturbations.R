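#' Perturbation records
#'
#' A perturbation is a tagged description of one structural or dynamical
#' change to a network, applied by [simulate_network()] /
#' [simulate_slow_network()] via the `perturbations` argument. Kinds:
#'
#' * `"kill"` — remove the target neurons (their faces leave the box). With a
#'   `window`, the neurons are silenced only inside the window (their
#'   thresholds are pushed effectively to infinity).
#' * `"current"` — injected current of amplitude `magnitude` (V/s, positive =
#'   excitatory) into the targets during `window`; equivalent to a transient
#'   threshold shift of \eqn{-(h * p)} with \eqn{h(t) = \Theta(t) e^{-\lambda t}}.
#' * `"threshold_shift"` — additive shift of the targets' thresholds.
#' * `"reset_mistune"` — post-spike voltage becomes ideal reset + `magnitude`
#'   (the self-reset weight is adjusted).
#' * `"synaptic_mistune"` — every off-diagonal weight is multiplied by
#'   \eqn{(1-\delta_\Omega)^{u}}, \eqn{u \sim U(-1,1)}; `magnitude` is
#'   \eqn{\delta_\Omega \in [0, 1)}; a `seed` makes the draw reproducible.
#' * `"widen_box"` — all thresholds scaled by `magnitude` (>= 1); reset
#'   weights unchanged.
#' * `"prune_excitatory"` — the `magnitude` largest positive off-diagonal
#'   weights set to zero, pair-symmetrically.
#' * `"delay"` — overrides the synaptic delay for the whole trial (a window
#'   is not supported for this kind).
#' * `"voltage_noise"` — extra voltage noise of scale `magnitude` added (in
#'   quadrature) inside the window.
#'
#' Windowed `reset_mistune`, `synaptic_mistune` and `prune_excitatory`
#' perturbations share a single alternate-connectivity window; at most one
#' such window may be active per run.
#'
#' @param kind one of the kinds above.
#' @param targets integer vector of neuron indices, or `"all"`.
#' @param magnitude kind-specific scalar.
#' @param window optional `c(t_on, t_off)` in seconds; `NULL` = whole trial.
#' @param seed optional seed for the stochastic kinds.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(kind, targets = "all", magnitude = NULL,
                         window = NULL, seed = NULL) {
  kinds <- c("kill", "current", "threshold_shift", "reset_mistune",
             "synaptic_mistune", "delay", "widen_box", "prune_excitatory",
             "voltage_noise")
  kind <- match.arg(kind, kinds)
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] < 0 || window[2] <= window[1])
      stop("'window' must be c(t_on, t_off) with 0 <= t_on < t_off")
  }
  structure(list(kind = kind, targets = targets, magnitude = magnitude,
                 window = window, seed = seed),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s, targets = %s, magnitude = %s, window = %s\n",
              x$kind, paste(x$targets, collapse = ","),
              if (is.null(x$magnitude)) "-" else format(x$magnitude),
              if (is.null(x$window)) "whole trial"
              else paste(format(x$window), collapse = "-")))
  invisible(x)
}

resolve_targets <- function(targets, N) {
  if (identical(targets, "all")) return(seq_len(N))
  targets <- as.integer(targets)
  if (any(targets < 1 | targets > N))
    stop("perturbation targets out of range 1..N")
  targets
}

#' Remove neurons from a network
#'
#' The death of a neuron removes its face from the bounding box: its column
#' leaves the decoder set and its row/column leave the connectivity; its
#' threshold is dropped.
#'
#' @param decoders a [decoder_set()].
#' @param params a [network_params()].
#' @param idx indices of neurons to remove (an empty set is the identity).
#' @return A list with the reduced `decoders` and `params`.
#' @export
kill_neurons <- function(decoders, params, idx) {
  N <- ncol(decoders)
  idx <- as.integer(idx)
  if (!length(idx)) return(list(decoders = decoders, params = params))
  if (any(idx < 1 | idx > N)) stop("'idx' out of range")
  keep <- setdiff(seq_len(N), idx)
  if (!length(keep)) stop("empty network: cannot kill all neurons")
  list(decoders = decoder_set(unclass(decoders)[, keep, drop = FALSE]),
       params = subset_params(params, keep, N))
}

#' Injected-current perturbation
#'
#' Convenience constructor for a `"current"` [perturbation()]. A constant
#' current `p` on a neuron shifts its effective threshold by
#' \eqn{-(h * p)(t)}, approaching \eqn{-p/\lambda} at steady state.
#'
#' @param targets neuron indices or `"all"`.
#' @param amplitude current in V/s (positive = excitatory).
#' @param window `c(t_on, t_off)` seconds; `NULL` = whole trial.
#' @return A [perturbation()] record.
#' @export
inject_current <- function(targets, amplitude, window = NULL) {
  perturbation("current", targets = targets, magnitude = amplitude,
               window = window)
}

#' Mistune self-reset weights
#'
#' Sets the post-spike voltage of the target neurons to the ideal reset plus
#' `delta` by adding `delta` to the corresponding diagonal entries of the
#' connectivity. A positive `delta` leaves the neuron closer to threshold
#' after each spike (an inward push of its face that decays with the leak).
#'
#' @param Omega fast connectivity matrix.
#' @param targets neuron indices.
#' @param delta voltage offset added to the ideal reset.
#' @return The adjusted connectivity.
#' @export
mistune_resets <- function(Omega, targets, delta) {
  targets <- resolve_targets(targets, nrow(Omega))
  if (any(delta >= -diag(Omega)[targets]))
    warning("reset offset >= |self-reset|: neuron re-crosses threshold immediately (runaway risk)")
  diag(Omega)[targets] <- diag(Omega)[targets] + delta
  Omega
}

#' Randomly mistune all synapses
#'
#' Multiplies every off-diagonal weight by \eqn{(1-\delta_\Omega)^{u_{ij}}}
#' with \eqn{u_{ij} \sim U(-1, 1)}, i.e. a random factor in
#' \eqn{[1-\delta_\Omega, (1-\delta_\Omega)^{-1}]}. Diagonal (self-reset)
#' entries are untouched.
#'
#' @param Omega fast connectivity matrix.
#' @param delta_Omega maximum relative weight change, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return The perturbed connectivity.
#' @export
mistune_synapses <- function(Omega, delta_Omega, seed = NULL) {
  if (delta_Omega < 0 || delta_Omega >= 1)
    stop("'delta_Omega' must be in [0, 1)")
  if (delta_Omega == 0) return(Omega)
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  N <- nrow(Omega)
  u <- matrix(runif(N * N, -1, 1), N, N)
  fac <- (1 - delta_Omega)^u
  diag(fac) <- 1
  Omega * fac
}

#' Widen the bounding box
#'
#' Scales all thresholds by `factor >= 1`; reset weights are unchanged, so the
#' box cross-section radii scale exactly by `factor`. Trades coding precision
#' for resilience against noise and delays.
#'
#' @param params a [network_params()].
#' @param factor widening factor, >= 1.
#' @return The adjusted [network_params()].
#' @export
widen_box <- function(params, factor) {
  if (factor < 1) stop("'factor' must be >= 1")
  params$threshold <- params$threshold * factor
  params
}

#' Prune the largest excitatory connections
#'
#' Sets the `k` largest positive off-diagonal weights to zero,
#' pair-symmetrically (both directions of each pair count as one connection).
#' Removing the excitation between near-antipodal neurons temporarily widens
#' the box in the overshoot direction after each spike, protecting against
#' ping-pong.
#'
#' @param Omega fast connectivity matrix (symmetric).
#' @param k number of excitatory pairs to remove; clamped with a warning when
#'   larger than the number of positive pairs.
#' @return The pruned connectivity.
#' @export
prune_excitatory <- function(Omega, k) {
  if (k < 0) stop("'k' must be non-negative")
  if (k == 0) return(Omega)
  N <- nrow(Omega)
  ut <- which(upper.tri(Omega) & Omega > 0, arr.ind = TRUE)
  if (!nrow(ut)) return(Omega)
  if (k > nrow(ut)) {
    warning(sprintf("only %d positive pairs present; clamping k", nrow(ut)))
    k <- nrow(ut)
  }
  w <- Omega[ut]
  sel <- ut[order(w, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
  Omega[sel] <- 0
  Omega[sel[, c(2, 1), drop = FALSE]] <- 0
  Omega
}

#' Threshold schedule equivalent to an injected current
#'
#' The discrete counterpart of the current/threshold equivalence: with
#' per-step currents `Pcur` (N x nsteps, V/s), the equivalent additive
#' threshold shift at grid point `n` is minus the leaky accumulation
#' \eqn{c_n = e^{-\lambda dt} c_{n-1} + dt\, p_n}. Simulating with the current
#' or with this shift yields identical spike trains.
#'
#' @param Pcur N x nsteps matrix of currents.
#' @param lambda leak rate (1/s).
#' @param dt time step (s).
#' @return An N x (nsteps + 1) threshold-shift matrix (first column zero).
#' @export
equivalent_threshold_shift <- function(Pcur, lambda, dt) {
  N <- nrow(Pcur); nsteps <- ncol(Pcur)
  out <- matrix(0, N, nsteps + 1)
  dec <- exp(-lambda * dt)
  acc <- numeric(N)
  for (n in seq_len(nsteps)) {
    acc <- dec * acc + dt * Pcur[, n]
    out[, n + 1] <- -acc
  }
  out
}

# window -> step index range (1-based, steps 1..nsteps); step n spans
# ((n-1) dt, n dt]
window_steps <- function(window, nsteps, dt) {
  if (is.null(window)) return(c(1L, nsteps))
  i0 <- max(1L, as.integer(floor(window[1] / dt + 1e-9)) + 1L)
  i1 <- min(nsteps, as.integer(ceiling(window[2] / dt - 1e-9)))
  if (i1 < i0) stop("perturbation window does not overlap the trial")
  c(i0, i1)
}

# Assemble per-step schedules and connectivity variants from a list of
# perturbation records. Returns early with `kill_idx` when an unwindowed kill
# is present (the caller rebuilds the reduced network and re-applies the
# remaining records, whose targets then refer to the reduced indexing).
build_schedules <- function(perturbations, decoders, params, Omega, nsteps,
                            dt) {
  N <- ncol(decoders)
  out <- list(Omega = Omega, Omega2 = NULL, om2_start = -1L, om2_end = -1L,
              Tshift = NULL, Pcur = NULL,
              sigma_t = rep(params$sigma_V, nsteps),
              kill_idx = NULL, rest = list(), delay_override = NULL)
  if (!length(perturbations)) return(out)
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)

  for (j in seq_along(perturbations)) {
    p <- perturbations[[j]]
    if (!inherits(p, "perturbation")) stop("perturbations must be perturbation() records")
    if (p$kind == "kill" && is.null(p$window)) {
      out$kill_idx <- resolve_targets(p$targets, N)
      out$rest <- perturbations[-j]
      return(out)
    }
  }

  need_T <- function() {
    if (is.null(out$Tshift)) out$Tshift <<- matrix(0, N, nsteps + 1)
  }
  need_P <- function() {
    if (is.null(out$Pcur)) out$Pcur <<- matrix(0, N, nsteps)
  }
  om2_window <- NULL

  for (p in perturbations) {
    idx <- resolve_targets(p$targets, N)
    ws <- window_steps(p$window, nsteps, dt)
    switch(p$kind,
      kill = {  # windowed kill: silence via an effectively infinite threshold
        need_T()
        out$Tshift[idx, (ws[1] + 1):(ws[2] + 1)] <-
          out$Tshift[idx, (ws[1] + 1):(ws[2] + 1)] + 1e9
      },
      current = {
        need_P()
        out$Pcur[idx, ws[1]:ws[2]] <- out$Pcur[idx, ws[1]:ws[2]] + p$magnitude
      },
      threshold_shift = {
        need_T()
        if (is.matrix(p$magnitude)) {
          # a full N x (nsteps + 1) schedule, e.g. from
          # equivalent_threshold_shift(); the window must be NULL
          if (!is.null(p$window))
            stop("a threshold-shift schedule matrix carries its own timing; 'window' must be NULL")
          if (!all(dim(p$magnitude) == c(N, nsteps + 1)))
            stop("threshold-shift schedule must be N x (nsteps + 1)")
          out$Tshift <- out$Tshift + p$magnitude
        } else {
          cols <- if (is.null(p$window)) seq_len(nsteps + 1)
                  else (ws[1] + 1):(ws[2] + 1)
          out$Tshift[idx, cols] <- out$Tshift[idx, cols] + p$magnitude
        }
      },
      widen_box = {
        if (p$magnitude < 1) stop("widen_box factor must be >= 1")
        need_T()
        Tv <- threshold_vector(params, N)
        cols <- if (is.null(p$window)) seq_len(nsteps + 1)
                else (ws[1] + 1):(ws[2] + 1)
        out$Tshift[idx, cols] <- out$Tshift[idx, cols] +
          (p$magnitude - 1) * Tv[idx]
      },
      voltage_noise = {
        rng <- ws[1]:ws[2]
        out$sigma_t[rng] <- sqrt(out$sigma_t[rng]^2 + p$magnitude^2)
      },
      delay = {
        if (!is.null(p$window))
          warning("windowed 'delay' perturbations are not supported; applying to the whole trial")
        out$delay_override <- p$magnitude
      },
      reset_mistune = ,
      synaptic_mistune = ,
      prune_excitatory = {
        apply_om <- function(Om) {
          switch(p$kind,
            reset_mistune = mistune_resets(Om, idx, p$magnitude),
            synaptic_mistune = mistune_synapses(Om, p$magnitude, p$seed),
            prune_excitatory = prune_excitatory(Om, p$magnitude))
        }
        if (is.null(p$window)) {
          out$Omega <- apply_om(out$Omega)
        } else {
          if (!is.null(om2_window) && !isTRUE(all.equal(om2_window, p$window)))
            stop("at most one windowed connectivity-perturbation window per run")
          om2_window <- p$window
          if (is.null(out$Omega2)) out$Omega2 <- out$Omega
          out$Omega2 <- apply_om(out$Omega2)
        }
      })
  }
  if (!is.null(om2_window)) {
    ws <- window_steps(om2_window, nsteps, dt)
    out$om2_start <- ws[1] - 1L   # 0-based step indices for the core
    out$om2_end <- ws[2]
  }
  out
}
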