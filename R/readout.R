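#' Exponentially filtered spike trains
#'
#' \eqn{r_k(t) = \sum_{\mathrm{spikes}\ t_s \le t} e^{-\lambda (t - t_s)}}:
#' each spike of neuron `k` adds a unit jump to `r_k` that decays with rate
#' `lambda`.
#'
#' @param spikes data frame with columns `time_s` and `neuron` (1-based ids).
#' @param lambda filter rate, 1/s.
#' @param times evaluation grid (uniform step).
#' @param N number of neurons; defaults to `max(spikes$neuron)`.
#' @return An N x length(times) matrix of filtered spike trains.
#' @export
filter_spikes <- function(spikes, lambda, times, N = NULL) {
  if (is.null(N)) N <- if (nrow(spikes)) max(spikes$neuron) else 1L
  n <- length(times)
  dt <- if (n > 1) times[2] - times[1] else 1
  r <- matrix(0, N, n)
  if (!nrow(spikes)) return(r)
  if (any(spikes$time_s < times[1] - 1e-12 |
          spikes$time_s > times[n] + 1e-12))
    stop("spike times outside the grid span")
  dec <- exp(-lambda * dt)
  # bucket spike jumps onto the nearest grid point at or after the spike,
  # then run the exact per-step decay recursion
  bins <- pmin(n, pmax(1L, as.integer(ceiling((spikes$time_s - times[1]) / dt - 1e-9)) + 1L))
  jumps <- matrix(0, N, n)
  for (s in seq_len(nrow(spikes))) {
    jumps[spikes$neuron[s], bins[s]] <- jumps[spikes$neuron[s], bins[s]] +
      exp(-lambda * (times[bins[s]] - spikes$time_s[s]))
  }
  r[, 1] <- jumps[, 1]
  for (j in 2:n) r[, j] <- dec * r[, j - 1] + jumps[, j]
  r
}

#' Linear readout
#'
#' \eqn{\hat x(t) = D r(t)}: the decoder-weighted sum of the filtered spike
#' trains.
#'
#' @param decoders a [decoder_set()].
#' @param r N x timesteps matrix of filtered spike trains.
#' @return The M x timesteps readout.
#' @export
decode <- function(decoders, r) {
  if (nrow(r) != ncol(decoders))
    stop("'r' must have one row per decoder column")
  unclass(decoders) %*% r
}

#' Hypersphere readout correction
#'
#' Rescales the readout by
#' \eqn{(\langle\|Dr\|\rangle + T - 1/2)/\langle\|Dr\|\rangle}, which removes
#' the systematic inward bias of the time-averaged readout when the box is
#' (close to) a hypersphere and spikes jump a fixed length 1. The
#' instantaneous variant replaces the time average by \eqn{\|Dr(t)\|} and is
#' the default for nonstationary signals. The correction changes only the
#' length of the readout, never its direction.
#'
#' @param xhat M x timesteps raw readout (`D r`).
#' @param threshold the (scalar) threshold `T`.
#' @param method `"instantaneous"` (default) or `"average"`.
#' @return An object of class `corrected_readout`: list with
#'   `xhat_corrected`, `method`, `scale_trace`.
#' @export
correct_sphere <- function(xhat, threshold,
                           method = c("instantaneous", "average")) {
  method <- match.arg(method)
  nrm <- sqrt(colSums(xhat^2))
  if (method == "average") {
    mn <- mean(nrm)
    if (mn <= 0) stop("undefined correction: zero time-averaged readout norm")
    scale <- (mn + threshold - 0.5) / mn
    out <- xhat * scale
  } else {
    scale <- ifelse(nrm > 0, (nrm + threshold - 0.5) / nrm, 1)
    out <- sweep(xhat, 2, scale, "*")
  }
  structure(list(xhat_corrected = out, method = paste0("sphere_", method),
                 scale_trace = scale),
            class = "corrected_readout")
}

#' Hypercube readout correction
#'
#' Adds \eqn{\sum_{i \in S} (1/2 - T/\|D_i\|^2) D_i} to the readout, where `S`
#' is the set of neurons that spiked within a trailing time window. Exact for
#' a hypercube box where each active face contributes a known offset.
#'
#' @param xhat M x timesteps raw readout.
#' @param decoders a [decoder_set()].
#' @param spikes spike data frame (`time_s`, `neuron`).
#' @param times the readout time grid.
#' @param threshold the (scalar) threshold `T`.
#' @param active_window trailing window length in seconds defining `S`;
#'   defaults to `1/lambda` via the caller (pass explicitly here).
#' @return A `corrected_readout` (the `scale_trace` holds the per-neuron
#'   offsets `1/2 - T/||D_i||^2`).
#' @export
correct_cube <- function(xhat, decoders, spikes, times, threshold,
                         active_window) {
  if (active_window <= 0) stop("'active_window' must be positive")
  D <- unclass(decoders)
  offs <- 0.5 - threshold / colSums(D^2)
  out <- xhat
  if (nrow(spikes)) {
    for (j in seq_along(times)) {
      S <- unique(spikes$neuron[spikes$time_s <= times[j] + 1e-12 &
                                  spikes$time_s > times[j] - active_window])
      if (length(S))
        out[, j] <- out[, j] + D[, S, drop = FALSE] %*% offs[S]
    }
  }
  structure(list(xhat_corrected = out, method = "cube", scale_trace = offs),
            class = "corrected_readout")
}

#' @export
print.corrected_readout <- function(x, ...) {
  cat(sprintf("<corrected_readout> method = %s, %d timesteps\n", x$method,
              ncol(x$xhat_corrected)))
  invisible(x)
}
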