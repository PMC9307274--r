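#' Input signals on a uniform time grid
#'
#' A signal bundles a uniform time grid (seconds), the M x length(times) value
#' matrix `x`, and its time derivative `xdot` on the same grid.
#'
#' @param times strictly increasing, uniformly spaced times in seconds.
#' @param x M x length(times) numeric matrix of signal values.
#' @param xdot matrix of the same shape with the time derivative.
#' @return An object of class `sbx_signal`.
#' @export
sbx_signal <- function(times, x, xdot) {
  x <- as.matrix(x); xdot <- as.matrix(xdot)
  if (ncol(x) != length(times) || !all(dim(x) == dim(xdot)))
    stop("'x' and 'xdot' must be M x length(times) matrices")
  dts <- diff(times)
  if (length(dts) && (any(dts <= 0) || diff(range(dts)) > 1e-9 * dts[1]))
    stop("'times' must be strictly increasing with a uniform step")
  structure(list(times = times, x = x, xdot = xdot,
                 dt = if (length(dts)) dts[1] else NA_real_),
            class = "sbx_signal")
}

#' @export
print.sbx_signal <- function(x, ...) {
  cat(sprintf("<sbx_signal> M = %d dimensions, %d steps of dt = %g s (%.3g s)\n",
              nrow(x$x), length(x$times) - 1, x$dt,
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' Circular two-dimensional input signal
#'
#' \eqn{x(t) = (a \sin\omega t, a \cos\omega t)} with constant amplitude `a`
#' and angular frequency `omega`; the derivative is analytic.
#'
#' @param a amplitude (> 0), signal units.
#' @param omega angular frequency in rad/s (non-zero).
#' @param duration trial duration in seconds.
#' @param dt grid step in seconds.
#' @return An [sbx_signal()] with M = 2.
#' @export
circular_signal <- function(a, omega, duration, dt = 1e-4) {
  if (a <= 0) stop("'a' must be positive")
  if (omega == 0) stop("'omega' must be non-zero")
  times <- seq(0, duration, by = dt)
  x <- rbind(a * sin(omega * times), a * cos(omega * times))
  xdot <- rbind(a * omega * cos(omega * times), -a * omega * sin(omega * times))
  sbx_signal(times, x, xdot)
}

# centred moving average with truncated boundaries, O(n) via cumulative sums
moving_average <- function(z, half) {
  n <- length(z)
  cs <- c(0, cumsum(z))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# central finite differences on a uniform grid (one-sided at the ends)
central_diff <- function(x, dt) {
  n <- ncol(x)
  xd <- matrix(0, nrow(x), n)
  if (n >= 3) xd[, 2:(n - 1)] <- (x[, 3:n] - x[, 1:(n - 2)]) / (2 * dt)
  if (n >= 2) {
    xd[, 1] <- (x[, 2] - x[, 1]) / dt
    xd[, n] <- (x[, n] - x[, n - 1]) / dt
  }
  xd
}

#' Constant input with ramp and slow trial-to-trial variability
#'
#' Draws an operating point \eqn{x_0 \sim N(0, \sigma_x^2 I)}, ramps the
#' signal linearly from zero to \eqn{x_0} during the first 400 ms, and
#' afterwards adds a slow wander: white Gaussian noise twice smoothed with a
#' centred 1 s moving-average window, mean-centred per dimension, and rescaled
#' so that its magnitude never exceeds `eta_x`. The derivative is obtained by
#' central finite differences on the grid.
#'
#' @param M number of signal dimensions.
#' @param sigma_x standard deviation of the operating point (default 1).
#' @param eta_x cap on the slow variability magnitude (default 0.5).
#' @param duration trial duration in seconds (> 0.4).
#' @param dt grid step in seconds.
#' @param seed optional integer seed; the same seed gives a bit-identical
#'   signal.
#' @param x0 optional fixed operating point (length M), bypassing the random
#'   draw; the slow variability is still applied.
#' @return An [sbx_signal()]; the operating point is attached as attribute
#'   `x0`.
#' @export
ramped_slow_noise_signal <- function(M, sigma_x = 1, eta_x = 0.5, duration = 2,
                                     dt = 1e-4, seed = NULL, x0 = NULL) {
  ramp <- 0.4
  if (duration <= ramp)
    stop("'duration' must exceed the 400 ms ramp")
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  times <- seq(0, duration, by = dt)
  n <- length(times)
  if (is.null(x0)) x0 <- rnorm(M, sd = sigma_x)
  stopifnot(length(x0) == M)
  x <- outer(x0, pmin(times / ramp, 1))
  post <- which(times > ramp + 1e-12)
  if (length(post) > 1) {
    half <- round(0.5 / dt)
    slow <- matrix(rnorm(M * length(post)), M)
    for (d in seq_len(M)) {
      s <- moving_average(moving_average(slow[d, ], half), half)
      s <- s - mean(s)
      mx <- max(abs(s))
      if (mx > 0) s <- s * (eta_x / mx)
      slow[d, ] <- s
    }
    x[, post] <- x[, post] + slow
  }
  out <- sbx_signal(times, x, central_diff(x, dt))
  attr(out, "x0") <- x0
  out
}

#' Write a signal to CSV
#'
#' One row per time point: `time_s`, the M signal values, then the M
#' derivative values.
#'
#' @param signal an [sbx_signal()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  M <- nrow(signal$x)
  df <- data.frame(time_s = signal$times, t(signal$x), t(signal$xdot))
  names(df) <- c("time_s", paste0("x", seq_len(M)), paste0("xdot", seq_len(M)))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
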