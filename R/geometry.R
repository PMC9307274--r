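#' Decoder sets
#'
#' A decoder set is the M x N matrix `D` whose columns are the neurons'
#' decoding vectors: column `i` is the direction (and magnitude) by which a
#' spike of neuron `i` moves the linear readout. Every column must have unit
#' Euclidean norm; together with the thresholds, the columns define the faces
#' of the error bounding box \eqn{\{e : D^\top e \le T\}}.
#'
#' @param D numeric matrix, M signal dimensions x N neurons, unit-norm columns.
#' @return An object of class `decoder_set` (a matrix with attributes).
#' @seealso [random_unit_decoders()], [polygon_decoders()], [gabor_decoder()]
#' @export
decoder_set <- function(D) {
  D <- as.matrix(D)
  if (!is.numeric(D) || nrow(D) < 1L || ncol(D) < 1L)
    stop("'D' must be a numeric matrix with M >= 1 rows and N >= 1 columns")
  nrm <- sqrt(colSums(D^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("all decoder columns must have unit norm (tolerance 1e-12)")
  dimnames(D) <- NULL
  structure(D, class = c("decoder_set", "matrix"))
}

#' @export
print.decoder_set <- function(x, ...) {
  cat(sprintf("<decoder_set> M = %d signal dimensions, N = %d neurons (rho = %.3g)\n",
              nrow(x), ncol(x), redundancy(x)))
  invisible(x)
}

#' Redundancy of a decoder set
#'
#' The redundancy \eqn{\rho = N/M} is the number of neurons per encoded signal
#' dimension. It is always derived from the decoder matrix, never stored.
#'
#' @param decoders a [decoder_set()].
#' @return A scalar, `ncol/nrow`.
#' @export
redundancy <- function(decoders) ncol(decoders) / nrow(decoders)

#' Random decoder vectors on the unit sphere
#'
#' Draws each column from an M-dimensional standard normal distribution and
#' normalizes it to unit length, giving columns i.i.d. uniform on the unit
#' (M-1)-sphere.
#'
#' @param M number of signal dimensions (>= 1).
#' @param N number of neurons (>= 1).
#' @param seed optional integer seed; when given the draw is deterministic.
#' @return A [decoder_set()] of dimension M x N.
#' @export
random_unit_decoders <- function(M, N, seed = NULL) {
  if (!is.numeric(M) || M < 1 || !is.numeric(N) || N < 1)
    stop("'M' and 'N' must be positive integers")
  M <- as.integer(M); N <- as.integer(N)
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  D <- matrix(rnorm(M * N), M, N)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  decoder_set(D)
}

#' Regular-polygon decoders in two dimensions
#'
#' Column `k` (k = 0, ..., N-1) is `(cos(2*pi*k/N), sin(2*pi*k/N))`, so the
#' bounding box with equal thresholds is a regular N-gon. `N = 4` gives the
#' square box of four pairwise independent neurons; as N grows the box
#' approaches a circle.
#'
#' @param N number of neurons, at least 3 for a closed box (4 for the square).
#' @return A 2 x N [decoder_set()].
#' @export
polygon_decoders <- function(N) {
  if (!is.numeric(N) || N < 3)
    stop("open box: at least N = 3 polygon decoders are needed to close a 2-D box")
  N <- as.integer(N)
  k <- 0:(N - 1)
  decoder_set(rbind(cos(2 * pi * k / N), sin(2 * pi * k / N)))
}

#' Coordinate-axis decoders (hypercube box)
#'
#' Returns the 2M columns `+e_1, -e_1, ..., +e_M, -e_M`, whose bounding box
#' with equal thresholds `T` is the L-infinity ball of radius `T` (the
#' equivalent hypercube).
#'
#' @param M number of signal dimensions.
#' @return A M x 2M [decoder_set()].
#' @export
axis_decoders <- function(M) {
  I <- diag(M)
  D <- matrix(0, M, 2 * M)
  D[, seq(1, 2 * M, 2)] <- I
  D[, seq(2, 2 * M, 2)] <- -I
  decoder_set(D)
}

# centre offsets of the 3 x 3 grid of Gabor patch locations on the 13 x 13
# pixel lattice (coordinates -6..6)
gabor_centres <- function() {
  g <- expand.grid(cx = c(-3, 0, 3), cy = c(-3, 0, 3))
  as.matrix(g)
}

check_gabor_params <- function(wavelength, orientation, envelope_sd, aspect,
                               strict) {
  ok <- wavelength %in% c(3, 5, 10) &&
    orientation >= 0 && orientation <= 2 * pi &&
    envelope_sd %in% c(1, 1.5) && aspect %in% c(1, 1.5)
  if (!ok) {
    msg <- "Gabor parameters outside the sampled sets (wavelength {3,5,10}, orientation [0,2*pi], envelope_sd {1,1.5}, aspect {1,1.5})"
    if (strict) stop(msg) else warning(msg)
  }
  invisible(ok)
}

#' Raw Gabor patch on the 13 x 13 pixel grid
#'
#' Evaluates
#' \deqn{g(x,y) = \exp(-(\tilde x^2 + \gamma^2 \tilde y^2)/2\sigma^2)
#'   \cos(2\pi \tilde x/\lambda + \pi/2)}
#' with \eqn{\tilde x = x'\cos\theta + y'\sin\theta},
#' \eqn{\tilde y = -x'\sin\theta + y'\cos\theta} and \eqn{(x', y')} the pixel
#' coordinates relative to the patch centre, on the integer lattice
#' `x, y = -6, ..., 6`.
#'
#' @param wavelength wavelength of the sinusoidal stripe pattern (3, 5 or 10).
#' @param orientation stripe orientation in radians, in `[0, 2*pi]`.
#' @param envelope_sd standard deviation of the Gaussian envelope (1 or 1.5).
#' @param aspect spatial aspect ratio gamma (1 or 1.5).
#' @param centre patch centre: either an index 1..9 into the 3 x 3 grid of
#'   locations at offsets `{-3, 0, 3}` per axis, or a length-2 numeric vector
#'   of offsets.
#' @param strict if `TRUE` (default) parameters outside the stated sets are an
#'   error; if `FALSE`, a warning.
#' @return A 13 x 13 numeric matrix of raw (unnormalized) pixel values; rows
#'   index x, columns y.
#' @export
gabor_patch <- function(wavelength, orientation, envelope_sd, aspect,
                        centre = 5, strict = TRUE) {
  check_gabor_params(wavelength, orientation, envelope_sd, aspect, strict)
  if (length(centre) == 1) {
    if (!(centre %in% 1:9)) stop("'centre' index must be in 1..9")
    centre <- gabor_centres()[centre, ]
  }
  xy <- expand.grid(x = -6:6, y = -6:6)
  xs <- xy$x - centre[[1]]
  ys <- xy$y - centre[[2]]
  xt <- xs * cos(orientation) + ys * sin(orientation)
  yt <- -xs * sin(orientation) + ys * cos(orientation)
  g <- exp(-(xt^2 + aspect^2 * yt^2) / (2 * envelope_sd^2)) *
    cos(2 * pi * xt / wavelength + pi / 2)
  matrix(g, 13, 13)
}

#' Gabor decoder column
#'
#' Flattens a [gabor_patch()] to a length-169 pixel vector and normalizes it to
#' unit length for use as a decoder column.
#'
#' @inheritParams gabor_patch
#' @return A unit-norm numeric vector of length 169.
#' @export
gabor_decoder <- function(wavelength, orientation, envelope_sd, aspect,
                          centre = 5, strict = TRUE) {
  g <- as.vector(gabor_patch(wavelength, orientation, envelope_sd, aspect,
                             centre, strict))
  g / sqrt(sum(g^2))
}

#' Ensemble of randomly parameterized Gabor decoders
#'
#' Samples `n` parameter sets (wavelength uniform on \{3, 5, 10\}, orientation
#' uniform on `[0, 2*pi]`, envelope sd uniform on \{1, 1.5\}, aspect uniform on
#' \{1, 1.5\}, centre uniform over the 9 grid locations) and returns the
#' corresponding 169 x n decoder set.
#'
#' @param n number of patches.
#' @param seed optional integer seed.
#' @return A 169 x n [decoder_set()] with a `params` attribute (data frame of
#'   the sampled parameters).
#' @export
random_gabor_decoders <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  params <- data.frame(
    wavelength = sample(c(3, 5, 10), n, replace = TRUE),
    orientation = runif(n, 0, 2 * pi),
    envelope_sd = sample(c(1, 1.5), n, replace = TRUE),
    aspect = sample(c(1, 1.5), n, replace = TRUE),
    centre = sample.int(9, n, replace = TRUE)
  )
  D <- vapply(seq_len(n), function(i) {
    gabor_decoder(params$wavelength[i], params$orientation[i],
                  params$envelope_sd[i], params$aspect[i], params$centre[i])
  }, numeric(169))
  out <- decoder_set(D)
  attr(out, "params") <- params
  out
}

#' Angle between two vectors in degrees
#'
#' @param a,b numeric vectors of equal length.
#' @return The angle in `[0, 180]` degrees.
#' @export
vector_angle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Fraction of decoders quasi-orthogonal to a reference
#'
#' Computes the pixel-space (or signal-space) angle between every decoder
#' column and a reference column and reports the percentage falling in the
#' quasi-orthogonality band (by default 85-95 degrees).
#'
#' @param decoders a [decoder_set()].
#' @param reference column index of the reference decoder (default 1), or a
#'   numeric vector to compare against.
#' @param band two-sided angle band in degrees, default `c(85, 95)`.
#' @return A list with `fraction_percent`, and the vector of `angles` (the
#'   reference column itself is excluded when `reference` is an index).
#' @export
quasi_orthogonal_fraction <- function(decoders, reference = 1,
                                      band = c(85, 95)) {
  if (length(reference) == 1) {
    ref <- decoders[, reference]
    others <- decoders[, -reference, drop = FALSE]
  } else {
    ref <- reference
    others <- decoders
  }
  angles <- apply(others, 2, vector_angle, b = ref)
  list(fraction_percent = 100 * mean(angles >= band[1] & angles <= band[2]),
       angles = angles)
}

#' Random orthonormal 2-plane
#'
#' Draws two orthonormal M-vectors `u`, `v` spanning a random two-dimensional
#' plane through the origin (Gram-Schmidt on standard normal draws).
#'
#' @param M ambient dimension.
#' @param seed optional integer seed.
#' @return A list with unit vectors `u` and `v`, `u . v = 0`.
#' @export
random_plane <- function(M, seed = NULL) {
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  u <- rnorm(M); u <- u / sqrt(sum(u^2))
  v <- rnorm(M); v <- v - sum(v * u) * u
  n <- sqrt(sum(v^2))
  if (n < 1e-8) return(random_plane(M))
  list(u = u, v = v / n)
}

#' Cross-section of the bounding box with a 2-plane
#'
#' Intersects the border of the polytope \eqn{\{e : D^\top e \le T\}} with the
#' plane spanned by the orthonormal vectors `u` and `v`. Along the ray
#' \eqn{w(\rho) = \rho(\cos\theta\, u + \sin\theta\, v)} the border distance has
#' the closed form \eqn{\rho(\theta) = \min_i T_i / (D_i^\top w)} over faces
#' with positive projection; rays along which no face has positive projection
#' are open and reported as `Inf` (never an error).
#'
#' @param decoders a [decoder_set()].
#' @param threshold scalar or length-N vector of thresholds `T` (default 0.5).
#' @param u,v orthonormal M-vectors defining the plane; drawn at random (see
#'   [random_plane()]) when omitted.
#' @param n_angles number of equally spaced angles in `[0, 2*pi)`.
#' @param seed seed for the random plane when `u`, `v` are omitted.
#' @return An object of class `box_section`: list with `angles`, `radii`
#'   (`Inf` where open), `u`, `v`, `open` (logical: any infinite radius).
#' @export
box_cross_section <- function(decoders, threshold = 0.5, u = NULL, v = NULL,
                              n_angles = 360, seed = NULL) {
  M <- nrow(decoders)
  Tv <- rep_len(threshold, ncol(decoders))
  if (is.null(u) || is.null(v)) {
    pl <- random_plane(M, seed)
    u <- pl$u; v <- pl$v
  }
  stopifnot(length(u) == M, length(v) == M)
  if (abs(sum(u * v)) > 1e-8 || abs(sum(u^2) - 1) > 1e-8 ||
      abs(sum(v^2) - 1) > 1e-8)
    stop("'u' and 'v' must be orthonormal")
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  pu <- drop(crossprod(decoders, u))   # N projections of u
  pv <- drop(crossprod(decoders, v))
  radii <- vapply(angles, function(th) {
    d <- pu * cos(th) + pv * sin(th)   # D_i^T w for unit w
    pos <- d > 1e-12
    if (!any(pos)) return(Inf)
    min(Tv[pos] / d[pos])
  }, numeric(1))
  structure(list(angles = angles, radii = radii, u = u, v = v,
                 open = any(is.infinite(radii))),
            class = "box_section")
}

#' @export
print.box_section <- function(x, ...) {
  cat(sprintf("<box_section> %d rays, radii in [%.4g, %.4g]%s\n",
              length(x$angles), min(x$radii), max(x$radii),
              if (x$open) " (open box: some rays unbounded)" else ""))
  invisible(x)
}

#' Maximum cross-section radius of a closed box
#'
#' The largest distance from the box centre to its border, i.e. the
#' circumradius \eqn{\max_e \{\|e\| : D^\top e \le T\}}, obtained as the
#' maximum over vertices of the polytope restricted to sampled 2-planes. For
#' `M = 2` the exact vertex enumeration is used.
#'
#' @param decoders a [decoder_set()].
#' @param threshold scalar or per-neuron thresholds.
#' @param n_angles ray resolution for `M > 2` (per sampled plane).
#' @param n_planes number of random planes for `M > 2`.
#' @param seed seed for the random planes.
#' @return The circumradius (possibly `Inf` for an open box).
#' @export
max_box_radius <- function(decoders, threshold = 0.5, n_angles = 3600,
                           n_planes = 8, seed = 1L) {
  M <- nrow(decoders)
  Tv <- rep_len(threshold, ncol(decoders))
  if (M == 2) {
    # exact: circumradius is attained at a vertex, the intersection of two
    # active faces
    N <- ncol(decoders)
    best <- 0
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      A <- t(decoders[, c(i, j)])
      if (abs(det(A)) < 1e-12) next
      p <- solve(A, Tv[c(i, j)])
      if (all(crossprod(decoders, p) <= Tv + 1e-9)) best <- max(best, sqrt(sum(p^2)))
    }
    if (best == 0) return(Inf)
    return(best)
  }
  rmax <- 0
  for (k in seq_len(n_planes)) {
    cs <- box_cross_section(decoders, Tv, n_angles = n_angles,
                            seed = seed + k)
    rmax <- max(rmax, max(cs$radii))
  }
  rmax
}

#' Angles between neighbouring faces of the bounding box
#'
#' For each sample: pick a face at random, start from its central point
#' `T_i * D_i`, and walk along the face in a random tangent direction with a
#' fixed arc-length step until the walk first leaves the polytope through the
#' face of a different neuron; report the angle (degrees) between the two
#' faces' decoder vectors. On regular polygons this returns the adjacent-face
#' angle `360/N` exactly.
#'
#' @param decoders a [decoder_set()] describing a closed box.
#' @param threshold scalar or per-neuron thresholds.
#' @param n_samples number of sampled face pairs.
#' @param seed optional integer seed.
#' @param step arc-length step of the surface walk; defaults to
#'   `1e-3 * min(threshold)`.
#' @param max_steps resampling guard on the walk length.
#' @return A numeric vector of `n_samples` angles in degrees.
#' @export
neighbor_angles <- function(decoders, threshold = 0.5, n_samples = 100,
                            seed = NULL, step = NULL, max_steps = 1e7) {
  if (!is.null(seed)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
  }
  M <- nrow(decoders); N <- ncol(decoders)
  if (N < 2) stop("need at least two faces")
  Tv <- rep_len(threshold, N)
  if (is.null(step)) step <- 1e-3 * min(Tv)
  out <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    done <- FALSE
    for (attempt in 1:100) {
      i <- sample.int(N, 1)
      p0 <- Tv[i] * decoders[, i]
      if (any(crossprod(decoders, p0) > Tv + 1e-9)) next  # centre outside box
      g <- rnorm(M)
      tg <- g - sum(g * decoders[, i]) * decoders[, i]
      nt <- sqrt(sum(tg^2))
      if (nt < 1e-10) next
      tg <- tg / nt
      # along p(s) = p0 + s*tg the constraint values are linear in s, so the
      # first step index at which face k is violated is available in closed
      # form; this reproduces the fixed-step walk without looping
      ck <- drop(crossprod(decoders, p0))
      bk <- drop(crossprod(decoders, tg))
      cand <- which(bk > 1e-12)
      cand <- cand[cand != i]
      if (!length(cand)) next  # walk never leaves: open box along tg
      nk <- floor((Tv[cand] - ck[cand]) / (step * bk[cand])) + 1
      nk[nk < 1] <- 1
      if (min(nk) > max_steps) {
        warning("surface walk exceeded max_steps; resampling")
        next
      }
      hit <- cand[nk == min(nk)]
      if (length(hit) > 1) {  # tie within one step: largest violation wins
        viol <- ck[hit] + min(nk) * step * bk[hit] - Tv[hit]
        hit <- hit[which.max(viol)]
      }
      out[s] <- vector_angle(decoders[, i], decoders[, hit])
      done <- TRUE
      break
    }
    if (!done)
      stop("could not sample a neighbouring face (box may be open)")
  }
  out
}

#' Write / read a decoder set as headerless CSV
#'
#' Decoders are stored as plain CSV with M rows and N columns, at 17
#' significant digits so that the decimal round-trip is bit exact.
#'
#' @param decoders a [decoder_set()].
#' @param path file path.
#' @return `write_decoders` returns `path` invisibly; `read_decoders` returns a
#'   [decoder_set()].
#' @export
write_decoders <- function(decoders, path) {
  txt <- apply(unclass(decoders), 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_decoders
#' @export
read_decoders <- function(path) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  decoder_set(m)
}

# Seed helpers: run a block under a given seed without clobbering the caller's
# RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
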