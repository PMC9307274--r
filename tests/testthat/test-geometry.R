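test_that("random unit decoders have unit columns and are seed-deterministic", {
  for (case in list(c(1, 5), c(2, 21), c(20, 100))) {
    D <- random_unit_decoders(case[1], case[2], seed = 3)
    expect_equal(dim(D), case)
    expect_lt(max(abs(sqrt(colSums(D^2)) - 1)), 1e-12)
  }
  expect_identical(random_unit_decoders(5, 40, seed = 9),
                   random_unit_decoders(5, 40, seed = 9))
  # M = 1: the only unit vectors are +1 and -1
  expect_true(all(abs(unclass(random_unit_decoders(1, 50, seed = 1))) == 1))
  expect_error(random_unit_decoders(0, 5), "positive")
})

test_that("high-dimensional decoders are near-orthogonal on average", {
  # oracle: empirical mean angle of independent random unit-vector pairs
  set.seed(42)
  A <- matrix(rnorm(20 * 1e5), 20); A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  B <- matrix(rnorm(20 * 1e5), 20); B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  oracle <- mean(acos(pmin(1, pmax(-1, colSums(A * B)))) * 180 / pi)
  D <- unclass(random_unit_decoders(20, 1000, seed = 5))
  G <- crossprod(D)
  ang <- acos(pmin(1, pmax(-1, G[upper.tri(G)]))) * 180 / pi
  # both should sit at 90 degrees within Monte-Carlo error
  expect_lt(abs(mean(ang) - oracle), 0.5)
  expect_lt(abs(oracle - 90), 1)
})

test_that("polygon decoders build regular closed boxes", {
  D4 <- polygon_decoders(4)
  G <- crossprod(unclass(D4))
  offd <- G[upper.tri(G)]
  # square: neighbours orthogonal, opposite faces antipodal
  expect_true(all(abs(offd) < 1e-12 | abs(offd + 1) < 1e-12))
  D3 <- polygon_decoders(3)
  expect_equal(neighbor_angles(D3, 0.5, n_samples = 10, seed = 1),
               rep(120, 10))
  expect_error(polygon_decoders(2), "open box")
  # inscribed 21-gon radius stays within the polygon/circle gap
  cs <- box_cross_section(polygon_decoders(21), 0.5,
                          u = c(1, 0), v = c(0, 1), n_angles = 720)
  Tv <- 0.5
  expect_true(all(cs$radii >= Tv - 1e-12))
  expect_lt(max(cs$radii - Tv), Tv * (1 / cos(pi / 21) - 1) + 1e-12)
})

test_that("gabor patches follow the stripe/envelope closed form", {
  # theta = 0, centred: tilde-x equals x, so the raw value at x = lambda/4,
  # y = 0 is -exp(-(lambda/4)^2 / (2 sigma^2)), and every x = 0 pixel is 0
  for (wl in c(3, 5, 10)) for (sg in c(1, 1.5)) {
    g <- gabor_patch(wl, 0, sg, 1, centre = 5)
    expect_equal(g[7, ], rep(0, 13), tolerance = 1e-15)  # x = 0 column
    if (wl == 10) {
      # x = 2.5 is not on the integer lattice; check x = 2 against the form
      expect_equal(g[9, 7], exp(-4 / (2 * sg^2)) * cos(2 * pi * 2 / wl + pi / 2))
    }
  }
  # strict parameter validation
  expect_error(gabor_decoder(4, 0, 1, 1), "outside")
  expect_warning(gabor_patch(4, 0, 1, 1, strict = FALSE), "outside")
  # decoder columns are unit-normalized
  expect_equal(sum(gabor_decoder(5, 1, 1.5, 1, centre = 3)^2), 1)
})

test_that("gabor ensembles are mostly quasi-orthogonal to a reference patch", {
  g <- random_gabor_decoders(1000, seed = 1)
  q <- quasi_orthogonal_fraction(g, reference = 1)
  expect_gt(q$fraction_percent, 70)
  expect_lt(q$fraction_percent, 90)
  expect_true(all(q$angles >= 0 & q$angles <= 180))
})

test_that("cross-sections match the bisection oracle and the sphere bound", {
  D <- random_unit_decoders(10, 100, seed = 17)
  Tv <- rep(0.5, 100)
  pl <- random_plane(10, seed = 4)
  cs <- box_cross_section(D, 0.5, u = pl$u, v = pl$v, n_angles = 24)
  for (j in seq_along(cs$angles)) {
    w <- cos(cs$angles[j]) * pl$u + sin(cs$angles[j]) * pl$v
    expect_equal(cs$radii[j], ray_radius_bisect(unclass(D), Tv, w),
                 tolerance = 1e-9)
  }
  # inscribed-sphere bound T <= rho(theta)
  expect_true(all(cs$radii >= 0.5 - 1e-12))
})

test_that("square cross-section and the equivalent hypersphere are exact", {
  cs <- box_cross_section(polygon_decoders(4), 0.5, u = c(1, 0), v = c(0, 1),
                          n_angles = 8)
  expect_equal(cs$radii[1], 0.5)                 # along a face normal
  expect_equal(cs$radii[3], 0.5)
  expect_equal(cs$radii[2], 0.5 * sqrt(2))       # through a vertex
  # a box containing the coordinate axes lies between sphere and cube section
  D <- decoder_set(cbind(unclass(axis_decoders(2)),
                         unclass(random_unit_decoders(2, 20, seed = 2))))
  cs2 <- box_cross_section(D, 0.5, u = c(1, 0), v = c(0, 1), n_angles = 90)
  cube <- box_cross_section(axis_decoders(2), 0.5, u = c(1, 0), v = c(0, 1),
                            n_angles = 90)
  expect_true(all(cs2$radii >= 0.5 - 1e-12))
  expect_true(all(cs2$radii <= cube$radii + 1e-12))
})

test_that("open boxes report infinite radii rather than failing", {
  # two faces cannot close a 2-D box
  D <- decoder_set(cbind(c(1, 0), c(0, 1)))
  cs <- box_cross_section(D, 0.5, u = c(1, 0), v = c(0, 1), n_angles = 8)
  expect_true(cs$open)
  expect_true(any(is.infinite(cs$radii)))
})

test_that("neighbor angles recover polygon geometry and concentrate with dimension", {
  expect_equal(neighbor_angles(polygon_decoders(4), 0.5, n_samples = 8,
                               seed = 2), rep(90, 8))
  expect_equal(neighbor_angles(polygon_decoders(21), 0.5, n_samples = 8,
                               seed = 2), rep(360 / 21, 8), tolerance = 1e-12)
  lo <- neighbor_angles(random_unit_decoders(2, 10, seed = 8), 0.5,
                        n_samples = 60, seed = 3)
  hi <- neighbor_angles(random_unit_decoders(20, 100, seed = 8), 0.5,
                        n_samples = 60, seed = 3)
  # higher signal dimension pushes neighbouring faces toward orthogonality
  expect_gt(median(hi), median(lo))
  expect_gt(median(hi), 60)
})

test_that("decoder CSV round-trip is bit exact", {
  D <- random_unit_decoders(3, 17, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_decoders(D, path)
  expect_identical(read_decoders(path), D)
})

test_that("redundancy is derived from the matrix shape", {
  expect_equal(redundancy(random_unit_decoders(2, 20, seed = 1)), 10)
  expect_equal(redundancy(polygon_decoders(21)), 10.5)
})
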