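# Trajectory assembly, polynomial fitting, included angles, lateral
# deviation and repeat-measurement spread.

test_that("assemble_trajectory sorts by level and rejects duplicates", {
  pts <- cbind(c(5, 1, 3), c(0, 0, 0), c(300, 100, 200))
  tr <- assemble_trajectory(pts)
  expect_equal(tr$points[, 3L], c(100, 200, 300))
  expect_equal(tr$points[, 1L], c(1, 3, 5))
  expect_error(assemble_trajectory(cbind(c(1, 2), c(0, 0), c(100, 100))),
               "duplicate")
  expect_error(assemble_trajectory(cbind(1, 0, 100)), "at least 2")
})

test_that("polynomial fits are exact on polynomial data", {
  z <- seq(0, 400, length.out = 12L)
  # collinear points, degree 1
  f1 <- fit_polynomial(assemble_trajectory(cbind(0.05 * z - 3, z)), 1L)
  expect_lt(f1$residual_rms, 1e-9)
  # exact quadratic recovered through prediction
  f2 <- fit_polynomial(assemble_trajectory(cbind(0.001 * z^2, z)), 2L)
  expect_lt(f2$residual_rms, 1e-9)
  expect_equal(predict(f2, z = z), 0.001 * z^2, tolerance = 1e-9)
  # degree n reproduces any degree <= n data
  f5 <- fit_polynomial(assemble_trajectory(cbind(0.001 * z^2, z)), 5L)
  expect_lt(f5$residual_rms, 1e-8)
  expect_error(fit_polynomial(assemble_trajectory(cbind(z, z)[1:3, ]), 4L),
               "underdetermined")
})

test_that("residual rms is non-increasing in degree", {
  set.seed(12)
  z <- seq(0, 400, length.out = 15L)
  x <- 20 * sin(z / 120) + rnorm(15L)
  tr <- assemble_trajectory(cbind(x, z))
  rms <- vapply(1:7, function(k) fit_polynomial(tr, k)$residual_rms, 0)
  expect_true(all(diff(rms) <= 1e-9))
})

test_that("noisy C-curve amplitude is recovered within 3*sigma/sqrt(n)", {
  set.seed(8)
  n <- 15L
  z <- seq(0, 400, length.out = n)
  u <- z / 400
  amp <- 25
  x <- 4 * amp * u * (1 - u) + rnorm(n, sd = 1)
  fit <- fit_polynomial(assemble_trajectory(cbind(x, z)), 2L)
  apex <- max(predict(fit))
  expect_lt(abs(apex - amp), 3 * 1 / sqrt(n))
})

test_that("included angles follow the tangent geometry", {
  z <- seq(0, 400, length.out = 12L)
  # straight line: all normals parallel
  f1 <- fit_polynomial(assemble_trajectory(cbind(0.3 * z, z)), 1L)
  expect_equal(included_angles(f1), 0)
  # C-type fit: one total angle from endpoint slopes
  f2 <- fit_polynomial(assemble_trajectory(cbind(0.0005 * z * (400 - z), z)),
                       2L)
  sl <- predict(f2, z = range(z), deriv = 1L)
  expect_equal(included_angles(f2),
               abs(atan(sl[1L]) - atan(sl[2L])) * 180 / pi,
               tolerance = 1e-9)
  # cubic with one inflexion: angles between the three knots' normals
  u <- z / 400
  f3 <- fit_polynomial(assemble_trajectory(cbind(30 * (u - 3 * u^2 + 2 * u^3),
                                                 z)), 3L)
  expect_length(f3$inflexion_levels, 1L)
  expect_equal(f3$inflexion_levels, 200, tolerance = 1e-6)
  knots <- c(0, f3$inflexion_levels, 400)
  sl3 <- atan(predict(f3, z = knots, deriv = 1L))
  expect_equal(included_angles(f3), abs(diff(sl3)) * 180 / pi,
               tolerance = 1e-9)
  # symmetric S-curve: the two included angles are equal
  expect_lt(abs(diff(included_angles(f3))), 1e-6)
})

test_that("lateral deviation and severity follow the printed bands", {
  z <- seq(0, 400, length.out = 21L)
  straight <- lateral_deviation(assemble_trajectory(cbind(0.1 * z + 5, z)))
  expect_equal(straight$max_lateral_deviation, 0, tolerance = 1e-9)
  expect_equal(straight$severity, "mild")

  arc15 <- assemble_trajectory(cbind(15 * 4 * (z / 400) * (1 - z / 400), z))
  d15 <- lateral_deviation(arc15)
  expect_equal(d15$max_lateral_deviation, 15, tolerance = 0.05)
  expect_equal(d15$severity, "moderate")

  arc40 <- assemble_trajectory(cbind(40 * 4 * (z / 400) * (1 - z / 400), z))
  expect_equal(lateral_deviation(arc40)$severity, "strong")
})

test_that("lateral deviation is invariant under rigid coronal transforms", {
  z <- seq(0, 400, length.out = 15L)
  x <- 18 * 4 * (z / 400) * (1 - z / 400)
  d0 <- lateral_deviation(assemble_trajectory(cbind(x, z)))
  rot <- rotate_points(cbind(x, z), 25, c(10, 200))
  rot[, 1L] <- rot[, 1L] + 40
  d1 <- lateral_deviation(assemble_trajectory(cbind(rot[, 1L], rot[, 2L])))
  expect_equal(d1$max_lateral_deviation, d0$max_lateral_deviation,
               tolerance = 1e-9)
})

test_that("trajectory spread matches closed forms and simulations", {
  z <- seq(0, 400, length.out = 15L)
  a <- assemble_trajectory(cbind(0.02 * z, z))
  expect_equal(trajectory_spread(list(a, a))$max_sd, 0)
  # two lines offset by 2w: SD = w * sqrt(2) at every level
  b <- assemble_trajectory(cbind(0.02 * z + 6, z))
  sp <- trajectory_spread(list(a, b))
  expect_equal(sp$sd, rep(3 * sqrt(2), length(sp$sd)), tolerance = 1e-9)
  # simulated repeats with jitter sigma: max SD close to sigma
  set.seed(5)
  reps <- lapply(1:20, function(i)
    assemble_trajectory(cbind(0.02 * z + rnorm(15L, sd = 2), z)))
  expect_lt(abs(trajectory_spread(reps)$max_sd - 2), 1.2)
  # non-overlapping ranges error
  c2 <- assemble_trajectory(cbind(c(0, 1), c(1000, 1100)))
  expect_error(trajectory_spread(list(a, c2)), "non-overlapping")
})
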