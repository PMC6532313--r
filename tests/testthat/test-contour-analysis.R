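# Dip detection, reflection-axis fitting and asymmetry quantification on
# analytic contours with known answers.

test_that("detect_dip locates centred and off-centre notches", {
  ct0 <- make_notched_ellipse(depth = 6, x0 = 0, sigma = 6)
  d0 <- detect_dip(ct0)
  expect_equal(d0$confidence, "clear")
  expect_lt(abs(d0$position[1L]), 0.5)

  ct12 <- make_notched_ellipse(depth = 6, x0 = 12, sigma = 6)
  d12 <- detect_dip(ct12)
  expect_lt(abs(d12$position[1L] - 12), 0.5)

  smooth <- make_notched_ellipse(depth = 0)
  expect_equal(detect_dip(smooth)$confidence, "none")
})

test_that("dip depth approximates the constructed notch depth", {
  ct <- generate_contour(torso_spec(noise_sigma = 0), 225, n_points = 1024L)
  d <- detect_dip(ct$contour)
  expect_lt(abs(d$depth - 6), 0.5)
})

test_that("reflection is an involution with signed-distance symmetry", {
  axis <- reflection_axis(angle = 7, offset = 3, y_ref = -50)
  set.seed(4)
  pts <- matrix(runif(60, -100, 100), ncol = 2L)
  twice <- reflect_across(reflect_across(pts, axis), axis)
  expect_lt(max(abs(twice - pts)), 1e-9)
  # a point at signed lateral distance +d maps to -d
  w <- spinescan:::.axis_lateral(pts, axis)
  w_refl <- spinescan:::.axis_lateral(reflect_across(pts, axis), axis)
  expect_equal(w_refl, -w, tolerance = 1e-12)
})

test_that("the reflected healthy half of a symmetric contour overlays the other", {
  ct <- make_symmetric_contour()
  axis <- reflection_axis(0, 0, y_ref = min(ct$points[, 2L]))
  left_refl <- reflect_side(ct, axis, "left")
  right <- reflect_side(ct, axis, "right", reflect = FALSE)
  n <- max(nrow(left_refl), nrow(right))
  a <- spinescan:::.resample_polyline(right, n)
  b <- spinescan:::.resample_polyline(left_refl, n)
  expect_lt(max(sqrt(rowSums((a - b)^2))), 1e-6)
})

test_that("fit_reflection_axis recovers symmetry axes", {
  ct <- make_notched_ellipse(depth = 6, sigma = 6)
  fit <- fit_reflection_axis(ct)
  expect_lt(abs(fit$axis$angle), 0.2)
  expect_lt(abs(fit$axis$offset), 0.3)
  expect_lt(fit$mismatch_area, 30)

  # equivariance: rigidly rotating the contour by 5 degrees (clockwise,
  # i.e. toward the patient's right) tilts the recovered axis by the same
  # angle under the from-anterior angle convention
  dip_y <- min(ct$points[, 2L])
  rot <- contour_line(rotate_points(ct$points, -5, c(0, dip_y)), level = 0)
  fit5 <- fit_reflection_axis(rot)
  expect_lt(abs(fit5$axis$angle - 5), 0.3)

  # known mid-sagittal plane at x = 7 (laterally shifted contour)
  shifted <- contour_line(cbind(ct$points[, 1L] + 7, ct$points[, 2L]))
  fit7 <- fit_reflection_axis(shifted)
  expect_lt(abs(fit7$axis$offset - 7), 1)
})

test_that("asymmetry_area matches analytic strip areas", {
  # identical curves enclose no area
  seg <- cbind(seq(0, 100, length.out = 51L), 0)
  expect_equal(asymmetry_area(seg, seg), 0)
  # two parallel straight segments of length L at distance w: L * w
  seg2 <- cbind(seq(0, 100, length.out = 51L), 4)
  expect_equal(asymmetry_area(seg, seg2), 400, tolerance = 1e-9)
  # Gaussian bump vs straight baseline: integral h * sigma * sqrt(2*pi)
  x <- seq(-200, 200, length.out = 2001L)
  bump <- cbind(x, 5 * exp(-x^2 / (2 * 15^2)))
  base <- cbind(x, 0)
  expect_lt(abs(asymmetry_area(base, bump) - 5 * 15 * sqrt(2 * pi)) /
              (5 * 15 * sqrt(2 * pi)), 0.05)
  expect_error(asymmetry_area(seg, seg2[-1L, ]), "mismatched")
})

test_that("mismatch area grows monotonically with a unilateral bump", {
  areas <- vapply(c(0, 2, 4, 6, 8), function(amp) {
    th <- seq(0, 2 * pi, length.out = 257L)[-257L]
    x <- 160 * cos(th); y <- 110 * sin(th)
    # posterior bump on the right side only
    y <- y - amp * exp(-(x - 80)^2 / (2 * 20^2)) * pmax(0, -y / 110)
    ct <- contour_line(cbind(x, y))
    axis <- reflection_axis(0, 0, y_ref = min(y))
    asymmetry_area(spinescan:::.resample_polyline(
                     reflect_side(ct, axis, "right", reflect = FALSE), 200L),
                   spinescan:::.resample_polyline(
                     reflect_side(ct, axis, "left"), 200L))
  }, 0)
  expect_true(all(diff(areas) > 0))
})
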