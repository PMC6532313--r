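# Sector partition, Gauss-formula areas and the lateral offset formula.

# build a sector_partition by hand for direct formula checks
hand_partition <- function(A, B, C, D, R_omega = 50) {
  structure(list(A = A, B = B, C = C, D = D, R_omega = R_omega, d = 50,
                 dip = c(0, 0), imbalance = (A - B) / (A + B) +
                   (C - D) / (C + D),
                 axis = reflection_axis(0, 0, 0)),
            class = "sector_partition")
}

test_that("polygon_area matches hand geometry", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0))), "at least 3")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("polygon_area agrees with a Monte-Carlo rejection oracle", {
  set.seed(21)
  poly <- random_convex_polygon(25L)
  expect_lt(abs(polygon_area(poly) - mc_convex_area(poly, n = 1e6)) /
              polygon_area(poly), 0.005)
})

test_that("compute_offset reproduces hand evaluations of the formula", {
  # symmetric: A = B and C = D gives exactly zero
  expect_equal(compute_offset(hand_partition(100, 100, 60, 60)), 0)
  # (0 + 0.2) * 50 = 10
  expect_equal(compute_offset(hand_partition(100, 100, 60, 40)), 10)
  # (-0.2 - 0.2) * 50 = -20
  expect_equal(compute_offset(hand_partition(40, 60, 40, 60)), -20)
  # alternative grouping: R_omega scales only the posterior term
  expect_equal(compute_offset(hand_partition(100, 100, 60, 40),
                              grouping = "second-term"), 0.2 * 50)
  expect_equal(compute_offset(hand_partition(60, 40, 100, 100),
                              grouping = "second-term"), 0.2)
})

test_that("a rectangle with d at mid-height splits into four equal sectors", {
  # 200 x 100 mm rectangle, dip at the posterior midpoint, d = 50
  xs <- seq(-100, 100, by = 5)
  ys <- seq(0, 100, by = 5)
  pts <- rbind(cbind(xs, 0), cbind(100, ys), cbind(rev(xs), 100),
               cbind(-100, rev(ys)))
  ct <- order_contour(pts, max_gap = 10)
  part <- partition_sectors(ct, dip = c(0, 0), d = 50)
  expect_equal(part$A, 5000, tolerance = 1e-9)
  expect_equal(part$B, 5000, tolerance = 1e-9)
  expect_equal(part$C, 5000, tolerance = 1e-9)
  expect_equal(part$D, 5000, tolerance = 1e-9)
  expect_equal(part$R_omega, 100, tolerance = 1e-9)
  expect_equal(compute_offset(part), 0)
})

test_that("symmetric contours give balanced sectors and zero offset", {
  ct <- make_symmetric_contour()
  dip <- detect_dip(ct)
  part <- partition_sectors(ct, dip, d = 50)
  expect_lt(abs(part$A - part$B) / (part$A + part$B), 0.005)
  expect_lt(abs(part$C - part$D) / (part$C + part$D), 0.005)
  expect_lt(abs(compute_offset(part)), 0.5)
})

test_that("x_off is antisymmetric under mirroring of the contour", {
  gc <- generate_contour(torso_spec(rotation_max = 15, noise_sigma = 0), 225)
  ct <- gc$contour
  dip <- detect_dip(ct)
  part <- partition_sectors(ct, dip, d = 50)
  x_off <- compute_offset(part)
  mirrored <- contour_line(cbind(-ct$points[, 1L], ct$points[, 2L]),
                           level = ct$level)
  dip_m <- detect_dip(mirrored)
  part_m <- partition_sectors(mirrored, dip_m, d = 50)
  x_off_m <- compute_offset(part_m)
  expect_lt(abs(x_off + x_off_m), 0.01 * part$R_omega)
})

test_that("rotated-vertebra contours unbalance the sectors with the right sign", {
  gc <- generate_contour(torso_spec(rotation_max = 15, noise_sigma = 0), 225)
  dip <- detect_dip(gc$contour)
  sym <- fit_reflection_axis(gc$contour)
  part <- partition_sectors(gc$contour, dip, axis = sym$axis, d = 50)
  expect_gt(part$A, part$B)  # rotation to the right: more area on the right
  expect_gt(compute_offset(part), 0)
})

test_that("|x_off| increases monotonically with vertebral rotation", {
  x_offs <- vapply(c(0, 5, 10, 15, 20, 25), function(r) {
    gc <- generate_contour(torso_spec(rotation_max = r, noise_sigma = 0), 225)
    dip <- detect_dip(gc$contour)
    sym <- fit_reflection_axis(gc$contour)
    abs(compute_offset(partition_sectors(gc$contour, dip, sym$axis, d = 50)))
  }, 0)
  expect_true(all(diff(x_offs) >= 0))
})

test_that("degenerate sector configurations raise errors", {
  ct <- make_notched_ellipse()
  # d beyond the anterior extent
  expect_error(partition_sectors(ct, c(0, -110), d = 500), "anterior extent")
  expect_error(compute_offset(hand_partition(0, 0, 10, 10)), "degenerate")
})

test_that("correct_marker shifts the dip laterally and keeps the raw dip", {
  m0 <- correct_marker(c(3, -100), x_off = 0, level = 120)
  expect_equal(m0$corrected_position, m0$dip_position)
  m <- correct_marker(c(3, -100), x_off = 10, level = 120)
  expect_equal(m$corrected_position[1L], 13)
  expect_equal(m$dip_position[1L], 3)
  expect_equal(m$level, 120)
})

test_that("offset-corrected positions beat raw dips on rotated torsos", {
  spec <- torso_spec(spine_coef = c(0, 60, -60), rotation_max = 14,
                     noise_sigma = 0.5, seed = 31L)
  lv <- seq(0.15, 0.85, length.out = 10L) * spec$height
  set.seed(31)
  rows <- lapply(lv, function(z) {
    gc <- generate_contour(spec, z)
    p <- gc$contour$points +
      matrix(rnorm(2L * nrow(gc$contour$points), sd = 0.5), ncol = 2L)
    ct <- resample_contour(order_contour(p, level = z, max_gap = 30), 256L)
    dip <- detect_dip(ct)
    sym <- fit_reflection_axis(ct)
    x_off <- compute_offset(partition_sectors(ct, dip, sym$axis, d = 50))
    c(dip = dip$position[1L], corr = dip$position[1L] + x_off,
      vb = gc$truth$vertebral_body[1L])
  })
  m <- do.call(rbind, rows)
  rms_dip <- sqrt(mean((m[, "dip"] - m[, "vb"])^2))
  rms_corr <- sqrt(mean((m[, "corr"] - m[, "vb"])^2))
  expect_lt(rms_corr, rms_dip)
})
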