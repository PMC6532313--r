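# Transverse slicing: plane placement, contour extraction, ordering and
# arc-length resampling.

test_that("plan_levels spaces levels evenly and validates arguments", {
  expect_equal(plan_levels(0, 100, 11)$levels, seq(0, 100, 10))
  expect_equal(plan_levels(0, 100, 2)$levels, c(0, 100))
  # default clinical plan: 15 levels on a 400 mm torso, ~28.6 mm apart
  p <- plan_levels(0, 400, 15)
  expect_equal(unique(round(diff(p$levels), 4)), round(400 / 14, 4))
  expect_error(plan_levels(0, 100, 1), "at least 2")
  expect_error(plan_levels(100, 0, 5), "z_min")
})

test_that("slicing a cylinder mesh recovers its circular cross-section", {
  # triangulated vertical cylinder, radius 100 mm, height 200 mm
  n <- 64L
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  ring <- cbind(100 * cos(th), 100 * sin(th))
  v <- rbind(cbind(ring, 0), cbind(ring, 200))
  k <- seq_len(n); kn <- c(2:n, 1L)
  f <- rbind(cbind(k, kn, n + k), cbind(kn, n + kn, n + k))
  cyl <- surface_scan(v, f)
  pts <- extract_slice(cyl, 100)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(abs(r - 100) < 0.5))
  expect_true(all(abs(r - 100) < 1e-9 | r < 100))  # chords lie inside
  expect_error(extract_slice(cyl, 500), "empty slice")
})

test_that("point-cloud slabs project vertices near the plane", {
  set.seed(1)
  th <- runif(500, 0, 2 * pi)
  v <- cbind(80 * cos(th), 80 * sin(th), runif(500, 0, 100))
  scan <- surface_scan(v)
  pts <- extract_slice(scan, 50, thickness = 5)
  expect_equal(nrow(pts), sum(abs(v[, 3L] - 50) <= 5))
  expect_error(extract_slice(scan, 50, thickness = 0.001), "empty slice")
})

test_that("order_contour is permutation-invariant and oriented CCW", {
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  circle <- cbind(cos(th), sin(th))
  set.seed(3)
  shuffled <- circle[sample(nrow(circle)), ]
  ct <- order_contour(shuffled, max_gap = 1)
  ct_ref <- order_contour(circle, max_gap = 1)
  expect_equal(contour_area(ct), contour_area(ct_ref), tolerance = 1e-12)
  # counter-clockwise: positive signed area under the vertex order
  p <- ct$points
  i2 <- c(2:nrow(p), 1L)
  expect_gt(sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]), 0)
})

test_that("ordered square has the right perimeter and area", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1),
              c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  ct <- order_contour(sq, max_gap = 2)
  expect_equal(contour_perimeter(ct), 8)
  expect_equal(contour_area(ct), 4)
})

test_that("ordering a shuffled synthetic slice preserves its area", {
  ct0 <- generate_contour(torso_spec(noise_sigma = 0), 225)$contour
  set.seed(11)
  shuffled <- ct0$points[sample(nrow(ct0$points)), ]
  ct <- order_contour(shuffled, level = 225, max_gap = 30)
  expect_equal(contour_area(ct), contour_area(ct0), tolerance = 1e-9)
})

test_that("fragmented point sets (disjoint clusters) are rejected", {
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  two <- rbind(cbind(10 * cos(th), 10 * sin(th)),
               cbind(10 * cos(th) + 500, 10 * sin(th)))
  expect_error(order_contour(two, level = 50, max_gap = 15),
               "fragmented contour")
})

test_that("resample_contour spaces points uniformly and is idempotent", {
  th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  circle <- contour_line(cbind(100 * cos(th), 100 * sin(th)))
  rs <- resample_contour(circle, 360L)
  gaps <- sqrt(rowSums(diff(rbind(rs$points, rs$points[1L, ]))^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-6)

  sq <- order_contour(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1),
                            c(0, 1), c(-1, 0), c(0, -1), c(1, 0)),
                      max_gap = 2)
  rs2 <- resample_contour(sq, 400L)
  expect_lt(abs(contour_perimeter(rs2) - 8) / 8, 0.005)

  ct <- generate_contour(torso_spec(noise_sigma = 0), 200,
                         n_points = 1024L)$contour
  r1 <- resample_contour(ct, 512L)
  r2 <- resample_contour(r1, 512L)
  expect_lt(max(abs(r1$points - r2$points)), 0.1)
})

test_that("slice areas match the generator's analytic cross-sections", {
  tg <- generate_torso(torso_spec(noise_sigma = 0, rotation_max = 10,
                                  spine_coef = c(0, 40, -40), seed = 2L))
  plan <- plan_levels(100, 350, 4)
  cts <- slice_scan(tg$scan, plan)
  expect_length(cts, 4L)
  for (ct in cts) {
    truth <- generate_contour(tg$truth$spec, ct$level)$truth
    expect_lt(abs(contour_area(ct) - truth$area_mm2) / truth$area_mm2, 0.02)
  }
})

test_that("slicing a convex solid yields a convex polygon", {
  # dip-free, rotation-free torso: every cross-section is a superellipse
  tg <- generate_torso(torso_spec(dip_depth = 0, noise_sigma = 0, seed = 2L))
  for (lv in c(120, 225, 330)) {
    ct <- resample_contour(order_contour(extract_slice(tg$scan, lv),
                                         level = lv, max_gap = 30), 256L)
    expect_lt(abs(polygon_area(ct$points) - contour_area(ct)) /
                contour_area(ct), 0.001)
  }
})
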