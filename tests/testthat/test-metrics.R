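make_axis <- function(points, ...) fit_needle_axis(points, ...)

test_that("needle axis fit: collinear, cylindrical and degenerate clouds", {
  z <- seq(0, 50, by = 0.01)
  line <- cbind(0, 0, z)
  ax <- fit_needle_axis(line)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-12)
  expect_lt(ax$residual_rms_mm, 1e-9)
  expect_equal(ax$s_max - ax$s_min, 50, tolerance = 1e-9)

  # cylinder of radius 0.5 about a known oblique line
  dir <- c(1, 2, 2) / 3
  e1 <- c(2, -1, 0) / sqrt(5); e2 <- c(2, 4, -5) / sqrt(45)
  s <- rep(seq(0, 80, by = 0.5), each = 16)
  phi <- rep(2 * pi * (0:15) / 16, times = 161)
  cyl <- outer(s, dir) + 0.5 * (outer(cos(phi), e1) + outer(sin(phi), e2))
  axc <- fit_needle_axis(cyl)
  ang <- acos(min(1, abs(sum(axc$direction * dir)))) * 180 / pi
  expect_lt(ang, 0.1)

  set.seed(10)
  sph <- matrix(rnorm(3000), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2))
  expect_error(fit_needle_axis(sph), "ambiguous")
})

test_that("tip-end orientation follows nerve proximity", {
  z <- seq(0, 50, by = 0.1)
  needle <- cbind(0, 0, z)
  nerve_near_top <- matrix(c(0, 3, 50), 1, 3)
  ax <- fit_needle_axis(needle, nerve = nerve_near_top)
  expect_equal(as.numeric(ax$tip_point), c(0, 0, 50), tolerance = 1e-9)
  nerve_near_bottom <- matrix(c(0, 3, 0), 1, 3)
  ax2 <- fit_needle_axis(needle, nerve = nerve_near_bottom)
  expect_equal(as.numeric(ax2$tip_point), c(0, 0, 0), tolerance = 1e-9)
})

test_that("extract_tip returns exactly the outermost segment", {
  z <- seq(0, 50, by = 0.01)
  cloud <- point_cloud(cbind(0, 0, z), 0.01)
  ax <- fit_needle_axis(cloud)
  tip <- extract_tip(cloud, ax, 5.00)
  expect_identical(nrow(tip$points), 501L)
  expect_true(all(tip$points[, 3] >= 45 - 1e-12))

  whole <- extract_tip(cloud, ax, 100)
  expect_identical(nrow(whole$points), nrow(cloud$points))

  one <- point_cloud(matrix(c(0, 0, 7), 1, 3), 0.01)
  expect_identical(extract_tip(one, ax, 5)$points, one$points)
  expect_error(extract_tip(cloud, ax, 0), "tip_length")

  # point count is monotone non-decreasing in tip length
  lens <- c(0.5, 1, 2, 5, 10, 25, 50, 60)
  counts <- vapply(lens, function(L) nrow(extract_tip(cloud, ax, L)$points), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("euclidean_distance equals the exhaustive double-loop oracle", {
  expect_equal(euclidean_distance(matrix(c(0, 0, 0), 1, 3),
                                  matrix(c(3, 4, 0), 1, 3)), 5)
  nerve <- matrix(rnorm(60), ncol = 3)
  expect_equal(euclidean_distance(nerve[7, , drop = FALSE], nerve), 0)
  set.seed(8)
  for (i in 1:5) {
    A <- matrix(rnorm(600, 0, 10), ncol = 3)
    B <- matrix(rnorm(600, 5, 10), ncol = 3)
    expect_identical(euclidean_distance(A, B), brute_min_dist(A, B))
  }
  expect_error(euclidean_distance(matrix(numeric(0), 0, 3), nerve), "nonempty")
})

test_that("lateral/depth decomposition follows the sign conventions", {
  # needle along +z, tip at the origin (s_max at the tip)
  z <- seq(-50, 0, by = 0.05)
  ax <- fit_needle_axis(cbind(0, 0, z), nerve = matrix(c(0, 3, 4), 1, 3))
  expect_equal(as.numeric(ax$tip_point), c(0, 0, 0), tolerance = 1e-9)

  tgrid <- seq(-40, 40, by = 0.01)
  nerve_under <- cbind(tgrid, 3, 4)     # target beyond the tip: undershoot
  ld <- lateral_depth(ax, nerve_under, lateral_ref = c(0, 1, 0))
  expect_equal(ld$lateral_signed_mm, 3, tolerance = 1e-9)
  expect_equal(ld$depth_signed_mm, 4, tolerance = 1e-9)
  # Pythagoras against the point-tip Euclidean distance
  eu <- euclidean_distance(matrix(ax$tip_point, 1, 3), nerve_under)
  expect_equal(eu^2, ld$lateral_signed_mm^2 + ld$depth_signed_mm^2,
               tolerance = 1e-6)

  nerve_over <- cbind(tgrid, 3, -4)     # tip deeper than the target
  ld2 <- lateral_depth(ax, nerve_over, lateral_ref = c(0, 1, 0))
  expect_equal(ld2$depth_signed_mm, -4, tolerance = 1e-9)
  ld2b <- lateral_depth(ax, nerve_over, lateral_ref = c(0, -1, 0))
  expect_equal(ld2b$lateral_signed_mm, -3, tolerance = 1e-9)

  on_axis <- matrix(c(0, 0, -10), 1, 3)
  ld3 <- lateral_depth(ax, on_axis, lateral_ref = c(0, 1, 0))
  expect_identical(ld3$lateral_signed_mm, 0)

  expect_error(lateral_depth(ax, nerve_under, lateral_ref = c(0, 0.01, 1)),
               "5 degrees")
})

test_that("metrics are invariant under a common rigid motion", {
  set.seed(12)
  cfg <- synth_config(true_lateral_mm = 2.5, true_depth_mm = -3,
                      truth_spacing_mm = NA)
  nv <- generate_nerve(cfg)
  nd <- generate_needle(cfg, nv)
  nerve_pc <- sample_surface(nv$mesh, 0.3)
  needle_pc <- sample_surface(nd$mesh, 0.3)

  measure <- function(nerve_pts, needle_pts, ref) {
    ax <- fit_needle_axis(needle_pts, nerve = nerve_pts)
    tip <- extract_tip(point_cloud(needle_pts, 0.3), ax, 5)
    ld <- lateral_depth(ax, nerve_pts, ref)
    c(euclidean_distance(tip, nerve_pts), ld$lateral_signed_mm,
      ld$depth_signed_mm)
  }
  base <- measure(nerve_pc$points, needle_pc$points, nd$lateral_ref)
  for (i in 1:5) {
    tf <- random_rigid()
    m <- measure(apply_transform(tf, nerve_pc$points),
                 apply_transform(tf, needle_pc$points),
                 as.numeric(tf$rotation %*% nd$lateral_ref))
    expect_lt(max(abs(m - base)), 1e-6)
  }
})

test_that("assess_trial with the reference trial itself is registration-free", {
  cfg <- synth_config(true_lateral_mm = 2, true_depth_mm = 2,
                      pose_jitter_rot_deg = 0, pose_jitter_trans_mm = 0,
                      truth_spacing_mm = NA)
  rc <- run_config(spacing_mm = 0.2)
  ref <- generate_reference(cfg, rc)
  rc$lateral_ref <- ref$lateral_ref
  tr <- generate_trial(cfg, "t", seed = 1)
  res <- assess_trial(tr, ref, rc)

  # direct computation without any registration step
  needle_pc <- sample_surface(tr$needle, rc$spacing_mm)
  ax <- fit_needle_axis(needle_pc, nerve = ref$surface)
  tip <- extract_tip(needle_pc, ax, 5)
  ld <- lateral_depth(ax, ref$surface, rc$lateral_ref)
  eu <- euclidean_distance(tip, ref$surface)
  expect_equal(res$euclidean_mm, eu, tolerance = 1e-6)
  expect_equal(res$lateral_signed_mm, ld$lateral_signed_mm, tolerance = 1e-6)
  expect_equal(res$depth_signed_mm, ld$depth_signed_mm, tolerance = 1e-6)
})

test_that("accuracy_result flags use strict < 5.00 mm", {
  r <- accuracy_result("t", euclidean_mm = 5.00, lateral_signed_mm = 4.999,
                       depth_signed_mm = -5.001)
  expect_false(r$within_range_euclidean)
  expect_true(r$within_range_lateral)
  expect_false(r$within_range_depth)
  expect_identical(r$lateral_mm, 4.999)
  expect_identical(r$depth_mm, 5.001)
})
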