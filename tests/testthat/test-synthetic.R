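poly_len <- function(p) sum(sqrt(rowSums(diff(p)^2)))

test_that("generated nerve has the phantom wire's length and diameter", {
  straight <- generate_nerve(synth_config(nerve_curvature_mm = 0))
  expect_equal(poly_len(straight$centerline), 75, tolerance = 0.01)

  # every non-cap surface vertex sits exactly one radius from the centerline
  d <- needleplace:::.cpp_dist_to_polyline(
    straight$mesh$vertices[!straight$is_cap, ], straight$centerline)
  expect_lt(max(abs(d - 1.0)), 1e-6)

  curved <- generate_nerve(synth_config(nerve_curvature_mm = 10))
  expect_equal(poly_len(curved$centerline), 75, tolerance = 0.05)
  # deflection from the chord equals the configured sagitta
  chord <- curved$centerline[c(1, nrow(curved$centerline)), ]
  dev <- needleplace:::.cpp_dist_to_polyline(curved$centerline, chord)
  expect_equal(max(dev), 10, tolerance = 0.01)

  expect_error(synth_config(nerve_curvature_mm = 40), "infeasible")
})

test_that("needle construction realizes the configured offsets exactly", {
  cfg0 <- synth_config(nerve_curvature_mm = 0, true_lateral_mm = 3,
                       true_depth_mm = 4)
  nv <- generate_nerve(cfg0)
  nd <- generate_needle(cfg0, nv)
  d_tip <- needleplace:::.cpp_dist_to_polyline(matrix(nd$tip_point, 1, 3),
                                               nv$centerline)
  expect_equal(as.numeric(d_tip), 5, tolerance = 1e-9)

  cfg00 <- synth_config(nerve_curvature_mm = 0)
  nd0 <- generate_needle(cfg00, generate_nerve(cfg00))
  d0 <- needleplace:::.cpp_dist_to_polyline(matrix(nd0$tip_point, 1, 3),
                                            nv$centerline)
  expect_lt(as.numeric(d0), 1e-9)

  # overshoot: tip past the closest-approach foot along the insertion direction
  cfgo <- synth_config(nerve_curvature_mm = 0, true_lateral_mm = 3,
                       true_depth_mm = -4)
  ndo <- generate_needle(cfgo, generate_nerve(cfgo))
  do_ <- needleplace:::.cpp_dist_to_polyline(matrix(ndo$tip_point, 1, 3),
                                             nv$centerline)
  expect_equal(as.numeric(do_), 5, tolerance = 1e-9)
  foot <- ndo$tip_point - 4 * ndo$direction   # q = tip + depth * dir
  expect_gt(sum((ndo$tip_point - foot) * ndo$direction), 3.9)
})

test_that("ground truth satisfies the Pythagorean identity by construction", {
  for (off in list(c(3, 4), c(1.5, -2), c(0, 0), c(-2, 3.5))) {
    cfg <- synth_config(true_lateral_mm = off[1], true_depth_mm = off[2],
                        truth_spacing_mm = NA)
    tr <- generate_trial(cfg, "t", seed = 5)
    expect_equal(tr$truth$true_euclidean_mm^2, off[1]^2 + off[2]^2,
                 tolerance = 1e-9)
  }
})

test_that("trial generation is bitwise deterministic in (config, id, seed)", {
  cfg <- synth_config(true_lateral_mm = 2, true_depth_mm = 1,
                      surface_noise_sd_mm = 0.1, landmark_noise_sd_mm = 0.5,
                      truth_spacing_mm = NA)
  a <- generate_trial(cfg, "trial_007", seed = 123)
  b <- generate_trial(cfg, "trial_007", seed = 123)
  expect_identical(a$nerve$vertices, b$nerve$vertices)
  expect_identical(a$needle$vertices, b$needle$vertices)
  expect_identical(a$landmarks$points, b$landmarks$points)
  c3 <- generate_trial(cfg, "trial_008", seed = 123)
  expect_false(identical(a$nerve$vertices, c3$nerve$vertices))
})

test_that("zero-noise zero-jitter trials recover configured offsets end-to-end", {
  cfg <- synth_config(true_lateral_mm = 3, true_depth_mm = 4,
                      pose_jitter_rot_deg = 0, pose_jitter_trans_mm = 0,
                      truth_spacing_mm = NA)
  rc <- run_config(spacing_mm = 0.1, nerve_reference = "centerline",
                   tip_mode = "extreme")
  ref <- generate_reference(cfg, rc)
  rc$lateral_ref <- ref$lateral_ref
  res <- assess_trial(generate_trial(cfg, "t", seed = 3), ref, rc)
  expect_equal(res$euclidean_mm, 5, tolerance = 0.2)
  expect_equal(res$lateral_signed_mm, 3, tolerance = 0.2)
  expect_equal(res$depth_signed_mm, 4, tolerance = 0.2)
})

test_that("surface-referenced ground truth matches the surface pipeline", {
  cfg <- synth_config(true_lateral_mm = 3, true_depth_mm = 4,
                      truth_spacing_mm = 0.1)
  rc <- run_config(spacing_mm = 0.1)
  ref <- generate_reference(cfg, rc)
  rc$lateral_ref <- ref$lateral_ref
  tr <- generate_trial(cfg, "t", seed = 21)
  res <- assess_trial(tr, ref, rc)
  st <- tr$truth$surface
  expect_equal(res$euclidean_mm, st$euclidean_mm, tolerance = 0.05)
  expect_equal(res$lateral_signed_mm, st$lateral_signed_mm, tolerance = 0.05)
  expect_equal(res$depth_signed_mm, st$depth_signed_mm, tolerance = 0.05)
})

test_that("cohorts have unique ids and honor per-trial offsets", {
  cfg <- synth_config(truth_spacing_mm = NA)
  off <- cbind(lateral = c(1, 2, 3), depth = c(0, -1, 2))
  trs <- generate_cohort(cfg, 3, seed = 9, offsets = off)
  expect_identical(vapply(trs, `[[`, "", "trial_id"),
                   c("trial_001", "trial_002", "trial_003"))
  expect_identical(vapply(trs, function(t) t$truth$true_lateral_mm, 0),
                   c(1, 2, 3))
  expect_error(generate_cohort(cfg, 2, offsets = off), "offsets")
  single <- generate_cohort(cfg, 1, seed = 2)
  expect_length(single, 1L)
})
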