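#' Configuration of the synthetic phantom-trial generator
#'
#' Describes the phantom world the generator emulates: a curved nerve tube
#' 75 mm long and 2 mm in diameter (the copper-wire nerve surrogate of the
#' pelvic phantom), a straight needle with a conical point, per-trial rigid
#' pose jitter standing in for the per-scan coordinate frame, surface noise
#' standing in for threshold-segmentation boundary error, and configurable
#' true lateral/depth offsets of the tip from the nerve.
#'
#' @param nerve_length_mm Nerve centerline arclength (default 75).
#' @param nerve_diameter_mm Nerve tube diameter (default 2).
#' @param nerve_curvature_mm Maximum deflection of the smooth circular-arc
#'   centerline from its chord (sagitta, mm; 0 = straight, default 5: a
#'   gently bent wire).
#' @param needle_length_mm Needle shaft length (default 100, a typical PRF
#'   cannula).
#' @param needle_diameter_mm Needle diameter (default 1).
#' @param needle_cone_mm Length of the conical point (default 2); gives the
#'   model a unique deepest apex, like a real bevelled needle.
#' @param true_lateral_mm Signed perpendicular offset of the needle axis from
#'   the nerve centerline at closest approach (default 0).
#' @param true_depth_mm Signed axial offset of the tip from the closest-
#'   approach foot point (positive = tip stopped short of the target,
#'   negative = deeper than the target; default 0).
#' @param approach_polar_deg,approach_azimuth_deg Needle direction relative
#'   to the local nerve frame. With azimuth 0 (default) the needle is
#'   perpendicular to the nerve tangent, so
#'   \code{euclidean^2 = lateral^2 + depth^2} holds exactly for the tip apex.
#' @param surface_noise_sd_mm SD of iid Gaussian displacement of mesh
#'   vertices along their normals (default 0; 0.1 is a realistic
#'   segmentation-boundary error for 0.3 mm voxels).
#' @param pose_jitter_rot_deg,pose_jitter_trans_mm Maximum per-trial random
#'   rigid perturbation (rotation about the nerve centroid, translation;
#'   defaults 5 deg / 10 mm).
#' @param landmark_noise_sd_mm SD of iid Gaussian landmark jitter (default 0).
#' @param mesh_edge_mm Target mesh edge length (default 0.5 mm; surface
#'   sampling subdivides far below this).
#' @param centerline_step_mm Centerline polyline spacing (default 0.01 mm).
#' @param truth_spacing_mm Sampling spacing for the numeric surface-referenced
#'   ground-truth oracles (default 0.05 mm); set to NA to skip them.
#' @param seed Integer seed; fully determines all randomness.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(nerve_length_mm = 75, nerve_diameter_mm = 2,
                         nerve_curvature_mm = 5,
                         needle_length_mm = 100, needle_diameter_mm = 1,
                         needle_cone_mm = 2,
                         true_lateral_mm = 0, true_depth_mm = 0,
                         approach_polar_deg = 30, approach_azimuth_deg = 0,
                         surface_noise_sd_mm = 0,
                         pose_jitter_rot_deg = 5, pose_jitter_trans_mm = 10,
                         landmark_noise_sd_mm = 0,
                         mesh_edge_mm = 0.5, centerline_step_mm = 0.01,
                         truth_spacing_mm = 0.05,
                         seed = 1L) {
  cfg <- list(nerve_length_mm = nerve_length_mm,
              nerve_diameter_mm = nerve_diameter_mm,
              nerve_curvature_mm = nerve_curvature_mm,
              needle_length_mm = needle_length_mm,
              needle_diameter_mm = needle_diameter_mm,
              needle_cone_mm = needle_cone_mm,
              true_lateral_mm = true_lateral_mm,
              true_depth_mm = true_depth_mm,
              approach_polar_deg = approach_polar_deg,
              approach_azimuth_deg = approach_azimuth_deg,
              surface_noise_sd_mm = surface_noise_sd_mm,
              pose_jitter_rot_deg = pose_jitter_rot_deg,
              pose_jitter_trans_mm = pose_jitter_trans_mm,
              landmark_noise_sd_mm = landmark_noise_sd_mm,
              mesh_edge_mm = mesh_edge_mm,
              centerline_step_mm = centerline_step_mm,
              truth_spacing_mm = truth_spacing_mm,
              seed = as.integer(seed))
  lens <- c("nerve_length_mm", "nerve_diameter_mm", "needle_length_mm",
            "needle_diameter_mm", "needle_cone_mm", "mesh_edge_mm",
            "centerline_step_mm")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      .np_stopf("synth_config: %s must be > 0", f)
  if (cfg$nerve_curvature_mm < 0) .np_stopf("nerve_curvature_mm must be >= 0")
  if (cfg$nerve_curvature_mm > 0) {
    # tube self-intersects when the bend radius drops below the tube radius
    r_bend <- .arc_radius(cfg$nerve_length_mm, cfg$nerve_curvature_mm)
    if (r_bend <= cfg$nerve_diameter_mm / 2)
      .np_stopf("nerve_curvature_mm = %.1f makes the tube self-intersect (bend radius %.2f mm)",
                cfg$nerve_curvature_mm, r_bend)
  }
  structure(cfg, class = "synth_config")
}

# circular arc with arclength L and sagitta d: solve L = R*theta,
# d = R*(1 - cos(theta/2)) for the opening angle theta
.arc_theta <- function(L, d) {
  if (d <= 0) return(0)
  th_max <- 2 * pi * 0.999
  if (d / L >= (1 - cos(th_max / 2)) / th_max)
    .np_stopf("nerve_curvature_mm = %.2f infeasible for a %.1f mm arc (max deflection %.1f mm)",
              d, L, L * (1 - cos(th_max / 2)) / th_max)
  f <- function(th) (1 - cos(th / 2)) / th - d / L
  uniroot(f, c(1e-8, th_max), tol = 1e-14)$root
}

.arc_radius <- function(L, d) {
  th <- .arc_theta(L, d)
  if (th == 0) Inf else L / th
}

# centerline points + unit tangents at arclengths s (vector), arc in the
# xy-plane bending towards +y, centered on the origin
.arc_eval <- function(L, d, s) {
  th <- .arc_theta(L, d)
  if (th == 0) {
    pts <- cbind(s - L / 2, 0, 0)
    tan <- matrix(rep(c(1, 0, 0), each = length(s)), ncol = 3)
  } else {
    R <- L / th
    a <- (s - L / 2) / R
    pts <- cbind(R * sin(a), R * (1 - cos(a)), 0)
    tan <- cbind(cos(a), sin(a), 0)
  }
  list(points = pts, tangents = tan)
}

#' Generate the synthetic nerve
#'
#' A capped tube of the configured length and diameter swept along a smooth
#' circular arc, plus its centerline polyline at fine spacing.
#'
#' @param config A \code{synth_config}.
#' @return List with \code{mesh} (\code{tri_mesh}), \code{centerline}
#'   (n x 3 matrix at \code{centerline_step_mm} spacing) and
#'   \code{is_cap} (logical per mesh vertex; cap-region vertices are not at
#'   tube-radius distance from the centerline).
#' @export
generate_nerve <- function(config) {
  L <- config$nerve_length_mm
  d <- config$nerve_curvature_mm
  r <- config$nerve_diameter_mm / 2

  s_cl <- seq(0, L, by = config$centerline_step_mm)
  if (s_cl[length(s_cl)] < L) s_cl <- c(s_cl, L)
  centerline <- .arc_eval(L, d, s_cl)$points

  n_rings <- max(2L, as.integer(ceiling(L / config$mesh_edge_mm)) + 1L)
  s_ring <- seq(0, L, length.out = n_rings)
  ce <- .arc_eval(L, d, s_ring)
  n_circ <- max(12L, as.integer(ceiling(2 * pi * r / config$mesh_edge_mm)))
  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ

  # frame: tangent T in xy-plane, normal N in-plane, binormal B = +z
  verts <- matrix(0, n_rings * n_circ + 2L, 3)
  for (i in seq_len(n_rings)) {
    Tv <- ce$tangents[i, ]
    Nv <- c(-Tv[2], Tv[1], 0)
    Bv <- c(0, 0, 1)
    ring <- matrix(ce$points[i, ], n_circ, 3, byrow = TRUE) +
      outer(cos(phi), r * Nv) + outer(sin(phi), r * Bv)
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }
  i_c0 <- n_rings * n_circ + 1L   # start cap center
  i_c1 <- n_rings * n_circ + 2L   # end cap center
  verts[i_c0, ] <- ce$points[1, ]
  verts[i_c1, ] <- ce$points[n_rings, ]

  faces <- .tube_faces(n_rings, n_circ, i_c0, i_c1)
  is_cap <- rep(FALSE, nrow(verts))
  is_cap[c(i_c0, i_c1)] <- TRUE

  list(mesh = tri_mesh(verts, faces, "nerve"),
       centerline = centerline, is_cap = is_cap)
}

# quad strips between consecutive rings + triangle fans to the cap centers
.tube_faces <- function(n_rings, n_circ, i_c0, i_c1) {
  f <- vector("list", n_rings - 1L + 2L)
  nxt <- c(seq_len(n_circ)[-1], 1L)
  for (i in seq_len(n_rings - 1L)) {
    a <- (i - 1L) * n_circ + seq_len(n_circ)
    b <- (i - 1L) * n_circ + nxt
    c2 <- i * n_circ + seq_len(n_circ)
    d2 <- i * n_circ + nxt
    f[[i]] <- rbind(cbind(a, b, c2), cbind(b, d2, c2))
  }
  first <- seq_len(n_circ)
  last <- (n_rings - 1L) * n_circ + seq_len(n_circ)
  f[[n_rings]] <- cbind(first[nxt], first, i_c0)
  f[[n_rings + 1L]] <- cbind(last, last[nxt], i_c1)
  do.call(rbind, f)
}

#' Generate the synthetic needle
#'
#' A straight cylinder with a conical point whose axis passes at perpendicular
#' distance \code{|true_lateral_mm|} from the nerve centerline's midpoint,
#' with the apex stopped \code{true_depth_mm} short of (positive) or past
#' (negative) the closest-approach foot point. The construction places the
#' axis along the common perpendicular, so the configured offsets are exact.
#'
#' @param config A \code{synth_config}.
#' @param nerve From \code{\link{generate_nerve}} (uses its centerline).
#' @return List with \code{mesh}, \code{tip_point} (the exact apex),
#'   \code{direction} (unit insertion direction, hub -> tip) and
#'   \code{lateral_ref} (unit vector making the measured signed lateral equal
#'   \code{true_lateral_mm}).
#' @export
generate_needle <- function(config, nerve) {
  L <- config$nerve_length_mm
  mid <- .arc_eval(L, config$nerve_curvature_mm, L / 2)
  c0 <- as.numeric(mid$points)
  Tv <- as.numeric(mid$tangents)

  theta <- config$approach_polar_deg * pi / 180
  phi <- config$approach_azimuth_deg * pi / 180
  U <- c(0, 0, 1)                               # perpendicular to the arc plane
  V <- c(Tv[2], -Tv[1], 0)                      # in-plane, perpendicular to T
  dirv <- cos(theta) * U + sin(theta) * (cos(phi) * V + sin(phi) * Tv)
  dirv <- dirv / sqrt(sum(dirv^2))
  if (abs(sum(dirv * Tv)) > 0.999)
    .np_stopf("infeasible geometry: needle direction parallel to the nerve tangent")

  nvec <- c(Tv[2] * dirv[3] - Tv[3] * dirv[2],
            Tv[3] * dirv[1] - Tv[1] * dirv[3],
            Tv[1] * dirv[2] - Tv[2] * dirv[1])
  nvec <- nvec / sqrt(sum(nvec^2))              # common perpendicular

  q <- c0 + config$true_lateral_mm * nvec       # foot of the perpendicular
  tip <- q - config$true_depth_mm * dirv

  mesh <- .needle_mesh(tip, dirv, config)
  list(mesh = mesh, tip_point = tip, direction = dirv, lateral_ref = -nvec)
}

.needle_mesh <- function(tip, dirv, config) {
  r <- config$needle_diameter_mm / 2
  cone <- min(config$needle_cone_mm, config$needle_length_mm / 2)
  Lsh <- config$needle_length_mm - cone
  # orthonormal frame around the axis
  ref <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dirv) * dirv
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dirv[2] * e1[3] - dirv[3] * e1[2],
          dirv[3] * e1[1] - dirv[1] * e1[3],
          dirv[1] * e1[2] - dirv[2] * e1[1])

  n_circ <- max(12L, as.integer(ceiling(2 * pi * r / config$mesh_edge_mm)))
  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  circle <- outer(cos(phi), r * e1) + outer(sin(phi), r * e2)

  n_rings <- max(2L, as.integer(ceiling(Lsh / config$mesh_edge_mm)) + 1L)
  s_ring <- seq(cone, config$needle_length_mm, length.out = n_rings)
  verts <- matrix(0, n_rings * n_circ + 2L, 3)
  for (i in seq_len(n_rings))
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <-
      matrix(tip - s_ring[i] * dirv, n_circ, 3, byrow = TRUE) + circle
  i_apex <- n_rings * n_circ + 1L
  i_hub <- n_rings * n_circ + 2L
  verts[i_apex, ] <- tip
  verts[i_hub, ] <- tip - config$needle_length_mm * dirv

  faces <- .tube_faces(n_rings, n_circ, i_apex, i_hub)
  tri_mesh(verts, faces, "needle")
}

# deterministic per-trial seed below 2^31
.trial_seed <- function(seed, trial_id) {
  h <- 17
  for (ch in utf8ToInt(as.character(trial_id)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

.landmark_template <- function() {
  pts <- rbind(
    ischial_tuberosity_left      = c(-45, -10, -70),
    ischial_tuberosity_right     = c( 45, -10, -70),
    sacrum_lateral_border_left   = c(-40, -30,  40),
    sacrum_lateral_border_right  = c( 40, -30,  40),
    greater_trochanter_left      = c(-95,   0, -35),
    greater_trochanter_right     = c( 95,   0, -35))
  landmark_set(pts)
}

.random_pose <- function(max_rot_deg, max_trans_mm, center) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_rot_deg) * pi / 180
  R <- rotation_about_axis(ax, ang)
  dirv <- rnorm(3)
  dirv <- dirv / sqrt(sum(dirv^2))
  tvec <- dirv * runif(1, 0, max_trans_mm)
  # rotate about `center`, then translate
  rigid_transform(R, center - as.numeric(R %*% center) + tvec)
}

.vertex_normals <- function(mesh) {
  fn <- .face_normals(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    for (k in 1:3)
      vn[, k] <- vn[, k] + unname(tapply(fn[, k], factor(idx, levels = seq_len(nrow(vn))),
                                         sum, default = 0))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

.add_surface_noise <- function(mesh, sd_mm) {
  if (sd_mm <= 0) return(mesh)
  vn <- .vertex_normals(mesh)
  mesh$vertices <- mesh$vertices + vn * rnorm(nrow(mesh$vertices), 0, sd_mm)
  mesh
}

#' Generate one synthetic phantom trial
#'
#' Builds the nerve and needle in the unposed model frame, applies one random
#' rigid pose to both (simulating the per-scan coordinate frame), then adds
#' surface noise along vertex normals (simulating segmentation-boundary
#' error). Ground truth records the noiseless configured offsets, the exact
#' tip point/axis, the applied pose, and numeric surface-referenced oracles.
#' Identical \code{(config, trial_id, seed)} give bitwise-identical output.
#'
#' @param config A \code{synth_config}.
#' @param trial_id Trial identifier (default \code{"trial_001"}).
#' @param seed Integer seed; defaults to \code{config$seed}.
#' @return An object of class \code{trial_record}: \code{trial_id},
#'   \code{nerve}, \code{needle} (\code{tri_mesh}, posed + noisy),
#'   \code{landmarks} (\code{landmark_set}, posed + jittered) and
#'   \code{truth} (list: offsets, centerline-referenced and
#'   surface-referenced expected values, pose, exact tip/axis in both
#'   frames, \code{lateral_ref}).
#' @export
generate_trial <- function(config, trial_id = "trial_001", seed = config$seed) {
  set.seed(.trial_seed(seed, trial_id))
  nerve <- generate_nerve(config)
  needle <- generate_needle(config, nerve)

  lat <- config$true_lateral_mm
  dep <- config$true_depth_mm
  cosTd <- sum(needle$direction * .arc_eval(config$nerve_length_mm,
                                            config$nerve_curvature_mm,
                                            config$nerve_length_mm / 2)$tangents)
  # exact distance from the apex to the local nerve tangent line
  true_euclid <- sqrt(lat^2 + dep^2 - (dep * cosTd)^2)
  euclid_centerline <- min(.cpp_dist_to_polyline(matrix(needle$tip_point, 1, 3),
                                                 nerve$centerline))

  surface_truth <- NULL
  if (is.finite(config$truth_spacing_mm) && config$truth_spacing_mm > 0)
    surface_truth <- .surface_truth(nerve, needle, config)

  pose <- .random_pose(config$pose_jitter_rot_deg, config$pose_jitter_trans_mm,
                       center = colMeans(nerve$centerline))
  nerve_mesh <- .add_surface_noise(apply_transform(pose, nerve$mesh),
                                   config$surface_noise_sd_mm)
  needle_mesh <- .add_surface_noise(apply_transform(pose, needle$mesh),
                                    config$surface_noise_sd_mm)

  lm <- .landmark_template()
  lm_posed <- landmark_set(apply_transform.default(pose, lm$points),
                           rownames(lm$points))
  if (config$landmark_noise_sd_mm > 0)
    lm_posed$points <- lm_posed$points +
      matrix(rnorm(length(lm_posed$points), 0, config$landmark_noise_sd_mm),
             ncol = 3)

  truth <- list(
    true_lateral_mm = lat,
    true_depth_mm = dep,
    true_euclidean_mm = true_euclid,
    euclidean_centerline_mm = euclid_centerline,
    surface = surface_truth,
    nerve_centerline = nerve$centerline,
    applied_pose = pose,
    tip_point_model = needle$tip_point,
    direction_model = needle$direction,
    lateral_ref_model = needle$lateral_ref,
    landmark_truth = lm)

  structure(list(trial_id = trial_id, nerve = nerve_mesh, needle = needle_mesh,
                 landmarks = lm_posed, truth = truth),
            class = "trial_record")
}

# numeric surface-referenced oracles on the noiseless, unposed geometry
.surface_truth <- function(nerve, needle, config) {
  sp <- config$truth_spacing_mm
  nerve_cloud <- sample_surface(nerve$mesh, sp)
  needle_cloud <- sample_surface(needle$mesh, sp)
  axis <- list(anchor = needle$tip_point, direction = needle$direction,
               s_min = -config$needle_length_mm, s_max = 0,
               tip_point = needle$tip_point)
  class(axis) <- "needle_axis"
  s <- .axial_coord(axis, needle_cloud$points)
  tip_cloud <- needle_cloud$points[s >= max(s) - 5.00, , drop = FALSE]
  ld <- lateral_depth(axis, nerve_cloud, needle$lateral_ref)
  list(euclidean_mm = euclidean_distance(tip_cloud, nerve_cloud),
       lateral_signed_mm = ld$lateral_signed_mm,
       depth_signed_mm = ld$depth_signed_mm,
       spacing_mm = sp)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s: nerve %d faces, needle %d faces, truth (lat %+.2f, depth %+.2f) mm\n",
              x$trial_id, nrow(x$nerve$faces), nrow(x$needle$faces),
              x$truth$true_lateral_mm, x$truth$true_depth_mm))
  invisible(x)
}

#' Generate a cohort of synthetic trials
#'
#' @param config A \code{synth_config}; its offsets are used for every trial
#'   unless \code{offsets} is given.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer master seed (defaults to \code{config$seed}); each
#'   trial derives an independent sub-seed from it and its trial id.
#' @param offsets Optional \code{n_trials} x 2 matrix of per-trial
#'   (lateral, depth) offsets in mm.
#' @return List of \code{trial_record}s.
#' @export
generate_cohort <- function(config, n_trials, seed = config$seed,
                            offsets = NULL) {
  if (n_trials < 1) .np_stopf("n_trials must be >= 1")
  if (!is.null(offsets)) {
    offsets <- as.matrix(offsets)
    if (nrow(offsets) != n_trials || ncol(offsets) != 2L)
      .np_stopf("offsets must be an n_trials x 2 matrix (lateral, depth)")
  }
  lapply(seq_len(n_trials), function(i) {
    cfg <- config
    if (!is.null(offsets)) {
      cfg$true_lateral_mm <- offsets[i, 1]
      cfg$true_depth_mm <- offsets[i, 2]
    }
    generate_trial(cfg, sprintf("trial_%03d", i), seed = seed)
  })
}

#' Reference geometry for a synthetic cohort
#'
#' The unposed nerve model the generator worked from, with centerline and
#' unjittered landmarks: the analogue of the planned "simulated nerve" all
#' trials are aligned onto.
#'
#' @param config A \code{synth_config}.
#' @param run_cfg A \code{run_config} (sampling spacing).
#' @return A reference object as from \code{\link{make_reference}}; also
#'   carries \code{mesh} and \code{lateral_ref}.
#' @export
generate_reference <- function(config, run_cfg = run_config()) {
  nerve <- generate_nerve(config)
  needle <- generate_needle(config, nerve)
  ref <- make_reference(nerve$mesh, run_cfg,
                        centerline = point_cloud(nerve$centerline,
                                                 config$centerline_step_mm),
                        landmarks = .landmark_template())
  ref$mesh <- nerve$mesh
  ref$lateral_ref <- needle$lateral_ref
  ref
}
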