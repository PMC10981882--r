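#' Fit the needle axis by total least squares
#'
#' Principal axis of the centered needle cloud. The axial coordinate of a
#' point is its projection onto the direction; the direction is oriented so
#' that the tip lies at the larger axial coordinate. Which extreme is the tip
#' is decided by proximity to the nerve when a nerve cloud is supplied (the
#' only automatic rule consistent with an inserted needle, since segmented
#' needles may include hub geometry); otherwise a deterministic sign
#' convention (largest-magnitude component positive) is used.
#'
#' @param needle A \code{point_cloud} (or n x 3 matrix) of the needle surface.
#' @param nerve Optional \code{point_cloud} used to orient the tip end.
#' @return An object of class \code{needle_axis}: \code{anchor} (centroid),
#'   unit \code{direction} (hub -> tip), axial extent \code{s_min}/\code{s_max},
#'   \code{tip_point} (the sample with the largest axial coordinate) and
#'   \code{residual_rms_mm} (RMS perpendicular distance to the line).
#' @export
fit_needle_axis <- function(needle, nerve = NULL) {
  P <- if (inherits(needle, "point_cloud")) needle$points else as.matrix(needle)
  if (nrow(P) < 3L) .np_stopf("needle cloud must contain at least 3 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  C <- crossprod(Pc) / nrow(P)
  eig <- eigen(C, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  if (lam[1] <= 0) .np_stopf("needle cloud is a single point: no axis")
  if (sqrt(lam[2] / lam[1]) > 0.9)
    .np_stopf("ambiguous needle axis: top two spreads within 10%% (ratio %.3f)",
              sqrt(lam[2] / lam[1]))
  dir <- eig$vectors[, 1]
  s <- as.numeric(Pc %*% dir)
  if (!is.null(nerve)) {
    Qn <- if (inherits(nerve, "point_cloud")) nerve$points else as.matrix(nerve)
    tree <- .cpp_nn_build(Qn)
    ends <- rbind(P[which.max(s), ], P[which.min(s), ])
    d <- .cpp_nn_query(tree, ends)$dist
    if (d[2] < d[1]) { dir <- -dir; s <- -s }
  } else {
    k <- which.max(abs(dir))
    if (dir[k] < 0) { dir <- -dir; s <- -s }
  }
  i_tip <- which.max(s)
  perp2 <- rowSums(Pc^2) - s^2
  structure(list(anchor = ctr, direction = dir,
                 s_min = min(s), s_max = max(s),
                 tip_point = P[i_tip, ],
                 residual_rms_mm = sqrt(max(mean(perp2), 0))),
            class = "needle_axis")
}

#' @export
print.needle_axis <- function(x, ...) {
  cat(sprintf("<needle_axis> dir (%.4f, %.4f, %.4f), length %.2f mm, residual rms %.4g mm\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$s_max - x$s_min, x$residual_rms_mm))
  invisible(x)
}

.axial_coord <- function(axis, P) {
  as.numeric(sweep(as.matrix(P), 2L, axis$anchor) %*% axis$direction)
}

#' Extract the active tip of the needle
#'
#' All needle points in the outermost \code{tip_length_mm} of the shaft
#' (axial coordinate \code{s >= s_max - tip_length_mm}, closed interval),
#' matching the 5.00 mm active tip of the PRF needles the analysis targets.
#'
#' @param needle A \code{point_cloud}.
#' @param axis A \code{needle_axis} fitted to the same cloud.
#' @param tip_length_mm Tip length (default 5.00 mm).
#' @return A \code{point_cloud} of the tip points (never empty).
#' @export
extract_tip <- function(needle, axis, tip_length_mm = 5.00) {
  if (!is.numeric(tip_length_mm) || tip_length_mm <= 0)
    .np_stopf("tip_length_mm must be > 0")
  P <- needle$points
  s <- .axial_coord(axis, P)
  keep <- s >= max(s) - tip_length_mm
  point_cloud(P[keep, , drop = FALSE], needle$spacing_mm)
}

#' Minimal Euclidean distance between tip and nerve
#'
#' Minimum over all pairs of a tip point and a nerve point; kd-tree
#' accelerated but identical to the exhaustive double loop.
#'
#' @param tip,nerve \code{point_cloud} objects (or n x 3 matrices).
#' @return Distance in mm.
#' @export
euclidean_distance <- function(tip, nerve) {
  A <- if (inherits(tip, "point_cloud")) tip$points else as.matrix(tip)
  B <- if (inherits(nerve, "point_cloud")) nerve$points else as.matrix(nerve)
  if (nrow(A) < 1L || nrow(B) < 1L) .np_stopf("clouds must be nonempty")
  tree <- .cpp_nn_build(B)
  .cpp_min_dist(tree, A)
}

#' Lateral and depth decomposition of the placement error
#'
#' Let L be the infinite line through the needle axis (so an undershooting
#' needle still has a defined lateral offset). The nerve point closest to L
#' (in perpendicular distance) defines the lateral distance; its orthogonal
#' projection onto L is the foot point with axial coordinate \code{s_foot}.
#' The signed depth is \code{s_foot - s_max}: positive means the target lies
#' beyond the tip (undershoot), negative means the tip went deeper than the
#' target. The lateral sign is the sign of
#' \code{dot(nerve_closest - foot, lateral_ref)}; mapping positive to the
#' subject's right is a configuration choice since patient orientation is not
#' recoverable from STL coordinates alone. Unsigned statistics never depend
#' on \code{lateral_ref}.
#'
#' @param axis A \code{needle_axis}.
#' @param nerve \code{point_cloud} (or matrix) of the nerve.
#' @param lateral_ref Unit reference vector defining positive lateral sign;
#'   must be more than 5 degrees away from the axis direction.
#' @return List with \code{lateral_signed_mm}, \code{depth_signed_mm},
#'   \code{foot_point}, \code{nerve_closest_point}.
#' @export
lateral_depth <- function(axis, nerve, lateral_ref = c(1, 0, 0)) {
  Q <- if (inherits(nerve, "point_cloud")) nerve$points else as.matrix(nerve)
  if (nrow(Q) < 1L) .np_stopf("nerve cloud must be nonempty")
  lateral_ref <- as.numeric(lateral_ref)
  nref <- sqrt(sum(lateral_ref^2))
  if (nref == 0) .np_stopf("lateral_ref must be nonzero")
  lateral_ref <- lateral_ref / nref
  cosang <- abs(sum(lateral_ref * axis$direction))
  if (cosang > cos(5 * pi / 180))
    .np_stopf("lateral_ref is within 5 degrees of the needle axis: lateral sign ill-conditioned")
  rel <- sweep(Q, 2L, axis$anchor)
  s <- as.numeric(rel %*% axis$direction)
  perp2 <- pmax(rowSums(rel^2) - s^2, 0)
  i <- which.min(perp2)
  lat <- sqrt(perp2[i])
  foot <- axis$anchor + s[i] * axis$direction
  nc <- Q[i, ]
  latsign <- sum((nc - foot) * lateral_ref)
  lat_signed <- if (lat == 0) 0 else lat * sign(latsign)
  list(lateral_signed_mm = lat_signed,
       depth_signed_mm = s[i] - axis$s_max,
       foot_point = foot,
       nerve_closest_point = nc)
}

#' Per-trial accuracy result
#'
#' @param trial_id Trial identifier.
#' @param euclidean_mm Minimal Euclidean tip-to-nerve distance (mm).
#' @param lateral_signed_mm,depth_signed_mm Signed lateral / depth distances.
#' @param threshold_mm Effective-range threshold (default 5.00 mm, strict <).
#' @param icp_rms_mm,icp_iterations,icp_converged Registration diagnostics.
#' @return Object of class \code{accuracy_result}.
#' @export
accuracy_result <- function(trial_id, euclidean_mm, lateral_signed_mm,
                            depth_signed_mm, threshold_mm = 5.00,
                            icp_rms_mm = NA_real_, icp_iterations = NA_integer_,
                            icp_converged = NA) {
  structure(list(
    trial_id = trial_id,
    euclidean_mm = euclidean_mm,
    lateral_mm = abs(lateral_signed_mm),
    depth_mm = abs(depth_signed_mm),
    lateral_signed_mm = lateral_signed_mm,
    depth_signed_mm = depth_signed_mm,
    within_range_euclidean = euclidean_mm < threshold_mm,
    within_range_lateral = abs(lateral_signed_mm) < threshold_mm,
    within_range_depth = abs(depth_signed_mm) < threshold_mm,
    threshold_mm = threshold_mm,
    icp_rms_mm = icp_rms_mm,
    icp_iterations = icp_iterations,
    icp_converged = icp_converged), class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %s: euclidean %.3f, lateral %+.3f, depth %+.3f mm (range %.2f mm)\n",
              x$trial_id, x$euclidean_mm, x$lateral_signed_mm,
              x$depth_signed_mm, x$threshold_mm))
  invisible(x)
}

#' @export
as.data.frame.accuracy_result <- function(x, ...) {
  data.frame(trial_id = x$trial_id, euclidean_mm = x$euclidean_mm,
             lateral_mm = x$lateral_mm, depth_mm = x$depth_mm,
             lateral_signed_mm = x$lateral_signed_mm,
             depth_signed_mm = x$depth_signed_mm,
             within_range_euclidean = x$within_range_euclidean,
             within_range_lateral = x$within_range_lateral,
             within_range_depth = x$within_range_depth,
             icp_rms_mm = x$icp_rms_mm, icp_iterations = x$icp_iterations,
             icp_converged = x$icp_converged,
             stringsAsFactors = FALSE)
}

#' Assess one trial against a reference nerve
#'
#' The per-trial pipeline: sample the trial's nerve and needle surfaces,
#' register the trial nerve onto the reference nerve (Procrustes on landmarks
#' for the initial guess when both landmark sets are present, then ICP),
#' apply the fitted transform to the needle, fit the needle axis, extract the
#' 5 mm active tip, and compute the Euclidean / lateral / depth distances.
#'
#' @param trial A \code{trial_record} (see \code{\link{generate_trial}}) or a
#'   list with \code{nerve}, \code{needle} (\code{tri_mesh}) and optionally
#'   \code{landmarks}.
#' @param reference A reference object from \code{\link{make_reference}}.
#' @param config A \code{run_config} (see \code{\link{run_config}}); controls
#'   sampling spacing, tip length, threshold, nerve reference
#'   (\code{"surface"} or \code{"centerline"}), tip mode (\code{"all"} tip
#'   points or \code{"extreme"} single deepest point), lateral sign reference
#'   and ICP parameters.
#' @return An \code{accuracy_result}.
#' @export
assess_trial <- function(trial, reference, config = run_config()) {
  nerve_cloud <- sample_surface(trial$nerve, config$spacing_mm)
  needle_cloud <- sample_surface(trial$needle, config$spacing_mm)

  init <- identity_transform()
  if (!is.null(trial$landmarks) && !is.null(reference$landmarks))
    init <- procrustes_rigid(trial$landmarks, reference$landmarks)$transform

  icp <- icp_rigid(nerve_cloud, reference$surface, init = init,
                   max_iter = config$icp_max_iter, tol_mm = config$icp_tol_mm,
                   subsample_max = config$icp_subsample_max)
  if (!icp$converged)
    .np_warnf("trial %s: ICP did not converge within %d iterations (rms %.4g mm)",
              trial$trial_id %||% "?", icp$iterations, icp$rms_mm)

  needle_reg <- apply_transform(icp$transform, needle_cloud)

  nerve_ref <- if (identical(config$nerve_reference, "centerline")) {
    if (is.null(reference$centerline))
      .np_stopf("nerve_reference = 'centerline' but the reference has no centerline")
    reference$centerline
  } else reference$surface

  axis <- fit_needle_axis(needle_reg, nerve = nerve_ref)
  tip <- extract_tip(needle_reg, axis, config$tip_length_mm)
  tip_for_euclid <- if (identical(config$tip_mode, "extreme"))
    matrix(axis$tip_point, 1, 3) else tip
  euclid <- euclidean_distance(tip_for_euclid, nerve_ref)
  ld <- lateral_depth(axis, nerve_ref, config$lateral_ref)

  accuracy_result(trial$trial_id %||% "trial", euclid,
                  ld$lateral_signed_mm, ld$depth_signed_mm,
                  threshold_mm = config$threshold_mm,
                  icp_rms_mm = icp$rms_mm, icp_iterations = icp$iterations,
                  icp_converged = icp$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the reference frame for a cohort analysis
#'
#' All trials are matched onto one reference nerve. For synthetic cohorts the
#' natural reference is the unposed nerve model the generator worked from;
#' for measured data it is one chosen trial's segmented nerve.
#'
#' @param nerve A \code{tri_mesh} of the reference nerve.
#' @param config A \code{run_config} (sampling spacing).
#' @param centerline Optional n x 3 polyline of the nerve centerline (mm),
#'   enabling \code{nerve_reference = "centerline"}.
#' @param landmarks Optional \code{landmark_set} in the reference frame.
#' @return A list with \code{surface} (\code{point_cloud}),
#'   \code{centerline} (\code{point_cloud} or NULL) and \code{landmarks}.
#' @export
make_reference <- function(nerve, config = run_config(), centerline = NULL,
                           landmarks = NULL) {
  cl <- NULL
  if (!is.null(centerline)) {
    cl <- if (inherits(centerline, "point_cloud")) centerline
          else point_cloud(centerline, config$spacing_mm)
  }
  list(surface = sample_surface(nerve, config$spacing_mm),
       centerline = cl, landmarks = landmarks)
}

#' Assess a whole cohort of trials
#'
#' @param trials List of trial records.
#' @param reference From \code{\link{make_reference}}.
#' @param config A \code{run_config}.
#' @return List with \code{results} (data frame, one row per assessed trial)
#'   and \code{skipped} (named character vector of per-trial error messages).
#' @export
assess_cohort <- function(trials, reference, config = run_config()) {
  rows <- list()
  skipped <- character(0)
  for (tr in trials) {
    res <- tryCatch(assess_trial(tr, reference, config), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[tr$trial_id %||% "?"]] <- conditionMessage(res)
      next
    }
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  list(results = if (length(rows)) do.call(rbind, rows) else NULL,
       skipped = skipped)
}
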