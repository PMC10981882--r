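#' Canonical pelvic landmark names
#'
#' The six bony landmarks used to align the virtual anatomy onto the phantom:
#' left/right ischial tuberosity, left/right midpoint of the lateral border of
#' the sacrum, left/right greater trochanter.
#' @export
PELVIC_LANDMARKS <- c("ischial_tuberosity_left", "ischial_tuberosity_right",
                      "sacrum_lateral_border_left", "sacrum_lateral_border_right",
                      "greater_trochanter_left", "greater_trochanter_right")

#' Named landmark set
#'
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @param names Character vector of distinct landmark names (defaults to the
#'   matrix rownames). Six pelvic landmarks are the canonical configuration
#'   for Procrustes alignment.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(points, names = rownames(points)) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 1L)
    .np_stopf("landmarks must be a nonempty n x 3 matrix")
  if (any(!is.finite(points))) .np_stopf("landmark coordinates must be finite")
  if (is.null(names)) .np_stopf("landmarks must be named")
  names <- as.character(names)
  if (anyDuplicated(names)) .np_stopf("landmark names must be distinct")
  rownames(points) <- names
  structure(list(points = points), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks: %s\n", nrow(x$points),
              paste(rownames(x$points), collapse = ", ")))
  invisible(x)
}

#' Read / write landmark CSV (name,x,y,z in mm)
#' @param path CSV path.
#' @return \code{read_landmarks}: a \code{landmark_set}.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    .np_stopf("landmark CSV %s must have columns name,x,y,z", path)
  landmark_set(as.matrix(df[, c("x", "y", "z")]), df$name)
}

#' @rdname read_landmarks
#' @param lm A \code{landmark_set}.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(name = rownames(lm$points), x = lm$points[, 1],
                   y = lm$points[, 2], z = lm$points[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

registration_report <- function(transform, rms_mm, iterations, converged,
                                rms_history = numeric(0)) {
  structure(list(transform = transform, rms_mm = rms_mm,
                 iterations = iterations, converged = converged,
                 rms_history = rms_history),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> rms %.6g mm after %d iteration(s), converged: %s\n",
              x$rms_mm, x$iterations, x$converged))
  invisible(x)
}

.check_noncollinear <- function(pts, what = "landmarks") {
  sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
  if (sv[1] < 1e-9 || sv[2] / sv[1] < 1e-9)
    .np_stopf("degenerate configuration: %s are collinear or coincident", what)
}

#' Rigid Procrustes alignment of named landmarks
#'
#' Closed-form proper rigid fit (rotation + translation, no scaling, no
#' reflection) minimizing the sum of squared distances between landmarks
#' paired by name, as used to overlay the virtual anatomy on the phantom.
#'
#' @param source,target \code{landmark_set} objects sharing the same names
#'   (canonically the six pelvic landmarks).
#' @return A \code{registration_report}; \code{transform} maps source onto
#'   target, \code{rms_mm} is the residual at the optimum.
#' @export
procrustes_rigid <- function(source, target) {
  sn <- rownames(source$points); tn <- rownames(target$points)
  if (!setequal(sn, tn) || length(sn) != length(tn))
    .np_stopf("landmark sets cannot be paired: names differ (%s vs %s)",
              paste(sn, collapse = ","), paste(tn, collapse = ","))
  if (length(sn) < 3L) .np_stopf("at least 3 paired landmarks are required")
  p <- source$points
  q <- target$points[sn, , drop = FALSE]
  .check_noncollinear(p, "source landmarks")
  .check_noncollinear(q, "target landmarks")
  fit <- fit_rigid(p, q)
  registration_report(fit$transform, fit$rms_mm, iterations = 0L,
                      converged = TRUE)
}

#' Iterative closest point rigid registration
#'
#' Plain point-to-point ICP: each iteration pairs every (subsampled) source
#' point with its nearest target point via a kd-tree, solves the closed-form
#' proper rigid fit on those pairs, and repeats until the RMS improvement
#' drops below \code{tol_mm} or \code{max_iter} is reached. The RMS of the
#' matched pairs is non-increasing across iterations. No trimming or outlier
#' rejection is applied: trial nerves are near-complete copies of the
#' reference, so robust variants are unnecessary.
#'
#' @param source,target \code{point_cloud} objects (or n x 3 matrices).
#' @param init Initial \code{rigid_transform} (identity by default; a
#'   landmark Procrustes fit when available).
#' @param max_iter Maximum iterations (default 100).
#' @param tol_mm Convergence tolerance on the RMS improvement (default 1e-6).
#' @param subsample_max Deterministic cap on the number of source points used
#'   for correspondences (evenly strided; default 50000). The returned RMS is
#'   evaluated on this subsample.
#' @return A \code{registration_report} with the source-to-target transform,
#'   final RMS, iteration count, convergence flag and per-iteration RMS
#'   history.
#' @export
icp_rigid <- function(source, target, init = identity_transform(),
                      max_iter = 100L, tol_mm = 1e-6, subsample_max = 50000L) {
  P <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  Q <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(P) < 1L || nrow(Q) < 1L) .np_stopf("ICP inputs must be nonempty")
  if (any(!is.finite(P)) || any(!is.finite(Q)))
    .np_stopf("ICP inputs contain non-finite coordinates")
  if (tol_mm <= 0) .np_stopf("tol_mm must be > 0")
  if (nrow(P) > subsample_max) {
    idx <- unique(as.integer(round(seq(1, nrow(P), length.out = subsample_max))))
    P <- P[idx, , drop = FALSE]
  }
  tree <- .cpp_nn_build(Q)
  tf <- init
  rms_hist <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Pt <- apply_transform(tf, P)
    nn <- .cpp_nn_query(tree, Pt)
    rms <- sqrt(mean(nn$dist^2))
    rms_hist <- c(rms_hist, rms)
    if (nrow(P) >= 3L) {
      fit <- fit_rigid(P, Q[nn$index, , drop = FALSE])
      tf <- fit$transform
    }
    if (rms <= tol_mm || (is.finite(prev_rms) && prev_rms - rms < tol_mm)) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  registration_report(tf, rms_hist[length(rms_hist)], iterations = iter,
                      converged = converged, rms_history = rms_hist)
}
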