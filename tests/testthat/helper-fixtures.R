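# shared fixtures and independent oracles, all built in code

# 12-triangle unit cube [0,1]^3
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  tri_mesh(v, f, "cube")
}

# random proper rotation via axis-angle
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  needleplace:::rotation_about_axis(ax, runif(1, 0, pi))
}

random_rigid <- function(trans_scale = 20) {
  rigid_transform(random_rotation(), rnorm(3, 0, trans_scale))
}

# exhaustive O(n^2) minimum distance oracle
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# full 2^n sign-flip enumeration of the one-sample signed-rank test
# (mid-ranks, zeros already removed); returns the two-sided p for V observed
brute_wilcoxon_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.numeric(signs %*% r)
  p_le <- mean(V_all <= V_obs)
  p_ge <- mean(V_all >= V_obs)
  min(1, 2 * min(p_le, p_ge))
}

# six well-spread labelled landmarks
demo_landmarks <- function() {
  needleplace:::.landmark_template()
}

coarse_run_config <- function(...) {
  run_config(spacing_mm = 0.2, icp_subsample_max = 20000L, ...)
}
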