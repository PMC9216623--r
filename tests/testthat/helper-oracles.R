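# Independent oracles used to check the package's geometric primitives.

# Brute-force continuous-time oracle for the edge-cut predicate: linearly
# interpolate P, Q, R between two frames at `steps`-fold supersampling and
# report whether R crosses the interior of the moving segment PQ (sign change
# of the cross product between consecutive substeps while the projection of R
# onto PQ stays strictly interior at both substeps).
oracle_segment_cut <- function(p1, q1, r1, p2, q2, r2, steps = 100) {
  s <- seq(0, 1, length.out = steps + 1)
  lerp <- function(a, b) cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
  P <- lerp(p1, p2); Q <- lerp(q1, q2); R <- lerp(r1, r2)
  pq <- Q - P; pr <- R - P
  cr <- pq[, 1] * pr[, 2] - pq[, 2] * pr[, 1]
  dt <- pq[, 1] * pr[, 1] + pq[, 2] * pr[, 2]
  l2 <- pq[, 1]^2 + pq[, 2]^2
  interior <- dt > 0 & dt < l2
  n <- length(s)
  any(cr[-n] * cr[-1] < 0 & interior[-n] & interior[-1])
}

# Rotation-sweep oracle for the minimum-area bounding rectangle.
oracle_bbox_area <- function(points, step_deg = 0.01) {
  pts <- as.matrix(points)
  th <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  # vectorized over angles in blocks to bound memory
  for (block in split(th, ceiling(seq_along(th) / 2000))) {
    ct <- cos(block); st <- sin(block)
    xr <- outer(pts[, 1], ct) + outer(pts[, 2], st)
    yr <- -outer(pts[, 1], st) + outer(pts[, 2], ct)
    area <- (apply(xr, 2, max) - apply(xr, 2, min)) *
      (apply(yr, 2, max) - apply(yr, 2, min))
    best <- min(best, min(area))
  }
  best
}

# Exhaustive fine-grid oracle for the sinusoid fit score: gamma step 0.25 deg,
# lambda step 1 cm, psi step 1 deg. Returns the best score found on the grid.
oracle_fit_grid <- function(points_by_group, mode = "whole_crowd",
                            lambda_bounds = c(1, 3),
                            gamma_range = c(45, 135)) {
  if (identical(mode, "whole_crowd")) {
    p1 <- as.matrix(points_by_group[[1]]); p2 <- as.matrix(points_by_group[[2]])
    pts <- rbind(p1, p2)
    w <- c(rep(1 / nrow(p1), nrow(p1)), rep(-1 / nrow(p2), nrow(p2)))
  } else {
    pts <- as.matrix(points_by_group[[mode]])
    w <- rep(1 / nrow(pts), nrow(pts))
  }
  gammas <- seq(gamma_range[1], gamma_range[2], by = 0.25) * pi / 180
  lambdas <- seq(lambda_bounds[1], lambda_bounds[2], by = 0.01)
  psis <- seq(-179, 180, by = 1) * pi / 180
  cp <- cos(psis); sp <- sin(psis)
  best <- -Inf
  for (g in gammas) {
    X <- pts[, 1] * sin(g) - pts[, 2] * cos(g)
    ph <- outer(X, 2 * pi / lambdas)
    S <- colSums(w * sin(ph))
    K <- colSums(w * cos(ph))
    # score over the psi grid: max_j (S cos(psi_j) + K sin(psi_j))
    sc <- apply(outer(S, cp) + outer(K, sp), 1, max)
    best <- max(best, max(sc))
  }
  best
}

# Shared small, fast generator configs for tests (overridable defaults).
cfg_small <- function(...) {
  do.call(trial_config, utils::modifyList(
    list(n_per_group = 10, n_stripes_per_group = 2, frame_rate_hz = 60,
         speed_sd = 0, gait_amplitude_m = 0),
    list(...)))
}
cfg_noiseless <- function(...) {
  do.call(trial_config, utils::modifyList(
    list(speed_sd = 0, gait_amplitude_m = 0, position_noise_sd_m = 0),
    list(...)))
}
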