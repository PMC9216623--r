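#' Estimate the observed crossing angle and bisector frame
#'
#' Per group, the direction of motion is the line from the barycenter of the
#' initial positions to the barycenter of the final positions (each averaged
#' over a short window of frames for robustness). The observed crossing angle
#' alpha is the angle between the two unit directions; the bisector is their
#' normalized sum. Groups are labeled left (L) / right (R) by the sign of the
#' cross product of the bisector with their direction vector.
#'
#' @param trial A `stripeflow_trial` with two groups.
#' @param head_window_s,tail_window_s Averaging windows at the start and end
#'   of each pedestrian's track, seconds.
#' @param bisector_override_deg Bisector direction (degrees from the x-axis)
#'   to use when the two group directions are antiparallel within tolerance
#'   and the bisector is otherwise undefined.
#' @return An object of class `stripeflow_geometry`: `alpha_deg`, unit
#'   vectors `dir_L` and `dir_R`, `bisector` (unit vector),
#'   `bisector_theta_deg` (angle theta_B of the bisector from the x-axis),
#'   and the `left_group` / `right_group` labels.
#' @export
estimate_crossing_geometry <- function(trial, head_window_s = 0.5,
                                       tail_window_s = 0.5,
                                       bisector_override_deg = NULL) {
  groups <- trial_groups(trial)
  if (length(groups) != 2) {
    rlang::abort("crossing geometry requires exactly two groups",
                 class = "stripeflow_error_one_group")
  }
  dirs <- list()
  for (g in groups) {
    d <- trial$data[trial$data$group == g, ]
    bary <- function(sel) c(mean(d$x[sel]), mean(d$y[sel]))
    # per-pedestrian windows relative to each track's own head/tail
    sp <- split(seq_len(nrow(d)), d$id)
    p0 <- p1 <- matrix(0, length(sp), 2)
    for (i in seq_along(sp)) {
      idx <- sp[[i]]
      tt <- d$time[idx]
      h <- idx[tt <= tt[1] + head_window_s]
      tl <- idx[tt >= tt[length(tt)] - tail_window_s]
      p0[i, ] <- bary(match(h, seq_len(nrow(d))))
      p1[i, ] <- bary(match(tl, seq_len(nrow(d))))
    }
    disp <- colMeans(p1) - colMeans(p0)
    len <- sqrt(sum(disp^2))
    if (len < 0.5) {
      rlang::abort(sprintf("group %s did not move (displacement %.3f m < 0.5 m)",
                           g, len),
                   class = "stripeflow_error_group_did_not_move")
    }
    dirs[[g]] <- disp / len
  }

  u1 <- dirs[[groups[1]]]
  u2 <- dirs[[groups[2]]]
  alpha <- rad2deg(acos(max(-1, min(1, sum(u1 * u2)))))

  bsum <- u1 + u2
  if (sqrt(sum(bsum^2)) < 1e-6) {
    if (is.null(bisector_override_deg)) {
      rlang::abort(
        paste("degenerate bisector: group directions are antiparallel;",
              "supply `bisector_override_deg`"),
        class = "stripeflow_error_degenerate_bisector"
      )
    }
    bis <- c(cos(deg2rad(bisector_override_deg)), sin(deg2rad(bisector_override_deg)))
  } else {
    bis <- bsum / sqrt(sum(bsum^2))
  }

  c1 <- cross2(bis, u1)
  if (c1 > 0 || (c1 == 0 && cross2(bis, u2) <= 0)) {
    left <- groups[1]; right <- groups[2]
    dir_L <- u1; dir_R <- u2
  } else {
    left <- groups[2]; right <- groups[1]
    dir_L <- u2; dir_R <- u1
  }

  structure(
    list(
      alpha_deg = alpha,
      dir_L = dir_L, dir_R = dir_R,
      bisector = bis,
      bisector_theta_deg = rad2deg(atan2(bis[2], bis[1])),
      left_group = left, right_group = right
    ),
    class = "stripeflow_geometry"
  )
}

#' @export
print.stripeflow_geometry <- function(x, ...) {
  cat("<stripeflow_geometry>\n")
  cat(sprintf("  observed crossing angle alpha: %.3f deg\n", x$alpha_deg))
  cat(sprintf("  bisector theta_B: %.3f deg from x-axis\n", x$bisector_theta_deg))
  cat(sprintf("  left group: %s, right group: %s\n", x$left_group, x$right_group))
  invisible(x)
}

#' Rotate points into the bisector frame
#'
#' Rigid rotation by `-theta_B` about the origin so the new x'-axis lies along
#' the bisector of the crossing angle; lengths are preserved.
#'
#' @param points n x 2 matrix (or data frame with `x`, `y`).
#' @param geometry A `stripeflow_geometry`.
#' @return n x 2 matrix of (x', y') coordinates.
#' @export
to_bisector_frame <- function(points, geometry) {
  rotate2(points, -deg2rad(geometry$bisector_theta_deg))
}

#' Inverse of [to_bisector_frame()]
#' @inheritParams to_bisector_frame
#' @return n x 2 matrix in the original frame.
#' @export
from_bisector_frame <- function(points, geometry) {
  rotate2(points, deg2rad(geometry$bisector_theta_deg))
}

#' Signed angular deviations from the expected walking direction
#'
#' For every frame where a pedestrian moves faster than `speed_floor_mps`
#' (heading is undefined at standstill), the signed angle delta from the
#' group's expected direction to the instantaneous velocity (central
#' differences) is returned. Counterclockwise deviations are positive.
#'
#' @param trial A `stripeflow_trial` (normally filtered).
#' @param expected_dirs Named list mapping each group label to a length-2
#'   direction vector or a single angle in degrees.
#' @param speed_floor_mps Frames slower than this are excluded (default 0.2).
#' @return Tibble with columns `id`, `group`, `frame`, `time`, `speed_mps`,
#'   `delta_deg`, each delta in (-180, 180].
#' @export
angular_deviations <- function(trial, expected_dirs, speed_floor_mps = 0.2) {
  dirvec <- function(v) {
    if (length(v) == 1) c(cos(deg2rad(v)), sin(deg2rad(v))) else v / sqrt(sum(v^2))
  }
  exp_dirs <- lapply(expected_dirs, dirvec)
  d <- trial$data[base::order(trial$data$id, trial$data$time), ]
  sp <- split(seq_len(nrow(d)), d$id)
  out <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    idx <- sp[[i]]
    n <- length(idx)
    if (n < 3) next
    tt <- d$time[idx]; xx <- d$x[idx]; yy <- d$y[idx]
    vx <- c(NA, (xx[3:n] - xx[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
    vy <- c(NA, (yy[3:n] - yy[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
    speed <- sqrt(vx^2 + vy^2)
    g <- d$group[idx[1]]
    u <- exp_dirs[[g]]
    delta <- rad2deg(atan2(u[1] * vy - u[2] * vx, u[1] * vx + u[2] * vy))
    keep <- which(is.finite(speed) & speed > speed_floor_mps)
    out[[i]] <- tibble::tibble(
      id = d$id[idx[keep]], group = g,
      frame = match(tt[keep], trial$frame_times),
      time = tt[keep], speed_mps = speed[keep], delta_deg = wrap_deg(delta[keep])
    )
  }
  dplyr::bind_rows(out)
}
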