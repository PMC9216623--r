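#' Crossing-flow trial object
#'
#' A trial holds the head trajectories of every pedestrian in one crossing-flow
#' recording: a long-format table with one row per pedestrian per frame, the
#' frame rate, and optional metadata (the crossing angle the trial was set up
#' for). All pedestrians share a uniform frame grid; individual pedestrians may
#' be missing frames only at the head or tail of the trial, never inside it.
#'
#' @param data Data frame with columns `time` (seconds), `id` (pedestrian
#'   identifier), `group` (one of at most two group labels), `x`, `y` (meters).
#' @param frame_rate_hz Sampling rate in Hz. If `NULL`, inferred from `time`.
#' @param expected_angle_deg Optional target crossing angle (degrees).
#' @return An object of class `stripeflow_trial`.
#' @export
trial <- function(data, frame_rate_hz = NULL, expected_angle_deg = NA_real_) {
  req <- c("time", "id", "group", "x", "y")
  if (!all(req %in% names(data))) {
    rlang::abort(
      paste0("trial data must have columns ", paste(req, collapse = ", ")),
      class = "stripeflow_error_bad_header"
    )
  }
  data <- tibble::as_tibble(data[, req])
  data$id <- as.character(data$id)
  data$group <- as.character(data$group)
  for (col in c("time", "x", "y")) {
    if (!is.numeric(data[[col]])) {
      rlang::abort(paste0("column `", col, "` must be numeric"),
                   class = "stripeflow_error_bad_values")
    }
  }
  if (anyNA(data$x) || anyNA(data$y) || anyNA(data$time)) {
    rlang::abort("trial data contains missing coordinates or times",
                 class = "stripeflow_error_bad_values")
  }

  grid <- sort(unique(data$time))
  if (length(grid) > 1) {
    dt <- diff(grid)
    if (max(dt) - min(dt) > 1e-6) {
      rlang::abort("frame times are not a uniform grid (tolerance 1e-6 s)",
                   class = "stripeflow_error_nonuniform_grid")
    }
  }
  groups <- unique(data$group)
  if (length(groups) > 2) {
    rlang::abort(
      paste0("too many groups: found ", length(groups), ", at most 2 allowed"),
      class = "stripeflow_error_too_many_groups"
    )
  }

  # interior gaps: frames of each pedestrian must be contiguous on the grid
  frame_of <- match(data$time, grid)
  by_id <- split(frame_of, data$id)
  for (pid in names(by_id)) {
    fr <- sort(by_id[[pid]])
    if (anyDuplicated(fr)) {
      rlang::abort(paste0("pedestrian ", pid, " has duplicated frames"),
                   class = "stripeflow_error_duplicate_frames")
    }
    if (length(fr) > 1 && any(diff(fr) != 1L)) {
      rlang::abort(
        paste0("pedestrian ", pid, " has an interior gap in its frames"),
        class = "stripeflow_error_interior_gap"
      )
    }
  }

  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- if (length(grid) > 1) 1 / stats::median(diff(grid)) else NA_real_
  }

  data <- data[order(match(data$time, grid), data$id), ]

  # wide-format cache (frames x pedestrians), built once
  ids <- sort(unique(data$id))
  fi <- match(data$time, grid)
  pi_ <- match(data$id, ids)
  X <- matrix(NA_real_, length(grid), length(ids))
  Y <- X
  X[cbind(fi, pi_)] <- data$x
  Y[cbind(fi, pi_)] <- data$y
  colnames(X) <- colnames(Y) <- ids
  group_of <- vapply(split(data$group, data$id), `[`, "", 1)[ids]

  structure(
    list(
      data = data,
      frame_times = grid,
      frame_rate_hz = frame_rate_hz,
      expected_angle_deg = expected_angle_deg,
      arrays = list(times = grid, ids = ids, group_of = group_of, X = X, Y = Y)
    ),
    class = "stripeflow_trial"
  )
}

#' @export
print.stripeflow_trial <- function(x, ...) {
  ids <- unique(x$data$id)
  grp <- table(vapply(split(x$data$group, x$data$id), `[`, "", 1))
  cat("<stripeflow_trial>\n")
  cat("  pedestrians:", length(ids),
      "(", paste(sprintf("%s: %d", names(grp), as.integer(grp)), collapse = ", "), ")\n")
  cat("  frames:", length(x$frame_times),
      sprintf(" @ %.6g Hz", x$frame_rate_hz),
      sprintf(" [%.3f, %.3f] s", min(x$frame_times), max(x$frame_times)), "\n")
  if (!is.na(x$expected_angle_deg)) {
    cat("  expected crossing angle:", x$expected_angle_deg, "deg\n")
  }
  invisible(x)
}

#' Number of frames in a trial
#' @param x A `stripeflow_trial`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) length(x$frame_times)

#' Group labels of a trial
#' @param x A `stripeflow_trial`.
#' @return Character vector of (at most two) group labels, in order of first appearance.
#' @export
trial_groups <- function(x) unique(x$data$group)

#' Pedestrian ids of a trial, optionally for one group
#' @param x A `stripeflow_trial`.
#' @param group Optional group label.
#' @return Character vector of pedestrian ids (sorted).
#' @export
trial_ids <- function(x, group = NULL) {
  d <- x$data
  if (!is.null(group)) d <- d[d$group == group, ]
  sort(unique(d$id))
}

# Wide-format view: list(times, ids, group_of (named), X, Y) where X, Y are
# n_frames x n_peds matrices (NA where a pedestrian is absent).
#' @keywords internal
trial_arrays <- function(trial) {
  if (!is.null(trial$arrays)) return(trial$arrays)
  grid <- trial$frame_times
  ids <- sort(unique(trial$data$id))
  fi <- match(trial$data$time, grid)
  pi_ <- match(trial$data$id, ids)
  X <- matrix(NA_real_, length(grid), length(ids))
  Y <- X
  X[cbind(fi, pi_)] <- trial$data$x
  Y[cbind(fi, pi_)] <- trial$data$y
  colnames(X) <- colnames(Y) <- ids
  group_of <- vapply(split(trial$data$group, trial$data$id), `[`, "", 1)[ids]
  list(times = grid, ids = ids, group_of = group_of, X = X, Y = Y)
}

#' Pedestrian positions at one frame, split by group
#'
#' @param trial A `stripeflow_trial`.
#' @param frame Frame index (1-based).
#' @param geometry Optional [estimate_crossing_geometry()] result; if supplied,
#'   positions are rotated into the bisector frame and the list is ordered with
#'   the left group first.
#' @return Named list of n x 2 matrices (rownames = pedestrian ids), one per group.
#' @export
points_at_frame <- function(trial, frame, geometry = NULL) {
  arr <- trial_arrays(trial)
  stopifnot(frame >= 1, frame <= length(arr$times))
  pts <- cbind(arr$X[frame, ], arr$Y[frame, ])
  keep <- stats::complete.cases(pts)
  pts <- pts[keep, , drop = FALSE]
  grp <- arr$group_of[keep]
  if (!is.null(geometry)) pts <- to_bisector_frame(pts, geometry)
  rownames(pts) <- arr$ids[keep]
  out <- lapply(split(seq_len(nrow(pts)), grp), function(i) pts[i, , drop = FALSE])
  if (!is.null(geometry) && !is.null(geometry$left_group) &&
      geometry$left_group %in% names(out)) {
    ord <- c(geometry$left_group, setdiff(names(out), geometry$left_group))
    out <- out[ord]
  }
  out
}
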