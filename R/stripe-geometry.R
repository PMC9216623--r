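#' Minimum-area bounding rectangle (rotating calipers)
#'
#' The minimum-area rectangle enclosing a point set has a side collinear with
#' an edge of the convex hull, so the optimum is found by rotating a box over
#' the hull edges. Orientation is reported along the long side, in
#' `[0, 180)` degrees; ties among equal-area orientations are broken by the
#' smallest angle.
#'
#' @param points n x 2 matrix (or data frame with `x`, `y`), meters.
#' @return An object of class `stripeflow_bbox`: `center` (x, y), `length_m`
#'   (long side), `width_m` (short side), `angle_deg` (long-side orientation
#'   from the x-axis), `area_m2`, and a `degenerate` flag (`TRUE` for exactly
#'   collinear input, which yields a zero-width box).
#' @export
min_bounding_box <- function(points) {
  pts <- unique(as_points_matrix(points))
  if (nrow(pts) < 2) {
    rlang::abort("degenerate stripe: fewer than 2 distinct points",
                 class = "stripeflow_error_degenerate_stripe")
  }
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)

  # collinearity: all hull cross products ~ 0 relative to the extent
  extent <- max(apply(pts, 2, function(v) diff(range(v))))
  collinear <- nh <= 2
  if (!collinear && nh >= 3) {
    v1 <- hp[2, ] - hp[1, ]
    crs <- abs((hp[, 1] - hp[1, 1]) * v1[2] - (hp[, 2] - hp[1, 2]) * v1[1])
    collinear <- all(crs <= 1e-12 * max(extent^2, 1))
  }
  if (collinear) {
    dvec <- pts[which.max(rowSums((pts - matrix(pts[1, ], nrow(pts), 2,
                                                byrow = TRUE))^2)), ] - pts[1, ]
    u <- dvec / sqrt(sum(dvec^2))
    proj <- pts %*% u
    ctr_along <- mean(range(proj))
    perp <- c(-u[2], u[1])
    ctr <- ctr_along * u + mean(range(pts %*% perp)) * perp
    return(structure(
      list(center = as.numeric(ctr), length_m = diff(range(proj)),
           width_m = 0, angle_deg = wrap_axial_deg(rad2deg(atan2(u[2], u[1]))),
           area_m2 = 0, degenerate = TRUE),
      class = "stripeflow_bbox"
    ))
  }

  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ev <- hp[j, ] - hp[i, ]
    el <- sqrt(sum(ev^2))
    if (el == 0) next
    e <- ev / el
    nvec <- c(-e[2], e[1])
    pe <- hp %*% e
    pn <- hp %*% nvec
    ext_e <- range(pe); ext_n <- range(pn)
    de <- diff(ext_e); dn <- diff(ext_n)
    area <- de * dn
    long_is_e <- de >= dn
    ang <- if (long_is_e) atan2(e[2], e[1]) else atan2(nvec[2], nvec[1])
    ang <- wrap_axial_deg(rad2deg(ang))
    cand <- list(
      center = as.numeric(mean(ext_e) * e + mean(ext_n) * nvec),
      length_m = max(de, dn), width_m = min(de, dn),
      angle_deg = ang, area_m2 = area, degenerate = FALSE
    )
    if (is.null(best) || area < best$area_m2 - 1e-12 ||
        (abs(area - best$area_m2) <= 1e-12 && ang < best$angle_deg)) {
      best <- cand
    }
  }
  structure(best, class = "stripeflow_bbox")
}

#' @export
print.stripeflow_bbox <- function(x, ...) {
  cat(sprintf("<stripeflow_bbox> %.3f x %.3f m @ %.2f deg%s\n",
              x$length_m, x$width_m, x$angle_deg,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Stripe constructor
#'
#' @param group Group label.
#' @param members Character vector of pedestrian ids.
#' @param formed_at Optional frame of the last internal change.
#' @return A `stripeflow_stripe`.
#' @export
as_stripe <- function(group, members, formed_at = NA_integer_) {
  structure(list(group = group, members = sort(as.character(members)),
                 formed_at = formed_at),
            class = "stripeflow_stripe")
}

#' Per-stripe geometry at one frame
#'
#' Bounding box, orientation relative to the bisector, width and aspect
#' ratio of one stripe's member positions at a frame, plus the eligibility
#' flag used by per-stripe orientation analysis: a stripe is eligible when it
#' is sufficiently elongated (aspect ratio below `aspect_cutoff`) and has at
#' least `min_size` members.
#'
#' @param trial A `stripeflow_trial`.
#' @param stripe A `stripeflow_stripe` (see [extract_stripes()], [as_stripe()]).
#' @param frame Frame index.
#' @param geometry A `stripeflow_geometry`.
#' @param aspect_cutoff Maximum width/length ratio (default 0.5).
#' @param min_size Minimum stripe size (default 3).
#' @return An object of class `stripeflow_stripe_geometry`: `stripe`, `box`,
#'   `gamma_stripe_deg` (long-side orientation counterclockwise from the
#'   bisector, mod 180), `width_m`, `aspect_ratio`, `eligible`.
#' @export
stripe_geometry_at <- function(trial, stripe, frame, geometry,
                               aspect_cutoff = 0.5, min_size = 3) {
  arr <- trial_arrays(trial)
  idx <- match(stripe$members, arr$ids)
  pts <- cbind(arr$X[frame, idx], arr$Y[frame, idx])
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  size <- length(stripe$members)

  box <- try(min_bounding_box(pts), silent = TRUE)
  if (inherits(box, "try-error")) {
    return(structure(
      list(stripe = stripe, box = NULL, gamma_stripe_deg = NA_real_,
           width_m = NA_real_, aspect_ratio = NA_real_, eligible = FALSE),
      class = "stripeflow_stripe_geometry"
    ))
  }
  aspect <- if (box$length_m > 0) box$width_m / box$length_m else NA_real_
  gam <- wrap_axial_deg(box$angle_deg - geometry$bisector_theta_deg)
  eligible <- isTRUE(aspect < aspect_cutoff) && size >= min_size && !box$degenerate
  structure(
    list(stripe = stripe, box = box, gamma_stripe_deg = gam,
         width_m = box$width_m, aspect_ratio = aspect, eligible = eligible),
    class = "stripeflow_stripe_geometry"
  )
}

#' Time-averaged per-stripe orientations
#'
#' For every stripe of the final partition, averages the bounding-box
#' orientation (counterclockwise from the bisector, mod-180 branch nearest
#' 90) over the frames in the window `[(T_i + T_f)/2, T_f]` where the stripe
#' is eligible; reports pooled medians for the left and right groups.
#'
#' @inheritParams select_analysis_time
#' @param aspect_cutoff,min_size Eligibility parameters (defaults 0.5 and 3).
#' @param max_frames Maximum frames evaluated per stripe (default 60).
#' @param stripes Optional list of stripes to analyze (default: extracted
#'   from the timeline at the final frame).
#' @return List with `per_stripe` (tibble: `stripe_id`, `group`, `side`,
#'   `size`, `gamma_mean_deg`, `width_mean_m`, `aspect_mean`,
#'   `n_frames_eligible`, `n_frames`), `pooled` (median `gamma_L` / `gamma_R`),
#'   and `eligibility_rate` (share of size-eligible stripe-frames passing the
#'   aspect cutoff).
#' @export
per_stripe_time_average <- function(trial, timeline, geometry,
                                    aspect_cutoff = 0.5, min_size = 3,
                                    max_frames = 60, stripes = NULL) {
  if (is.null(stripes)) stripes <- extract_stripes(timeline)
  t_mid <- (timeline$T_i + timeline$T_f) / 2
  frames <- which(timeline$frame_times >= t_mid - 1e-12 &
                    timeline$frame_times <= timeline$T_f + 1e-12)
  if (length(frames) > max_frames) {
    frames <- frames[unique(round(seq(1, length(frames), length.out = max_frames)))]
  }
  side_of <- stats::setNames(c("L", "R"),
                             c(geometry$left_group, geometry$right_group))
  rows <- list()
  n_pass <- 0L; n_sized <- 0L
  for (si in seq_along(stripes)) {
    s <- stripes[[si]]
    gams <- numeric(0); widths <- numeric(0); aspects <- numeric(0)
    nelig <- 0L
    for (fr in frames) {
      sg <- stripe_geometry_at(trial, s, fr, geometry,
                               aspect_cutoff = aspect_cutoff, min_size = min_size)
      if (length(s$members) >= min_size && !is.na(sg$aspect_ratio)) {
        n_sized <- n_sized + 1L
        if (sg$aspect_ratio < aspect_cutoff) n_pass <- n_pass + 1L
      }
      if (sg$eligible) {
        nelig <- nelig + 1L
        gams <- c(gams, sg$gamma_stripe_deg)
        widths <- c(widths, sg$width_m)
        aspects <- c(aspects, sg$aspect_ratio)
      }
    }
    rows[[si]] <- tibble::tibble(
      stripe_id = paste0(s$group, "#", si),
      group = s$group,
      side = unname(side_of[s$group]),
      size = length(s$members),
      gamma_mean_deg = if (nelig > 0) axial_mean_deg(gams) else NA_real_,
      width_mean_m = if (nelig > 0) mean(widths) else NA_real_,
      aspect_mean = if (nelig > 0) mean(aspects) else NA_real_,
      n_frames_eligible = nelig,
      n_frames = length(frames)
    )
  }
  per <- dplyr::bind_rows(rows)
  elig <- per[per$n_frames_eligible > 0, , drop = FALSE]
  pooled <- list(
    gamma_L_median = stats::median(elig$gamma_mean_deg[elig$side == "L"]),
    gamma_R_median = stats::median(elig$gamma_mean_deg[elig$side == "R"])
  )
  list(per_stripe = per, pooled = pooled,
       eligibility_rate = if (n_sized > 0) n_pass / n_sized else NA_real_)
}

#' Stripe width as a function of scaled time
#'
#' Tracks the bounding-box width of one stripe (membership frozen at the
#' final partition) across frames, with time scaled so that 0 corresponds to
#' `T_i` and 1 to `T_f`.
#'
#' @inheritParams stripe_geometry_at
#' @param timeline A `stripeflow_timeline` with `T_i < T_f`.
#' @param frames Frame indices to evaluate (`NULL` = all frames where every
#'   member is present, decimated to at most 200).
#' @return An object of class `stripeflow_width_series`: tibble `series`
#'   (`frame`, `time`, `scaled_time`, `width_m`) plus `min_scaled_time` and
#'   `min_width_m`.
#' @export
width_time_series <- function(trial, timeline, stripe, geometry = NULL,
                              frames = NULL) {
  if (is.na(timeline$T_i) || timeline$T_f == timeline$T_i) {
    rlang::abort("zero-length crossing window: T_i equals T_f (or is absent)",
                 class = "stripeflow_error_zero_window")
  }
  arr <- trial_arrays(trial)
  idx <- match(stripe$members, arr$ids)
  if (is.null(frames)) {
    present <- rowSums(is.na(arr$X[, idx, drop = FALSE])) == 0
    frames <- which(present)
    if (length(frames) > 200) {
      frames <- frames[unique(round(seq(1, length(frames), length.out = 200)))]
    }
  }
  width <- vapply(frames, function(fr) {
    pts <- cbind(arr$X[fr, idx], arr$Y[fr, idx])
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    bb <- try(min_bounding_box(pts), silent = TRUE)
    if (inherits(bb, "try-error")) NA_real_ else bb$width_m
  }, 0)
  st <- (arr$times[frames] - timeline$T_i) / (timeline$T_f - timeline$T_i)
  ser <- tibble::tibble(frame = frames, time = arr$times[frames],
                        scaled_time = st, width_m = width)
  jmin <- which.min(ser$width_m)
  structure(
    list(series = ser,
         min_scaled_time = ser$scaled_time[jmin],
         min_width_m = ser$width_m[jmin]),
    class = "stripeflow_width_series"
  )
}

#' Detect the squeezing of a stripe
#'
#' A stripe is squeezed when its width attains a global minimum strictly
#' inside the crossing interval (scaled time in (0, 1)) that is lower than
#' the widths at both ends of the interval by more than a tolerance.
#'
#' @param series A `stripeflow_width_series`.
#' @param tol_m Minimum depth of the dip, meters (default 0.01).
#' @return List with `squeezed` (logical), `min_scaled_time`, `min_width_m`,
#'   and the interpolated widths `width_at_0_m`, `width_at_1_m`.
#' @export
detect_squeeze <- function(series, tol_m = 0.01) {
  ser <- series$series
  ser <- ser[is.finite(ser$width_m), , drop = FALSE]
  if (nrow(ser) < 3 || min(ser$scaled_time) > 0 || max(ser$scaled_time) < 1) {
    return(list(squeezed = FALSE, min_scaled_time = series$min_scaled_time,
                min_width_m = series$min_width_m,
                width_at_0_m = NA_real_, width_at_1_m = NA_real_))
  }
  w0 <- stats::approx(ser$scaled_time, ser$width_m, xout = 0, rule = 2)$y
  w1 <- stats::approx(ser$scaled_time, ser$width_m, xout = 1, rule = 2)$y
  inside <- ser[ser$scaled_time > 0 & ser$scaled_time < 1, , drop = FALSE]
  jmin <- which.min(ser$width_m)
  gmin <- ser$width_m[jmin]; gloc <- ser$scaled_time[jmin]
  squeezed <- gloc > 0 && gloc < 1 && gmin < w0 - tol_m && gmin < w1 - tol_m
  list(squeezed = squeezed, min_scaled_time = gloc, min_width_m = gmin,
       width_at_0_m = w0, width_at_1_m = w1)
}

#' Stripe count and size curves across crossing angles
#'
#' Aggregates per-trial stripe counts and sizes into per-angle means with
#' standard errors and a monotonicity report.
#'
#' @param results Data frame with columns `alpha_deg`, `trial_id`, `group`,
#'   `n_stripes`, `mean_stripe_size`.
#' @return List with `by_angle` (tibble: per angle, mean and SEM of count and
#'   size, n) and `monotonic` (`count_decreasing`, `size_increasing` over the
#'   angle-ordered means).
#' @export
stripe_count_size_curves <- function(results) {
  stopifnot(all(c("alpha_deg", "n_stripes", "mean_stripe_size") %in% names(results)))
  by_angle <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(results), .data$alpha_deg),
    count_mean = mean(.data$n_stripes),
    count_sem = stats::sd(.data$n_stripes) / sqrt(dplyr::n()),
    size_mean = mean(.data$mean_stripe_size),
    size_sem = stats::sd(.data$mean_stripe_size) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  by_angle <- by_angle[base::order(by_angle$alpha_deg), ]
  list(
    by_angle = by_angle,
    monotonic = list(
      count_decreasing = all(diff(by_angle$count_mean) <= 0),
      size_increasing = all(diff(by_angle$size_mean) >= 0)
    )
  )
}
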