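# Wave coordinate X = x' sin(gamma) - y' cos(gamma): distance along the
# direction perpendicular to the stripes (gradient of the fitted sinusoid).
#' @keywords internal
wave_coord <- function(points, gamma_rad) {
  pts <- as_points_matrix(points)
  pts[, 1] * sin(gamma_rad) - pts[, 2] * cos(gamma_rad)
}

# For fixed (gamma, lambda) the score is linear in (cos psi, sin psi):
# sum w * sin(2 pi X / lambda + psi) = S cos(psi) + K sin(psi), so the
# optimum over psi is sqrt(S^2 + K^2) at psi* = atan2(K, S). `w` carries the
# crest/trough sign and the per-group normalization.
#' @keywords internal
score_SK <- function(X, w, lambda) {
  phase <- 2 * pi * X / lambda
  c(S = sum(w * sin(phase)), K = sum(w * cos(phase)))
}

#' Sinusoid matching score C
#'
#' Evaluates the stripe-pattern matching score for the 2D sinusoid
#' `f(x', y') = sin(2 pi X / lambda + psi)` with `X = x' sin(gamma) - y' cos(gamma)`
#' on pedestrian positions in the bisector frame. In whole-crowd mode the
#' score is `C = (sum_crest f - sum_trough f) / N` over both groups (ceiling
#' 2, attained when the crest group sits exactly on crests and the trough
#' group on troughs); in single-group mode it is the mean of `f` over that
#' group alone (ceiling 1).
#'
#' @param points_by_group Named list of n x 2 matrices in the bisector frame.
#'   In whole-crowd mode the first element is the crest group (by convention
#'   the left group) and the second the trough group.
#' @param gamma_deg,lambda_m,psi_deg Sinusoid parameters (degrees, meters,
#'   degrees).
#' @param mode `"whole_crowd"`, or the name (or index) of one group for the
#'   single-group score.
#' @return The score, a scalar in `[-2, 2]` (whole crowd) or `[-1, 1]`
#'   (single group).
#' @details The whole-crowd score is the sum of the two per-group means,
#'   `mean_crest(f) - mean_trough(f)`, which attains its ceiling of 2 when
#'   every crest-group pedestrian sits exactly on a crest and every
#'   trough-group pedestrian on a trough; for equal group sizes this is
#'   proportional to the signed sum over all pedestrians.
#' @export
sinusoid_score <- function(points_by_group, gamma_deg, lambda_m, psi_deg,
                           mode = "whole_crowd") {
  stopifnot(lambda_m > 0)
  if (is.matrix(points_by_group) || is.data.frame(points_by_group)) {
    points_by_group <- list(points_by_group)
    if (identical(mode, "whole_crowd")) mode <- 1L
  }
  g <- deg2rad(gamma_deg); psi <- deg2rad(psi_deg)
  fval <- function(pts) sin(2 * pi * wave_coord(pts, g) / lambda_m + psi)
  if (identical(mode, "whole_crowd")) {
    if (length(points_by_group) < 2) {
      rlang::abort("whole-crowd score needs two groups of points",
                   class = "stripeflow_error_empty_points")
    }
    fc <- fval(points_by_group[[1]])
    ft <- fval(points_by_group[[2]])
    if (length(fc) == 0 || length(ft) == 0) {
      rlang::abort("empty point set", class = "stripeflow_error_empty_points")
    }
    mean(fc) - mean(ft)
  } else {
    pts <- points_by_group[[mode]]
    f <- fval(pts)
    if (length(f) == 0) {
      rlang::abort("empty point set", class = "stripeflow_error_empty_points")
    }
    mean(f)
  }
}

# internal: points, score weights (sign x per-group normalization) for a mode
#' @keywords internal
score_inputs <- function(points_by_group, mode) {
  if (identical(mode, "whole_crowd")) {
    p1 <- as_points_matrix(points_by_group[[1]])
    p2 <- as_points_matrix(points_by_group[[2]])
    list(pts = rbind(p1, p2),
         w = c(rep(1 / nrow(p1), nrow(p1)), rep(-1 / nrow(p2), nrow(p2))),
         n = nrow(p1) + nrow(p2))
  } else {
    p <- as_points_matrix(points_by_group[[mode]])
    list(pts = p, w = rep(1 / nrow(p), nrow(p)), n = nrow(p))
  }
}

#' Fit the 2D stripe sinusoid by maximizing the matching score
#'
#' Estimates stripe orientation gamma, wavelength lambda and phase psi by
#' maximizing the matching score: a deterministic coarse grid over
#' (gamma, lambda) — with the optimal psi available in closed form at every
#' grid cell, since the score is linear in (cos psi, sin psi) — followed by
#' Nelder-Mead refinement from the best cell. The refined score can never
#' fall below the grid best. Parameters are canonicalized to
#' `gamma in [0, 180)`, `lambda > 0`, `psi in (-180, 180]`.
#'
#' @inheritParams sinusoid_score
#' @param lambda_bounds_m Length-2 search bounds for lambda, meters. `NULL`
#'   uses `[0.5, half the extent of the point cloud along the wave direction]`.
#' @param gamma_window_deg Half-width of the gamma search window around 90
#'   degrees (default 45).
#' @param gamma_step_deg Coarse grid step in gamma (default 2).
#' @param n_lambda Number of log-spaced lambda grid values (default 40).
#' @param refine Run local refinement (default `TRUE`).
#' @return An object of class `stripeflow_fit`: `gamma_deg`, `lambda_m`,
#'   `psi_deg`, `score`, `mode`, `n_points`, `lambda_bounds_m`.
#' @export
fit_sinusoid <- function(points_by_group, mode = "whole_crowd",
                         lambda_bounds_m = NULL, gamma_window_deg = 45,
                         gamma_step_deg = 2, n_lambda = 40, refine = TRUE) {
  si <- score_inputs(points_by_group, mode)
  if (si$n < 6) {
    rlang::abort("need at least 6 points to fit the sinusoid",
                 class = "stripeflow_error_too_few_points")
  }
  if (is.null(lambda_bounds_m)) {
    ext <- diff(range(wave_coord(si$pts, pi / 2)))
    lambda_bounds_m <- c(0.5, max(1, ext / 2))
  }
  stopifnot(length(lambda_bounds_m) == 2, lambda_bounds_m[1] > 0,
            lambda_bounds_m[1] < lambda_bounds_m[2])

  gammas <- seq(90 - gamma_window_deg, 90 + gamma_window_deg, by = gamma_step_deg)
  lambdas <- exp(seq(log(lambda_bounds_m[1]), log(lambda_bounds_m[2]),
                     length.out = n_lambda))

  obj <- function(gamma_deg, lambda_m) {
    X <- wave_coord(si$pts, deg2rad(gamma_deg))
    sk <- score_SK(X, si$w, lambda_m)
    sqrt(sk[["S"]]^2 + sk[["K"]]^2)
  }

  best <- list(score = -Inf, gamma = 90, lambda = mean(lambda_bounds_m))
  for (gm in gammas) {
    X <- wave_coord(si$pts, deg2rad(gm))
    sinX <- sin(outer(X, 2 * pi / lambdas))
    cosX <- cos(outer(X, 2 * pi / lambdas))
    S <- colSums(si$w * sinX)
    K <- colSums(si$w * cosX)
    sc <- sqrt(S^2 + K^2)
    j <- which.max(sc)
    if (sc[j] > best$score) {
      best <- list(score = sc[j], gamma = gm, lambda = lambdas[j])
    }
  }

  if (refine) {
    neg <- function(par) {
      lam <- exp(par[2])
      if (lam < lambda_bounds_m[1] || lam > lambda_bounds_m[2]) return(1e6)
      -obj(par[1], lam)
    }
    opt <- stats::optim(c(best$gamma, log(best$lambda)), neg,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 1000))
    if (-opt$value >= best$score) {
      best <- list(score = -opt$value, gamma = opt$par[1],
                   lambda = exp(opt$par[2]))
    }
  }

  X <- wave_coord(si$pts, deg2rad(best$gamma))
  sk <- score_SK(X, si$w, best$lambda)
  psi <- rad2deg(atan2(sk[["K"]], sk[["S"]]))

  # canonicalize gamma into [0, 180); f is invariant under
  # (gamma, psi) -> (gamma - 180, 180 - psi)
  gamma <- best$gamma
  while (gamma >= 180) { gamma <- gamma - 180; psi <- 180 - psi }
  while (gamma < 0) { gamma <- gamma + 180; psi <- 180 - psi }
  psi <- wrap_deg(psi)

  # collinear point sets share (up to rotation) a single wave coordinate, so
  # the wavelength and phase are unidentifiable
  ctr <- sweep(si$pts, 2, colMeans(si$pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1)) {
    rlang::warn("unidentifiable fit: points are collinear, so the wave direction carries no spread",
                class = "stripeflow_warning_unidentifiable")
  }

  score <- sinusoid_score(points_by_group, gamma, best$lambda, psi, mode = mode)
  structure(
    list(gamma_deg = gamma, lambda_m = best$lambda, psi_deg = psi,
         score = score, mode = if (identical(mode, "whole_crowd")) "whole_crowd" else
           paste0("group_", mode),
         n_points = si$n, lambda_bounds_m = lambda_bounds_m),
    class = "stripeflow_fit"
  )
}

#' @export
print.stripeflow_fit <- function(x, ...) {
  cat("<stripeflow_fit>", x$mode, "\n")
  cat(sprintf("  gamma = %.3f deg, lambda = %.4f m, psi = %.2f deg\n",
              x$gamma_deg, x$lambda_m, x$psi_deg))
  cat(sprintf("  score C = %.5f over %d points\n", x$score, x$n_points))
  invisible(x)
}

#' Choose the analysis time for pattern matching
#'
#' The sinusoid is fitted at a single frame; the periodicity of the stripes
#' is best maintained somewhere between the midpoint of the crossing and its
#' end, so the analysis frame T* maximizes the whole-crowd score over frames
#' in `[(T_i + T_f)/2, T_f]` (at most `max_frames` candidate frames, coarse
#' fits; earliest frame wins ties).
#'
#' @param trial A filtered `stripeflow_trial`.
#' @param timeline A `stripeflow_timeline` with at least one event (or manual
#'   bounds).
#' @param geometry A `stripeflow_geometry`.
#' @param max_frames Maximum number of candidate frames scored (default 50).
#' @param lambda_bounds_m Passed to the per-frame coarse fits.
#' @return List with `frame`, `time`, and the coarse `score` at T*.
#' @export
select_analysis_time <- function(trial, timeline, geometry, max_frames = 50,
                                 lambda_bounds_m = NULL) {
  if (is.na(timeline$T_i)) {
    rlang::abort("timeline has no events; T* undefined",
                 class = "stripeflow_error_no_events")
  }
  t_mid <- (timeline$T_i + timeline$T_f) / 2
  cand <- which(timeline$frame_times >= t_mid - 1e-12 &
                  timeline$frame_times <= timeline$T_f + 1e-12)
  if (length(cand) == 0) cand <- timeline$T_f_frame
  if (length(cand) > max_frames) {
    cand <- cand[unique(round(seq(1, length(cand), length.out = max_frames)))]
  }
  scores <- vapply(cand, function(fr) {
    pbg <- points_at_frame(trial, fr, geometry)
    if (length(pbg) < 2) return(-Inf)
    ft <- try(fit_sinusoid(pbg, mode = "whole_crowd",
                           lambda_bounds_m = lambda_bounds_m,
                           gamma_step_deg = 5, n_lambda = 15, refine = FALSE),
              silent = TRUE)
    if (inherits(ft, "try-error")) -Inf else ft$score
  }, 0)
  j <- which.max(scores)
  list(frame = cand[j], time = timeline$frame_times[cand[j]], score = scores[j])
}

#' Per-frame sinusoid fits over the crossing window
#'
#' Fits the stripe sinusoid at every frame (or a supplied subset) in the
#' window `[(T_i + T_f)/2, T_f]`, for the whole crowd, one group, or both
#' groups; per-frame failures are reported as gaps (`NA` rows).
#'
#' @inheritParams select_analysis_time
#' @param mode `"whole_crowd"`, `"left_group"`, `"right_group"`, or
#'   `"both_groups"` (left and right fitted independently per frame, with
#'   their differences).
#' @param frames Frame indices to fit; `NULL` = all frames in the window.
#' @param ... Passed to [fit_sinusoid()].
#' @return Tibble with one row per frame: `frame`, `time`, and per fitted
#'   group `gamma_deg`, `lambda_m`, `psi_deg`, `score` (suffixed `_L` / `_R`
#'   in `both_groups` mode, plus `d_gamma_deg = gamma_L - gamma_R` and
#'   `d_lambda_abs_m = |lambda_L - lambda_R|`).
#' @export
fit_time_series <- function(trial, timeline, geometry,
                            mode = c("whole_crowd", "left_group", "right_group",
                                     "both_groups"),
                            frames = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(frames)) {
    t_mid <- (timeline$T_i + timeline$T_f) / 2
    frames <- which(timeline$frame_times >= t_mid - 1e-12 &
                      timeline$frame_times <= timeline$T_f + 1e-12)
  }
  one <- function(fr, which_mode) {
    pbg <- points_at_frame(trial, fr, geometry)
    md <- switch(which_mode,
                 whole_crowd = "whole_crowd",
                 left_group = geometry$left_group,
                 right_group = geometry$right_group)
    ft <- try(fit_sinusoid(pbg, mode = md, ...), silent = TRUE)
    if (inherits(ft, "try-error")) {
      c(gamma_deg = NA_real_, lambda_m = NA_real_, psi_deg = NA_real_,
        score = NA_real_)
    } else {
      c(gamma_deg = ft$gamma_deg, lambda_m = ft$lambda_m, psi_deg = ft$psi_deg,
        score = ft$score)
    }
  }
  if (mode == "both_groups") {
    L <- t(vapply(frames, one, numeric(4), which_mode = "left_group"))
    R <- t(vapply(frames, one, numeric(4), which_mode = "right_group"))
    colnames(L) <- paste0(colnames(L), "_L")
    colnames(R) <- paste0(colnames(R), "_R")
    out <- tibble::as_tibble(cbind(L, R))
    out$d_gamma_deg <- out$gamma_deg_L - out$gamma_deg_R
    out$d_lambda_abs_m <- abs(out$lambda_m_L - out$lambda_m_R)
  } else {
    out <- tibble::as_tibble(t(vapply(frames, one, numeric(4), which_mode = mode)))
  }
  out <- cbind(tibble::tibble(frame = frames,
                              time = timeline$frame_times[frames]), out)
  tibble::as_tibble(out)
}

#' Time averages of a per-frame fit series
#'
#' Orientation averages unwrap gamma to the branch nearest 90 degrees (mod
#' 180) before averaging; frames where the fit failed are excluded and
#' counted.
#'
#' @param series Output of [fit_time_series()].
#' @return List with `gamma_mean_deg`, `lambda_mean_m`, `n_used`, `n_failed`;
#'   in `both_groups` mode per-group means plus `gamma_diff_mean_deg`
#'   (`<gamma_L - gamma_R>`) and `lambda_absdiff_mean_m` (`<|lambda_L -
#'   lambda_R|>`).
#' @export
time_average <- function(series) {
  if ("gamma_deg_L" %in% names(series)) {
    ok <- stats::complete.cases(series[, c("gamma_deg_L", "gamma_deg_R")])
    list(
      gamma_mean_deg_L = axial_mean_deg(series$gamma_deg_L[ok]),
      gamma_mean_deg_R = axial_mean_deg(series$gamma_deg_R[ok]),
      lambda_mean_m_L = mean(series$lambda_m_L[ok]),
      lambda_mean_m_R = mean(series$lambda_m_R[ok]),
      gamma_diff_mean_deg = mean(series$d_gamma_deg[ok]),
      lambda_absdiff_mean_m = mean(series$d_lambda_abs_m[ok]),
      n_used = sum(ok), n_failed = sum(!ok)
    )
  } else {
    ok <- !is.na(series$gamma_deg)
    list(
      gamma_mean_deg = axial_mean_deg(series$gamma_deg[ok]),
      lambda_mean_m = mean(series$lambda_m[ok]),
      n_used = sum(ok), n_failed = sum(!ok)
    )
  }
}

#' Residual errors of a sinusoid fit
#'
#' Signed distance of every pedestrian from the nearest crest (crest group)
#' or trough (trough group) of the fitted sinusoid, measured along the wave
#' direction and wrapped into `(-lambda/2, lambda/2]`. For a perfect stripe
#' pattern every distance is 0; for a pattern matched up to stripe
#' assignment, all points lie within a quarter wavelength.
#'
#' @inheritParams sinusoid_score
#' @param fit A `stripeflow_fit`.
#' @return An object of class `stripeflow_residuals`: `distances` (tibble
#'   with `group`, `role`, `distance_m`), `frac_within_quarter`, and
#'   `gaussian_sigma_lambda` (sigma of a Gaussian fitted to distances in
#'   units of lambda; `NA` with fewer than 30 points).
#' @export
residual_errors <- function(points_by_group, fit) {
  stopifnot(fit$lambda_m > 0)
  lam <- fit$lambda_m
  g <- deg2rad(fit$gamma_deg); psi <- deg2rad(fit$psi_deg)
  roles <- if (fit$mode == "whole_crowd") {
    stats::setNames(c("crest", "trough"), names(points_by_group)[1:2])
  } else {
    nm <- sub("^group_", "", fit$mode)
    stats::setNames("crest", nm)
  }
  rows <- list()
  for (nm in names(roles)) {
    X <- wave_coord(points_by_group[[nm]], g)
    u <- 2 * pi * X / lam + psi
    target <- if (roles[[nm]] == "crest") pi / 2 else -pi / 2
    w <- (u - target) %% (2 * pi)
    w[w > pi] <- w[w > pi] - 2 * pi   # wrap into (-pi, pi]
    rows[[nm]] <- tibble::tibble(group = nm, role = roles[[nm]],
                                 distance_m = w * lam / (2 * pi))
  }
  d <- dplyr::bind_rows(rows)
  sigma <- NA_real_
  if (nrow(d) >= 30) {
    gf <- try(fit_gaussian_pdf(d$distance_m / lam), silent = TRUE)
    if (!inherits(gf, "try-error")) sigma <- gf$sigma
  }
  structure(
    list(distances = d,
         frac_within_quarter = mean(abs(d$distance_m) <= lam / 4),
         gaussian_sigma_lambda = sigma),
    class = "stripeflow_residuals"
  )
}

#' Fit a Gaussian curve to a sample's histogram density
#'
#' Least-squares fit of `a * exp(-b (x - c)^2)` to the normalized histogram
#' of `samples`, as used for angular-deviation and residual-error
#' distributions.
#'
#' @param samples Numeric vector (at least 30 values).
#' @param breaks Histogram breaks specification (default `"FD"`).
#' @return List with `a`, `b`, `c`, `sigma = 1/sqrt(2 b)`, and `mean = c`.
#' @export
fit_gaussian_pdf <- function(samples, breaks = "FD") {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30) {
    rlang::abort("need at least 30 samples for the Gaussian fit",
                 class = "stripeflow_error_too_few_points")
  }
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$density)
  s0 <- max(stats::sd(samples), 1e-6)
  start <- list(a = max(h$density), b = 1 / (2 * s0^2), c = mean(samples))
  ft <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * (x - c)^2), data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  cf <- if (!is.null(ft)) {
    stats::coef(ft)
  } else {
    # Levenberg-Marquardt can hit a singular Jacobian on sparse or highly
    # symmetric histograms; fall back to derivative-free least squares
    # (b is unconstrained, as in nls; b < 0 marks a non-bell optimum)
    sse <- function(par) {
      v <- par[1] * exp(-par[2] * (df$x - par[3])^2)
      if (any(!is.finite(v))) return(1e300)
      sum((df$y - v)^2)
    }
    starts <- list(unlist(start),
                   c(start$a, -start$b, start$c))
    opts <- lapply(starts, function(s) {
      stats::optim(s, sse, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14))
    })
    opt <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]
    if (!is.finite(opt$value)) {
      rlang::abort("Gaussian fit did not converge",
                   class = "stripeflow_error_gaussian_fit",
                   last_iterate = start)
    }
    c(a = opt$par[[1]], b = opt$par[[2]], c = opt$par[[3]])
  }
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       sigma = unname(1 / sqrt(2 * abs(cf["b"]))), mean = unname(cf["c"]))
}

#' Heuristic wavelength from crossing width and stripe count
#'
#' With `n` stripes (both groups pooled, alternating) packed into a crossing
#' region of width `W` along the wave direction, consecutive same-group
#' stripes are about `2 W / n` apart. Used to set the lambda search bounds
#' and to flag over- or under-fitted wavelengths.
#'
#' @param crossing_width_m Width of the crossing region, meters.
#' @param n_subgroups_total Total number of stripes over both groups.
#' @return Approximate wavelength, meters.
#' @export
heuristic_wavelength <- function(crossing_width_m, n_subgroups_total) {
  stopifnot(crossing_width_m > 0, n_subgroups_total >= 1)
  2 * crossing_width_m / n_subgroups_total
}
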