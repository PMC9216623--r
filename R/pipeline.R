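#' Pipeline configuration
#'
#' Bundles the defaults of every analysis stage: simulation, gait filtering,
#' crossing-geometry estimation, sinusoid fitting, per-stripe geometry, and
#' squeeze detection.
#'
#' @param sim A [trial_config()] used when the pipeline simulates its input.
#' @param filter_cutoff_hz,filter_order Butterworth settings.
#' @param geometry_window_s Barycenter averaging window, seconds.
#' @param speed_floor_mps Speed floor for angular deviations.
#' @param gamma_window_deg,gamma_step_deg,n_lambda Fit grid settings.
#' @param lambda_bounds_m Fixed lambda search bounds; `NULL` derives them
#'   from the heuristic wavelength (0.5x to 2x) when stripe counts are
#'   available.
#' @param aspect_cutoff,min_size Stripe eligibility parameters.
#' @param analysis_max_frames Candidate frames for the analysis-time search.
#' @param series_max_frames Frames in the per-group fit time series.
#' @param squeeze_tol_m Squeeze detection tolerance, meters.
#' @param do_series,do_stripes,do_squeeze Toggle the heavier report sections.
#' @return A list of class `stripeflow_pipeline_config`.
#' @export
pipeline_config <- function(sim = trial_config(),
                            filter_cutoff_hz = 0.5, filter_order = 4,
                            geometry_window_s = 0.5, speed_floor_mps = 0.2,
                            gamma_window_deg = 45, gamma_step_deg = 2,
                            n_lambda = 40, lambda_bounds_m = NULL,
                            aspect_cutoff = 0.5, min_size = 3,
                            analysis_max_frames = 50, series_max_frames = 40,
                            squeeze_tol_m = 0.01,
                            do_series = TRUE, do_stripes = TRUE,
                            do_squeeze = TRUE) {
  structure(as.list(environment()), class = "stripeflow_pipeline_config")
}

#' Run the full stripe-analysis pipeline on one trial
#'
#' Stages, in order: simulate (optional), low-pass filter, crossing geometry,
#' edge-cut detection, crossing summary, analysis-time selection, whole-crowd
#' and per-group sinusoid fits at T*, per-group fit time series and averages,
#' residual errors, per-stripe orientation averages, and squeeze flags.
#' Deterministic given (input, config, seed).
#'
#' @param config A [pipeline_config()].
#' @param trial A `stripeflow_trial`, or `NULL` to simulate from `config$sim`.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `stripeflow_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), trial = NULL,
                         verbose = FALSE) {
  log_ <- function(...) if (verbose) message("[stripeflow] ", sprintf(...))
  truth <- NULL
  if (is.null(trial)) {
    log_("simulating trial (alpha = %g deg, seed = %d)",
         config$sim$crossing_angle_deg, config$sim$seed)
    sim <- generate_crossing_trial(config$sim)
    trial <- sim$trial
    truth <- sim$truth
  }

  log_("filtering (cutoff %.3g Hz, order %d)", config$filter_cutoff_hz,
       config$filter_order)
  filtered <- lowpass_filter_trial(trial, config$filter_cutoff_hz,
                                   config$filter_order)

  geometry <- estimate_crossing_geometry(filtered,
                                         head_window_s = config$geometry_window_s,
                                         tail_window_s = config$geometry_window_s)
  log_("observed alpha = %.2f deg, theta_B = %.2f deg", geometry$alpha_deg,
       geometry$bisector_theta_deg)

  timeline <- detect_edge_cuts(filtered)
  summary <- crossing_summary(timeline)
  log_("edge cuts: %d events", nrow(timeline$events))

  report <- list(
    config_hash = rlang::hash(unclass(config)),
    expected_angle_deg = trial$expected_angle_deg,
    alpha_deg = geometry$alpha_deg,
    bisector_theta_deg = geometry$bisector_theta_deg,
    left_group = geometry$left_group,
    right_group = geometry$right_group,
    T_i = summary$T_i, T_f = summary$T_f,
    crossing_time = summary$crossing_time,
    n_stripes = as.list(summary$n_stripes),
    stripe_sizes = summary$stripe_sizes,
    truth = truth
  )

  if (is.na(summary$T_i)) {
    log_("no crossing detected; fits skipped")
    report$status <- "no crossing detected"
    class(report) <- "stripeflow_report"
    return(report)
  }
  report$status <- "ok"

  tstar <- select_analysis_time(filtered, timeline, geometry,
                                max_frames = config$analysis_max_frames)
  report$analysis_frame <- tstar$frame
  report$analysis_time <- tstar$time
  pbg <- points_at_frame(filtered, tstar$frame, geometry)

  lambda_bounds <- config$lambda_bounds_m
  if (is.null(lambda_bounds)) {
    n_sub <- sum(summary$n_stripes)
    W <- diff(range(vapply(pbg, function(m) range(m[, 1]),
                           numeric(2))))
    lam0 <- heuristic_wavelength(W, n_sub)
    lambda_bounds <- c(0.5 * lam0, 2 * lam0)
    report$heuristic_lambda_m <- lam0
    report$crossing_width_m <- W
  }

  fit_args <- list(lambda_bounds_m = lambda_bounds,
                   gamma_window_deg = config$gamma_window_deg,
                   gamma_step_deg = config$gamma_step_deg,
                   n_lambda = config$n_lambda)
  fit_one <- function(mode) {
    ft <- try(do.call(fit_sinusoid, c(list(pbg, mode = mode), fit_args)),
              silent = TRUE)
    if (inherits(ft, "try-error")) NULL else ft
  }
  whole <- fit_one("whole_crowd")
  fitL <- fit_one(geometry$left_group)
  fitR <- fit_one(geometry$right_group)
  as_fit_entry <- function(ft) {
    if (is.null(ft)) return(NULL)
    list(gamma_deg = ft$gamma_deg, lambda_m = ft$lambda_m,
         psi_deg = ft$psi_deg, score = ft$score, n_points = ft$n_points)
  }
  report$fit_whole <- as_fit_entry(whole)
  report$fit_left <- as_fit_entry(fitL)
  report$fit_right <- as_fit_entry(fitR)
  if (!is.null(whole)) {
    res <- residual_errors(pbg, whole)
    report$residuals <- list(
      frac_within_quarter = res$frac_within_quarter,
      gaussian_sigma_lambda = res$gaussian_sigma_lambda
    )
  }

  if (config$do_series) {
    log_("per-group fit time series")
    t_mid <- (timeline$T_i + timeline$T_f) / 2
    frames <- which(timeline$frame_times >= t_mid - 1e-12 &
                      timeline$frame_times <= timeline$T_f + 1e-12)
    if (length(frames) > config$series_max_frames) {
      frames <- frames[unique(round(seq(1, length(frames),
                                        length.out = config$series_max_frames)))]
    }
    series <- fit_time_series(filtered, timeline, geometry,
                              mode = "both_groups", frames = frames,
                              lambda_bounds_m = lambda_bounds,
                              gamma_window_deg = config$gamma_window_deg,
                              gamma_step_deg = config$gamma_step_deg,
                              n_lambda = config$n_lambda)
    report$series_averages <- time_average(series)
  }

  if (config$do_stripes) {
    log_("per-stripe geometry")
    ps <- per_stripe_time_average(filtered, timeline, geometry,
                                  aspect_cutoff = config$aspect_cutoff,
                                  min_size = config$min_size)
    report$per_stripe <- list(
      gamma_L_median = ps$pooled$gamma_L_median,
      gamma_R_median = ps$pooled$gamma_R_median,
      eligibility_rate = ps$eligibility_rate,
      table = as.data.frame(ps$per_stripe)
    )
  }

  if (config$do_squeeze) {
    stripes <- extract_stripes(timeline)
    flags <- list()
    for (si in seq_along(stripes)) {
      s <- stripes[[si]]
      if (length(s$members) < config$min_size) next
      ws <- try(width_time_series(filtered, timeline, s,
                                  frames = NULL), silent = TRUE)
      if (inherits(ws, "try-error")) next
      sq <- detect_squeeze(ws, tol_m = config$squeeze_tol_m)
      flags[[paste0(s$group, "#", si)]] <- list(
        squeezed = sq$squeezed, min_scaled_time = sq$min_scaled_time)
    }
    report$squeeze <- flags
  }

  class(report) <- "stripeflow_report"
  report
}

#' @export
print.stripeflow_report <- function(x, ...) {
  cat("<stripeflow_report>", x$status, "\n")
  cat(sprintf("  alpha = %.2f deg", x$alpha_deg))
  if (!is.na(x$T_i)) {
    cat(sprintf("; T_i = %.2f s, T_f = %.2f s", x$T_i, x$T_f))
  }
  cat("\n")
  if (!is.null(x$fit_whole)) {
    cat(sprintf("  whole-crowd fit: gamma = %.2f deg, lambda = %.3f m, C = %.3f\n",
                x$fit_whole$gamma_deg, x$fit_whole$lambda_m, x$fit_whole$score))
  }
  invisible(x)
}

#' Write a report to JSON
#'
#' Deterministic: re-running the pipeline on the same input and config gives
#' a byte-identical file.
#'
#' @param report A `stripeflow_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null", dataframe = "columns")
  invisible(path)
}

#' Summarize reports by crossing angle
#'
#' Per configured angle: medians and quartiles of the whole-crowd and
#' per-group orientations and wavelengths, score ratios, stripe counts and
#' crossing times, plus medians of the observed angle.
#'
#' @param reports List of `stripeflow_report` objects.
#' @return Tibble with one row per configured crossing angle.
#' @export
summarize_by_angle <- function(reports) {
  pull <- function(r, path, default = NA_real_) {
    v <- r
    for (k in path) {
      if (is.null(v[[k]])) return(default)
      v <- v[[k]]
    }
    if (is.null(v)) default else v
  }
  rows <- lapply(reports, function(r) {
    tibble::tibble(
      angle_config = pull(r, "expected_angle_deg"),
      alpha_obs = pull(r, "alpha_deg"),
      gamma_bar = pull(r, c("fit_whole", "gamma_deg")),
      gamma_L = pull(r, c("fit_left", "gamma_deg")),
      gamma_R = pull(r, c("fit_right", "gamma_deg")),
      lambda_bar = pull(r, c("fit_whole", "lambda_m")),
      lambda_L = pull(r, c("fit_left", "lambda_m")),
      lambda_R = pull(r, c("fit_right", "lambda_m")),
      score_ratio = pull(r, c("fit_whole", "score")) / 2,
      score_L = pull(r, c("fit_left", "score")),
      score_R = pull(r, c("fit_right", "score")),
      d_lambda_series = pull(r, c("series_averages", "lambda_absdiff_mean_m")),
      n_stripes_total = sum(unlist(r$n_stripes)),
      crossing_time = pull(r, "crossing_time")
    )
  })
  d <- dplyr::bind_rows(rows)
  d$dev_lambda_L <- abs(d$lambda_bar - d$lambda_L)
  d$dev_lambda_R <- abs(d$lambda_bar - d$lambda_R)
  q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE)
  dplyr::summarise(
    dplyr::group_by(d, .data$angle_config),
    alpha_obs_median = stats::median(.data$alpha_obs, na.rm = TRUE),
    gamma_bar_median = stats::median(.data$gamma_bar, na.rm = TRUE),
    gamma_bar_q1 = q(.data$gamma_bar, 0.25),
    gamma_bar_q3 = q(.data$gamma_bar, 0.75),
    gamma_L_median = stats::median(.data$gamma_L, na.rm = TRUE),
    gamma_R_median = stats::median(.data$gamma_R, na.rm = TRUE),
    lambda_bar_median = stats::median(.data$lambda_bar, na.rm = TRUE),
    lambda_L_median = stats::median(.data$lambda_L, na.rm = TRUE),
    lambda_R_median = stats::median(.data$lambda_R, na.rm = TRUE),
    dev_lambda_L_median = stats::median(.data$dev_lambda_L, na.rm = TRUE),
    dev_lambda_R_median = stats::median(.data$dev_lambda_R, na.rm = TRUE),
    d_lambda_series_median = stats::median(.data$d_lambda_series, na.rm = TRUE),
    score_ratio_median = stats::median(.data$score_ratio, na.rm = TRUE),
    score_L_median = stats::median(.data$score_L, na.rm = TRUE),
    score_R_median = stats::median(.data$score_R, na.rm = TRUE),
    n_stripes_median = stats::median(.data$n_stripes_total, na.rm = TRUE),
    crossing_time_median = stats::median(.data$crossing_time, na.rm = TRUE),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}
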