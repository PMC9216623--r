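#' Configuration for a synthetic crossing-flow trial
#'
#' Defines the study conditions a generated trial emulates: two groups of
#' walkers start in square boxes facing each other at a crossing angle, each
#' organized into parallel rows (the ground-truth stripes) perpendicular to the
#' bisector of the crossing angle, and walk straight across so that the rows of
#' the two groups interleave during the crossing.
#'
#' Defaults mirror a small-group motion-capture crossing study: 19 walkers per
#' group sampled at 120 Hz, preferred speed about 1.3 m/s, and stripe spacing
#' of 2 m (consecutive same-group stripe centers), which interleaves opposing
#' stripes 1 m apart.
#'
#' @param crossing_angle_deg Target crossing angle alpha in `[0, 180]` degrees.
#' @param n_per_group Number of walkers per group.
#' @param n_stripes_per_group Number of ground-truth stripes (rows) per group.
#' @param stripe_spacing_m Ground-truth wavelength lambda: distance between
#'   consecutive same-group stripe centers, meters.
#' @param walk_speed_mps Mean walking speed, m/s.
#' @param speed_sd Between-pedestrian SD of walking speed, m/s (drawn once per
#'   pedestrian; speeds are constant within a trial).
#' @param start_separation_m Distance from each group's start box to the
#'   crossing point, times two (the groups meet after walking half of it).
#' @param box_side_m Side of the start box; sets the lateral extent of a row.
#' @param frame_rate_hz Sampling rate, Hz.
#' @param duration_s Trial duration, seconds. `NULL` picks a duration long
#'   enough for the groups to fully cross and separate.
#' @param gait_amplitude_m Amplitude of the sinusoidal head sway perpendicular
#'   to heading, meters.
#' @param gait_freq_hz Frequency of the head sway, Hz.
#' @param position_noise_sd_m SD of additive iid Gaussian positional noise per
#'   coordinate per frame, meters.
#' @param stripe_depth_m Structural depth of a stripe along the travel axis,
#'   meters. The default 0 places same-stripe walkers at exactly the same
#'   phase along the bisector.
#' @param squeeze_factor Fractional compression of `stripe_depth_m` at
#'   mid-crossing (0 = rigid stripes, 0.6 = depth shrinks to 40% at the
#'   closest encounter), emulating the transient squeezing of stripes.
#' @param lateral_drift_m Amplitude of slow within-stripe lateral drift,
#'   meters (0 disables it).
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return A list of class `stripeflow_config`.
#' @export
trial_config <- function(crossing_angle_deg = 90,
                         n_per_group = 19,
                         n_stripes_per_group = 5,
                         stripe_spacing_m = 2,
                         walk_speed_mps = 1.3,
                         speed_sd = 0.05,
                         start_separation_m = 12,
                         box_side_m = 2.5,
                         frame_rate_hz = 120,
                         duration_s = NULL,
                         gait_amplitude_m = 0.03,
                         gait_freq_hz = 0.9,
                         position_noise_sd_m = 0,
                         stripe_depth_m = 0,
                         squeeze_factor = 0,
                         lateral_drift_m = 0,
                         seed = 1L) {
  stopifnot(
    crossing_angle_deg >= 0, crossing_angle_deg <= 180,
    n_per_group >= 1, n_stripes_per_group >= 1,
    stripe_spacing_m > 0, frame_rate_hz > 0,
    walk_speed_mps > 0, speed_sd >= 0,
    start_separation_m > 0, box_side_m > 0,
    gait_amplitude_m >= 0, position_noise_sd_m >= 0,
    stripe_depth_m >= 0, squeeze_factor >= 0, squeeze_factor <= 1
  )
  cfg <- list(
    crossing_angle_deg = crossing_angle_deg,
    n_per_group = as.integer(n_per_group),
    n_stripes_per_group = as.integer(n_stripes_per_group),
    stripe_spacing_m = stripe_spacing_m,
    walk_speed_mps = walk_speed_mps,
    speed_sd = speed_sd,
    start_separation_m = start_separation_m,
    box_side_m = box_side_m,
    frame_rate_hz = frame_rate_hz,
    duration_s = duration_s,
    gait_amplitude_m = gait_amplitude_m,
    gait_freq_hz = gait_freq_hz,
    position_noise_sd_m = position_noise_sd_m,
    stripe_depth_m = stripe_depth_m,
    squeeze_factor = squeeze_factor,
    lateral_drift_m = lateral_drift_m,
    seed = as.integer(seed)
  )
  class(cfg) <- "stripeflow_config"
  cfg
}

# duration long enough that the groups have fully crossed and separated
#' @keywords internal
auto_duration <- function(cfg) {
  alpha <- deg2rad(cfg$crossing_angle_deg)
  v <- cfg$walk_speed_mps
  t_meet <- (cfg$start_separation_m / 2) / v
  s <- sin(alpha / 2)
  if (s < 1e-6) return(t_meet * 2 + 5)
  clearance <- (2 * cfg$box_side_m + 2) / (2 * v * s)
  t_meet + clearance
}

#' Generate a synthetic crossing-flow trial with known ground truth
#'
#' Two groups start in boxes facing each other at the configured crossing
#' angle, each arranged into `n_stripes_per_group` rows perpendicular to the
#' bisector; consecutive same-group rows are `stripe_spacing_m` apart along the
#' bisector and the two groups' rows interleave at half that spacing. Every
#' walker moves in a straight line at an individually drawn constant speed,
#' with an additive sinusoidal gait sway perpendicular to heading and optional
#' iid Gaussian positional noise. Same-stripe walkers share the same phase
#' along the bisector axis (exactly so when `stripe_depth_m = 0` and noise is
#' off).
#'
#' @param config A [trial_config()].
#' @return List with elements `trial` (a [trial()]) and `truth`, the ground
#'   truth: `true_alpha_deg`, `true_gamma_deg` (construction value 90),
#'   `true_lambda_m`, and `stripe_membership` (named map pedestrian id ->
#'   stripe label).
#' @export
generate_crossing_trial <- function(config = trial_config()) {
  cfg <- config
  if (cfg$crossing_angle_deg == 0 && cfg$n_stripes_per_group > 1) {
    rlang::abort(
      paste("no-crossing configuration: at crossing angle 0 the groups never",
            "cross, so stripe interleaving is undefined"),
      class = "stripeflow_error_no_crossing"
    )
  }
  withr::with_seed(cfg$seed, generate_crossing_trial_impl(cfg))
}

#' @keywords internal
generate_crossing_trial_impl <- function(cfg) {
  alpha <- deg2rad(cfg$crossing_angle_deg)
  half <- alpha / 2
  # bisector along +x; group g1 heads to the left of it, g2 to the right
  u <- list(g1 = c(cos(half), sin(half)), g2 = c(cos(half), -sin(half)))

  duration <- if (is.null(cfg$duration_s)) auto_duration(cfg) else cfg$duration_s
  times <- seq(0, duration, by = 1 / cfg$frame_rate_hz)
  nt <- length(times)
  t_meet <- (cfg$start_separation_m / 2) / cfg$walk_speed_mps

  K <- cfg$n_stripes_per_group
  n <- cfg$n_per_group
  # distribute members over rows as evenly as possible
  row_sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  lambda <- cfg$stripe_spacing_m

  rows <- list()
  membership <- character(0)
  for (g in c("g1", "g2")) {
    ug <- u[[g]]
    ng <- c(-ug[2], ug[1])  # unit normal to heading (gait axis)
    start_center <- -(cfg$start_separation_m / 2) * ug
    interleave <- if (g == "g2") lambda / 2 else 0
    pid <- 0L
    for (k in seq_len(K)) {
      m <- row_sizes[k]
      x_off <- (k - 1 - (K - 1) / 2) * lambda + interleave
      w_spacing <- cfg$box_side_m / max(m - 1, 1)
      for (j in seq_len(m)) {
        pid <- pid + 1L
        id <- sprintf("%s_%02d", g, pid)
        y_off <- (j - 1 - (m - 1) / 2) * w_spacing
        depth <- if (cfg$stripe_depth_m > 0) {
          (cfg$stripe_depth_m / 2) * (-1)^j
        } else 0
        speed <- max(0.3, stats::rnorm(1, cfg$walk_speed_mps, cfg$speed_sd))
        gait_phase <- stats::runif(1, 0, 2 * pi)
        drift_phase <- stats::runif(1, 0, 2 * pi)

        # squeeze schedule: depth offsets contract mid-crossing, between the
        # first contact of the groups and their full overlap at t_meet
        sched <- if (cfg$squeeze_factor > 0 && cfg$stripe_depth_m > 0) {
          s_half <- sin(half)
          t_first <- if (s_half > 1e-6) {
            t_meet - cfg$box_side_m / (2 * cfg$walk_speed_mps * s_half)
          } else t_meet / 2
          t_center <- (t_first + t_meet) / 2
          tau <- max((t_meet - t_first) / 3, 0.2)
          1 - cfg$squeeze_factor * exp(-((times - t_center) / tau)^2)
        } else rep(1, nt)

        base <- matrix(start_center, nt, 2, byrow = TRUE) +
          outer(speed * times, ug) +
          # constant offsets in the bisector frame: bisector = +x axis here
          cbind(x_off + depth * sched, rep(y_off, nt))
        if (cfg$gait_amplitude_m > 0) {
          sway <- cfg$gait_amplitude_m *
            sin(2 * pi * cfg$gait_freq_hz * times + gait_phase)
          base <- base + outer(sway, ng)
        }
        if (cfg$lateral_drift_m > 0) {
          drift <- cfg$lateral_drift_m * sin(2 * pi * 0.1 * times + drift_phase)
          base <- base + cbind(rep(0, nt), drift)
        }
        if (cfg$position_noise_sd_m > 0) {
          base <- base + matrix(stats::rnorm(2 * nt, 0, cfg$position_noise_sd_m), nt, 2)
        }
        rows[[id]] <- tibble::tibble(
          time = times, id = id, group = g, x = base[, 1], y = base[, 2]
        )
        membership[id] <- sprintf("%s_s%d", g, k)
      }
    }
  }

  dat <- do.call(rbind, rows)
  tr <- trial(dat, frame_rate_hz = cfg$frame_rate_hz,
              expected_angle_deg = cfg$crossing_angle_deg)
  truth <- list(
    true_alpha_deg = cfg$crossing_angle_deg,
    true_gamma_deg = 90,
    true_lambda_m = lambda,
    stripe_membership = as.list(membership)
  )
  list(trial = tr, truth = truth)
}

#' Ideal crest/trough point sets for a 2D sinusoid
#'
#' Places one group of points exactly on the crest lines and a second group
#' exactly on the trough lines of the stripe sinusoid
#' `f(x', y') = sin(2*pi*X/lambda + psi)` with wave coordinate
#' `X = x' sin(gamma) - y' cos(gamma)`, jittered only along the line direction
#' (zero phase error). These are the point sets on which the whole-crowd
#' matching score attains its ceiling of 2 and the single-group score its
#' ceiling of 1.
#'
#' @param gamma_deg Stripe orientation, degrees counterclockwise from the x' axis.
#' @param lambda_m Wavelength, meters.
#' @param psi_deg Phase offset, degrees.
#' @param n_per_group Points per group.
#' @param extent_m Spatial extent over which lines and points are spread, meters.
#' @param seed Integer seed for the along-line jitter.
#' @return Named list of two n x 2 matrices, `crest` and `trough`, in the
#'   bisector frame.
#' @export
generate_ideal_stripe_points <- function(gamma_deg = 90, lambda_m = 2,
                                         psi_deg = 0, n_per_group = 10,
                                         extent_m = 10, seed = 1L) {
  stopifnot(lambda_m > 0, n_per_group >= 1, extent_m > 0)
  withr::with_seed(seed, {
    g <- deg2rad(gamma_deg)
    psi <- deg2rad(psi_deg)
    wave <- c(sin(g), -cos(g))   # direction of increasing X
    line <- c(cos(g), sin(g))    # along-stripe direction
    n_lines <- max(2L, min(n_per_group, floor(extent_m / lambda_m)))
    X_crest0 <- ((pi / 2 - psi) %% (2 * pi)) * lambda_m / (2 * pi)
    X_trough0 <- ((-pi / 2 - psi) %% (2 * pi)) * lambda_m / (2 * pi)
    place <- function(X0) {
      k <- (seq_len(n_per_group) - 1) %% n_lines
      Xv <- X0 + k * lambda_m
      uv <- stats::runif(n_per_group, -extent_m / 2, extent_m / 2)
      outer(Xv, wave) + outer(uv, line)
    }
    list(crest = place(X_crest0), trough = place(X_trough0))
  })
}

#' Degenerate control trials
#'
#' Two extreme crossing outcomes with no stripe formation in the usual sense:
#' `no_penetration` shifts one group along the bisector so the groups pass
#' side by side and never interleave (zero edge cuts expected);
#' `full_isolation` puts every walker in a stripe of their own, interleaved
#' with the opposing group, so every intra-group edge is cut and all residual
#' stripes are singletons.
#'
#' @param mode `"no_penetration"` or `"full_isolation"`.
#' @param config A [trial_config()].
#' @return A `stripeflow_trial`.
#' @export
generate_degenerate_trial <- function(mode = c("no_penetration", "full_isolation"),
                                      config = trial_config()) {
  mode <- match.arg(mode)
  cfg <- config
  if (mode == "full_isolation") {
    cfg$n_stripes_per_group <- cfg$n_per_group
    return(generate_crossing_trial(cfg)$trial)
  }
  # no_penetration: both groups advance along the bisector at the same rate,
  # so a large offset along the bisector keeps them apart forever
  sim <- generate_crossing_trial(cfg)
  tr <- sim$trial
  extent <- (cfg$n_stripes_per_group + 1) * cfg$stripe_spacing_m +
    cfg$stripe_depth_m + 2
  shift <- extent * c(1, 0)  # along the bisector, which is +x by construction
  d <- tr$data
  sel <- d$group == "g2"
  d$x[sel] <- d$x[sel] + shift[1]
  d$y[sel] <- d$y[sel] + shift[2]
  trial(d, frame_rate_hz = tr$frame_rate_hz,
        expected_angle_deg = tr$expected_angle_deg)
}
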