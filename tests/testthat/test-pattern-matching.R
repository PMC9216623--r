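test_that("matching score hits its ceilings on ideal point sets", {
  ip <- generate_ideal_stripe_points(gamma_deg = 90, lambda_m = 2, psi_deg = 0,
                                     n_per_group = 10, seed = 1)
  expect_equal(sinusoid_score(ip, 90, 2, 0, mode = "whole_crowd"), 2,
               tolerance = 1e-12)
  expect_equal(sinusoid_score(ip, 90, 2, 0, mode = "crest"), 1,
               tolerance = 1e-12)
  # off-axis generating parameters work too
  ip2 <- generate_ideal_stripe_points(gamma_deg = 75, lambda_m = 1.3,
                                      psi_deg = 40, n_per_group = 12, seed = 2)
  expect_equal(sinusoid_score(ip2, 75, 1.3, 40), 2, tolerance = 1e-9)
})

test_that("uniform random points score near zero", {
  set.seed(7)
  pts <- list(g1 = matrix(runif(10000, -10, 10), ncol = 2),
              g2 = matrix(runif(10000, -10, 10), ncol = 2))
  for (lam in c(0.7, 2, 5)) {
    expect_lt(abs(sinusoid_score(pts, 72, lam, 30)), 0.1)
  }
})

test_that("score symmetries hold", {
  ip <- generate_ideal_stripe_points(gamma_deg = 80, lambda_m = 1.7,
                                     psi_deg = 10, n_per_group = 9, seed = 3)
  set.seed(8)
  pars <- cbind(runif(20, 0, 180), runif(20, 0.5, 4), runif(20, -180, 180))
  for (i in seq_len(nrow(pars))) {
    g <- pars[i, 1]; l <- pars[i, 2]; p <- pars[i, 3]
    s <- sinusoid_score(ip, g, l, p)
    expect_lte(abs(s), 2)
    # swapping crest and trough groups = shifting psi by half a period
    swapped <- sinusoid_score(list(ip$trough, ip$crest), g, l, p + 180)
    expect_equal(swapped, s, tolerance = 1e-12)
    # single-group score bounded by 1
    expect_lte(abs(sinusoid_score(ip, g, l, p, mode = "crest")), 1)
    # translating all points along the crest direction changes nothing
    shift <- 1.234 * c(cos(g * pi / 180), sin(g * pi / 180))
    moved <- lapply(ip, function(m) sweep(m, 2, -shift))
    expect_equal(sinusoid_score(moved, g, l, p), s, tolerance = 1e-12)
  }
})

test_that("fit recovers ideal parameters to grid-free precision", {
  ip <- generate_ideal_stripe_points(gamma_deg = 95, lambda_m = 1.8,
                                     psi_deg = -30, n_per_group = 15,
                                     extent_m = 8, seed = 4)
  ft <- fit_sinusoid(ip, lambda_bounds_m = c(1, 3))
  expect_lt(abs(ft$gamma_deg - 95), 0.1)
  expect_lt(abs(ft$lambda_m - 1.8) / 1.8, 0.001)
  expect_equal(ft$score, 2, tolerance = 1e-6)
  expect_equal(sinusoid_score(ip, ft$gamma_deg, ft$lambda_m, ft$psi_deg),
               ft$score, tolerance = 1e-9)
})

test_that("fit recovers noisy stripe parameters across seeds", {
  errs <- t(sapply(1:20, function(sd) {
    ip <- generate_ideal_stripe_points(gamma_deg = 90, lambda_m = 2,
                                       psi_deg = 0, n_per_group = 19,
                                       extent_m = 8, seed = sd)
    noisy <- withr::with_seed(1000 + sd, {
      lapply(ip, function(m) m + matrix(rnorm(length(m), 0, 0.1), ncol = 2))
    })
    ft <- fit_sinusoid(noisy, lambda_bounds_m = c(1, 4))
    c(abs(ft$gamma_deg - 90), abs(ft$lambda_m - 2) / 2)
  }))
  expect_lt(max(errs[, 1]), 2)
  expect_lt(max(errs[, 2]), 0.05)
})

test_that("optimizer never falls below the fine-grid oracle", {
  set.seed(11)
  for (i in 1:10) {
    ip <- generate_ideal_stripe_points(
      gamma_deg = runif(1, 70, 110), lambda_m = runif(1, 1.2, 2.6),
      psi_deg = runif(1, -180, 180), n_per_group = 8, extent_m = 8,
      seed = 100 + i)
    noisy <- lapply(ip, function(m) m + matrix(rnorm(length(m), 0, 0.15),
                                               ncol = 2))
    ft <- fit_sinusoid(noisy, lambda_bounds_m = c(1, 3))
    oracle <- oracle_fit_grid(noisy, lambda_bounds = c(1, 3))
    expect_gte(ft$score, oracle - 1e-6)
  }
})

test_that("degenerate point sets trigger the unidentifiable-fit warning", {
  # a single group on one line parallel to the stripes (irregular spacing so
  # no off-axis orientation can also reach a perfect score): every point
  # shares the same wave coordinate and the wavelength is unidentifiable
  set.seed(13)
  pts <- cbind(rep(0.5, 12), sort(runif(12, -3, 3)))
  expect_warning(
    fit_sinusoid(list(a = pts), mode = "a", lambda_bounds_m = c(1, 3)),
    class = "stripeflow_warning_unidentifiable"
  )
})

test_that("analysis time maximizes periodicity inside the stated window", {
  sim <- generate_crossing_trial(cfg_small(crossing_angle_deg = 90, seed = 21))
  tr <- sim$trial
  geo <- estimate_crossing_geometry(tr)
  tl <- detect_edge_cuts(tr)
  ts <- select_analysis_time(tr, tl, geo)
  expect_gte(ts$time, (tl$T_i + tl$T_f) / 2 - 1e-9)
  expect_lte(ts$time, tl$T_f + 1e-9)
  full <- fit_sinusoid(points_at_frame(tr, ts$frame, geo),
                       lambda_bounds_m = c(1, 4))
  expect_equal(full$score, 2, tolerance = 1e-6)

  # scatter the stripes in the last 20% of the window: T* must avoid it
  t_cut <- tl$T_i / 2 + tl$T_f / 2 + 0.8 * (tl$T_f - (tl$T_i + tl$T_f) / 2)
  d <- tr$data
  late <- d$time > t_cut & d$time <= tl$T_f
  set.seed(5)
  d$x[late] <- d$x[late] + runif(sum(late), -1, 1)
  d$y[late] <- d$y[late] + runif(sum(late), -1, 1)
  ts2 <- select_analysis_time(trial(d, frame_rate_hz = 60), tl, geo)
  expect_lte(ts2$time, t_cut)
})

test_that("per-frame fit series matches frame-by-frame fits and averages correctly", {
  sim <- generate_crossing_trial(cfg_small(crossing_angle_deg = 90, seed = 22))
  tr <- sim$trial
  geo <- estimate_crossing_geometry(tr)
  tl <- detect_edge_cuts(tr)
  frames <- seq(tl$T_i_frame, tl$T_f_frame, length.out = 5)
  frames <- unique(round(frames))
  ser <- fit_time_series(tr, tl, geo, mode = "whole_crowd", frames = frames,
                         lambda_bounds_m = c(1, 4))
  for (k in seq_along(frames)) {
    ft <- fit_sinusoid(points_at_frame(tr, frames[k], geo),
                       lambda_bounds_m = c(1, 4))
    expect_equal(ser$score[k], ft$score, tolerance = 1e-6)
  }

  both <- fit_time_series(tr, tl, geo, mode = "both_groups", frames = frames,
                          lambda_bounds_m = c(1, 4))
  avg <- time_average(both)
  expect_equal(avg$gamma_mean_deg_L, 90, tolerance = 0.5)
  expect_equal(avg$gamma_mean_deg_R, 90, tolerance = 0.5)
  expect_lt(avg$lambda_absdiff_mean_m, 1e-3)
  expect_equal(avg$n_failed, 0L)
})

test_that("per-group fits resolve different stripe orientations", {
  # hand-built trial: bisector along +x, left-group stripes at 85 degrees,
  # right-group stripes at 95 degrees from the bisector
  times <- seq(0, 4, by = 1 / 30)
  mk_group <- function(gname, gamma_deg, heading, interleave) {
    g <- gamma_deg * pi / 180
    wave <- c(sin(g), -cos(g)); line <- c(cos(g), sin(g))
    rows <- list()
    pid <- 0
    for (k in 0:2) for (j in 0:4) {
      pid <- pid + 1
      p0 <- (k * 2 + interleave) * wave + (j - 2) * 0.8 * line
      rows[[pid]] <- data.frame(
        time = times, id = sprintf("%s_%02d", gname, pid), group = gname,
        x = p0[1] + heading[1] * 1.3 * times,
        y = p0[2] + heading[2] * 1.3 * times)
    }
    do.call(rbind, rows)
  }
  s45 <- sqrt(2) / 2
  d <- rbind(mk_group("gl", 85, c(s45, s45), 0),
             mk_group("gr", 95, c(s45, -s45), 1))
  tr <- trial(d)
  geo <- estimate_crossing_geometry(tr)
  tl <- manual_timeline(tr, T_i = 0.5, T_f = 3.5)
  frames <- unique(round(seq(tl$T_i_frame, tl$T_f_frame, length.out = 6)))
  both <- fit_time_series(tr, tl, geo, mode = "both_groups", frames = frames,
                          lambda_bounds_m = c(1, 3))
  avg <- time_average(both)
  expect_equal(avg$gamma_mean_deg_L - avg$gamma_mean_deg_R, -10, tolerance = 1)
})

test_that("residual errors wrap distances and summarize them", {
  ip <- generate_ideal_stripe_points(gamma_deg = 90, lambda_m = 2, psi_deg = 0,
                                     n_per_group = 20, seed = 31)
  ft <- fit_sinusoid(ip, lambda_bounds_m = c(1, 3))
  res <- residual_errors(ip, ft)
  expect_equal(max(abs(res$distances$distance_m)), 0, tolerance = 1e-6)
  expect_equal(res$frac_within_quarter, 1)

  # shift every point by +lambda/4 along the wave direction
  shifted <- lapply(ip, function(m) sweep(m, 2, -c(0.5, 0)))
  res2 <- residual_errors(shifted, ft)
  expect_equal(res2$distances$distance_m,
               rep(0.5, nrow(res2$distances)), tolerance = 1e-6)
  # shifting by a full wavelength changes nothing
  res3 <- residual_errors(lapply(ip, function(m) sweep(m, 2, -c(2, 0))), ft)
  expect_lt(max(abs(res3$distances$distance_m - res$distances$distance_m)), 1e-6)
})

test_that("residual sigma recovers injected phase noise", {
  sigmas <- sapply(1:20, function(sd) {
    ip <- generate_ideal_stripe_points(gamma_deg = 90, lambda_m = 2,
                                       psi_deg = 0, n_per_group = 60,
                                       extent_m = 12, seed = sd)
    noisy <- withr::with_seed(2000 + sd, {
      lapply(ip, function(m) {
        m[, 1] <- m[, 1] + rnorm(nrow(m), 0, 0.15 * 2)  # along the wave axis
        m
      })
    })
    fit <- list(gamma_deg = 90, lambda_m = 2, psi_deg = 0,
                mode = "whole_crowd")
    class(fit) <- "stripeflow_fit"
    residual_errors(noisy, fit)$gaussian_sigma_lambda
  })
  expect_lt(abs(median(sigmas) - 0.15) / 0.15, 0.2)
})

test_that("Gaussian histogram fit recovers known distributions", {
  set.seed(12)
  g1 <- fit_gaussian_pdf(rnorm(10000))
  expect_lt(abs(g1$mean), 0.05)
  expect_lt(abs(g1$sigma - 1), 0.05)

  g2 <- fit_gaussian_pdf(rnorm(5000, 2, 0.5))
  expect_lt(abs(g2$mean - 2), 0.05)

  sym <- rep(c(-1, 1), each = 200)
  g3 <- fit_gaussian_pdf(sym)
  expect_lt(abs(g3$mean), 1e-3)

  expect_error(fit_gaussian_pdf(rnorm(10)),
               class = "stripeflow_error_too_few_points")
})

test_that("heuristic wavelength matches its algebra", {
  expect_equal(round(heuristic_wavelength(8.06, 9), 2), 1.79)
  expect_equal(heuristic_wavelength(7, 1), 14)
  for (k in 1:4) expect_equal(heuristic_wavelength(6, 2 * k), 6 / k)
})
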