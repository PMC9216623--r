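test_that("minimum bounding box handles rectangles, rotations and degeneracy", {
  rect <- cbind(c(0, 4, 4, 0), c(0, 0, 1, 1))
  bb <- min_bounding_box(rect)
  expect_equal(bb$length_m, 4, tolerance = 1e-12)
  expect_equal(bb$width_m, 1, tolerance = 1e-12)
  expect_equal(bb$angle_deg, 0, tolerance = 1e-9)
  expect_equal(bb$width_m / bb$length_m, 0.25, tolerance = 1e-12)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  bb30 <- min_bounding_box(rect %*% t(R))
  expect_equal(bb30$angle_deg, 30, tolerance = 1e-9)
  expect_equal(bb30$length_m, 4, tolerance = 1e-9)
  expect_equal(bb30$width_m, 1, tolerance = 1e-9)

  expect_error(min_bounding_box(rbind(c(1, 1), c(1, 1))),
               class = "stripeflow_error_degenerate_stripe")
  line <- cbind(seq(0, 3, by = 0.5), 2 * seq(0, 3, by = 0.5))
  bbl <- min_bounding_box(line)
  expect_true(bbl$degenerate)
  expect_equal(bbl$width_m, 0)
  expect_equal(bbl$angle_deg, atan(2) * 180 / pi, tolerance = 1e-9)
})

test_that("bounding box is minimal against a rotation-sweep oracle", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    pts <- cbind(rnorm(n, sd = runif(1, 0.5, 3)),
                 rnorm(n, sd = runif(1, 0.2, 2)))
    bb <- min_bounding_box(pts)
    oracle <- oracle_bbox_area(pts, step_deg = 0.01)
    # the calipers box can never exceed the sweep minimum; the sweep itself
    # overshoots the true minimum by up to O(step) at a kinked optimum
    expect_lte(bb$area_m2, oracle * (1 + 1e-6))
    expect_lte(oracle, bb$area_m2 * (1 + 1e-3))
    # the box contains every point
    e <- c(cos(bb$angle_deg * pi / 180), sin(bb$angle_deg * pi / 180))
    nv <- c(-e[2], e[1])
    rel <- sweep(pts, 2, bb$center)
    expect_lte(max(abs(rel %*% e)), bb$length_m / 2 + 1e-9)
    expect_lte(max(abs(rel %*% nv)), bb$width_m / 2 + 1e-9)
  }
})

test_that("bounding box is equivariant under rotation", {
  set.seed(34)
  pts <- cbind(rnorm(12, sd = 2), rnorm(12, sd = 0.5))
  bb <- min_bounding_box(pts)
  for (th_deg in c(15, 72, 133)) {
    th <- th_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    bbr <- min_bounding_box(pts %*% t(R))
    expect_equal(bbr$length_m, bb$length_m, tolerance = 1e-9)
    expect_equal(bbr$width_m, bb$width_m, tolerance = 1e-9)
    expect_equal((bbr$angle_deg - bb$angle_deg - th_deg) %% 180, 0,
                 tolerance = 1e-6)
  }
})

test_that("stripe geometry classifies elongated and compact stripes", {
  sim <- generate_crossing_trial(cfg_small(crossing_angle_deg = 90, seed = 41))
  geo <- estimate_crossing_geometry(sim$trial)

  # elongated stripe perpendicular to the bisector: 6 members over 3 m with
  # 0.3 m depth (in original coordinates the bisector is +x)
  times <- sim$trial$frame_times
  d <- sim$trial$data
  mk_static <- function(ids, pts) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(time = times, id = ids[i], group = "g1",
                 x = pts[i, 1], y = pts[i, 2])
    }))
  }
  pts6 <- cbind(rep(c(0, 0.3), 3), seq(-1.5, 1.5, length.out = 6))
  tr6 <- trial(mk_static(sprintf("s%02d", 1:6), pts6))
  sg <- stripe_geometry_at(tr6, as_stripe("g1", sprintf("s%02d", 1:6)),
                           frame = 10, geometry = geo)
  expect_equal(sg$gamma_stripe_deg, 90, tolerance = 0.5)
  expect_lt(sg$aspect_ratio, 0.15)
  expect_true(sg$eligible)

  # compact square-ish cluster: ineligible
  sq <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  trs <- trial(mk_static(sprintf("q%02d", 1:5), sq))
  sgq <- stripe_geometry_at(trs, as_stripe("g1", sprintf("q%02d", 1:5)),
                            frame = 10, geometry = geo)
  expect_gt(sgq$aspect_ratio, 0.9)
  expect_false(sgq$eligible)

  # 2-member stripe: excluded regardless of shape
  tr2 <- trial(mk_static(c("t01", "t02"), cbind(c(0, 3), c(0, 0))))
  sg2 <- stripe_geometry_at(tr2, as_stripe("g1", c("t01", "t02")),
                            frame = 10, geometry = geo)
  expect_false(sg2$eligible)
})

test_that("per-stripe averages recover the constructed orientation", {
  sim <- generate_crossing_trial(
    cfg_noiseless(crossing_angle_deg = 90, n_per_group = 12,
                  n_stripes_per_group = 3, frame_rate_hz = 60,
                  stripe_depth_m = 0.3, seed = 42))
  tr <- sim$trial
  geo <- estimate_crossing_geometry(tr)
  tl <- detect_edge_cuts(tr)
  ps <- per_stripe_time_average(tr, tl, geo, max_frames = 20)
  expect_equal(ps$pooled$gamma_L_median, 90, tolerance = 1)
  expect_equal(ps$pooled$gamma_R_median, 90, tolerance = 1)
  expect_true(all(ps$per_stripe$size == 4))

  # stripes constructed at 80 degrees from the bisector are recovered at 80
  times <- seq(0, 4, by = 1 / 30)
  g <- 80 * pi / 180
  line <- c(cos(g), sin(g))
  mk <- function(gname, heading, off) {
    do.call(rbind, lapply(1:6, function(j) {
      p0 <- off + (j - 3.5) * 0.7 * line + (j %% 2) * c(0.12, 0)
      data.frame(time = times, id = sprintf("%s%02d", gname, j), group = gname,
                 x = p0[1] + heading[1] * 1.3 * times,
                 y = p0[2] + heading[2] * 1.3 * times)
    }))
  }
  s45 <- sqrt(2) / 2
  d80 <- rbind(mk("a", c(s45, s45), c(0, 0)), mk("b", c(s45, -s45), c(40, 0)))
  tr80 <- trial(d80)
  geo80 <- estimate_crossing_geometry(tr80)
  tl80 <- manual_timeline(tr80, 0.5, 3.5)
  ps80 <- per_stripe_time_average(
    tr80, tl80, geo80, max_frames = 10,
    stripes = list(as_stripe("a", sprintf("a%02d", 1:6)),
                   as_stripe("b", sprintf("b%02d", 1:6))))
  expect_equal(ps80$per_stripe$gamma_mean_deg,
               rep(80, 2), tolerance = 1)

  # averaging a constant series returns the constant
  expect_equal(axial_mean_deg(rep(77.7, 10)), 77.7)
})

test_that("width series detects scheduled squeezing and not rigid stripes", {
  cfg_sq <- cfg_noiseless(crossing_angle_deg = 90, n_per_group = 12,
                          n_stripes_per_group = 3, frame_rate_hz = 60,
                          stripe_depth_m = 0.4, squeeze_factor = 0.6,
                          seed = 43)
  sim <- generate_crossing_trial(cfg_sq)
  tl <- detect_edge_cuts(sim$trial)
  stripes <- extract_stripes(tl)
  s <- stripes[[which.max(vapply(stripes, function(x) length(x$members), 0L))]]
  ws <- width_time_series(sim$trial, tl, s)
  sq <- detect_squeeze(ws)
  expect_true(sq$squeezed)
  expect_gt(sq$min_scaled_time, 0)
  expect_lt(sq$min_scaled_time, 1)

  # rigid stripes: same construction without the compression schedule
  cfg_rigid <- cfg_sq
  cfg_rigid$squeeze_factor <- 0
  sim_r <- generate_crossing_trial(cfg_rigid)
  tl_r <- detect_edge_cuts(sim_r$trial)
  stripes_r <- extract_stripes(tl_r)
  s_r <- stripes_r[[which.max(vapply(stripes_r, function(x) length(x$members), 0L))]]
  ws_r <- width_time_series(sim_r$trial, tl_r, s_r)
  expect_false(detect_squeeze(ws_r)$squeezed)

  # scaled time maps T_i and T_f to exactly 0 and 1
  ws2 <- width_time_series(sim$trial, tl, s,
                           frames = c(tl$T_i_frame, tl$T_f_frame))
  expect_equal(ws2$series$scaled_time, c(0, 1), tolerance = 1e-12)

  zero_tl <- manual_timeline(sim$trial, 1, 1)
  expect_error(width_time_series(sim$trial, zero_tl, s),
               class = "stripeflow_error_zero_window")
})

test_that("count and size curves aggregate and check monotonicity", {
  res <- data.frame(alpha_deg = rep(c(30, 90, 150), each = 3),
                    trial_id = rep(1:3, times = 3), group = "g1")
  res$n_stripes <- c(7, 7, 6, 5, 5, 5, 4, 3, 4)
  res$mean_stripe_size <- 19 / res$n_stripes
  cs <- stripe_count_size_curves(res)
  expect_true(cs$monotonic$count_decreasing)
  expect_true(cs$monotonic$size_increasing)
  expect_equal(cs$by_angle$count_mean[1], mean(c(7, 7, 6)))

  # partition identity: mean size x count = group size
  sim <- generate_crossing_trial(cfg_small(crossing_angle_deg = 90, seed = 44))
  s <- crossing_summary(detect_edge_cuts(sim$trial))
  for (g in names(s$n_stripes)) {
    expect_equal(mean(s$stripe_sizes[[g]]) * s$n_stripes[[g]], 10)
  }
})
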