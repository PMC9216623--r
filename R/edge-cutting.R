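#' Edge-cut predicate for one (P, Q, R) triple over one frame step
#'
#' The virtual edge between same-group pedestrians P and Q is cut by the
#' opposing pedestrian R between frames t-1 and t when three conditions hold:
#' (i) `PQ . PR > 0` and (ii) `d = PQ . PR < |PQ|^2` — together these state
#' that the projection of R onto the edge lies strictly between P and Q (a
#' condition that is symmetric in the roles of P and Q) — and (iii) the signed
#' angle beta from PQ to PR (counterclockwise positive, in (-pi, pi])
#' changes sign between the frames: `beta(t) * beta(t-1) < 0`. Conditions (i)
#' and (ii) are required at both frames, which ties the sign flip of beta to R
#' crossing the interior of the segment PQ. A grazing `beta(t) = 0` with (i)
#' and (ii) holding also counts as a cut.
#'
#' @param p1,q1,r1 Positions (length-2) of P, Q, R at frame t-1.
#' @param p2,q2,r2 Positions at frame t.
#' @return `TRUE` (cut) or `FALSE` (no cut), with attributes `beta_before`,
#'   `beta_after` (degrees) and `d_value` (the value of d at frame t).
#' @export
edge_cut_predicate <- function(p1, q1, r1, p2, q2, r2) {
  pq1 <- q1 - p1; pr1 <- r1 - p1
  pq2 <- q2 - p2; pr2 <- r2 - p2
  l1 <- sum(pq1^2); l2 <- sum(pq2^2)
  if (l1 == 0 || l2 == 0) {
    rlang::abort("degenerate edge: P and Q coincide",
                 class = "stripeflow_error_degenerate_edge")
  }
  d1 <- sum(pq1 * pr1); d2 <- sum(pq2 * pr2)
  cr1 <- pq1[1] * pr1[2] - pq1[2] * pr1[1]
  cr2 <- pq2[1] * pr2[2] - pq2[2] * pr2[1]
  cond1 <- d1 > 0 && d1 < l1
  cond2 <- d2 > 0 && d2 < l2
  flip <- (cr1 * cr2 < 0) || (cr2 == 0 && cr1 != 0)
  cut <- cond1 && cond2 && flip
  structure(cut,
            beta_before = rad2deg(atan2(cr1, d1)),
            beta_after = rad2deg(atan2(cr2, d2)),
            d_value = d2)
}

#' Detect all edge cuts in a trial
#'
#' Initializes each group as a complete graph at the first frame, then scans
#' frames in order, applying the edge-cut predicate to every surviving
#' intra-group edge against every pedestrian of the opposing group. An edge is
#' suppressed permanently at its first cut. The times of the first and last
#' cut, `T_i` and `T_f`, delimit the crossing.
#'
#' @param trial A `stripeflow_trial` (normally low-pass filtered) with two groups.
#' @return An object of class `stripeflow_timeline`: `events` (tibble with
#'   `frame`, `time`, `group`, `p`, `q`, `cutter`, `beta_before_deg`,
#'   `beta_after_deg`, `d_value`), `T_i`, `T_f` (seconds, `NA` when there are
#'   no events), frame counterparts `T_i_frame` / `T_f_frame`, and the group
#'   memberships.
#' @export
detect_edge_cuts <- function(trial) {
  groups <- trial_groups(trial)
  if (length(groups) != 2) {
    rlang::abort("edge cutting requires two groups",
                 class = "stripeflow_error_one_group")
  }
  arr <- trial_arrays(trial)
  nt <- length(arr$times)
  members <- lapply(groups, function(g) which(arr$group_of == g))
  names(members) <- groups

  state <- list()
  for (g in groups) {
    idx <- members[[g]]
    if (length(idx) >= 2) {
      pairs <- utils::combn(idx, 2)
      state[[g]] <- list(P = pairs[1, ], Q = pairs[2, ],
                         alive = rep(TRUE, ncol(pairs)))
    } else {
      state[[g]] <- list(P = integer(0), Q = integer(0), alive = logical(0))
    }
  }

  events <- vector("list", 256); nev <- 0L
  other <- stats::setNames(rev(groups), groups)

  # bounding boxes per frame per group for a cheap proximity prefilter
  bb <- lapply(groups, function(g) {
    idx <- members[[g]]
    cbind(
      apply(arr$X[, idx, drop = FALSE], 1, min), apply(arr$X[, idx, drop = FALSE], 1, max),
      apply(arr$Y[, idx, drop = FALSE], 1, min), apply(arr$Y[, idx, drop = FALSE], 1, max)
    )
  })
  names(bb) <- groups
  margin <- 0.5
  overlap <- (bb[[1]][, 1] - margin <= bb[[2]][, 2]) &
    (bb[[2]][, 1] - margin <= bb[[1]][, 2]) &
    (bb[[1]][, 3] - margin <= bb[[2]][, 4]) &
    (bb[[2]][, 3] - margin <= bb[[1]][, 4])

  for (t in 2:nt) {
    if (!overlap[t] && !overlap[t - 1]) next
    for (g in groups) {
      st <- state[[g]]
      live <- which(st$alive)
      if (length(live) == 0) next
      cutters <- members[[other[[g]]]]
      if (length(cutters) == 0) next

      P <- st$P[live]; Q <- st$Q[live]
      p1x <- arr$X[t - 1, P]; p1y <- arr$Y[t - 1, P]
      q1x <- arr$X[t - 1, Q]; q1y <- arr$Y[t - 1, Q]
      p2x <- arr$X[t, P];     p2y <- arr$Y[t, P]
      q2x <- arr$X[t, Q];     q2y <- arr$Y[t, Q]
      r1x <- arr$X[t - 1, cutters]; r1y <- arr$Y[t - 1, cutters]
      r2x <- arr$X[t, cutters];     r2y <- arr$Y[t, cutters]

      ok <- is.finite(p1x) & is.finite(q1x) & is.finite(p2x) & is.finite(q2x)
      okR <- is.finite(r1x) & is.finite(r2x)
      if (!any(ok) || !any(okR)) next

      pq1x <- q1x - p1x; pq1y <- q1y - p1y
      pq2x <- q2x - p2x; pq2y <- q2y - p2y
      l1 <- pq1x^2 + pq1y^2; l2 <- pq2x^2 + pq2y^2

      # m edges x k cutters matrices
      d1 <- outer(pq1x, r1x) + outer(pq1y, r1y) - (pq1x * p1x + pq1y * p1y)
      d2 <- outer(pq2x, r2x) + outer(pq2y, r2y) - (pq2x * p2x + pq2y * p2y)
      cr1 <- outer(pq1x, r1y) - outer(pq1y, r1x) - (pq1x * p1y - pq1y * p1x)
      cr2 <- outer(pq2x, r2y) - outer(pq2y, r2x) - (pq2x * p2y - pq2y * p2x)

      cond <- (d1 > 0) & (d1 < l1) & (d2 > 0) & (d2 < l2)
      flip <- (cr1 * cr2 < 0) | (cr2 == 0 & cr1 != 0)
      cut <- cond & flip & ok & outer(rep(TRUE, length(P)), okR)

      hits <- which(rowSums(cut) > 0)
      for (e in hits) {
        rpick <- which(cut[e, ])[1]  # deterministic: lowest cutter index
        nev <- nev + 1L
        if (nev > length(events)) events <- c(events, vector("list", length(events)))
        events[[nev]] <- list(
          frame = t, time = arr$times[t], group = g,
          p = arr$ids[P[e]], q = arr$ids[Q[e]], cutter = arr$ids[cutters[rpick]],
          beta_before_deg = rad2deg(atan2(cr1[e, rpick], d1[e, rpick])),
          beta_after_deg = rad2deg(atan2(cr2[e, rpick], d2[e, rpick])),
          d_value = d2[e, rpick]
        )
        state[[g]]$alive[live[e]] <- FALSE
      }
    }
  }

  ev <- if (nev > 0) {
    dplyr::bind_rows(lapply(events[seq_len(nev)], tibble::as_tibble))
  } else {
    tibble::tibble(frame = integer(0), time = numeric(0), group = character(0),
                   p = character(0), q = character(0), cutter = character(0),
                   beta_before_deg = numeric(0), beta_after_deg = numeric(0),
                   d_value = numeric(0))
  }
  ev <- ev[base::order(ev$frame, ev$group, ev$p, ev$q), ]

  structure(
    list(
      events = ev,
      T_i = if (nev > 0) min(ev$time) else NA_real_,
      T_f = if (nev > 0) max(ev$time) else NA_real_,
      T_i_frame = if (nev > 0) min(ev$frame) else NA_integer_,
      T_f_frame = if (nev > 0) max(ev$frame) else NA_integer_,
      groups = stats::setNames(lapply(groups, function(g) arr$ids[members[[g]]]), groups),
      frame_times = arr$times
    ),
    class = "stripeflow_timeline"
  )
}

#' Construct a timeline manually
#'
#' Builds a `stripeflow_timeline` with no recorded events but explicit
#' crossing bounds, for analyses (time-windowed fitting, width series) of
#' trials whose edge-cut history is known or irrelevant.
#'
#' @param trial A `stripeflow_trial`.
#' @param T_i,T_f Crossing bounds, seconds.
#' @return A `stripeflow_timeline`.
#' @export
manual_timeline <- function(trial, T_i, T_f) {
  stopifnot(T_i <= T_f)
  arr <- trial_arrays(trial)
  groups <- trial_groups(trial)
  structure(
    list(
      events = tibble::tibble(frame = integer(0), time = numeric(0),
                              group = character(0), p = character(0),
                              q = character(0), cutter = character(0),
                              beta_before_deg = numeric(0),
                              beta_after_deg = numeric(0), d_value = numeric(0)),
      T_i = T_i, T_f = T_f,
      T_i_frame = which.min(abs(arr$times - T_i)),
      T_f_frame = which.min(abs(arr$times - T_f)),
      groups = stats::setNames(
        lapply(groups, function(g) arr$ids[arr$group_of[arr$ids] == g]), groups),
      frame_times = arr$times
    ),
    class = "stripeflow_timeline"
  )
}

#' @export
print.stripeflow_timeline <- function(x, ...) {
  cat("<stripeflow_timeline>\n")
  cat("  events:", nrow(x$events), "\n")
  if (is.na(x$T_i)) {
    cat("  no edge cuts detected (T_i / T_f absent)\n")
  } else {
    cat(sprintf("  T_i = %.3f s, T_f = %.3f s (crossing time %.3f s)\n",
                x$T_i, x$T_f, x$T_f - x$T_i))
  }
  invisible(x)
}

#' Surviving intra-group edges at a frame
#'
#' @param timeline A `stripeflow_timeline`.
#' @param group Group label.
#' @param at_frame Frame index; edges cut at frames `<= at_frame` are removed.
#' @return Two-column character matrix of surviving edges (p, q).
#' @export
residual_edges <- function(timeline, group, at_frame = Inf) {
  ids <- timeline$groups[[group]]
  if (length(ids) < 2) return(matrix(character(0), 0, 2))
  pairs <- t(utils::combn(sort(ids), 2))
  ev <- timeline$events
  ev <- ev[ev$group == group & ev$frame <= at_frame, , drop = FALSE]
  if (nrow(ev) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    cutk <- key(ev$p, ev$q)
    pairs <- pairs[!(key(pairs[, 1], pairs[, 2]) %in% cutk), , drop = FALSE]
  }
  pairs
}

#' Extract stripes as residual clusters
#'
#' Stripes are the connected components of the residual (uncut) intra-group
#' edge set at a frame; they partition the group.
#'
#' @param timeline A `stripeflow_timeline`.
#' @param group Group label, or `NULL` for all groups.
#' @param at_frame Frame index (default: after all events).
#' @return List of stripes; each is a list with `group`, `members` (sorted
#'   ids), and `formed_at` (frame of the last cut involving a member, `NA` if
#'   the group was never cut).
#' @export
extract_stripes <- function(timeline, group = NULL, at_frame = Inf) {
  gs <- if (is.null(group)) names(timeline$groups) else group
  out <- list()
  for (g in gs) {
    ids <- sort(timeline$groups[[g]])
    edges <- residual_edges(timeline, g, at_frame)
    gr <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    gr <- igraph::set_vertex_attr(gr, "name", value = ids)
    if (nrow(edges) > 0) gr <- igraph::add_edges(gr, t(edges))
    comp <- igraph::components(gr)
    ev <- timeline$events
    ev <- ev[ev$group == g & ev$frame <= at_frame, , drop = FALSE]
    for (ci in seq_len(comp$no)) {
      mem <- sort(ids[comp$membership == ci])
      touched <- ev$frame[ev$p %in% mem | ev$q %in% mem]
      out[[length(out) + 1L]] <- structure(
        list(group = g, members = mem,
             formed_at = if (length(touched)) max(touched) else NA_integer_),
        class = "stripeflow_stripe"
      )
    }
  }
  out
}

#' Summarize a crossing from its edge-cut timeline
#'
#' @param timeline A `stripeflow_timeline`.
#' @return List with `T_i`, `T_f`, `crossing_time` (`T_f - T_i`; `NA`, not 0,
#'   for a zero-event timeline), and per group `n_stripes` and `stripe_sizes`
#'   at the final frame.
#' @export
crossing_summary <- function(timeline) {
  stripes <- extract_stripes(timeline)
  grp <- vapply(stripes, function(s) s$group, "")
  sizes <- vapply(stripes, function(s) length(s$members), 0L)
  list(
    T_i = timeline$T_i,
    T_f = timeline$T_f,
    crossing_time = if (is.na(timeline$T_i)) NA_real_ else timeline$T_f - timeline$T_i,
    n_stripes = vapply(split(sizes, grp), length, 0L),
    stripe_sizes = split(sizes, grp)
  )
}
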