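# Kinematic simulation of the three-sphere manipulation task: two spheres
# track the physical controllers 1:1, the third is carried by the virtual
# hand once an accepted activation locks it. No physics engine - a point
# hand with a hard speed cap, optional stabilising assistance, and sphere
# capture when the hand enters the sphere radius.

#' Three-sphere scene
#'
#' Spheres of 0.10 m diameter at the vertices of an equilateral triangle
#' with 0.40 m sides, centred in front of the viewer. Wireframe target
#' positions default to a fixed displacement of each sphere.
#'
#' @param side triangle side length (m).
#' @param radius sphere radius (m).
#' @param centre scene centre (m), z forward from the viewer.
#' @param target_shift displacement applied to each sphere to form its
#'   wireframe target.
#' @param n_distractors distractor count (recorded for complexity scoring).
#' @export
scene <- function(side = 0.4, radius = 0.05, centre = c(0, 0, 0.6),
                  target_shift = c(0.10, 0.05, 0), n_distractors = 0) {
  h <- side * sqrt(3) / 2
  v <- rbind(
    c(-side / 2, -h / 3, 0),
    c(side / 2, -h / 3, 0),
    c(0, 2 * h / 3, 0)
  )
  spheres <- data.frame(
    id = 1:3,
    x = v[, 1] + centre[1], y = v[, 2] + centre[2], z = v[, 3] + centre[3],
    radius = radius
  )
  targets <- spheres
  targets$x <- targets$x + target_shift[1]
  targets$y <- targets$y + target_shift[2]
  targets$z <- targets$z + target_shift[3]
  structure(list(spheres = spheres, targets = targets[c("id", "x", "y", "z")],
                 n_distractors = n_distractors),
            class = "trimanus_scene")
}

sphere_pos <- function(sc) as.matrix(sc$spheres[c("x", "y", "z")])

#' Run one simulated trial
#'
#' Ticks at `1/dt` Hz. The two manual spheres are captured by and then
#' track their controller hands 1:1; the virtual hand idles at a rest pose
#' until an accepted activation arrives, then seeks sphere 3, captures it,
#' and carries it to its wireframe target. Speed is hard-capped at the
#' adaptation state's `vmax`; when adaptation is active an additional
#' stabilising pull proportional to the position error (gain `stiffness`
#' per second) assists terminal positioning. Per-tick authority is resolved
#' with [resolve_authority()]; manual overlap freezes the virtual hand.
#'
#' @param sc a [scene()].
#' @param pose controller pose [sample_stream()] (from
#'   [gen_controllers()]).
#' @param activations accepted activation events ([detect_activations()]);
#'   the first accepted event engages the virtual hand.
#' @param duration trial length (s); defaults to the pose stream length.
#' @param dt simulation step (s).
#' @param adaptation an [adaptation_state()].
#' @param cfg an [arbitration_config()].
#' @param eps_bci BCI confidence fed to the arbitration softmax once the
#'   virtual hand is engaged.
#' @return data.frame trace (class `trial_trace`): sphere and hand
#'   positions, authority weights and controller per tick. The virtual
#'   hand's goal waypoints ride along as attribute `"waypoints"`.
#' @export
run_trial <- function(sc, pose, activations = NULL, duration = NULL,
                      dt = 1 / 90, adaptation = adaptation_state(),
                      cfg = arbitration_config(), eps_bci = 0.9) {
  duration <- duration %||% stream_duration(pose)
  nt <- floor(duration / dt)
  t <- (seq_len(nt) - 1) * dt
  act_t <- if (!is.null(activations) && any(activations$accepted)) {
    min(activations$time[activations$accepted])
  } else {
    Inf
  }
  sp <- sphere_pos(sc)
  tg <- as.matrix(sc$targets[c("x", "y", "z")])
  rest <- c(0, -0.15, 0.45)
  vh <- rest
  vvel <- c(0, 0, 0)
  carrying <- FALSE
  engaged <- FALSE
  lt <- approx_pose(pose, t, c("lx", "ly", "lz"))
  rt <- approx_pose(pose, t, c("rx", "ry", "rz"))
  held <- c(FALSE, FALSE) # spheres 1, 2 captured by hands
  waypoints <- rbind(rest)
  S <- matrix(NA_real_, nt, 12) # s1..s3, vh positions
  wv <- numeric(nt)
  ov <- logical(nt)
  ctrl <- character(nt)
  v_speed <- numeric(nt)
  k_seek <- 3 # proportional speed gain toward the goal, 1/s
  for (i in seq_len(nt)) {
    hands <- rbind(lt[i, ], rt[i, ])
    # manual spheres: capture on contact, then 1:1 tracking
    for (h in 1:2) {
      if (!held[h] && sqrt(sum((hands[h, ] - sp[h, ])^2)) <= sc$spheres$radius[h]) {
        held[h] <- TRUE
      }
      if (held[h]) sp[h, ] <- hands[h, ]
    }
    if (!engaged && t[i] >= act_t) {
      engaged <- TRUE
    }
    w <- authority_weights(
      eps_bci = if (engaged) eps_bci else 0,
      t_gaze = if (engaged) min(t[i] - act_t, cfg$t_cap) else 0,
      cfg = cfg
    )
    auth <- resolve_authority(w, hands, vh, cfg, time = t[i])
    if (engaged && auth$controller == "virtual") {
      goal <- if (carrying) tg[3, ] else sp[3, ]
      err <- goal - vh
      v_des <- k_seek * err
      if (adaptation$active) v_des <- v_des + adaptation$stiffness * err
      spd <- sqrt(sum(v_des^2))
      if (spd > adaptation$vmax) v_des <- v_des * adaptation$vmax / spd
      vvel <- v_des
      vh <- vh + vvel * dt
      if (!carrying && sqrt(sum((vh - sp[3, ])^2)) <= sc$spheres$radius[3]) {
        carrying <- TRUE
        waypoints <- rbind(waypoints, vh) # hand position at goal change
      }
      if (carrying) sp[3, ] <- vh
    } else {
      vvel <- c(0, 0, 0)
    }
    S[i, ] <- c(sp[1, ], sp[2, ], sp[3, ], vh)
    wv[i] <- w[["virtual"]]
    ov[i] <- auth$overlap
    ctrl[i] <- auth$controller
    v_speed[i] <- sqrt(sum(vvel^2))
  }
  out <- data.frame(
    t = t,
    s1x = S[, 1], s1y = S[, 2], s1z = S[, 3],
    s2x = S[, 4], s2y = S[, 5], s2z = S[, 6],
    s3x = S[, 7], s3y = S[, 8], s3z = S[, 9],
    vhx = S[, 10], vhy = S[, 11], vhz = S[, 12],
    w_virtual = wv, overlap = ov, controller = ctrl, speed_v = v_speed,
    lhx = lt[, 1], lhy = lt[, 2], lhz = lt[, 3],
    rhx = rt[, 1], rhy = rt[, 2], rhz = rt[, 3]
  )
  waypoints <- rbind(waypoints, vh) # final hand position
  structure(out, waypoints = waypoints, dt = dt,
            class = c("trial_trace", "data.frame"))
}

approx_pose <- function(pose, t, cols) {
  sapply(cols, function(cn) approx(pose$t, pose[[cn]], xout = t, rule = 2)$y)
}

#' Trial success check
#'
#' Success at the first time a continuous `hold`-second window has all
#' three sphere-to-target Euclidean errors within `tol` simultaneously.
#'
#' @param trace a [run_trial()] trace (>= 30 Hz sampling).
#' @param targets data.frame `id`, `x`, `y`, `z` of wireframe targets.
#' @param tol positional tolerance (m), default 5 mm.
#' @param hold required hold duration (s).
#' @return list `success` (logical) and `time` (s, `NA` on failure).
#' @export
check_success <- function(trace, targets, tol = 0.005, hold = 1.0) {
  dt <- trace$t[2] - trace$t[1]
  if (1 / dt < 30) stop("trace must be sampled at >= 30 Hz")
  err <- sphere_errors(trace, targets)
  ok <- err[, 1] <= tol & err[, 2] <= tol & err[, 3] <= tol
  need <- ceiling(hold / dt)
  run <- 0
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1 else 0
    if (run >= need) return(list(success = TRUE, time = trace$t[i]))
  }
  list(success = FALSE, time = NA_real_)
}

sphere_errors <- function(trace, targets) {
  sapply(1:3, function(k) {
    tx <- targets$x[targets$id == k]
    ty <- targets$y[targets$id == k]
    tz <- targets$z[targets$id == k]
    sqrt((trace[[paste0("s", k, "x")]] - tx)^2 +
           (trace[[paste0("s", k, "y")]] - ty)^2 +
           (trace[[paste0("s", k, "z")]] - tz)^2)
  })
}

path_length <- function(P) {
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Trajectory efficiency (%)
#'
#' `100 * optimal / actual` path length, where the optimal path is the
#' straight polyline through the supplied waypoints, so the score lies in
#' (0, 100\] and equals 100 only for a straight path.
#'
#' @param P n x 3 position matrix.
#' @param waypoints waypoint matrix (defaults to first and last position).
#' @export
trajectory_efficiency <- function(P, waypoints = NULL) {
  actual <- path_length(P)
  if (actual == 0) return(NA_real_)
  wp <- waypoints %||% rbind(P[1, ], P[nrow(P), ])
  optimal <- path_length(wp)
  100 * optimal / actual
}

#' Negated log dimensionless jerk smoothness score
#'
#' `-log( T^5 / L^2 * integral |d3x/dt3|^2 dt )`: duration- and
#' amplitude-normalised, so smoother trajectories score higher; the
#' minimum-jerk profile is the optimum among trajectories with the same
#' endpoints and duration.
#'
#' @param P n x 3 position matrix sampled at fixed `dt`.
#' @param dt sampling interval (s).
#' @export
jerk_score <- function(P, dt) {
  n <- nrow(P)
  if (n < 5) return(NA_real_)
  j <- diff(P, differences = 3) / dt^3
  dur <- (n - 1) * dt
  L <- path_length(P)
  if (L == 0) return(NA_real_)
  dj <- dur^5 / L^2 * sum(rowSums(j^2)) * dt
  -log(dj)
}

#' Peak normalised cross-correlation of two speed profiles
#'
#' Mean-removed, SD-normalised cross-correlation, maximised over lags up to
#' `max_lag` seconds. Identical profiles give 1 at lag 0.
#'
#' @param v1,v2 speed series at a common fixed rate.
#' @param dt sampling interval (s).
#' @param max_lag maximum lag searched (s).
#' @export
velocity_xcorr <- function(v1, v2, dt, max_lag = 2) {
  n <- min(length(v1), length(v2))
  v1 <- v1[seq_len(n)] - mean(v1[seq_len(n)])
  v2 <- v2[seq_len(n)] - mean(v2[seq_len(n)])
  s1 <- sqrt(sum(v1^2)); s2 <- sqrt(sum(v2^2))
  if (s1 == 0 || s2 == 0) return(NA_real_)
  lmax <- min(round(max_lag / dt), n - 1)
  best <- -Inf
  for (l in (-lmax):lmax) {
    k <- n - abs(l)
    a <- v1[seq_len(k) + max(-l, 0)]
    b <- v2[seq_len(k) + max(l, 0)]
    best <- max(best, sum(a * b) / (s1 * s2))
  }
  best
}

#' Objective trial metrics
#'
#' The six per-trial measures: final spatial error per sphere (mm),
#' trajectory efficiency of the virtual hand (%), jerk smoothness score,
#' peak manual-virtual velocity cross-correlation, completion time and the
#' success flag.
#'
#' @param trace a [run_trial()] trace.
#' @param targets wireframe target positions.
#' @return list of class `trial_result`.
#' @export
trial_metrics <- function(trace, targets) {
  dt <- attr(trace, "dt") %||% (trace$t[2] - trace$t[1])
  err <- sphere_errors(trace, targets)
  final_err_mm <- 1000 * err[nrow(trace), ]
  V <- as.matrix(trace[c("vhx", "vhy", "vhz")])
  moving <- which(trace$speed_v > 0)
  eff <- if (length(moving) > 1) {
    # include the tick before motion starts so the path begins at rest
    seg <- max(min(moving) - 1, 1):max(moving)
    trajectory_efficiency(V[seg, , drop = FALSE], attr(trace, "waypoints"))
  } else {
    NA_real_
  }
  manual_speed <- sqrt(rowSums(diff(as.matrix(trace[c("lhx", "lhy", "lhz")]))^2)) / dt
  res <- check_success(trace, targets)
  structure(
    list(
      success = res$success, success_time = res$time,
      spatial_error_mm = final_err_mm,
      efficiency = eff,
      jerk = if (length(moving) > 4) jerk_score(V[min(moving):max(moving), , drop = FALSE], dt) else NA_real_,
      coordination = velocity_xcorr(manual_speed, trace$speed_v[-1], dt),
      completion_time = if (res$success) res$time else trace$t[nrow(trace)]
    ),
    class = "trial_result"
  )
}
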