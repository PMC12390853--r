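# Gaze filtering and targeting: a linear-Gaussian state-space filter over
# gaze direction (constant-velocity transition, position-only observation),
# 45-degree cone target selection, PD gaze stabilisation, and fixation-map
# entropy.

#' Generic Kalman model/state
#'
#' @param A,H,Q,R system matrices (transition, observation, process noise,
#'   observation noise).
#' @param x0,P0 initial state mean and covariance.
#' @export
kalman_model <- function(A, H, Q, R, x0, P0) {
  A <- as.matrix(A); H <- as.matrix(H); Q <- as.matrix(Q); R <- as.matrix(R)
  structure(
    list(A = A, H = H, Q = Q, R = R, x = as.numeric(x0), P = as.matrix(P0),
         innovation = NULL, S = NULL),
    class = "kalman_model"
  )
}

#' Constant-velocity gaze filter
#'
#' State `[x, y, vx, vy]` in degrees and degrees/s; position-only
#' observations. Process noise is a white-noise-acceleration model with
#' variance `q` driving the velocity components (discretised per axis as
#' `q * [[dt^3/3, dt^2/2], [dt^2/2, dt]]`); observation noise `r` per axis.
#' Defaults follow the assumed gaze model: `q = 0.1^2`, `r = 0.5^2`.
#'
#' @param dt sampling interval (s), e.g. 1/120.
#' @param q process noise variance (deg^2).
#' @param r observation noise variance per axis (deg^2).
#' @param x0 initial state; `P0` initial covariance.
#' @export
gaze_kalman <- function(dt, q = 0.1^2, r = 0.5^2,
                        x0 = c(0, 0, 0, 0), P0 = diag(c(25, 25, 100, 100))) {
  A <- diag(4)
  A[1, 3] <- dt
  A[2, 4] <- dt
  H <- matrix(0, 2, 4)
  H[1, 1] <- 1
  H[2, 2] <- 1
  qa <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- qa
  Q[c(2, 4), c(2, 4)] <- qa
  kalman_model(A, H, Q, R = diag(r, 2), x0 = x0, P0 = P0)
}

#' One predict/update step
#'
#' Standard Kalman recursion with the Joseph-form covariance update for
#' numerical symmetry. A missing observation (`NULL` or any `NA`) performs
#' the prediction only.
#'
#' @param km a [kalman_model()].
#' @param z observation vector, or `NULL`/`NA` for predict-only.
#' @return the updated model (fields `x`, `P`, plus the last `innovation`
#'   and its covariance `S`).
#' @export
kalman_step <- function(km, z = NULL) {
  xp <- as.numeric(km$A %*% km$x)
  Pp <- km$A %*% km$P %*% t(km$A) + km$Q
  if (is.null(z) || any(is.na(z))) {
    km$x <- xp
    km$P <- (Pp + t(Pp)) / 2
    km$innovation <- NULL
    km$S <- NULL
  } else {
    S <- km$H %*% Pp %*% t(km$H) + km$R
    v <- as.numeric(z) - as.numeric(km$H %*% xp)
    K <- Pp %*% t(km$H) %*% solve(S)
    km$x <- xp + as.numeric(K %*% v)
    IKH <- diag(nrow(Pp)) - K %*% km$H
    P <- IKH %*% Pp %*% t(IKH) + K %*% km$R %*% t(K)
    P <- (P + t(P)) / 2
    if (any(eigen(P, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
      stop("state covariance lost positive semidefiniteness")
    }
    km$P <- P
    km$innovation <- v
    km$S <- S
  }
  km
}

#' Filter a whole gaze series
#'
#' @param km a [kalman_model()] (typically [gaze_kalman()]).
#' @param Z observation matrix (rows = time steps); rows with `NA` are
#'   treated as missing (predict-only).
#' @param t optional time vector for the output.
#' @return data.frame of state estimates plus the normalised innovation
#'   squared (`nis`, `NA` on missing steps).
#' @export
kalman_filter <- function(km, Z, t = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  d <- length(km$x)
  X <- matrix(NA_real_, n, d)
  nis <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    zi <- Z[i, ]
    km <- kalman_step(km, if (any(is.na(zi))) NULL else zi)
    X[i, ] <- km$x
    if (!is.null(km$innovation)) {
      nis[i] <- as.numeric(t(km$innovation) %*% solve(km$S, km$innovation))
    }
  }
  out <- as.data.frame(X)
  names(out) <- paste0("x", seq_len(d))
  if (d == 4) names(out) <- c("x_deg", "y_deg", "vx", "vy")
  out$nis <- nis
  if (!is.null(t)) out <- cbind(t = t, out)
  out
}

deg2vec <- function(az, el) {
  az <- az * pi / 180
  el <- el * pi / 180
  c(cos(el) * sin(az), sin(el), cos(el) * cos(az))
}

angular_sep <- function(az1, el1, az2, el2) {
  v1 <- deg2vec(az1, el1)
  v2 <- deg2vec(az2, el2)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

#' Targets inside the gaze cone
#'
#' Scene targets whose direction from the cyclopean origin lies within
#' `half_angle` degrees of the (filtered) gaze direction, ranked by angular
#' offset. The printed "45-degree visual cone" is read as a 45-degree
#' half-angle; pass `half_angle = 22.5` for the full-angle reading.
#'
#' @param gaze c(azimuth, elevation) in degrees.
#' @param scene_spec data.frame (id, x, y, z) of target positions (m), or a
#'   data.frame with `az`, `el` columns already in degrees.
#' @param half_angle cone half-angle in degrees.
#' @return data.frame `id`, `offset` (deg), sorted by offset.
#' @export
cone_candidates <- function(gaze, scene_spec, half_angle = 45) {
  if (nrow(scene_spec) == 0) stop("scene must be non-empty")
  dirs <- if (all(c("az", "el") %in% names(scene_spec))) {
    scene_spec[c("id", "az", "el")]
  } else {
    target_directions(scene_spec)
  }
  off <- vapply(seq_len(nrow(dirs)), function(i) {
    angular_sep(gaze[1], gaze[2], dirs$az[i], dirs$el[i])
  }, numeric(1))
  out <- data.frame(id = dirs$id, offset = off)
  out <- out[out$offset <= half_angle, , drop = FALSE]
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PD gaze stabilisation
#'
#' Critically-to-over-damped second-order tracker of the raw gaze signal:
#' `s'' = omega^2 (raw - s) - 2 zeta omega s'` with `zeta = c / 0.65`, so
#' the calibrated damping range \[0.65, 0.85\] maps to `zeta` in
#' \[1.0, ~1.31\] (monotone step response, no overshoot). Higher damping
#' lowers the output velocity variance.
#'
#' @param gaze data.frame with `t`, `x_deg`, `y_deg` (e.g. a gaze stream).
#' @param c damping parameter; values outside \[0.65, 0.85\] are clamped
#'   with a warning.
#' @param omega natural frequency (rad/s) of the tracker.
#' @return data.frame `t`, `x_deg`, `y_deg` of the smoothed series.
#' @export
stabilize <- function(gaze, c = 0.75, omega = 4 * pi) {
  if (c < 0.65 || c > 0.85) {
    warning("damping outside calibrated range [0.65, 0.85]; clamping")
    c <- min(max(c, 0.65), 0.85)
  }
  zeta <- c / 0.65
  dt <- diff(gaze$t[1:2])
  smooth_axis <- function(raw) {
    n <- length(raw)
    s <- numeric(n)
    v <- 0
    s[1] <- raw[1]
    for (i in 2:n) {
      a <- omega^2 * (raw[i - 1] - s[i - 1]) - 2 * zeta * omega * v
      v <- v + a * dt
      s[i] <- s[i - 1] + v * dt
    }
    s
  }
  data.frame(t = gaze$t, x_deg = smooth_axis(gaze$x_deg),
             y_deg = smooth_axis(gaze$y_deg))
}

#' Spatial fixation probability map
#'
#' Histogram of gaze samples over an `bins x bins` grid spanning the
#' workspace projection, normalised to a probability distribution.
#'
#' @param gaze data.frame with `x_deg`, `y_deg` (invalid samples should be
#'   removed by the caller).
#' @param bins grid resolution per axis.
#' @param xlim,ylim workspace extent in degrees.
#' @return object of class `fixation_map` with the probability matrix `p`.
#' @export
fixation_map <- function(gaze, bins = 8, xlim = c(-30, 30), ylim = c(-30, 30)) {
  xb <- cut(pmin(pmax(gaze$x_deg, xlim[1]), xlim[2] - 1e-9),
            breaks = seq(xlim[1], xlim[2], length.out = bins + 1),
            include.lowest = TRUE)
  yb <- cut(pmin(pmax(gaze$y_deg, ylim[1]), ylim[2] - 1e-9),
            breaks = seq(ylim[1], ylim[2], length.out = bins + 1),
            include.lowest = TRUE)
  counts <- table(xb, yb)
  p <- counts / sum(counts)
  structure(list(p = as.matrix(p), bins = bins), class = "fixation_map")
}

#' Gaze entropy (nats)
#'
#' Shannon entropy `H_g = -sum p log p` of a fixation probability
#' distribution, with `0 log 0 = 0`. Natural logarithm, so the maximum over
#' `k` bins is `log(k)`.
#'
#' @param p a probability vector/matrix or a [fixation_map()].
#' @export
gaze_entropy <- function(p) {
  if (inherits(p, "fixation_map")) p <- p$p
  p <- as.numeric(p)
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  if (any(p < 0)) stop("probabilities must be non-negative")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Lock the gaze target at an accepted activation
#'
#' @param candidates a [cone_candidates()] ranking at activation time.
#' @param activation one row of an activation-events table (or a list with
#'   `time` and `accepted`).
#' @param half_angle cone half-angle used (recorded in the lock).
#' @return a `target_lock` list (`target`, `time`, `half_angle`, `offset`)
#'   or `NULL` when the activation was rejected or the cone is empty.
#' @export
lock_target <- function(candidates, activation, half_angle = 45) {
  if (!isTRUE(activation$accepted[1])) return(NULL)
  if (nrow(candidates) == 0) return(NULL)
  structure(
    list(target = candidates$id[1], time = activation$time[1],
         half_angle = half_angle, offset = candidates$offset[1]),
    class = "target_lock"
  )
}
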