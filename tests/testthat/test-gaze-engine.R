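test_that("kalman filter reaches the closed-form Riccati fixed point", {
  # scalar random walk: q = 0.01, r = 0.25
  q <- 0.01
  r <- 0.25
  km <- kalman_model(A = 1, H = 1, Q = q, R = r, x0 = 0, P0 = 1)
  set.seed(1)
  for (i in 1:400) km <- kalman_step(km, rnorm(1))
  v_star <- (-q + sqrt(q^2 + 4 * q * r)) / 2 # steady posterior variance
  gain <- (v_star + q) / (v_star + q + r)
  expect_equal(km$P[1, 1], v_star, tolerance = 1e-6)
  expect_equal(v_star, 0.0452494, tolerance = 1e-6)
  expect_equal(gain, 0.1810, tolerance = 1e-4)
})

test_that("kalman limiting behaviours", {
  # R -> 0: posterior mean -> observation
  km <- kalman_model(A = 1, H = 1, Q = 0.01, R = 1e-12, x0 = 0, P0 = 1)
  km <- kalman_step(km, 7.3)
  expect_equal(km$x, 7.3, tolerance = 1e-6)
  # constant observations: velocity estimate -> 0
  g <- gaze_kalman(1 / 120)
  for (i in 1:600) g <- kalman_step(g, c(5, -3))
  expect_equal(g$x[1:2], c(5, -3), tolerance = 1e-3)
  expect_equal(g$x[3:4], c(0, 0), tolerance = 1e-3)
  # missing observation: predict-only keeps the model running
  g2 <- kalman_step(g, NULL)
  expect_null(g2$innovation)
})

test_that("sequential filter equals the batch least-squares oracle", {
  set.seed(5)
  a <- 0.95
  q <- 0.04
  r <- 0.3
  z <- cumsum(rnorm(10)) + rnorm(10, sd = 0.5)
  km <- kalman_model(A = a, H = 1, Q = q, R = r, x0 = 0, P0 = 2)
  for (zi in z) km <- kalman_step(km, zi)
  ref <- oracle_batch_filter(a, 1, q, r, 0, 2, z)
  expect_equal(km$x, ref, tolerance = 1e-8)
})

test_that("filter is statistically consistent on model-generated data", {
  set.seed(11)
  dt <- 1 / 120
  g <- gaze_kalman(dt, x0 = c(0, 0, 0, 0), P0 = diag(1e-6, 4))
  x <- c(0, 0, 0, 0)
  A <- g$A
  Qc <- g$Q
  Lq <- chol(Qc + diag(1e-12, 4))
  n <- 2000
  Z <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    x <- as.numeric(A %*% x) + as.numeric(t(Lq) %*% rnorm(4))
    Z[i, ] <- x[1:2] + rnorm(2, sd = 0.5)
  }
  out <- kalman_filter(gaze_kalman(dt, P0 = diag(1e-2, 4)), Z)
  ratio <- mean(out$nis, na.rm = TRUE) / 2 # E[NIS] = obs dimension
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.5)
})

test_that("cone candidates are filtered and ranked by angular offset", {
  sc <- data.frame(id = 1:3, az = c(0, 10, 20), el = c(0, 0, 0))
  on_ray <- cone_candidates(c(0, 0), sc)
  expect_equal(on_ray$id[1], 1)
  expect_equal(on_ray$offset[1], 0)
  expect_equal(on_ray$id, c(1, 2, 3))
  far <- cone_candidates(c(0, 0), data.frame(id = 9, az = 50, el = 0))
  expect_equal(nrow(far), 0)
  edge <- cone_candidates(c(0, 0), data.frame(id = 9, az = 45, el = 0))
  expect_equal(nrow(edge), 1) # boundary inclusive
  # positions in metres are converted to directions
  pos <- cone_candidates(c(0, 0), data.frame(id = 1, x = 0, y = 0, z = 1))
  expect_equal(pos$offset, 0)
  expect_error(cone_candidates(c(0, 0), data.frame(id = integer(0), az = numeric(0), el = numeric(0))), "non-empty")
})

test_that("PD stabilisation is a smoothing fixed-point operator", {
  t <- seq(0, 3, by = 1 / 120)
  const <- data.frame(t = t, x_deg = 4, y_deg = -2)
  s <- stabilize(const, 0.75)
  expect_equal(s$x_deg, rep(4, length(t)))
  # step: monotone approach, no overshoot at default gains
  step <- data.frame(t = t, x_deg = ifelse(t > 0.5, 10, 0), y_deg = 0)
  st <- stabilize(step, 0.65)
  expect_lt(max(st$x_deg), 10 + 1e-6)
  expect_equal(st$x_deg[length(t)], 10, tolerance = 1e-3)
  late <- st$x_deg[t > 0.5]
  expect_true(all(diff(late) > -1e-9))
  # stronger damping lowers output velocity variance (same input)
  set.seed(3)
  noise <- data.frame(t = t, x_deg = rnorm(length(t)), y_deg = 0)
  v65 <- var(diff(stabilize(noise, 0.65)$x_deg))
  v85 <- var(diff(stabilize(noise, 0.85)$x_deg))
  expect_lt(v85, v65)
  expect_warning(stabilize(const, 0.5), "clamp")
})

test_that("gaze entropy satisfies its bounds and equality conditions", {
  one <- c(1, rep(0, 15))
  expect_equal(gaze_entropy(one), 0)
  expect_equal(gaze_entropy(rep(1 / 16, 16)), log(16))
  expect_equal(gaze_entropy(c(0.5, 0.5)), log(2))
  expect_error(gaze_entropy(c(0.5, 0.4)), "sum to 1")
  # map built from samples: entropy within [0, log(bins^2)]
  set.seed(4)
  g <- data.frame(x_deg = rnorm(2000, 0, 8), y_deg = rnorm(2000, 0, 8))
  fm <- fixation_map(g)
  h <- gaze_entropy(fm)
  expect_gte(h, 0)
  expect_lte(h, log(64))
})

test_that("target locking uses the rank-1 candidate of accepted activations", {
  cand <- data.frame(id = c(2, 3), offset = c(10, 20))
  lock <- lock_target(cand, list(time = 5, accepted = TRUE))
  expect_equal(lock$target, 2)
  expect_equal(lock$offset, 10)
  expect_null(lock_target(cand, list(time = 5, accepted = FALSE)))
  expect_null(lock_target(cand[0, ], list(time = 5, accepted = TRUE)))
})
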