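# Workload prediction and adaptation: exact Gaussian-process regression
# with a Matern-3/2 kernel mapping trial features (normalised duration,
# beta-band variance, gaze entropy) to a 0-100 workload score, plus the
# three interventions applied above 68/100 and the weighted task-complexity
# score.

#' Matern-3/2 covariance
#'
#' `k(r) = sigma2 (1 + sqrt(3) r / ell) exp(-sqrt(3) r / ell)`; sample
#' paths of the corresponding GP are once differentiable.
#'
#' @param r distance(s), >= 0 (vector or matrix).
#' @param sigma2 signal variance.
#' @param ell length-scale, > 0.
#' @export
matern32 <- function(r, sigma2 = 1, ell = 1) {
  stopifnot(all(r >= 0), ell > 0)
  s <- sqrt(3) * r / ell
  sigma2 * (1 + s) * exp(-s)
}

#' Fit an exact Matern-3/2 GP regression
#'
#' Features are standardised internally; hyperparameters (signal variance,
#' isotropic length-scale, noise variance) are chosen by maximising the log
#' marginal likelihood with multiple restarts. The prior mean is the sample
#' mean of the targets.
#'
#' @param X numeric matrix/data.frame of features (rows = observations).
#' @param y numeric targets (workload scores on 0-100).
#' @param noise if supplied, the noise variance is fixed at this value
#'   (on the scale of `y`) instead of being optimised; `0` is replaced by a
#'   small jitter for numerical stability.
#' @param restarts number of optimisation restarts.
#' @return object of class `gpr_model` (kernel parameters, standardisation
#'   constants, training data, fitted coefficients and training `r2`).
#' @export
gpr_fit <- function(X, y, noise = NULL, restarts = 3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 5) stop("need at least 5 training pairs")
  if (n != length(y)) stop("X and y size mismatch")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  mu <- mean(y)
  yc <- y - mu
  if (stats::sd(y) == 0) {
    model <- list(X = Xs, y = y, mu = mu, centre = ctr, scale = scl,
                  sigma2 = 0, ell = 1, noise = 0, alpha = rep(0, n),
                  L = NULL, r2 = NA_real_, constant = TRUE)
    class(model) <- "gpr_model"
    return(model)
  }
  D <- as.matrix(stats::dist(Xs))
  fixed_noise <- !is.null(noise)
  if (fixed_noise && noise <= 0) noise <- 1e-8
  nll <- function(par) {
    s2 <- exp(par[1]); ell <- exp(par[2])
    sn2 <- if (fixed_noise) noise else exp(par[3])
    K <- matern32(D, s2, ell) + diag(sn2 + 1e-8 * s2, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  vy <- stats::var(y)
  med_d <- stats::median(D[upper.tri(D)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  inits <- list(
    c(log(vy), log(med_d), log(0.1 * vy)),
    c(log(vy), log(0.3 * med_d), log(0.01 * vy)),
    c(log(0.5 * vy), log(3 * med_d), log(0.3 * vy))
  )[seq_len(max(1, restarts))]
  best <- NULL
  for (p0 in inits) {
    if (fixed_noise) p0 <- p0[1:2]
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B",
                   lower = rep(-15, length(p0)), upper = rep(15, length(p0))),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimisation failed")
  s2 <- exp(best$par[1]); ell <- exp(best$par[2])
  sn2 <- if (fixed_noise) noise else exp(best$par[3])
  K <- matern32(D, s2, ell) + diag(sn2 + 1e-8 * s2, n)
  L <- chol(K)
  if (any(!is.finite(diag(L)))) stop("kernel matrix singular after jitter")
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  pred <- mu + matern32(D, s2, ell) %*% alpha
  r2 <- 1 - sum((y - pred)^2) / sum((y - mu)^2)
  model <- list(X = Xs, y = y, mu = mu, centre = ctr, scale = scl,
                sigma2 = s2, ell = ell, noise = sn2, alpha = alpha, L = L,
                r2 = as.numeric(r2), constant = FALSE)
  class(model) <- "gpr_model"
  model
}

#' @export
print.gpr_model <- function(x, ...) {
  if (x$constant) {
    cat("gpr_model: constant targets; predictions constant, R^2 undefined\n")
  } else {
    cat(sprintf(
      "gpr_model: n = %d | sigma2 = %.3g | length-scale = %.3g | noise = %.3g | training R^2 = %.3f\n",
      nrow(x$X), x$sigma2, x$ell, x$noise, x$r2
    ))
  }
  invisible(x)
}

cross_dist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' GP posterior prediction
#'
#' @param object fitted [gpr_fit()] model.
#' @param newdata feature matrix/data.frame on the original scale.
#' @param clamp clamp the reported posterior mean to \[0, 100\] (the
#'   workload scale); the SD is never clamped.
#' @param ... unused.
#' @return data.frame with `mean` and `sd` (latent posterior SD).
#' @export
predict.gpr_model <- function(object, newdata, clamp = TRUE, ...) {
  Xn <- as.matrix(newdata)
  storage.mode(Xn) <- "double"
  Xs <- sweep(sweep(Xn, 2, object$centre), 2, object$scale, "/")
  if (object$constant) {
    return(data.frame(mean = rep(object$mu, nrow(Xs)), sd = 0))
  }
  Ks <- matern32(cross_dist(Xs, object$X), object$sigma2, object$ell)
  mean <- object$mu + as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(object$sigma2 - colSums(V^2), 0)
  if (clamp) mean <- pmin(pmax(mean, 0), 100)
  data.frame(mean = mean, sd = sqrt(var))
}

#' Adaptation state under the high-workload interventions
#'
#' @param active logical; when active the three interventions are set:
#'   threshold multiplier 1.2, virtual-hand speed cap 0.4 m/s (80% of the
#'   0.5 m/s baseline), stabilising stiffness 2.5 N/mm. Inactive restores
#'   all defaults.
#' @export
adaptation_state <- function(active = FALSE) {
  structure(
    if (active) {
      list(active = TRUE, threshold_multiplier = 1.2, vmax = 0.4, stiffness = 2.5)
    } else {
      list(active = FALSE, threshold_multiplier = 1.0, vmax = 0.5, stiffness = 0)
    },
    class = "adaptation_state"
  )
}

#' Apply the workload-triggered interventions with hysteresis
#'
#' Interventions engage when the predicted workload exceeds `on` (68/100)
#' and release only when it falls below `off` (63 = 68 - 5); inside the
#' band the previous state is held, preventing chattering around the
#' threshold. Idempotent: applying the same score twice yields the same
#' state.
#'
#' @param tlx predicted workload score in \[0, 100\].
#' @param state previous [adaptation_state()].
#' @param on,off engage/release thresholds.
#' @export
adapt_interventions <- function(tlx, state = adaptation_state(),
                                on = 68, off = 63) {
  stopifnot(tlx >= 0, tlx <= 100, off <= on)
  if (tlx > on) {
    adaptation_state(TRUE)
  } else if (tlx < off) {
    adaptation_state(FALSE)
  } else {
    state
  }
}

#' Weighted task-complexity score
#'
#' `C = 0.5 (dx / 1.8) + 0.3 (H_g / h_max) + 0.2 (n_d / n_max)` with each
#' term clamped to \[0, 1\], so C lies in \[0, 1\] and the weights sum
#' to 1. Pass `normalized = FALSE` for the raw unnormalised mixture
#' `0.5 dx + 0.3 H_g + 0.2 n_d` (mixed units; comparable only within one
#' scene).
#'
#' @param dx target displacement in metres (0-1.8 m workspace).
#' @param h_g gaze entropy (nats).
#' @param n_d distractor count.
#' @param h_max,n_max normalising maxima for entropy and distractors.
#' @param dx_max workspace displacement bound (m).
#' @param weights the three mixture weights.
#' @param normalized normalise each term to \[0, 1\] before weighting.
#' @export
task_complexity <- function(dx, h_g, n_d, h_max = log(64), n_max = 5,
                            dx_max = 1.8, weights = c(0.5, 0.3, 0.2),
                            normalized = TRUE) {
  stopifnot(dx >= 0, dx <= dx_max, n_d >= 0)
  if (!normalized) {
    return(weights[1] * dx + weights[2] * h_g + weights[3] * n_d)
  }
  if (h_max <= 0 || n_max <= 0 || dx_max <= 0) stop("normalisers must be positive")
  cl <- function(x) pmin(pmax(x, 0), 1)
  weights[1] * cl(dx / dx_max) + weights[2] * cl(h_g / h_max) +
    weights[3] * cl(n_d / n_max)
}

#' Per-trial workload features
#'
#' The three predictors of the workload model: normalised task duration
#' (completion time over the nominal trial length), variance of the
#' 15-22 Hz beta-band power over 2-s sliding windows, and gaze entropy of
#' the fixation map.
#'
#' @param eeg_stream raw EEG [sample_stream()].
#' @param gaze_stream gaze [sample_stream()] (invalid samples dropped).
#' @param completion_time task completion time (s).
#' @param nominal nominal trial duration (s).
#' @return one-row data.frame `norm_duration`, `beta_var`, `h_g`.
#' @export
load_features <- function(eeg_stream, gaze_stream, completion_time,
                          nominal = 60) {
  fs <- stream_rate(eeg_stream)
  dur <- stream_duration(eeg_stream)
  filt <- bandpass_detrend(eeg_stream)
  starts <- seq(0, dur - 2, by = 1)
  bp <- vapply(starts, function(s) {
    idx <- (round(s * fs) + 1):round((s + 2) * fs)
    sp <- welch_psd(filt$uv[idx], fs)
    df <- sp$freq[2] - sp$freq[1]
    sum(sp$psd[sp$freq >= 15 & sp$freq < 22]) * df
  }, numeric(1))
  g <- gaze_stream[gaze_stream$valid, ]
  data.frame(
    norm_duration = completion_time / nominal,
    beta_var = stats::var(bp),
    h_g = gaze_entropy(fixation_map(g))
  )
}

#' Synthetic workload study generator
#'
#' Generates `n` trials whose workload score is a linear function of the
#' three standardised predictors plus Gaussian noise with SD equal to
#' `sigma_frac` of the noiseless score SD. Used to characterise what the
#' GP model can recover under a known ground truth.
#'
#' @param n number of trials.
#' @param seed RNG seed.
#' @param sigma_frac noise SD as a fraction of the signal SD.
#' @return list with `X` (features), `y` (scores) and `y_true`.
#' @export
simulate_workload_study <- function(n = 160, seed = 1, sigma_frac = 0.15) {
  withr::with_seed(sub_seed(seed, 900), {
    X <- data.frame(
      norm_duration = runif(n, 0.5, 1.5),
      beta_var = exp(rnorm(n, 0, 0.6)),
      h_g = runif(n, 0.2, 2.8)
    )
    zs <- scale(as.matrix(X))
    y_true <- as.numeric(50 + 10 * zs[, 1] + 8 * zs[, 2] + 12 * zs[, 3])
    y <- y_true + rnorm(n, 0, sigma_frac * stats::sd(y_true))
    y <- pmin(pmax(y, 0), 100)
    list(X = X, y = y, y_true = y_true)
  })
}

#' Draw noisy samples from a known Matern-3/2 GP
#'
#' One-dimensional inputs on \[0, 5\]; used for length-scale recovery
#' checks.
#'
#' @param n sample size.
#' @param ell,sigma2 true kernel parameters.
#' @param noise_sd observation noise SD.
#' @param seed RNG seed.
#' @export
simulate_matern_gp <- function(n = 120, ell = 0.5, sigma2 = 4,
                               noise_sd = 0.2, seed = 1) {
  withr::with_seed(sub_seed(seed, 901), {
    x <- sort(runif(n, 0, 5))
    K <- matern32(as.matrix(stats::dist(x)), sigma2, ell) + diag(1e-8, n)
    L <- chol(K)
    f <- as.numeric(t(L) %*% rnorm(n))
    list(X = matrix(x, ncol = 1), y = f + rnorm(n, 0, noise_sd), f = f)
  })
}
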