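# Softmax control-authority arbitration between the manual and virtual
# channels, with unconditional manual priority on spatial overlap.

#' Arbitration configuration
#'
#' @param a confidence gain on the modality confidence epsilon (unitless).
#' @param b stabilisation gain per second of dwell/stability time.
#' @param overlap_radius manual-override radius around the virtual hand's
#'   engagement point (m).
#' @param eps_manual manual channel confidence (tracking validity; 1 when
#'   the controllers are tracked).
#' @param t_cap cap (s) on the stabilisation times.
#' @export
arbitration_config <- function(a = 4.0, b = 1.0, overlap_radius = 0.10,
                               eps_manual = 1.0, t_cap = 2.0) {
  stopifnot(a > 0, b > 0, overlap_radius > 0)
  structure(list(a = a, b = b, overlap_radius = overlap_radius,
                 eps_manual = eps_manual, t_cap = t_cap),
            class = "arbitration_config")
}

#' Softmax authority weights
#'
#' `w_m = exp(a eps_m + b t_m) / sum_m exp(a eps_m + b t_m)` over the two
#' modalities (manual, virtual). Confidences are clamped to \[0, 1\] and
#' times to \[0, t_cap\] with a warning.
#'
#' @param eps_bci BCI confidence in \[0, 1\].
#' @param t_gaze gaze dwell time on the locked target (s), in \[0, t_cap\].
#' @param eps_manual,t_manual manual channel confidence and capped
#'   time-since-motion (s).
#' @param cfg an [arbitration_config()].
#' @return named numeric `c(manual, virtual)`, summing to 1.
#' @export
authority_weights <- function(eps_bci, t_gaze, eps_manual = 1, t_manual = 0,
                              cfg = arbitration_config()) {
  clamp <- function(x, lo, hi, what) {
    if (x < lo || x > hi) {
      warning(what, " clamped to [", lo, ", ", hi, "]")
      x <- min(max(x, lo), hi)
    }
    x
  }
  eps_bci <- clamp(eps_bci, 0, 1, "eps_bci")
  eps_manual <- clamp(eps_manual, 0, 1, "eps_manual")
  t_gaze <- clamp(t_gaze, 0, cfg$t_cap, "t_gaze")
  t_manual <- clamp(t_manual, 0, cfg$t_cap, "t_manual")
  s <- c(manual = cfg$a * eps_manual + cfg$b * t_manual,
         virtual = cfg$a * eps_bci + cfg$b * t_gaze)
  e <- exp(s - max(s)) # stable softmax
  e / sum(e)
}

#' Resolve the controller of the virtual hand for one tick
#'
#' Manual override applies unconditionally whenever any tracked hand is
#' within `overlap_radius` of the virtual hand's engagement point,
#' regardless of the weights. Otherwise the virtual channel is active iff
#' `w_virtual > 0.5`; an exact tie resolves to manual.
#'
#' @param weights output of [authority_weights()].
#' @param hand_positions matrix (hands x 3) of manual hand positions (m).
#' @param virtual_point virtual hand engagement point (m).
#' @param cfg an [arbitration_config()].
#' @param time tick time (s), recorded in the state.
#' @return an `authority_state` list: `time`, `weights`, `overlap`,
#'   `controller` ("manual-override", "virtual" or "manual").
#' @export
resolve_authority <- function(weights, hand_positions, virtual_point,
                              cfg = arbitration_config(), time = NA_real_) {
  hp <- matrix(hand_positions, ncol = 3)
  d <- sqrt(rowSums((hp - matrix(virtual_point, nrow(hp), 3, byrow = TRUE))^2))
  overlap <- any(d < cfg$overlap_radius)
  controller <- if (overlap) {
    "manual-override"
  } else if (weights[["virtual"]] > 0.5) {
    "virtual"
  } else {
    "manual"
  }
  structure(
    list(time = time, weights = weights, overlap = overlap,
         controller = controller, min_distance = min(d)),
    class = "authority_state"
  )
}

#' Handover latencies from an authority trace
#'
#' For every controller flip, the latency is the time from the earliest
#' tick at which the flip's preconditions held continuously (column
#' `precond`) to the flip tick. Flips whose preconditions did not hold are
#' skipped.
#'
#' @param trace data.frame at a fixed tick rate with columns `t`,
#'   `controller` and logical `precond`.
#' @return numeric vector of latencies (s); empty when there are no flips.
#' @export
handover_latency <- function(trace) {
  n <- nrow(trace)
  if (n < 2) return(numeric(0))
  flips <- which(trace$controller[-1] != trace$controller[-n]) + 1
  out <- numeric(0)
  for (i in flips) {
    if (!isTRUE(trace$precond[i])) next
    j <- i
    while (j > 1 && isTRUE(trace$precond[j - 1])) j <- j - 1
    out <- c(out, trace$t[i] - trace$t[j])
  }
  out
}
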