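#' Segment a trajectory into waiting and sudden-movement phases
#'
#' Fish (and fish-like stimuli) alternate between staying near one spot and
#' dashing to a new location. The segmentation is a greedy left-to-right
#' anchored scan: a candidate waiting phase opens at the current sample
#' (which becomes its anchor) and extends while every sample stays within
#' `radius_px` of the anchor; the candidate is committed as a WAIT phase iff
#' it spans at least `min_wait_s` seconds, otherwise its samples are merged
#' into the surrounding MOVE phase. Phases tile the trajectory's time span
#' exactly, with shared boundaries at sample times.
#'
#' @param traj A [trajectory()].
#' @param radius_px Waiting-phase radius in pixels (default 60, the radius
#'   used to segment the aquarium recordings).
#' @param min_wait_s Minimum duration of a committed waiting phase, in
#'   seconds. Default 0.2 s, which at 25-30 Hz prevents single-frame "waits".
#' @return A data frame of class `fm_phases`, one row per phase, columns
#'   `kind` ("WAIT"/"MOVE"), `t_start`, `t_end`, `anchor_x`, `anchor_y`
#'   (WAIT only), `distance` (px, MOVE path length), `mean_velocity` (px/s),
#'   `direction` (radians, atan2 of net displacement; MOVE only).
#' @export
#' @examples
#' tr <- trajectory("still", t = seq(0, 10, by = 0.1),
#'                  x = rep(100, 101), y = rep(100, 101))
#' segment_trajectory(tr, radius_px = 60)
segment_trajectory <- function(traj, radius_px = 60, min_wait_s = 0.2) {
  if (!inherits(traj, "fm_trajectory")) {
    stop("invalid input: not a trajectory", call. = FALSE)
  }
  if (nrow(traj) < 2L) stop("invalid input: < 2 samples", call. = FALSE)
  if (any(diff(traj$t) <= 0)) {
    stop("invalid input: non-monotone time", call. = FALSE)
  }
  if (radius_px <= 0) stop("invalid input: radius_px must be > 0", call. = FALSE)
  if (min_wait_s < 0) stop("invalid input: min_wait_s must be >= 0", call. = FALSE)

  t <- traj$t; x <- traj$x; y <- traj$y; n <- length(t)
  waits <- list()  # committed WAIT index ranges [i, j]
  i <- 1L
  while (i <= n) {
    # extend candidate anchored at sample i
    j <- i
    while (j < n && (x[j + 1L] - x[i])^2 + (y[j + 1L] - y[i])^2 <= radius_px^2) {
      j <- j + 1L
    }
    if (j > i && (t[j] - t[i]) >= min_wait_s) {
      waits[[length(waits) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  phases_from_waits(traj, waits)
}

# Build the tiling phase table from a list of WAIT index ranges.
phases_from_waits <- function(traj, waits) {
  t <- traj$t; x <- traj$x; y <- traj$y; n <- length(t)
  step_len <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  cum_len <- cumsum(step_len)

  move_row <- function(i, j) {
    dist <- cum_len[j] - cum_len[i]
    dur <- t[j] - t[i]
    data.frame(kind = "MOVE", t_start = t[i], t_end = t[j],
               anchor_x = NA_real_, anchor_y = NA_real_,
               distance = dist, mean_velocity = dist / dur,
               direction = atan2(y[j] - y[i], x[j] - x[i]))
  }
  wait_row <- function(i, j) {
    data.frame(kind = "WAIT", t_start = t[i], t_end = t[j],
               anchor_x = x[i], anchor_y = y[i],
               distance = NA_real_, mean_velocity = NA_real_,
               direction = NA_real_)
  }

  rows <- list()
  prev_end <- 1L  # index where the previous phase ended
  for (w in waits) {
    if (w[1] > prev_end) rows[[length(rows) + 1L]] <- move_row(prev_end, w[1])
    rows[[length(rows) + 1L]] <- wait_row(w[1], w[2])
    prev_end <- w[2]
  }
  if (prev_end < n) rows[[length(rows) + 1L]] <- move_row(prev_end, n)
  out <- do.call(rbind, rows)
  attr(out, "object_id") <- attr(traj, "object_id")
  class(out) <- c("fm_phases", "data.frame")
  out
}

#' Summarize the phases of one or more trajectories
#'
#' Pools the kinematic summaries the motion model is fitted to: waiting
#' durations, dash distances, dash mean velocities, dash directions, and the
#' fraction of total time spent waiting vs. moving.
#'
#' @param phases An `fm_phases` data frame (or an rbind of several).
#' @return A list of class `fm_phase_summaries` with elements
#'   `wait_durations` (s), `dash_distances` (px), `dash_velocities` (px/s),
#'   `dash_directions` (rad), `time_fraction_wait`, `time_fraction_move`.
#' @export
summarize_phases <- function(phases) {
  if (is.null(phases) || nrow(phases) == 0L) {
    stop("invalid input: empty phase list", call. = FALSE)
  }
  dur <- phases$t_end - phases$t_start
  is_wait <- phases$kind == "WAIT"
  total <- sum(dur)
  out <- list(
    wait_durations = dur[is_wait],
    dash_distances = phases$distance[!is_wait],
    dash_velocities = phases$mean_velocity[!is_wait],
    dash_directions = phases$direction[!is_wait],
    time_fraction_wait = sum(dur[is_wait]) / total,
    time_fraction_move = sum(dur[!is_wait]) / total
  )
  class(out) <- "fm_phase_summaries"
  out
}

#' Maximum-likelihood fit of a two-parameter gamma distribution
#'
#' Fits shape k and scale theta by maximum likelihood (location fixed at 0).
#' The shape solves `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` by
#' safeguarded Newton iteration (bisection fallback); the scale is
#' `mean(x) / k` at the optimum.
#'
#' @param samples Positive numeric vector, length >= 3.
#' @return A list of class `fm_gamma_fit`: `shape`, `scale`, `n`, `loglik`.
#' @export
#' @examples
#' set.seed(1)
#' fit_gamma_mle(rgamma(500, shape = 2, scale = 3))
fit_gamma_mle <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 3L) stop("invalid input: need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("invalid input: samples must be positive and finite", call. = FALSE)
  }
  m <- mean(x)
  s <- log(m) - mean(log(x))  # > 0 unless all samples equal
  if (s < 1e-12 || stats::var(x) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  # Minka-style closed-form start, then Newton on f(k) = log k - psi(k) - s
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  lo <- 1e-8; hi <- k
  while (log(hi) - digamma(hi) > s) hi <- hi * 2  # bracket: f(hi) < 0
  for (iter in 1:100) {
    f <- log(k) - digamma(k) - s
    if (f > 0) lo <- max(lo, k) else hi <- min(hi, k)
    step <- f / (1 / k - trigamma(k))
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi) k_new <- (lo + hi) / 2
    if (abs(k_new - k) < 1e-12 * k) { k <- k_new; break }
    k <- k_new
  }
  theta <- m / k
  ll <- sum(stats::dgamma(x, shape = k, scale = theta, log = TRUE))
  structure(list(shape = k, scale = theta, n = length(x), loglik = ll),
            class = "fm_gamma_fit")
}

#' @export
print.fm_gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma MLE: shape = %.4f, scale = %.4f (n = %d, loglik = %.2f)\n",
              x$shape, x$scale, x$n, x$loglik))
  invisible(x)
}

#' Fit a fish motion model to a set of trajectories
#'
#' Segments every trajectory ([segment_trajectory()]), pools the phase
#' summaries, and fits gamma laws to waiting durations, dash distances and
#' dash mean velocities. Dash directions are recorded but modelled as
#' uniform on [0, 2*pi) at generation time.
#'
#' @inheritParams segment_trajectory
#' @param trajs A list of trajectories (or a single trajectory).
#' @param jitter_radius Positional jitter radius of the waiting phase, px.
#'   Must not exceed `radius_px`.
#' @return An object of class `fm_motion_model` with elements
#'   `wait_duration`, `dash_distance`, `dash_velocity` (each an
#'   `fm_gamma_fit` or a `list(shape, scale)`), `jitter_radius`,
#'   `direction_rule` ("uniform"), and the pooled `summaries`.
#' @export
fit_motion_model <- function(trajs, radius_px = 60, min_wait_s = 0.2,
                             jitter_radius = 10) {
  if (inherits(trajs, "fm_trajectory")) trajs <- list(trajs)
  if (length(trajs) < 1L) stop("invalid input: no trajectories", call. = FALSE)
  if (jitter_radius > radius_px) {
    stop("invalid input: jitter_radius must be <= radius_px", call. = FALSE)
  }
  ph <- do.call(rbind, lapply(trajs, segment_trajectory,
                              radius_px = radius_px, min_wait_s = min_wait_s))
  sm <- summarize_phases(ph)
  if (length(sm$wait_durations) < 3L || length(sm$dash_distances) < 3L) {
    stop("insufficient data: need >= 3 phases of each kind", call. = FALSE)
  }
  motion_model(
    wait_duration = fit_gamma_mle(sm$wait_durations),
    dash_distance = fit_gamma_mle(sm$dash_distances),
    dash_velocity = fit_gamma_mle(sm$dash_velocities),
    jitter_radius = jitter_radius,
    summaries = sm
  )
}

#' Construct a fish motion model
#'
#' Three gamma laws plus waiting-phase jitter and the dash-direction rule.
#' Used both as the output of [fit_motion_model()] and as the generative
#' input of [simulate_fishlike()].
#'
#' @param wait_duration,dash_distance,dash_velocity Gamma laws, each either
#'   an `fm_gamma_fit` or a `list(shape =, scale =)`; units s, px, px/s.
#' @param jitter_radius Waiting-phase jitter radius in px.
#' @param direction_rule Dash direction rule; only `"uniform"` is defined.
#' @param summaries Optional pooled `fm_phase_summaries` the fits came from.
#' @export
motion_model <- function(wait_duration, dash_distance, dash_velocity,
                         jitter_radius = 10, direction_rule = "uniform",
                         summaries = NULL) {
  chk <- function(g, what) {
    if (!is.list(g) || is.null(g$shape) || is.null(g$scale) ||
        g$shape <= 0 || g$scale <= 0) {
      stop("invalid gamma law for ", what, call. = FALSE)
    }
    g
  }
  structure(list(
    wait_duration = chk(wait_duration, "wait_duration"),
    dash_distance = chk(dash_distance, "dash_distance"),
    dash_velocity = chk(dash_velocity, "dash_velocity"),
    jitter_radius = jitter_radius,
    direction_rule = match.arg(direction_rule, "uniform"),
    summaries = summaries
  ), class = "fm_motion_model")
}

#' Default fish-like motion model
#'
#' Generative defaults chosen so that simulated objects spend about 19% of
#' the time waiting and 81% moving, the split observed in the aquarium
#' recordings: waiting durations Gamma(shape 2, scale 0.2) s (mean 0.4 s),
#' dash distances Gamma(3, 200) px (mean 600 px), dash velocities
#' Gamma(12, 30) px/s (mean 360 px/s), so a mean dash lasts about 1.8 s
#' and the expected waiting-time fraction is 0.4 / (0.4 + 1.8) = 0.18.
#'
#' @export
default_motion_model <- function() {
  motion_model(
    wait_duration = list(shape = 2, scale = 0.2),
    dash_distance = list(shape = 3, scale = 200),
    dash_velocity = list(shape = 12, scale = 30),
    jitter_radius = 10
  )
}

#' @export
print.fm_motion_model <- function(x, ...) {
  g <- function(f) sprintf("Gamma(%.3f, %.3f)", f$shape, f$scale)
  cat("Fish motion model\n",
      "  wait duration [s]:    ", g(x$wait_duration), "\n",
      "  dash distance [px]:   ", g(x$dash_distance), "\n",
      "  dash velocity [px/s]: ", g(x$dash_velocity), "\n",
      "  jitter radius [px]:   ", x$jitter_radius, "\n", sep = "")
  invisible(x)
}

#' Export phase tables to CSV
#'
#' Writes `object_id,kind,t_start,t_end,distance,mean_velocity,direction`.
#'
#' @param phases An `fm_phases` table or a list of them.
#' @param path Output CSV path.
#' @export
write_phases <- function(phases, path) {
  if (inherits(phases, "fm_phases")) phases <- list(phases)
  df <- do.call(rbind, lapply(phases, function(p) {
    data.frame(object_id = attr(p, "object_id") %||% NA_character_,
               kind = p$kind, t_start = p$t_start, t_end = p$t_end,
               distance = p$distance, mean_velocity = p$mean_velocity,
               direction = p$direction)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
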