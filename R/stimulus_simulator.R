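#' Arena and simulation configuration
#'
#' The circular tracking arena: 800 px diameter by default, centered in a
#' 960x600 px scene, matching the area of fish motion in the aquarium
#' videos as displayed on screen.
#'
#' @param center Arena center (x, y) in px. Defaults to the scene center.
#' @param diameter Arena diameter in px (default 800).
#' @param scene_extent Scene (width, height) in px (default c(960, 600)).
#'   The simulators only use the circle; the extent is kept as metadata and
#'   only checked when the circle is meant to fit on screen
#'   (`check_fit = TRUE`).
#' @param check_fit Require the circle to fit inside the scene extent.
#' @export
arena_spec <- function(center = NULL, diameter = 800,
                       scene_extent = c(960, 600), check_fit = FALSE) {
  if (diameter <= 0) stop("invalid arena: diameter must be > 0", call. = FALSE)
  if (is.null(center)) center <- scene_extent / 2
  if (check_fit && diameter > min(scene_extent)) {
    stop("invalid arena: circle does not fit in scene_extent", call. = FALSE)
  }
  structure(list(center = as.numeric(center), diameter = diameter,
                 scene_extent = as.numeric(scene_extent)),
            class = "fm_arena")
}

#' @rdname arena_spec
#' @param n_objects Number of objects (>= 1).
#' @param duration Trial duration in s (default 10, the moving-phase length).
#' @param dt Sampling step in s (default 1/30; 30 Hz).
#' @param speed Constant speed for ballistic motion, px/s (default 200).
#' @param object_radius Object radius in px (default 15; circles subtending
#'   about one degree of visual angle).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   trajectories.
#' @export
sim_config <- function(n_objects = 8, duration = 10, dt = 1 / 30,
                       speed = 200, object_radius = 15, seed = 1) {
  if (n_objects < 1) stop("invalid config: n_objects >= 1", call. = FALSE)
  if (duration <= 0 || dt <= 0 || speed <= 0) {
    stop("invalid config: duration, dt, speed must be > 0", call. = FALSE)
  }
  structure(list(n_objects = as.integer(n_objects), duration = duration,
                 dt = dt, speed = speed, object_radius = object_radius,
                 seed = seed),
            class = "fm_sim_config")
}

# Rejection-sample non-overlapping initial positions, uniform in the disc of
# radius r_eff around the arena center.
init_positions <- function(arena, cfg, r_eff) {
  n <- cfg$n_objects
  if (n * cfg$object_radius^2 > 0.6 * (arena$diameter / 2)^2) {
    stop("packing error: objects cover more than 60% of the arena",
         call. = FALSE)
  }
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      u <- stats::runif(1); a <- stats::runif(1, 0, 2 * pi)
      p <- arena$center + sqrt(u) * r_eff * c(cos(a), sin(a))
      ok <- TRUE
      if (i > 1) {
        d2 <- (pos[seq_len(i - 1), 1] - p[1])^2 +
              (pos[seq_len(i - 1), 2] - p[2])^2
        ok <- all(d2 >= (2 * cfg$object_radius)^2)
      }
      if (ok) { pos[i, ] <- p; break }
    }
    if (anyNA(pos[i, ])) {
      stop("packing error: could not place objects without overlap",
           call. = FALSE)
    }
  }
  pos
}

#' Simulate traditional ballistic MOT trajectories
#'
#' Objects move at constant speed inside the circular arena, reflecting
#' specularly off the border and bouncing off each other. Bounces are
#' resolved at the sampling boundaries, before each step is taken: if the
#' straight continuation of a step would cross the border, the velocity is
#' mirrored about the circle normal at the crossing point; if it would
#' bring a pair of objects into contact, their velocity components along
#' the line of centers are exchanged (elastic, equal masses) and each
#' velocity is rescaled to the configured speed. Every sampled step
#' displacement therefore equals exactly `speed * dt`, instantaneous speed
#' is conserved to machine precision, and objects never interpenetrate at
#' sample times.
#'
#' @param arena An [arena_spec()].
#' @param cfg A [sim_config()].
#' @param collisions Handle object-object bounces (TRUE for the traditional
#'   MOT condition).
#' @return A list of [trajectory()] objects, one per object.
#' @export
simulate_ballistic <- function(arena, cfg, collisions = TRUE) {
  with_seed(cfg$seed, {
    r_eff <- arena$diameter / 2 - cfg$object_radius
    if (r_eff <= 0) stop("invalid config: object larger than arena", call. = FALSE)
    n <- cfg$n_objects
    pos <- init_positions(arena, cfg, r_eff)
    ang <- stats::runif(n, 0, 2 * pi)
    vel <- cfg$speed * cbind(cos(ang), sin(ang))

    n_steps <- ceiling(cfg$duration / cfg$dt)
    times <- (0:n_steps) * cfg$dt
    X <- array(NA_real_, c(n_steps + 1L, n, 2))
    X[1, , ] <- pos
    ctr <- arena$center
    two_r <- 2 * cfg$object_radius
    for (s in seq_len(n_steps)) {
      # resolve all imminent border and pairwise bounces, then move
      for (sweep in 1:20) {
        changed <- FALSE
        for (i in seq_len(n)) {
          v_new <- reflect_at_border(pos[i, ], vel[i, ], cfg$dt, ctr, r_eff)
          if (any(v_new != vel[i, ])) { vel[i, ] <- v_new; changed <- TRUE }
        }
        if (collisions && n > 1) {
          for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            pi2 <- pos[i, ] + vel[i, ] * cfg$dt
            pj2 <- pos[j, ] + vel[j, ] * cfg$dt
            if (sum((pj2 - pi2)^2) < two_r^2) {
              dvec <- pos[j, ] - pos[i, ]
              d <- sqrt(sum(dvec^2))
              if (d == 0) next
              nhat <- dvec / d
              vi_n <- sum(vel[i, ] * nhat); vj_n <- sum(vel[j, ] * nhat)
              if (vi_n - vj_n > 0) {  # approaching: exchange and rescale
                vi <- vel[i, ] + (vj_n - vi_n) * nhat
                vj <- vel[j, ] + (vi_n - vj_n) * nhat
                vel[i, ] <- vi / sqrt(sum(vi^2)) * cfg$speed
                vel[j, ] <- vj / sqrt(sum(vj^2)) * cfg$speed
                changed <- TRUE
              }
            }
          }
        }
        if (!changed) break
      }
      pos <- pos + vel * cfg$dt
      X[s + 1L, , ] <- pos
    }
    lapply(seq_len(n), function(i) {
      trajectory(sprintf("obj%02d", i), times, X[, i, 1], X[, i, 2],
                 frame_rate = 1 / cfg$dt)
    })
  })
}

# Reflect v (specular, possibly repeatedly) so that p + v*dt stays inside
# the circle (center ctr, radius r). |v| is preserved exactly; as a final
# guard v is turned inward along the radial direction.
reflect_at_border <- function(p, v, dt, ctr, r) {
  speed <- sqrt(sum(v^2))
  for (guard in 1:8) {
    q <- p + v * dt
    if (sum((q - ctr)^2) <= r^2) return(v)
    w <- p - ctr
    a <- sum(v^2); b <- 2 * sum(w * v); cc <- sum(w^2) - r^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) break
    s <- (-b + sqrt(disc)) / (2 * a)
    hit <- p + v * pmax(pmin(s, dt), 0)
    nhat <- (hit - ctr) / sqrt(sum((hit - ctr)^2))
    v <- v - 2 * sum(v * nhat) * nhat
  }
  q <- p + v * dt
  if (sum((q - ctr)^2) > r^2) {
    w <- p - ctr
    nw <- sqrt(sum(w^2))
    v <- if (nw > 0) -w / nw * speed else c(speed, 0)
  }
  v
}

#' Simulate fish-like (wait/dash) MOT trajectories
#'
#' Each object alternates waiting phases (duration drawn from the model's
#' waiting gamma; the position jitters around the anchor by clipped Gaussian
#' steps inside `jitter_radius`) with straight-line dashes (distance and
#' mean velocity drawn from their gamma laws, direction uniform on
#' [0, 2*pi), resampled until the dash endpoint lies inside the arena, at
#' most 100 times, after which the distance is truncated at the border).
#' There is no object-object collision handling, mirroring the fact that
#' real fish pass each other freely.
#'
#' @param arena An [arena_spec()].
#' @param model An [motion_model()].
#' @param cfg A [sim_config()] (its `speed` field is ignored here).
#' @return A list of [trajectory()] objects. The generating phase schedule
#'   is attached to each as attribute `"phases"` (columns `kind`,
#'   `t_start`, `t_end`, `distance`, `velocity`, `direction`), useful as
#'   ground truth for segmentation round trips.
#' @export
simulate_fishlike <- function(arena, model, cfg) {
  stopifnot(inherits(model, "fm_motion_model"))
  with_seed(cfg$seed, {
    r_eff <- arena$diameter / 2
    ctr <- arena$center
    n_steps <- ceiling(cfg$duration / cfg$dt)
    times <- (0:n_steps) * cfg$dt
    lapply(seq_len(cfg$n_objects), function(i) {
      sim_one_fishlike(i, arena, model, cfg, times, ctr, r_eff)
    })
  })
}

#' Waiting-time fraction of simulated fish-like trajectories
#'
#' Pools either the generator's own phase schedules (ground truth) or the
#' phases recovered by [segment_trajectory()] and returns the fraction of
#' total time spent waiting. The schedule route is exact; the segmentation
#' route inherits the discretization of the sampled trajectory and, for
#' dashes slower than roughly `radius_px / min_wait_s`, classifies parts of
#' a dash as waiting.
#'
#' @param trajs List of trajectories from [simulate_fishlike()].
#' @param source `"schedule"` (default) or `"segmentation"`.
#' @param ... Passed to [segment_trajectory()] for the segmentation route.
#' @export
wait_time_fraction <- function(trajs, source = c("schedule", "segmentation"),
                               ...) {
  source <- match.arg(source)
  if (source == "schedule") {
    tot <- 0; wt <- 0
    for (tr in trajs) {
      sched <- attr(tr, "phases")
      if (is.null(sched)) stop("trajectory has no phase schedule", call. = FALSE)
      t_max <- tr$t[nrow(tr)]
      dur <- pmin(sched$t_end, t_max) - pmin(sched$t_start, t_max)
      tot <- tot + sum(dur)
      wt <- wt + sum(dur[sched$kind == "WAIT"])
    }
    wt / tot
  } else {
    sm <- summarize_phases(do.call(rbind, lapply(trajs, segment_trajectory, ...)))
    sm$time_fraction_wait
  }
}

sim_one_fishlike <- function(i, arena, model, cfg, times, ctr, r_eff) {
  # start at a uniform point in the disc
  u <- stats::runif(1); a0 <- stats::runif(1, 0, 2 * pi)
  p <- ctr + sqrt(u) * r_eff * c(cos(a0), sin(a0))

  total <- times[length(times)]
  t_cur <- 0
  xs <- numeric(length(times)); ys <- numeric(length(times))
  idx <- 1L  # next sample index to fill
  state_wait <- stats::runif(1) < 0.5  # random initial phase kind
  sched <- list()

  jitter_sd <- model$jitter_radius / 3

  while (t_cur < total) {
    if (state_wait) {
      dur <- stats::rgamma(1, shape = model$wait_duration$shape,
                           scale = model$wait_duration$scale)
      t_end <- min(t_cur + dur, total)
      anchor <- p
      while (idx <= length(times) && times[idx] <= t_end + 1e-12) {
        if (model$jitter_radius > 0 && times[idx] > t_cur) {
          step <- stats::rnorm(2, 0, jitter_sd)
          cand <- p + step
          off <- cand - anchor
          od <- sqrt(sum(off^2))
          if (od > model$jitter_radius) {
            cand <- anchor + off / od * model$jitter_radius
          }
          rk <- cand - ctr; dk <- sqrt(sum(rk^2))
          if (dk > r_eff) cand <- ctr + rk / dk * r_eff
          p <- cand
        }
        xs[idx] <- p[1]; ys[idx] <- p[2]
        idx <- idx + 1L
      }
      sched[[length(sched) + 1L]] <- data.frame(
        kind = "WAIT", t_start = t_cur, t_end = t_cur + dur,
        distance = NA_real_, velocity = NA_real_, direction = NA_real_)
      p <- anchor  # dash starts from the anchor
      t_cur <- t_cur + dur
    } else {
      dist <- stats::rgamma(1, shape = model$dash_distance$shape,
                            scale = model$dash_distance$scale)
      vel <- stats::rgamma(1, shape = model$dash_velocity$shape,
                           scale = model$dash_velocity$scale)
      dir <- NA_real_
      ok <- FALSE
      for (try in 1:100) {
        dir <- stats::runif(1, 0, 2 * pi)
        q <- p + dist * c(cos(dir), sin(dir))
        if (sum((q - ctr)^2) <= r_eff^2) { ok <- TRUE; break }
      }
      if (!ok) {
        # truncate the dash at the border along the last sampled direction
        vdir <- c(cos(dir), sin(dir))
        w <- p - ctr
        b <- 2 * sum(w * vdir); cc <- sum(w^2) - r_eff^2
        disc <- b^2 - 4 * cc
        smax <- if (disc > 0) (-b + sqrt(disc)) / 2 else 0
        dist <- max(min(dist, smax), 0)
      }
      dur <- dist / vel
      t_end <- min(t_cur + dur, total)
      vvec <- vel * c(cos(dir), sin(dir))
      start <- p
      while (idx <= length(times) && times[idx] <= t_end + 1e-12) {
        q <- start + vvec * (times[idx] - t_cur)
        xs[idx] <- q[1]; ys[idx] <- q[2]
        idx <- idx + 1L
      }
      sched[[length(sched) + 1L]] <- data.frame(
        kind = "MOVE", t_start = t_cur, t_end = t_cur + dur,
        distance = dist, velocity = vel, direction = dir)
      p <- start + vvec * dur
      t_cur <- t_cur + dur
    }
    state_wait <- !state_wait
  }
  tr <- trajectory(sprintf("fish%02d", i), times, xs, ys,
                   frame_rate = 1 / cfg$dt)
  attr(tr, "phases") <- do.call(rbind, sched)
  tr
}
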