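# Shared fixtures and independent oracles used across the suite.

VIDEOS23 <- sprintf("v%02d", 1:23)

# Build a trajectory from piecewise segments at a fixed frame rate.
# segs: list of lists with kind "wait" (duration, optional jitter function)
# or "dash" (duration, to = c(x, y)); starts at `start`.
build_piecewise_traj <- function(segs, start = c(100, 100), fps = 30,
                                 id = "built") {
  dt <- 1 / fps
  t <- 0; p <- start
  ts <- 0; xs <- p[1]; ys <- p[2]
  for (sg in segs) {
    n <- round(sg$duration * fps)
    if (sg$kind == "wait") {
      for (k in seq_len(n)) {
        t <- t + dt
        ts <- c(ts, t); xs <- c(xs, p[1]); ys <- c(ys, p[2])
      }
    } else {
      step <- (sg$to - p) / n
      for (k in seq_len(n)) {
        t <- t + dt
        q <- p + step * k
        ts <- c(ts, t); xs <- c(xs, q[1]); ys <- c(ys, q[2])
      }
      p <- sg$to
    }
  }
  trajectory(id, ts, xs, ys, frame_rate = fps)
}

# Exhaustive maximal-interval segmentation oracle. Independently of the
# greedy scan, computes for every start index the maximal run of samples
# within `radius` of it (via the full pairwise distance matrix), then walks
# left to right committing qualifying runs. Returns a list of c(i, j) WAIT
# index ranges.
oracle_wait_set <- function(traj, radius = 60, min_wait = 0.2) {
  n <- nrow(traj)
  D2 <- outer(traj$x, traj$x, "-")^2 + outer(traj$y, traj$y, "-")^2
  within <- D2 <= radius^2
  max_j <- integer(n)
  for (i in seq_len(n)) {
    run <- which(!within[i, i:n])
    max_j[i] <- if (length(run) == 0) n else i + run[1] - 2L
  }
  waits <- list()
  i <- 1L
  while (i <= n) {
    j <- max_j[i]
    if (j > i && traj$t[j] - traj$t[i] >= min_wait) {
      waits[[length(waits) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  waits
}

# WAIT index ranges reconstructed from a phase table (for oracle comparison).
wait_ranges_from_phases <- function(traj, phases) {
  w <- phases[phases$kind == "WAIT", , drop = FALSE]
  lapply(seq_len(nrow(w)), function(k) {
    c(which.min(abs(traj$t - w$t_start[k])),
      which.min(abs(traj$t - w$t_end[k])))
  })
}

# Replay checker for ballistic trajectories: recomputes containment, speed
# constancy and pairwise clearance directly from the sampled tables.
replay_check <- function(trajs, arena, cfg) {
  ctr <- arena$center
  R <- arena$diameter / 2
  max_r <- max(vapply(trajs, function(tr) {
    max(sqrt((tr$x - ctr[1])^2 + (tr$y - ctr[2])^2))
  }, numeric(1)))
  sp <- unlist(lapply(trajs, function(tr) {
    sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t)
  }))
  n <- length(trajs)
  min_pair <- Inf
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((trajs[[i]]$x - trajs[[j]]$x)^2 +
                  (trajs[[i]]$y - trajs[[j]]$y)^2)
      min_pair <- min(min_pair, min(d))
    }
  }
  list(max_radius = max_r, contained = max_r <= R + 1e-6,
       speed_rel_err = max(abs(sp - cfg$speed)) / cfg$speed,
       min_pair_dist = min_pair)
}

# A random wait/dash trajectory with <= max_n samples, for oracle sweeps.
random_piecewise_traj <- function(seed, max_n = 200) {
  set.seed(seed)
  fps <- 20
  segs <- list()
  total <- 0
  p <- c(0, 0)
  while (total < (max_n - 10) / fps) {
    if (runif(1) < 0.5) {
      d <- round(runif(1, 0.1, 1.5), 2)
      segs[[length(segs) + 1L]] <- list(kind = "wait", duration = d)
    } else {
      d <- round(runif(1, 0.1, 1.0), 2)
      to <- p + runif(2, -150, 150)
      segs[[length(segs) + 1L]] <- list(kind = "dash", duration = d, to = to)
      p <- to
    }
    total <- total + segs[[length(segs)]]$duration
  }
  tr <- build_piecewise_traj(segs, start = c(0, 0), fps = fps,
                             id = paste0("rand", seed))
  tr[seq_len(min(nrow(tr), max_n)), ] -> sub
  trajectory(paste0("rand", seed), sub$t, sub$x, sub$y, frame_rate = fps)
}

# Quick generative response set for inference tests.
sim_dataset <- function(pop, n_participants, design, seed) {
  obs <- sample_observers(pop, n_participants, seed = seed)
  simulate_responses(obs, design, pop, seed = seed + 5000L)
}
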