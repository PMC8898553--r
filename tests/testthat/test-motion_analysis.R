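test_that("degenerate trajectories segment into the obvious single phase", {
  t <- seq(0, 10, by = 1 / 30)
  still <- trajectory("still", t, rep(100, length(t)), rep(100, length(t)))
  ph <- segment_trajectory(still, radius_px = 60)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$kind, "WAIT")
  expect_equal(ph$t_end - ph$t_start, 10)

  # constant 200 px/s exits a 60 px radius immediately: one MOVE phase
  t <- seq(0, 5, by = 1 / 30)
  straight <- trajectory("line", t, 200 * t, rep(0, length(t)))
  ph <- segment_trajectory(straight, radius_px = 60, min_wait_s = 0.5)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$kind, "MOVE")
  expect_equal(ph$distance, 1000, tolerance = 1e-9)
  expect_equal(ph$mean_velocity, 200, tolerance = 1e-9)
})

test_that("segmentation rejects invalid trajectories", {
  expect_error(trajectory("x", t = 1, x = 1, y = 1), "2 samples")
  expect_error(trajectory("x", t = c(0, 1, 1), x = 1:3, y = 1:3),
               "strictly increasing")
  tr <- trajectory("ok", c(0, 0.5, 1), 1:3, 1:3)
  expect_error(segment_trajectory(tr, radius_px = -5), "radius")
})

test_that("wait-dash-wait construction matches the exhaustive-interval oracle", {
  tr <- build_piecewise_traj(list(
    list(kind = "wait", duration = 3),
    list(kind = "dash", duration = 1, to = c(400, 100)),
    list(kind = "wait", duration = 2)
  ), start = c(100, 100), fps = 30)

  ph <- segment_trajectory(tr, radius_px = 60, min_wait_s = 0.2)
  expect_equal(ph$kind, c("WAIT", "MOVE", "WAIT"))
  # phases tile the full span
  expect_equal(ph$t_start[-1], ph$t_end[-nrow(ph)])
  expect_equal(sum(ph$t_end - ph$t_start), tr$t[nrow(tr)] - tr$t[1])
  # the anchored scan keeps dash samples still within 60 px of the anchor
  # inside the first WAIT; expected boundaries frozen from the oracle
  ow <- oracle_wait_set(tr, radius = 60, min_wait = 0.2)
  expect_equal(length(ow), 2L)
  expect_equal(tr$t[ow[[1]][2]], ph$t_end[1])
  expect_equal(tr$t[ow[[2]][1]], ph$t_start[3])
  expect_gte(ph$t_end[1], 3)        # WAIT 1 covers the constructed 3 s
  expect_lt(ph$t_end[1], 3.3)
  expect_equal(ph$distance[2], 300, tolerance = 0.1 * 300)
})

test_that("greedy segmentation equals the exhaustive oracle on random paths", {
  for (seed in 1:25) {
    tr <- random_piecewise_traj(seed, max_n = 200)
    ph <- segment_trajectory(tr, radius_px = 60, min_wait_s = 0.2)
    got <- wait_ranges_from_phases(tr, ph)
    want <- oracle_wait_set(tr, radius = 60, min_wait = 0.2)
    expect_equal(got, want, info = paste("seed", seed))
    # tiling invariant
    expect_equal(sum(ph$t_end - ph$t_start), tr$t[nrow(tr)] - tr$t[1],
                 tolerance = 1e-9)
  }
})

test_that("phase summaries report time fractions and per-kind vectors", {
  # a [WAIT 2 s, MOVE 8 s] table gives exactly the 0.2 / 0.8 split
  tab <- data.frame(kind = c("WAIT", "MOVE"), t_start = c(0, 2),
                    t_end = c(2, 10), anchor_x = c(1, NA),
                    anchor_y = c(1, NA), distance = c(NA, 900),
                    mean_velocity = c(NA, 112.5), direction = c(NA, 0))
  sm0 <- summarize_phases(tab)
  expect_equal(sm0$time_fraction_wait, 0.2)
  expect_equal(sm0$time_fraction_move, 0.8)

  tr <- build_piecewise_traj(list(
    list(kind = "wait", duration = 2),
    list(kind = "dash", duration = 8, to = c(1000, 100))
  ), start = c(100, 100), fps = 30)
  ph <- segment_trajectory(tr, radius_px = 20, min_wait_s = 0.2)
  sm <- summarize_phases(ph)
  expect_equal(sm$time_fraction_wait + sm$time_fraction_move, 1)
  # the anchored scan keeps dash samples within the radius in the WAIT,
  # so the measured fraction sits slightly above the constructed 0.2
  expect_equal(sm$time_fraction_wait, 0.2, tolerance = 0.12)
  expect_length(sm$wait_durations, sum(ph$kind == "WAIT"))
  expect_length(sm$dash_distances, sum(ph$kind == "MOVE"))
  expect_error(summarize_phases(ph[0, ]), "empty")
})

test_that("gamma MLE recovers known parameters and rejects bad input", {
  set.seed(42)
  x <- rgamma(1e5, shape = 2, scale = 3)
  f <- fit_gamma_mle(x)
  expect_gte(f$shape, 1.96); expect_lte(f$shape, 2.04)
  expect_gte(f$scale, 2.94); expect_lte(f$scale, 3.06)
  # score equations hold at the optimum
  g1 <- sum(log(x)) - f$n * (log(f$scale) + digamma(f$shape))
  g2 <- sum(x) / f$scale^2 - f$n * f$shape / f$scale
  expect_lt(sqrt(g1^2 + g2^2) / f$n, 1e-6)

  expect_error(fit_gamma_mle(c(1, 2)), "n >= 3")
  expect_error(fit_gamma_mle(c(1, -1, 2)), "positive")
  expect_error(fit_gamma_mle(rep(2, 10)), "degenerate")
})

test_that("gamma MLE beats a 200x200 grid oracle on fixed samples", {
  set.seed(7)
  x <- round(rgamma(20, shape = 3.2, scale = 1.7), 3)
  f <- fit_gamma_mle(x)
  # independent grid centered on method-of-moments estimates
  k_mm <- mean(x)^2 / var(x)
  ks <- exp(seq(log(k_mm / 10), log(k_mm * 10), length.out = 200))
  ths <- exp(seq(log(mean(x) / (k_mm * 10)), log(mean(x) * 10 / k_mm),
                 length.out = 200))
  ll <- function(k, th) sum(dgamma(x, shape = k, scale = th, log = TRUE))
  grid_best <- max(outer(ks, ths, Vectorize(ll)))
  expect_gte(f$loglik, grid_best)
})

test_that("gamma MLE agrees with an independent optimizer", {
  set.seed(11)
  x <- rgamma(400, shape = 2.5, scale = 0.8)
  f <- fit_gamma_mle(x)
  alt <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(f$shape, unname(alt$estimate["shape"]), tolerance = 1e-4)
  expect_equal(f$scale, 1 / unname(alt$estimate["rate"]), tolerance = 1e-4)
})

test_that("motion-model fitting pools phases and flags insufficient data", {
  t <- seq(0, 10, by = 1 / 30)
  still <- trajectory("still", t, rep(5, length(t)), rep(5, length(t)))
  expect_error(fit_motion_model(list(still)), "insufficient")

  # pooling invariance: two identical trajectories = one with doubled n
  segs <- list(list(kind = "wait", duration = 1.5),
               list(kind = "dash", duration = 0.4, to = c(300, 0)),
               list(kind = "wait", duration = 0.8),
               list(kind = "dash", duration = 0.3, to = c(500, 250)),
               list(kind = "wait", duration = 1.1),
               list(kind = "dash", duration = 0.5, to = c(100, 50)),
               list(kind = "wait", duration = 0.9))
  tr <- build_piecewise_traj(segs, start = c(0, 0), fps = 30)
  m1 <- fit_motion_model(list(tr))
  m2 <- fit_motion_model(list(tr, tr))
  expect_equal(m2$wait_duration$shape, m1$wait_duration$shape, tolerance = 1e-8)
  expect_equal(m2$wait_duration$scale, m1$wait_duration$scale, tolerance = 1e-8)
  expect_equal(m2$wait_duration$n, 2L * m1$wait_duration$n)
  expect_equal(m2$dash_distance$shape, m1$dash_distance$shape, tolerance = 1e-8)
})

test_that("trajectory and phase CSV round trips are lossless", {
  tr <- build_piecewise_traj(list(list(kind = "wait", duration = 1),
                                  list(kind = "dash", duration = 0.5,
                                       to = c(250, 30))),
                             start = c(10, 20), fps = 30, id = "rt")
  tmp <- tempfile(fileext = ".csv")
  write_trajectories(list(tr), tmp)
  back <- read_trajectories(tmp)
  expect_equal(back[["rt"]]$x, tr$x, tolerance = 1e-9)
  expect_equal(back[["rt"]]$t, tr$t, tolerance = 1e-9)

  ph <- segment_trajectory(tr, radius_px = 30, min_wait_s = 0.2)
  tmp2 <- tempfile(fileext = ".csv")
  write_phases(ph, tmp2)
  back2 <- utils::read.csv(tmp2)
  expect_equal(nrow(back2), nrow(ph))
  expect_equal(back2$t_end, ph$t_end, tolerance = 1e-9)
})
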