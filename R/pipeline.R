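#' Experiment constants
#'
#' Timing and design constants of the tracking experiments, kept as
#' metadata: 75 ms fixation, 3 s cue phase, 10 s moving phase, 50% target
#' query probability, 23 scenes, loads 1/3/5 (single-condition experiment)
#' and 2/4 (three-condition experiment).
#'
#' @export
design_constants <- function() {
  list(fixation_ms = 75, cue_s = 3, move_s = 10,
       p_target_query = 0.5, n_videos = 23,
       loads_exp1 = c(1, 3, 5), loads_exp2 = c(2, 4),
       arena_diameter_px = 800, scene_extent_px = c(960, 600),
       ballistic_speed_px_s = 200, segmentation_radius_px = 60)
}

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage of [run_pipeline()] with
#' defaults matching the study constants (800 px arena, 200 px/s, 10 s
#' trials, 60 px segmentation radius, loads 1/3/5 and 2/4). The `demo`
#' scale keeps every stage small enough to run in seconds; `study` uses
#' the study's sample sizes.
#'
#' @param seed Root seed; every stage derives its own child seed from it.
#' @param scale `"demo"` (default) or `"study"`.
#' @param ... Named overrides of any top-level field.
#' @export
pipeline_config <- function(seed = 1, scale = c("demo", "study"), ...) {
  scale <- match.arg(scale)
  demo <- scale == "demo"
  cfg <- list(
    seed = seed,
    scale = scale,
    arena = list(diameter = 800, scene_extent = c(960, 600)),
    sim = list(n_objects = if (demo) 6 else 8, duration = 10, dt = 1 / 30,
               speed = 200, object_radius = 15,
               n_scenes = if (demo) 2 else 23),
    segmentation = list(radius_px = 60, min_wait_s = 0.2),
    design = list(n_videos = 23, set_sizes = c(1, 3, 5), loads = c(2, 4),
                  n_objects = 16),
    population = list(alpha_d = 3.58, beta_d = -0.50,
                      alpha_c = 1.97, beta_c = -0.22,
                      sigma_ad = 0.5, sigma_bd = 0.1,
                      sigma_ac = 0.3, sigma_bc = 0.05),
    observers = list(n_participants = if (demo) 6 else 10),
    sampler = list(chains = if (demo) 2 else 4,
                   warmup = if (demo) 200 else 1000,
                   iter = if (demo) 300 else 1000)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg A configuration list to check against the schema.
#' @export
validate_config <- function(cfg) {
  need <- list(
    c("arena", "diameter"), c("sim", "n_objects"), c("sim", "duration"),
    c("sim", "dt"), c("sim", "speed"), c("segmentation", "radius_px"),
    c("design", "n_videos"), c("design", "set_sizes"),
    c("observers", "n_participants"), c("sampler", "chains"),
    c("sampler", "warmup"), c("sampler", "iter"), "seed")
  for (f in need) {
    v <- cfg
    for (k in f) v <- v[[k]]
    if (is.null(v)) {
      stop("config schema error: missing field '",
           paste(f, collapse = "$"), "'", call. = FALSE)
    }
  }
  invisible(cfg)
}

stage_log <- function(con, stage, seed) {
  cat(sprintf("stage=%s seed=%d\n", stage, seed), file = con, append = TRUE)
}

#' Run the whole analysis pipeline end to end
#'
#' Simulates fish-like and ballistic stimuli, fits the motion model back to
#' the fish-like trajectories (round-trip recovery diagnostic), enumerates
#' both experiment designs with counterbalancing, simulates observer
#' responses from the generative SDT population, fits the hierarchical
#' probit model, and writes summaries plus a JSON report. Fully seeded:
#' the same config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  sd <- function(k) child_seed(config$seed, k)

  arena <- arena_spec(diameter = config$arena$diameter,
                      scene_extent = config$arena$scene_extent)
  model0 <- default_motion_model()

  # 1: stimuli -------------------------------------------------------------
  stage_log(logf, "stimuli", sd(1))
  fish_trajs <- list()
  for (sc in seq_len(config$sim$n_scenes)) {
    cfg_sc <- sim_config(n_objects = config$sim$n_objects,
                         duration = config$sim$duration, dt = config$sim$dt,
                         speed = config$sim$speed,
                         object_radius = config$sim$object_radius,
                         seed = child_seed(sd(1), sc))
    fish_trajs <- c(fish_trajs, simulate_fishlike(arena, model0, cfg_sc))
  }
  ball <- simulate_ballistic(arena, sim_config(
    n_objects = config$sim$n_objects, duration = config$sim$duration,
    dt = config$sim$dt, speed = config$sim$speed,
    object_radius = config$sim$object_radius, seed = sd(11)))
  write_trajectories(fish_trajs, file.path(out_dir, "fishlike_trajectories.csv"))
  write_trajectories(ball, file.path(out_dir, "ballistic_trajectories.csv"))

  # 2: motion model round trip ---------------------------------------------
  stage_log(logf, "motion", sd(2))
  mm <- fit_motion_model(fish_trajs,
                         radius_px = config$segmentation$radius_px,
                         min_wait_s = config$segmentation$min_wait_s)
  gamma_tab <- data.frame(
    parameter = c("wait_duration", "dash_distance", "dash_velocity"),
    true_shape = c(model0$wait_duration$shape, model0$dash_distance$shape,
                   model0$dash_velocity$shape),
    true_scale = c(model0$wait_duration$scale, model0$dash_distance$scale,
                   model0$dash_velocity$scale),
    fit_shape = c(mm$wait_duration$shape, mm$dash_distance$shape,
                  mm$dash_velocity$shape),
    fit_scale = c(mm$wait_duration$scale, mm$dash_distance$scale,
                  mm$dash_velocity$scale))
  utils::write.csv(gamma_tab, file.path(out_dir, "motion_model.csv"),
                   row.names = FALSE, quote = FALSE)

  # 3: designs --------------------------------------------------------------
  stage_log(logf, "design", sd(3))
  vids <- sprintf("v%02d", seq_len(config$design$n_videos))
  d1 <- build_design_exp1(vids, config$design$set_sizes,
                          n_objects = config$design$n_objects, seed = sd(3))
  conds <- c("FISH", "FAKEFISH", "TRADITIONAL")
  d2 <- do.call(rbind, lapply(conds, function(cn) {
    build_design_exp2(vids, config$design$loads,
                      n_objects = config$design$n_objects,
                      condition = cn, seed = child_seed(sd(3), match(cn, conds)))
  }))
  orders <- counterbalance_orders(conds, config$observers$n_participants)
  write_design(d1, file.path(out_dir, "design_exp1.csv"))
  write_design(d2, file.path(out_dir, "design_exp2.csv"))
  utils::write.csv(orders, file.path(out_dir, "block_orders.csv"),
                   row.names = FALSE, quote = FALSE)

  # 4: observers ------------------------------------------------------------
  stage_log(logf, "observers", sd(4))
  pop <- do.call(population_params, config$population)
  obs <- sample_observers(pop, config$observers$n_participants, seed = sd(4))
  resp <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    tr <- shuffle_trials(d1, child_seed(sd(4), i))
    simulate_responses(obs[i, , drop = FALSE], tr, pop,
                       seed = child_seed(sd(4), 1000 + i))
  }))
  write_responses(resp, file.path(out_dir, "responses_exp1.csv"))

  # 5: inference ------------------------------------------------------------
  stage_log(logf, "inference", sd(5))
  fit <- fit_sdt_probit(resp, chains = config$sampler$chains,
                        warmup = config$sampler$warmup,
                        iter = config$sampler$iter, seed = sd(5))
  summ <- summarize_dprime_bias(fit, at_loads = config$design$set_sizes)
  utils::write.csv(summ, file.path(out_dir, "sdt_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  bf_load <- savage_dickey_bf(fit, "d_load")
  ppd <- per_participant_dprime(resp)
  utils::write.csv(ppd, file.path(out_dir, "per_participant_dprime.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- list(
    seed = config$seed,
    wait_time_fraction_schedule = wait_time_fraction(fish_trajs),
    wait_time_fraction_segmented = mm$summaries$time_fraction_wait,
    motion_model = gamma_tab,
    design = list(n_trials_exp1 = nrow(d1),
                  target_query_fraction = mean(d1$queried_is_target),
                  n_trials_exp2_per_condition = nrow(d2) / length(conds),
                  n_block_orderings = length(unique(orders$ordering))),
    population_truth = config$population,
    posterior = list(
      d_intercept = unname(colMeans(fit$draws)["d_intercept"]),
      d_load = unname(colMeans(fit$draws)["d_load"]),
      c_intercept = unname(colMeans(fit$draws)["c_intercept"]),
      c_load = unname(colMeans(fit$draws)["c_load"]),
      max_rhat_population = max(fit$rhat[fit$pop_names], na.rm = TRUE)),
    bf10_load_on_dprime = bf_load$BF10)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

#' Write the small bundled test fixtures
#'
#' Generates, in `out_dir`: a 3-object 10 s fish-like trajectory CSV, a
#' 12-trial design CSV (3 scenes x set sizes 1 and 3 x both query types)
#' and a 4-participant response CSV for that design.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arena <- arena_spec()
  trajs <- simulate_fishlike(arena, default_motion_model(),
                             sim_config(n_objects = 3, duration = 10,
                                        seed = child_seed(seed, 1)))
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  d <- build_design_exp1(sprintf("v%02d", 1:3), set_sizes = c(1, 3),
                         n_objects = 8, seed = child_seed(seed, 2))
  write_design(d, file.path(out_dir, "design.csv"))
  pop <- population_params()
  obs <- sample_observers(pop, 4, seed = child_seed(seed, 3))
  resp <- simulate_responses(obs, d, pop, seed = child_seed(seed, 4))
  write_responses(resp, file.path(out_dir, "responses.csv"))
  invisible(out_dir)
}
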