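#!/usr/bin/env Rscript
# Stimulus sets for the circle-tracking conditions: traditional ballistic
# motion (constant 200 px/s, border + object bounces) and fake-fish motion
# (wait/dash phases, no object bounces), both inside the 800 px arena.
# Writes results/stimuli_ballistic.csv and results/stimuli_fishlike.csv.

library(fishmot)
dir.create("results", showWarnings = FALSE)
seed <- 1

arena <- arena_spec()
cfg <- sim_config(n_objects = 8, duration = 10, speed = 200, seed = seed)

ball <- simulate_ballistic(arena, cfg)
sp <- unlist(lapply(ball, function(tr) sqrt(diff(tr$x)^2 + diff(tr$y)^2) /
                                        diff(tr$t)))
maxr <- max(vapply(ball, function(tr) {
  max(sqrt((tr$x - arena$center[1])^2 + (tr$y - arena$center[2])^2))
}, numeric(1)))
cat(sprintf("ballistic: speed %.6f px/s (max |dev| %.2e), max radius %.1f px\n",
            mean(sp), max(abs(sp - 200)), maxr))

fake <- simulate_fishlike(arena, default_motion_model(),
                          sim_config(n_objects = 8, duration = 10,
                                     seed = seed + 1))
cat(sprintf("fake-fish: %d objects, waiting fraction %.2f\n",
            length(fake), wait_time_fraction(fake)))

write_trajectories(ball, "results/stimuli_ballistic.csv")
write_trajectories(fake, "results/stimuli_fishlike.csv")
cat("wrote results/stimuli_ballistic.csv and results/stimuli_fishlike.csv\n")
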