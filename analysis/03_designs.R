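#!/usr/bin/env Rscript
# Trial designs: 138 trials for the single-condition experiment (23 videos
# x loads 1/3/5 x target- or distractor-query), 92 trials per condition for
# the three-condition experiment (loads 2/4), and the six counterbalanced
# block orderings. Writes results/design_exp1.csv, results/design_exp2.csv,
# results/block_orders.csv.

library(fishmot)
dir.create("results", showWarnings = FALSE)
seed <- 1

videos <- sprintf("v%02d", 1:23)
d1 <- build_design_exp1(videos, seed = seed)
cat(sprintf("experiment 1: %d trials, %.0f%% target queries\n",
            nrow(d1), 100 * mean(d1$queried_is_target)))

conds <- c("FISH", "FAKEFISH", "TRADITIONAL")
d2 <- do.call(rbind, lapply(seq_along(conds), function(i) {
  build_design_exp2(videos, condition = conds[i], seed = seed + i)
}))
cat(sprintf("experiment 2: %d trials total, %d per condition\n",
            nrow(d2), nrow(d2) / 3))

orders <- counterbalance_orders(conds, 52)
cat(sprintf("counterbalancing: %d distinct block orderings over %d participants\n",
            length(unique(orders$ordering)), nrow(orders)))

write_design(d1, "results/design_exp1.csv")
write_design(d2, "results/design_exp2.csv")
write.csv(orders, "results/block_orders.csv", row.names = FALSE, quote = FALSE)
cat("wrote results/design_exp1.csv, design_exp2.csv, block_orders.csv\n")
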