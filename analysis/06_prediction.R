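#!/usr/bin/env Rscript
# Individual-level prediction: closed-form per-participant d'/bias per
# condition and load, then the multilevel Gaussian model predicting
# fish-tracking sensitivity from each circle-tracking condition, with
# coefficient Bayes factors and Bayesian R2. Reads
# results/responses_exp2.csv (run 04 first). Writes
# results/per_participant_dprime.csv and results/prediction_models.csv.

library(fishmot)
seed <- 1

resp2 <- read_responses("results/responses_exp2.csv")
kept <- apply_exclusion(resp2)$kept
dtab <- per_participant_dprime(kept)
write.csv(dtab, "results/per_participant_dprime.csv", row.names = FALSE,
          quote = FALSE)

rows <- list()
for (pred in c("TRADITIONAL", "FAKEFISH")) {
  fit <- fit_prediction_model(dtab, "FISH", pred, chains = 2,
                              warmup = 500, iter = 1000, seed = seed)
  for (par in c("slope", "load", "slope:load")) {
    s <- summarize_prediction(fit, par)
    bf <- savage_dickey_bf(fit$draws[, par])
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = pred, parameter = par, mean = s$mean,
      ci_low = s$ci_low, ci_high = s$ci_high, BF10 = bf$BF10)
  }
  r2 <- bayesian_r2(fit)
  rows[[length(rows) + 1L]] <- data.frame(
    predictor = pred, parameter = "R2", mean = r2$mean,
    ci_low = r2$ci_low, ci_high = r2$ci_high, BF10 = NA)
  cat(sprintf("predicting FISH d' from %s: slope %.2f [%.2f, %.2f], R2 %.2f\n",
              pred, rows[[length(rows) - 3]]$mean,
              rows[[length(rows) - 3]]$ci_low,
              rows[[length(rows) - 3]]$ci_high, r2$mean))
}
cat("(study values: slope 0.83 and R2 0.70 from traditional;",
    "slope 0.88 and R2 0.69 from fakefish)\n")
cat("note: slopes estimated from per-participant d' tables are attenuated\n",
    "by trial-level estimation noise (~46 trials per load x condition cell),\n",
    "so they sit below the generating cross-condition relation; the test\n",
    "suite's recovery checks use noise-free sensitivity tables\n")

out <- do.call(rbind, rows)
write.csv(out, "results/prediction_models.csv", row.names = FALSE,
          quote = FALSE)
cat("wrote results/per_participant_dprime.csv, prediction_models.csv\n")
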