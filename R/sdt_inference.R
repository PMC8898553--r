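#' Hierarchical Bayesian probit estimation of sensitivity and bias
#'
#' Fits the equal-variance SDT model as a multilevel probit regression:
#' `P(response = "target") = Phi(-c + d' * X)` with `X` the
#' queried-is-target indicator. Both `d'` and the criterion `c` are linear
#' in the tracking load, optionally carry deviation-coded condition offsets
#' (plus condition-by-load interactions) and extra covariates, and have
#' participant-level random intercepts and slopes. Priors are N(0, 1) on
#' all population intercepts and slopes and half-normal(0, 1) on the
#' random-effect SDs.
#'
#' Sampling is by Gibbs with truncated-normal data augmentation: latent
#' evidence variables given coefficients, a joint multivariate-normal
#' update of all coefficients and deviations, and slice updates of the four
#' random-effect SDs. Convergence is checked with split-R-hat on the
#' population parameters (error above `rhat_error`, warning above
#' `rhat_warn`); effective sample sizes are reported per parameter.
#'
#' @param responses Response data frame (see [simulate_responses()]):
#'   columns `participant`, `n_targets`, `queried_is_target`, `response`,
#'   and `condition` / covariate columns as needed.
#' @param condition `"none"` for a single-condition model or `"deviation"`
#'   to add deviation-coded condition offsets and condition-by-load
#'   interactions on both `d'` and `c`.
#' @param covariates Character vector of numeric covariate columns entering
#'   both linear predictors (e.g. `"sudden_target"`).
#' @param prior_sd Prior SD of population coefficients (default 1).
#' @param chains,warmup,iter MCMC layout (default 4 chains x 1000 warmup +
#'   1000 kept draws each).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param rhat_warn,rhat_error Split-R-hat thresholds for warning/error.
#' @return An `fm_sdt_posterior`: combined `draws` (iterations x
#'   parameters), `rhat`, `ess`, the linear-predictor column names, the
#'   condition levels and participant ids, and the sampler settings.
#' @export
fit_sdt_probit <- function(responses, condition = c("none", "deviation"),
                           covariates = character(), prior_sd = 1,
                           chains = 4, warmup = 1000, iter = 1000,
                           seed = 1, rhat_warn = 1.01, rhat_error = 1.05) {
  condition <- match.arg(condition)
  y <- as.integer(responses$response == "target")
  X <- as.numeric(responses$queried_is_target)
  if (length(unique(X)) < 2L) {
    stop("both query types (target and distractor) must be present",
         call. = FALSE)
  }
  load <- as.numeric(responses$n_targets)
  pid <- factor(responses$participant)
  P <- nlevels(pid)

  # perfect separation: a participant correct everywhere
  acc <- tapply(responses$correct, pid, mean)
  if (any(acc == 1)) {
    warning("participant(s) ", paste(names(acc)[acc == 1], collapse = ", "),
            " answered correctly everywhere (perfect separation); ",
            "estimates for them rely on the priors", call. = FALSE)
  }

  # The N(0,1) intercept priors apply at mean-centered predictors (the
  # standard multilevel-regression convention); draws are transformed back
  # to the uncentered intercepts afterwards.
  load_ctr <- mean(load)
  cond_levels <- character(0)
  W <- cbind(intercept = 1, load = load - load_ctr)
  if (condition == "deviation") {
    cf <- factor(responses$condition)
    cond_levels <- levels(cf)
    if (length(cond_levels) < 2L) {
      stop("deviation coding needs >= 2 conditions", call. = FALSE)
    }
    Cm <- stats::contr.sum(length(cond_levels))
    rownames(Cm) <- cond_levels
    Cc <- Cm[as.character(cf), , drop = FALSE]
    colnames(Cc) <- paste0("cond", seq_len(ncol(Cc)))
    W <- cbind(W, Cc, Cc * (load - load_ctr))
    colnames(W)[(ncol(W) - ncol(Cc) + 1):ncol(W)] <-
      paste0(colnames(Cc), ":load")
  }
  cov_ctr <- numeric(0)
  for (cv in covariates) {
    v <- as.numeric(responses[[cv]])
    cov_ctr[cv] <- mean(v)
    W <- cbind(W, v - cov_ctr[cv])
    colnames(W)[ncol(W)] <- cv
  }
  lin_names <- colnames(W)

  Zi <- diag(nlevels(pid))[as.integer(pid), , drop = FALSE]  # participant indicators
  load_c <- load - load_ctr
  U <- cbind(W * X, -W, Zi * X, (Zi * load_c) * X, -Zi, -(Zi * load_c))
  p_lin <- ncol(W)
  pop_names <- c(paste0("d_", lin_names), paste0("c_", lin_names))
  dev_names <- c(paste0("a[", levels(pid), "]"),
                 paste0("b[", levels(pid), "]"),
                 paste0("u[", levels(pid), "]"),
                 paste0("v[", levels(pid), "]"))
  colnames(U) <- c(pop_names, dev_names)
  n_pop <- 2L * p_lin
  blocks <- lapply(0:3, function(k) n_pop + k * P + seq_len(P))
  names(blocks) <- c("a", "b", "u", "v")
  sigma_names <- c("sigma_a_d", "sigma_b_d", "sigma_a_c", "sigma_b_c")

  XtX <- crossprod(U)
  p_all <- ncol(U)

  init_fn <- function(ch) {
    list(beta = stats::rnorm(p_all, 0, 0.1), sigmas = rep(0.5, 4))
  }
  kernel <- function(state) {
    eta <- as.numeric(U %*% state$beta)
    z <- rtruncnorm_latent(eta, y)
    Dinv <- c(rep(1 / prior_sd^2, n_pop),
              rep(1 / state$sigmas^2, each = P))
    beta <- draw_coefs(XtX, crossprod(U, z), Dinv)
    sigmas <- state$sigmas
    for (k in 1:4) {
      S <- sum(beta[blocks[[k]]]^2)
      sigmas[k] <- slice_pos(sigmas[k],
                             function(s) logpost_sigma(s, P, S))
    }
    list(beta = beta, sigmas = sigmas)
  }
  extract <- function(state) {
    stats::setNames(c(state$beta, state$sigmas),
                    c(colnames(U), sigma_names))
  }

  sims <- run_chains(init_fn, kernel, extract, chains, warmup, iter, seed)
  # de-center: intercepts (and condition offsets) back to raw load/covariates
  sims <- lapply(sims, function(s) {
    for (ms in c("d", "c")) {
      s[, paste0(ms, "_intercept")] <- s[, paste0(ms, "_intercept")] -
        s[, paste0(ms, "_load")] * load_ctr
      for (cv in covariates) {
        s[, paste0(ms, "_intercept")] <- s[, paste0(ms, "_intercept")] -
          s[, paste0(ms, "_", cv)] * cov_ctr[cv]
      }
      if (length(cond_levels)) {
        for (j in seq_len(length(cond_levels) - 1L)) {
          s[, paste0(ms, "_cond", j)] <- s[, paste0(ms, "_cond", j)] -
            s[, paste0(ms, "_cond", j, ":load")] * load_ctr
        }
      }
    }
    s
  })
  cc <- combine_chains(sims)

  check <- cc$rhat[pop_names]
  bad <- check[is.finite(check) & check > rhat_error]
  if (length(bad)) {
    stop("non-convergence: split-Rhat above ", rhat_error, " for ",
         paste(sprintf("%s (%.3f)", names(bad), bad), collapse = ", "),
         call. = FALSE)
  }
  marg <- check[is.finite(check) & check > rhat_warn]
  if (length(marg)) {
    warning("split-Rhat above ", rhat_warn, " for ",
            paste(sprintf("%s (%.3f)", names(marg), marg), collapse = ", "),
            call. = FALSE)
  }

  structure(list(draws = cc$draws, chain = cc$chain,
                 rhat = cc$rhat, ess = cc$ess,
                 lin_names = lin_names, pop_names = pop_names,
                 sigma_names = sigma_names,
                 cond_levels = cond_levels,
                 participants = levels(pid),
                 covariates = covariates,
                 load_range = range(load), prior_sd = prior_sd,
                 chains = chains, warmup = warmup, iter = iter, seed = seed),
            class = "fm_sdt_posterior")
}

#' @export
print.fm_sdt_posterior <- function(x, ...) {
  cat(sprintf("<SDT probit posterior: %d draws (%d chains), %d participants>\n",
              nrow(x$draws), x$chains, length(x$participants)))
  s <- summarize_draws(x$draws[, c(x$pop_names, x$sigma_names)])
  s$rhat <- round(x$rhat[rownames(s)], 3)
  s$ess <- round(x$ess[rownames(s)])
  print(round(s, 3))
  invisible(x)
}

# mean + central credible interval for each column of a draws matrix
summarize_draws <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  data.frame(mean = colMeans(draws),
             ci_low = apply(draws, 2, stats::quantile, a),
             ci_high = apply(draws, 2, stats::quantile, 1 - a),
             row.names = colnames(draws))
}

# Linear-predictor weight row for a given load/condition on one measure.
lin_weights <- function(post, load, cond = NULL) {
  w <- stats::setNames(numeric(length(post$lin_names)), post$lin_names)
  w["intercept"] <- 1
  w["load"] <- load
  if (length(post$cond_levels)) {
    if (is.null(cond)) stop("condition required for this model", call. = FALSE)
    if (!cond %in% post$cond_levels) {
      stop("condition '", cond, "' not in fitted model", call. = FALSE)
    }
    Cm <- stats::contr.sum(length(post$cond_levels))
    rownames(Cm) <- post$cond_levels
    codes <- Cm[cond, ]
    for (j in seq_along(codes)) {
      w[paste0("cond", j)] <- codes[j]
      w[paste0("cond", j, ":load")] <- codes[j] * load
    }
  }
  w
}

# Draws of d' (measure = "d") or bias c (measure = "c") at a load/condition.
cell_draws <- function(post, measure, load, cond = NULL) {
  w <- lin_weights(post, load, cond)
  cols <- paste0(measure, "_", names(w))
  as.numeric(post$draws[, cols, drop = FALSE] %*% w)
}

#' Posterior summaries of d' and bias at given loads
#'
#' Forms the linear combination of population draws at each requested load
#' (and condition, for condition-coded fits) and reports the posterior mean
#' with a central credible interval.
#'
#' @param post An `fm_sdt_posterior`.
#' @param at_loads Numeric vector of tracking loads.
#' @param by_condition Summarize per condition (only for condition-coded
#'   fits).
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `measure` ("dprime"/"bias"), `load`,
#'   `condition`, `mean`, `ci_low`, `ci_high`.
#' @export
summarize_dprime_bias <- function(post, at_loads, by_condition = TRUE,
                                  level = 0.95) {
  stopifnot(inherits(post, "fm_sdt_posterior"))
  if (any(at_loads < post$load_range[1] - 1e-9) ||
      any(at_loads > post$load_range[2] + 1e-9)) {
    warning("summarizing beyond the fitted load range [",
            post$load_range[1], ", ", post$load_range[2], "]", call. = FALSE)
  }
  conds <- if (by_condition && length(post$cond_levels)) post$cond_levels
           else list(NULL)
  rows <- list()
  for (ld in at_loads) for (cn in conds) {
    for (ms in c("d", "c")) {
      dr <- cell_draws(post, ms, ld, if (is.null(cn)) NULL else cn)
      s <- summarize_draws(dr, level)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = if (ms == "d") "dprime" else "bias",
        load = ld, condition = if (is.null(cn)) NA_character_ else cn,
        mean = s$mean, ci_low = s$ci_low, ci_high = s$ci_high)
    }
  }
  do.call(rbind, rows)
}

#' Pooled condition contrasts of d' and bias
#'
#' For each posterior draw, averages the load-specific values of each
#' condition over `pooled_over_loads`, takes the difference
#' `pair[1] - pair[2]`, and summarizes the contrast draws.
#'
#' @param post A condition-coded `fm_sdt_posterior`.
#' @param pair Character vector of two condition labels (A, B); the
#'   contrast is A - B.
#' @param pooled_over_loads Loads to average over (default `c(2, 4)`).
#' @param level Credible level.
#' @return Data frame with rows `dprime` and `bias`: posterior mean and CI
#'   of the pooled difference; contrast draws attached as attribute
#'   `"draws"`.
#' @export
contrast_conditions <- function(post, pair, pooled_over_loads = c(2, 4),
                                level = 0.95) {
  stopifnot(inherits(post, "fm_sdt_posterior"), length(pair) == 2L)
  for (cn in pair) {
    if (!cn %in% post$cond_levels) {
      stop("condition '", cn, "' not in fitted model", call. = FALSE)
    }
  }
  pooled <- function(ms, cn) {
    rowMeans(sapply(pooled_over_loads,
                    function(ld) cell_draws(post, ms, ld, cn)))
  }
  dd <- pooled("d", pair[1]) - pooled("d", pair[2])
  dc <- pooled("c", pair[1]) - pooled("c", pair[2])
  out <- rbind(summarize_draws(dd, level), summarize_draws(dc, level))
  rownames(out) <- c("dprime", "bias")
  out <- cbind(contrast = paste(pair[1], "-", pair[2]), out)
  attr(out, "draws") <- cbind(dprime = dd, bias = dc)
  out
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' For a nested point null at zero, `BF10` is the prior density at 0 over
#' the posterior density at 0. The posterior density is estimated from the
#' draws with a Gaussian kernel using Silverman's bandwidth; when fewer
#' than 50 draws fall within one bandwidth of 0 the estimate is flagged
#' unstable.
#'
#' @param post An `fm_sdt_posterior`, or a numeric vector of posterior
#'   draws of the parameter.
#' @param parameter Parameter name (ignored when `post` is a vector).
#' @param prior_mean,prior_sd The (normal) prior on the parameter; defaults
#'   N(0, 1), the analysis prior.
#' @return List of class `fm_bf`: `parameter`, `BF10`, `method`,
#'   `unstable`, `exp_coef` (the exponentiated posterior-mean coefficient,
#'   an odds-ratio-style effect size for probit slopes).
#' @export
savage_dickey_bf <- function(post, parameter = NULL,
                             prior_mean = 0, prior_sd = 1) {
  draws <- if (is.numeric(post)) post else {
    if (!parameter %in% colnames(post$draws)) {
      stop("parameter '", parameter, "' not in posterior", call. = FALSE)
    }
    post$draws[, parameter]
  }
  n <- length(draws)
  sdv <- stats::sd(draws)
  iqr <- stats::IQR(draws) / 1.34
  h <- 0.9 * min(sdv, if (iqr > 0) iqr else sdv) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) h <- max(sdv, 1e-8)
  dens0 <- mean(stats::dnorm((0 - draws) / h)) / h
  unstable <- sum(abs(draws) < h) < 50
  bf <- stats::dnorm(0, prior_mean, prior_sd) / max(dens0, .Machine$double.xmin)
  structure(list(parameter = parameter %||% "draws", BF10 = bf,
                 method = "savage-dickey-kde-silverman",
                 unstable = unstable,
                 exp_coef = exp(mean(draws))),
            class = "fm_bf")
}

#' @export
print.fm_bf <- function(x, ...) {
  cat(sprintf("BF10(%s) = %.3g%s  [exp(coef) = %.3f]\n", x$parameter,
              x$BF10, if (x$unstable) " (unstable)" else "", x$exp_coef))
  invisible(x)
}

#' Attention-check exclusion rule
#'
#' Excludes participants whose average accuracy in the traditional-MOT
#' two-target cell is strictly below 50%. Participants with no trials in
#' that cell are flagged rather than silently kept.
#'
#' @param responses Response data frame.
#' @param condition Condition label of the check cell (default
#'   "TRADITIONAL").
#' @param load Load of the check cell (default 2).
#' @return List: `kept` (filtered responses), `excluded` (participant ids),
#'   `flagged` (participants missing the cell).
#' @export
apply_exclusion <- function(responses, condition = "TRADITIONAL", load = 2) {
  cell <- responses$condition == condition & responses$n_targets == load
  ids <- unique(responses$participant)
  acc <- tapply(responses$correct[cell], responses$participant[cell], mean)
  excluded <- names(acc)[acc < 0.5]
  flagged <- setdiff(as.character(ids), names(acc))
  kept <- responses[!as.character(responses$participant) %in% excluded, ,
                    drop = FALSE]
  list(kept = kept, excluded = excluded, flagged = flagged)
}

#' Closed-form per-participant d' and bias
#'
#' Equal-variance SDT estimates per participant x condition x load cell
#' from hit and false-alarm rates: `d' = qnorm(hit) - qnorm(fa)` and
#' `c = -qnorm(fa)` (criterion distance from the distractor mean). Rates of
#' exactly 0 or 1 are continuity-corrected to `1/(2N)` resp. `1 - 1/(2N)`
#' with `N` the number of trials of that query type in the cell.
#'
#' @param responses Response data frame.
#' @return Data frame `participant`, `condition`, `n_targets`, `n_trials`,
#'   `hit_rate`, `fa_rate`, `dprime`, `bias` (NA for cells missing a query
#'   type).
#' @export
per_participant_dprime <- function(responses) {
  key <- interaction(responses$participant, responses$condition,
                     responses$n_targets, drop = TRUE)
  rows <- lapply(split(responses, key), function(d) {
    tq <- d[d$queried_is_target, ]
    dq <- d[!d$queried_is_target, ]
    rate <- function(sub) {
      if (nrow(sub) == 0L) return(NA_real_)
      r <- mean(sub$response == "target")
      n <- nrow(sub)
      if (r == 0) r <- 1 / (2 * n)
      if (r == 1) r <- 1 - 1 / (2 * n)
      r
    }
    h <- rate(tq); f <- rate(dq)
    data.frame(participant = d$participant[1], condition = d$condition[1],
               n_targets = d$n_targets[1], n_trials = nrow(d),
               hit_rate = h, fa_rate = f,
               dprime = stats::qnorm(h) - stats::qnorm(f),
               bias = -stats::qnorm(f))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$condition, out$n_targets), ]
}
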