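#' Predict per-participant sensitivity in one condition from another
#'
#' Multilevel Gaussian regression of per-participant sensitivity (or bias)
#' in condition B on the same participant's value in condition A, a
#' deviation-coded number-of-targets factor, and their interaction, with a
#' participant random intercept:
#' `y = b0 + b1 * x + b2 * load + b3 * x:load + u_p + eps`.
#' Priors are N(0, 1) on the coefficients and half-normal(0, 1) on both the
#' random-intercept SD and the residual SD. Sampling is conjugate Gibbs
#' (normal updates for coefficients and intercepts, slice updates for the
#' SDs).
#'
#' @param dtab Per-participant table from [per_participant_dprime()] (or
#'   any data frame with `participant`, `condition`, `n_targets` and the
#'   measure column).
#' @param outcome_condition,predictor_condition Condition labels B and A.
#' @param measure Column to model, `"dprime"` (default) or `"bias"`.
#' @param loads The two loads defining the load factor (deviation coded
#'   -1/+1; default `c(2, 4)`).
#' @param chains,warmup,iter,seed Sampler layout, as in [fit_sdt_probit()].
#' @return An `fm_prediction_fit`: `draws` with columns `intercept`,
#'   `slope`, `load`, `slope:load`, `sigma_u`, `sigma_eps` and random
#'   intercepts, plus `rhat`, `ess`, the model frame and fitted-value
#'   machinery used by [bayesian_r2()].
#' @export
fit_prediction_model <- function(dtab, outcome_condition, predictor_condition,
                                 measure = c("dprime", "bias"),
                                 loads = c(2, 4),
                                 chains = 4, warmup = 1000, iter = 1000,
                                 seed = 1) {
  measure <- match.arg(measure)
  a <- dtab[dtab$condition == predictor_condition &
              dtab$n_targets %in% loads, c("participant", "n_targets", measure)]
  b <- dtab[dtab$condition == outcome_condition &
              dtab$n_targets %in% loads, c("participant", "n_targets", measure)]
  names(a)[3] <- "x"; names(b)[3] <- "y"
  mf <- merge(b, a, by = c("participant", "n_targets"))
  mf <- mf[stats::complete.cases(mf), ]
  if (length(unique(mf$participant)) < 3L) {
    stop("need >= 3 participants with both conditions", call. = FALSE)
  }
  if (stats::var(mf$x) == 0) {
    stop("degenerate design: constant predictor", call. = FALSE)
  }
  load_code <- ifelse(mf$n_targets == max(loads), 1, -1)
  W <- cbind(intercept = 1, slope = mf$x, load = load_code,
             `slope:load` = mf$x * load_code)
  pid <- factor(mf$participant)
  Z <- diag(nlevels(pid))[as.integer(pid), , drop = FALSE]
  U <- cbind(W, Z)
  colnames(U) <- c(colnames(W), paste0("u[", levels(pid), "]"))
  y <- mf$y
  n_pop <- ncol(W); P <- ncol(Z)
  XtX <- crossprod(U); Xty0 <- crossprod(U, y)

  init_fn <- function(ch) {
    list(beta = stats::rnorm(ncol(U), 0, 0.1),
         sigma_u = 0.5, sigma_eps = stats::sd(y))
  }
  kernel <- function(state) {
    Dinv <- c(rep(1, n_pop), rep(1 / state$sigma_u^2, P))
    beta <- draw_coefs(XtX, Xty0, Dinv, s2 = state$sigma_eps^2)
    Su <- sum(beta[n_pop + seq_len(P)]^2)
    sigma_u <- slice_pos(state$sigma_u,
                         function(s) logpost_sigma(s, P, Su))
    res <- y - as.numeric(U %*% beta)
    SSe <- sum(res^2)
    sigma_eps <- slice_pos(state$sigma_eps,
                           function(s) logpost_sigma(s, length(y), SSe))
    list(beta = beta, sigma_u = sigma_u, sigma_eps = sigma_eps)
  }
  extract <- function(state) {
    stats::setNames(c(state$beta, state$sigma_u, state$sigma_eps),
                    c(colnames(U), "sigma_u", "sigma_eps"))
  }

  sims <- run_chains(init_fn, kernel, extract, chains, warmup, iter, seed)
  cc <- combine_chains(sims)
  structure(list(draws = cc$draws, rhat = cc$rhat, ess = cc$ess,
                 U = U, y = y, n_pop = n_pop,
                 model_frame = mf, measure = measure,
                 outcome_condition = outcome_condition,
                 predictor_condition = predictor_condition,
                 chains = chains, warmup = warmup, iter = iter, seed = seed),
            class = "fm_prediction_fit")
}

#' @export
print.fm_prediction_fit <- function(x, ...) {
  cat(sprintf("<prediction fit: %s[%s] ~ %s[%s], %d rows>\n",
              x$measure, x$outcome_condition, x$measure,
              x$predictor_condition, length(x$y)))
  keep <- c("intercept", "slope", "load", "slope:load",
            "sigma_u", "sigma_eps")
  print(round(summarize_draws(x$draws[, keep]), 3))
  invisible(x)
}

#' Posterior summary of a prediction-model coefficient
#'
#' @param fit An `fm_prediction_fit`.
#' @param parameter One of `"intercept"`, `"slope"`, `"load"`,
#'   `"slope:load"`.
#' @param level Credible level.
#' @export
summarize_prediction <- function(fit, parameter = "slope", level = 0.95) {
  s <- summarize_draws(fit$draws[, parameter, drop = FALSE], level)
  cbind(parameter = parameter, s)
}

#' Bayesian R-squared of a fitted prediction model
#'
#' Per posterior draw, `R2 = Var(fitted) / (Var(fitted) + Var(residual))`.
#' Fitted values are the population-level predictions (coefficients only);
#' the modeled residual variance is `sigma_u^2 + sigma_eps^2`, the marginal
#' variance left around the population line. Counting the fitted
#' participant intercepts as signal instead would let them absorb residual
#' noise and inflate R2 in small groups, so the population-level form is
#' the calibrated one.
#'
#' @param fit An `fm_prediction_fit`.
#' @param level Credible level (default 0.95).
#' @return One-row data frame `mean`, `ci_low`, `ci_high`; the per-draw R2
#'   values attached as attribute `"draws"`.
#' @export
bayesian_r2 <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fm_prediction_fit"))
  if (length(fit$y) < 2L) {
    stop("undefined variance: need >= 2 observations", call. = FALSE)
  }
  pop_cols <- colnames(fit$U)[seq_len(fit$n_pop)]
  fitted <- fit$draws[, pop_cols, drop = FALSE] %*%
    t(fit$U[, seq_len(fit$n_pop), drop = FALSE])
  var_fit <- apply(fitted, 1, stats::var)
  var_res <- fit$draws[, "sigma_u"]^2 + fit$draws[, "sigma_eps"]^2
  r2 <- var_fit / (var_fit + var_res)
  out <- summarize_draws(r2, level)
  rownames(out) <- "R2"
  attr(out, "draws") <- as.numeric(r2)
  out
}
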