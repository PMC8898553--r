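#' Population parameters of the generative SDT observer
#'
#' The equal-variance signal detection observer answers "target" with
#' probability `Phi(-c + d' * X)`, where `X` indicates that the queried
#' object really was a target, `d'` is sensitivity and `c` is the bias
#' (criterion), measured as the distance of the decision criterion from the
#' mean of the distractor-evidence distribution; positive `c` is
#' conservative (miss-prone). Both `d'` and `c` are linear in the tracking
#' load with participant-level random intercepts and slopes, optional
#' condition offsets, and an optional linear effect of a sudden-motion
#' covariate on either predictor.
#'
#' Defaults are the load-1 sensitivities/biases and per-target decrements
#' implied by tracking fish at loads 1/3/5: grand intercepts
#' `alpha_d = 3.58`, `alpha_c = 1.97` and slopes `beta_d = -0.50`,
#' `beta_c = -0.22` per added target (so d' = 3.08 and c = 1.75 at load 1).
#'
#' @param alpha_d,beta_d Sensitivity intercept and change per added target.
#' @param alpha_c,beta_c Criterion intercept and change per added target.
#' @param condition_offsets Named list: per condition a numeric
#'   `c(delta_d, delta_c)` added to d' and c (deviation offsets).
#' @param sigma_ad,sigma_bd SDs of participant deviations of the d'
#'   intercept and load slope.
#' @param sigma_ac,sigma_bc Same for the criterion.
#' @param rho Cross-condition correlation of participant d'-intercept
#'   deviations (equicorrelated across conditions).
#' @param gamma_d,gamma_c Change in d' / c per sudden-motion event counted
#'   in the covariate columns of the trial table.
#' @export
population_params <- function(alpha_d = 3.58, beta_d = -0.50,
                              alpha_c = 1.97, beta_c = -0.22,
                              condition_offsets = NULL,
                              sigma_ad = 0.5, sigma_bd = 0.1,
                              sigma_ac = 0.3, sigma_bc = 0.05,
                              rho = 0, gamma_d = 0, gamma_c = 0) {
  sds <- c(sigma_ad, sigma_bd, sigma_ac, sigma_bc)
  if (any(sds < 0)) stop("parameter error: SDs must be >= 0", call. = FALSE)
  if (abs(rho) > 1) stop("parameter error: |rho| must be <= 1", call. = FALSE)
  structure(list(alpha_d = alpha_d, beta_d = beta_d,
                 alpha_c = alpha_c, beta_c = beta_c,
                 condition_offsets = condition_offsets,
                 sigma_ad = sigma_ad, sigma_bd = sigma_bd,
                 sigma_ac = sigma_ac, sigma_bc = sigma_bc,
                 rho = rho, gamma_d = gamma_d, gamma_c = gamma_c),
            class = "fm_population")
}

#' Draw participant-level observer parameters
#'
#' Participant deviations are zero-mean Gaussian with the population SDs.
#' With `rho != 0` and named condition offsets present, the d'-intercept
#' deviation is drawn per condition from the equicorrelated multivariate
#' Gaussian with correlation `rho`.
#'
#' @param pop A [population_params()].
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return Data frame with one row per participant: `participant`, `a_p`,
#'   `b_p` (d' intercept/slope deviations), `u_p`, `v_p` (criterion
#'   deviations), plus `a_p.<condition>` columns when `rho != 0`.
#' @export
sample_observers <- function(pop, n, seed = 1) {
  stopifnot(inherits(pop, "fm_population"))
  if (n < 1) stop("parameter error: n >= 1", call. = FALSE)
  with_seed(seed, {
    out <- data.frame(
      participant = seq_len(n),
      a_p = stats::rnorm(n, 0, pop$sigma_ad),
      b_p = stats::rnorm(n, 0, pop$sigma_bd),
      u_p = stats::rnorm(n, 0, pop$sigma_ac),
      v_p = stats::rnorm(n, 0, pop$sigma_bc))
    conds <- names(pop$condition_offsets)
    if (pop$rho != 0 && length(conds) >= 2) {
      k <- length(conds)
      Sigma <- pop$sigma_ad^2 * ((1 - pop$rho) * diag(k) +
                                   pop$rho * matrix(1, k, k))
      L <- chol_psd(Sigma)
      Z <- matrix(stats::rnorm(n * k), n, k) %*% t(L)
      colnames(Z) <- paste0("a_p.", conds)
      out$a_p <- NULL
      out <- cbind(out, Z)
    }
    out
  })
}

# Cholesky factor tolerant of the rho = 1 (singular) boundary.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Simulate observer responses for a trial table
#'
#' Computes each participant x trial response probability
#' `Phi(-c_p + d'_p * X)` under the generative model of
#' [population_params()] and draws Bernoulli responses.
#'
#' @param observers Data frame from [sample_observers()].
#' @param trials Trial table (design builders); optional numeric columns
#'   `sudden_target`, `sudden_distractor` act as covariates through
#'   `gamma_d`/`gamma_c` (applied to the `sudden_target` count).
#' @param pop The generating [population_params()].
#' @param seed Integer seed.
#' @return Data frame with one row per participant x trial: `participant`,
#'   `trial_id`, `condition`, `n_targets`, `queried_is_target`,
#'   `sudden_target`, `sudden_distractor`, `response`
#'   ("target"/"distractor"), `correct`.
#' @export
simulate_responses <- function(observers, trials, pop, seed = 1) {
  stopifnot(inherits(pop, "fm_population"))
  conds <- unique(trials$condition)
  offs <- pop$condition_offsets
  if (!is.null(offs) && !all(conds %in% names(offs))) {
    stop("condition offsets missing for some trial conditions", call. = FALSE)
  }
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(observers)), function(pi) {
      ob <- observers[pi, ]
      n <- trials$n_targets
      X <- as.numeric(trials$queried_is_target)
      cov_t <- if ("sudden_target" %in% names(trials)) trials$sudden_target else 0
      dd <- dc <- numeric(nrow(trials))
      if (!is.null(offs)) {
        for (cn in conds) {
          sel <- trials$condition == cn
          dd[sel] <- offs[[cn]][1]
          dc[sel] <- offs[[cn]][2]
        }
      }
      a_p <- if ("a_p" %in% names(ob)) rep(ob$a_p, nrow(trials)) else {
        # condition-specific intercept deviations (correlated draws)
        vapply(trials$condition,
               function(cn) ob[[paste0("a_p.", cn)]], numeric(1))
      }
      dprime <- pop$alpha_d + dd + a_p + (pop$beta_d + ob$b_p) * n +
        pop$gamma_d * cov_t
      crit <- pop$alpha_c + dc + ob$u_p + (pop$beta_c + ob$v_p) * n +
        pop$gamma_c * cov_t
      p_target <- stats::pnorm(-crit + dprime * X)
      resp <- ifelse(stats::runif(nrow(trials)) < p_target,
                     "target", "distractor")
      data.frame(participant = ob$participant,
                 trial_id = trials$trial_id,
                 condition = trials$condition,
                 n_targets = n,
                 queried_is_target = trials$queried_is_target,
                 sudden_target = if (length(cov_t) == 1) rep(cov_t, nrow(trials)) else cov_t,
                 sudden_distractor = if ("sudden_distractor" %in% names(trials))
                   trials$sudden_distractor else 0,
                 response = resp,
                 correct = (resp == "target") == trials$queried_is_target)
    })
    do.call(rbind, recs)
  })
}

#' Read/write response CSV
#'
#' Columns `participant,trial_id,condition,n_targets,queried_is_target,
#' sudden_target,sudden_distractor,response,correct`.
#' @param responses Response data frame.
#' @param path CSV path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$queried_is_target <- as.logical(df$queried_is_target)
  df$correct <- as.logical(df$correct)
  df
}
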