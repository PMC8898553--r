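# Conjugate Gibbs machinery shared by the probit SDT model and the Gaussian
# prediction model: truncated-normal data augmentation (Albert & Chib),
# joint normal updates of coefficients + random effects, and slice sampling
# for standard-deviation hyperparameters under half-normal priors.

# Draw z_i ~ N(mu_i, 1) truncated to (0, Inf) if y_i = 1, (-Inf, 0) if 0.
# Inverse-CDF method, vectorized; u clamped away from 0/1 for stability at
# extreme linear predictors.
rtruncnorm_latent <- function(mu, y) {
  p0 <- stats::pnorm(-mu)            # mass below 0
  u <- stats::runif(length(mu))
  u <- ifelse(y == 1, p0 + u * (1 - p0), u * p0)
  u <- pmin(pmax(u, 1e-14), 1 - 1e-14)
  mu + stats::qnorm(u)
}

# One draw of beta ~ N(Lambda^-1 b, Lambda^-1) with Lambda = XtX/s2 + Dinv,
# b = Xty/s2. Dinv is the diagonal prior precision vector.
draw_coefs <- function(XtX, Xty, Dinv, s2 = 1) {
  Lambda <- XtX / s2
  diag(Lambda) <- diag(Lambda) + Dinv
  ch <- chol(Lambda)
  m <- backsolve(ch, backsolve(ch, Xty / s2, transpose = TRUE))
  m + backsolve(ch, stats::rnorm(length(m)))
}

# Univariate slice sampler (stepping out + shrinkage) for a positive scalar.
slice_pos <- function(x0, logf, w = 0.5, max_steps = 50) {
  ly <- logf(x0) - stats::rexp(1)
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  k <- max_steps
  while (k > 0 && lo > 1e-12 && logf(lo) > ly) { lo <- lo - w; k <- k - 1 }
  lo <- max(lo, 1e-12)
  k <- max_steps
  while (k > 0 && logf(hi) > ly) { hi <- hi + w; k <- k - 1 }
  for (i in 1:100) {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > ly) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  x0
}

# log density (up to a constant) of sigma given q deviations with sum of
# squares S, under a half-normal(0,1) prior on sigma.
logpost_sigma <- function(sigma, q, S) {
  if (sigma <= 0) return(-Inf)
  -q * log(sigma) - S / (2 * sigma^2) - sigma^2 / 2
}

# Split-Rhat (Gelman et al.): draws is iterations x chains.
split_rhat <- function(draws) {
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Run `chains` independent Gibbs chains of a model-specific kernel.
# kernel(state) advances one iteration and returns the new state; extract
# (state) returns the named numeric vector to store.
run_chains <- function(init_fn, kernel, extract, chains, warmup, iter, seed) {
  sims <- vector("list", chains)
  for (ch in seq_len(chains)) {
    with_seed(child_seed(seed, ch), {
      state <- init_fn(ch)
      first <- extract(state)
      out <- matrix(NA_real_, iter, length(first),
                    dimnames = list(NULL, names(first)))
      for (it in seq_len(warmup)) state <- kernel(state)
      for (it in seq_len(iter)) {
        state <- kernel(state)
        out[it, ] <- extract(state)
      }
      sims[[ch]] <- out
    })
  }
  sims
}

# Combine chain matrices; compute Rhat and ESS per column.
combine_chains <- function(sims) {
  draws <- do.call(rbind, sims)
  pn <- colnames(sims[[1]])
  rhat <- vapply(pn, function(p) {
    split_rhat(sapply(sims, function(s) s[, p]))
  }, numeric(1))
  ess <- vapply(pn, function(p) {
    sum(vapply(sims, function(s) {
      as.numeric(coda::effectiveSize(s[, p]))
    }, numeric(1)))
  }, numeric(1))
  list(draws = draws, rhat = rhat, ess = ess,
       chain = rep(seq_along(sims), each = nrow(sims[[1]])))
}
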