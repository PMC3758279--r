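# Shared fixtures: small in-code cohorts and matrices.  Event counts are
# kept small so the full suite stays fast; the generator's statistical
# structure is unchanged.

# A compact spec with a strong, tube-4/6-localized blast signal.
small_strong_spec <- function(n_aml = 6L, n_healthy = 10L,
                              events = c(100L, 150L), shift = 3) {
  cohort_spec(n_aml = n_aml, n_healthy = n_healthy,
              events_range = events, blast_shift = shift)
}

# Null spec: no blast population, no patient effect -> both classes are
# identically distributed, events i.i.d. within class.
small_null_spec <- function(n_aml = 6L, n_healthy = 10L,
                            events = c(100L, 150L),
                            patient_effect_sd = 0) {
  cohort_spec(n_aml = n_aml, n_healthy = n_healthy,
              events_range = events,
              blast_fraction_range = c(0, 0), blast_shift = 0,
              patient_effect_sd = patient_effect_sd)
}

# Spec whose blast population differs from base ONLY in tube 4 (no SS
# reduction, no tube-6 shift), so tube 4 is the only informative tube.
tube4_only_spec <- function(n_aml = 10L, n_healthy = 25L,
                            events = c(100L, 160L), shift = 3) {
  base <- flowlasso:::.default_base_populations()
  blast <- lapply(1:7, function(t) {
    pop <- base[[t]][[1L]]
    mu <- pop$mean
    if (t == 4L) {
      sd <- sqrt(diag(pop$cov))
      mu[c(4L, 6L)] <- mu[c(4L, 6L)] + shift * sd[c(4L, 6L)]
    }
    population_spec(1, mu, pop$cov)
  })
  cohort_spec(n_aml = n_aml, n_healthy = n_healthy,
              events_range = events,
              blast_fraction_range = c(0.25, 0.5),
              base_populations = base, blast_populations = blast,
              patient_effect_sd = 0.05)
}

# Deterministic patient with given per-tube constant rows (for exact
# feature values).
constant_patient <- function(value = 1, n_events = 5L) {
  tubes <- lapply(1:7, function(t) {
    event_matrix(matrix(value, n_events, 7))
  })
  names(tubes) <- as.character(1:7)
  patient_sample("const", 0, tubes)
}

random_patient <- function(id = "r1", label = 0, n_events = 50L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tubes <- lapply(1:7, function(t) {
    event_matrix(matrix(rnorm(n_events * 7, mean = 3), n_events, 7))
  })
  names(tubes) <- as.character(1:7)
  patient_sample(id, label, tubes)
}

# Simulated logistic design with the first `k_true` features informative.
logistic_instance <- function(n = 200L, p = 10L, k_true = 1L,
                              effect = 3, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- X[, seq_len(k_true), drop = FALSE] %*% rep(effect, k_true)
  y <- as.numeric(runif(n) < plogis(drop(eta)))
  # guard against degenerate draws
  if (sum(y) < 2 || sum(1 - y) < 2) {
    y[1:2] <- 1
    y[3:4] <- 0
  }
  list(X = X, y = y)
}

# Independent L1-logistic oracle: maximizes the penalized mean
# log-likelihood via box-constrained BFGS on the split beta = b+ - b-.
# `lambda` is on the mean-log-likelihood scale, features already
# standardized by the caller.
l1_logreg_oracle <- function(Xs, y, lambda, start = NULL) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  negobj <- function(par) {
    b0 <- par[1]
    bp <- par[2:(p + 1)]
    bm <- par[(p + 2):(2 * p + 1)]
    beta <- bp - bm
    pr <- plogis(b0 + drop(Xs %*% beta))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -(mean(y * log(pr) + (1 - y) * log(1 - pr)) -
        lambda * sum(bp + bm))
  }
  grad <- function(par) {
    b0 <- par[1]
    bp <- par[2:(p + 1)]
    bm <- par[(p + 2):(2 * p + 1)]
    beta <- bp - bm
    pr <- plogis(b0 + drop(Xs %*% beta))
    g <- drop(crossprod(Xs, y - pr)) / n
    -c(mean(y - pr), g - lambda, -g - lambda)
  }
  if (is.null(start)) start <- rep(0, 2 * p + 1)
  fit <- optim(start, negobj, grad, method = "L-BFGS-B",
               lower = c(-Inf, rep(0, 2 * p)),
               control = list(maxit = 5000, factr = 1e1))
  beta <- fit$par[2:(p + 1)] - fit$par[(p + 2):(2 * p + 1)]
  list(beta0 = fit$par[1], beta = beta, objective = -fit$value)
}

# Mean-log-likelihood-scale objective on standardized features.
mean_penalized_objective <- function(b0, beta, Xs, y, lambda) {
  pr <- plogis(b0 + drop(Xs %*% beta))
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  mean(y * log(pr) + (1 - y) * log(1 - pr)) - lambda * sum(abs(beta))
}
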