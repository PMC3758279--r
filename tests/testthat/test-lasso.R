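test_that("the penalized objective matches hand evaluation", {
  set.seed(20)
  X <- matrix(rnorm(4 * 3), 4, 3)
  y <- c(0, 1, 1, 0)
  # beta = 0: n * log(1/2), penalty inert
  expect_equal(penalized_objective(0, rep(0, 3), X, y, lambda = 5),
               4 * log(0.5))
  # lambda = 0 reduces to the Bernoulli log-likelihood
  b <- c(0.5, -1, 2)
  eta <- 0.3 + drop(X %*% b)
  ll <- sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  expect_equal(penalized_objective(0.3, b, X, y, 0), ll,
               tolerance = 1e-12)
  # manual four-term sum with the penalty
  expect_equal(penalized_objective(0.3, b, X, y, 1.5),
               ll - 1.5 * sum(abs(b)), tolerance = 1e-12)
})

test_that("the path starts empty at lambda_max with the null intercept", {
  inst <- logistic_instance(n = 80, p = 6, seed = 2)
  path <- fit_l1_path(inst$X, inst$y, nlambda = 25)
  expect_equal(path$df[1], 0)
  expect_equal(path$a0_std[1], qlogis(mean(inst$y)), tolerance = 1e-6)
  expect_gt(path$df[length(path$lambda)], 0)
  # a penalty above lambda_max also yields the empty model
  above <- fit_l1_path(inst$X, inst$y, lambda = path$lambda[1] * 1.01)
  expect_equal(sum(above$beta != 0), 0)
  expect_error(fit_l1_path(inst$X, rep(1, 80)), "per class")
})

test_that("path solutions match an independent convex solver", {
  for (s in 1:3) {
    inst <- logistic_instance(n = 20, p = 10, k_true = 2, effect = 1.5,
                              seed = s)
    path <- fit_l1_path(inst$X, inst$y, nlambda = 20,
                        lambda_min_ratio = 0.05)
    Xs <- sweep(sweep(inst$X, 2, path$center), 2, path$scale, `/`)
    for (l in c(3L, 10L, 17L)) {
      lam <- path$lambda[l]
      oracle <- l1_logreg_oracle(Xs, inst$y, lam)
      obj_fit <- mean_penalized_objective(path$a0_std[l],
                                          path$beta_std[, l],
                                          Xs, inst$y, lam)
      expect_equal(obj_fit, oracle$objective, tolerance = 1e-6)
    }
  }
})

test_that("KKT conditions hold along the path", {
  inst <- logistic_instance(n = 100, p = 8, k_true = 2, seed = 7)
  path <- fit_l1_path(inst$X, inst$y, nlambda = 40)
  expect_lt(max(kkt_violation(path, inst$X, inst$y)), 1e-6)
})

test_that("coefficients on the original scale reproduce predictions", {
  inst <- logistic_instance(n = 60, p = 5, seed = 9)
  X <- sweep(inst$X, 2, c(1, 2, 3, 4, 5), `*`)  # unequal scales
  path <- fit_l1_path(X, inst$y, nlambda = 15)
  l <- 12L
  m <- path_model(path, index = l)
  Xs <- sweep(sweep(X, 2, path$center), 2, path$scale, `/`)
  eta_std <- path$a0_std[l] + drop(Xs %*% path$beta_std[, l])
  eta_orig <- m$beta0 + drop(X %*% m$beta)
  expect_equal(eta_orig, eta_std, tolerance = 1e-10)
})

test_that("an informative feature enters the path first", {
  hits <- 0L
  for (s in 1:20) {
    inst <- logistic_instance(n = 200, p = 10, k_true = 1, effect = 3,
                              seed = 1000 + s)
    path <- fit_l1_path(inst$X, inst$y, nlambda = 50)
    first <- which(path$df > 0)[1]
    if (identical(names(which(path$beta_std[, first] != 0)), "f1")) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("cross-validated penalty selection is sparse and reproducible", {
  set.seed(12)
  X <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- as.numeric(X[, 1] > 0)   # perfectly separable on f1
  X[, 1] <- X[, 1] + (2 * y - 1) * 0.5  # with a clear margin
  cv1 <- select_lambda_cv(X, y, k = 5, seed = 3)
  cv2 <- select_lambda_cv(X, y, k = 5, seed = 3)
  expect_equal(cv1$lambda, cv2$lambda)
  expect_equal(cv1$model$beta, cv2$model$beta)
  # a perfectly separable single feature drives CV error to zero
  expect_equal(cv1$cv_error, 0)
  expect_true("f1" %in% model_support(cv1$model))

  # pure-noise features select heavy regularization: the selected index
  # concentrates near the sparse end of the grid (tie-break toward the
  # largest penalty), and never in the weakly regularized half
  idxs <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    Xn <- matrix(rnorm(100 * 10), 100, 10)
    yn <- rep(c(0, 1), each = 50)
    select_lambda_cv(Xn, yn, k = 10, seed = s, nlambda = 40)$index
  }, integer(1))
  expect_lte(median(idxs), 10L)          # typical pick: top quartile
  expect_gte(sum(idxs <= 20L), 19L)      # almost all in the top half
})

test_that("prediction applies the logistic map to the linear score", {
  m <- structure(list(beta0 = 0, beta = c(a = 0, b = 0),
                      labels = c("a", "b")),
                 class = "l1_logreg")
  expect_equal(predict_proba(m, c(a = 3, b = -2)), 0.5)
  set.seed(30)
  m2 <- structure(list(beta0 = 0.3, beta = c(a = 1.2, b = -0.7),
                       labels = c("a", "b")),
                  class = "l1_logreg")
  v <- c(a = 0.4, b = 1.1)
  expect_equal(predict_proba(m2, v),
               1 / (1 + exp(-(0.3 + sum(v * m2$beta)))),
               tolerance = 1e-15)
  # monotone in a positively weighted feature
  expect_gt(predict_proba(m2, c(a = 1.4, b = 1.1)),
            predict_proba(m2, v))
  expect_error(predict_proba(m2, c(zz = 1, b = 2)), "labels")
})

test_that("the best-subsets report picks the lowest-CV point per size", {
  inst <- logistic_instance(n = 150, p = 8, k_true = 3, effect = 2,
                            seed = 77)
  cv <- select_lambda_cv(inst$X, inst$y, k = 5, seed = 1, nlambda = 60)
  rep <- best_subsets_report(cv$path)
  expect_true(all(diff(rep$size) > 0))
  for (r in seq_len(nrow(rep))) {
    expect_length(rep$markers[[r]], rep$size[r])
    same_size <- cv$path$df == rep$size[r]
    expect_equal(rep$cv_error[r], min(cv$path$cv_error[same_size]))
  }
  # informative features recovered in the size-3 row (if present)
  if (3 %in% rep$size) {
    expect_setequal(rep$markers[[which(rep$size == 3)]],
                    c("f1", "f2", "f3"))
  }
  expect_error(best_subsets_report(fit_l1_path(inst$X, inst$y,
                                               nlambda = 5)),
               "no CV errors")
})

test_that("sparse models survive a JSON round trip", {
  inst <- logistic_instance(n = 60, p = 6, seed = 5)
  cv <- select_lambda_cv(inst$X, inst$y, k = 5, seed = 2, nlambda = 30)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(cv$model, f)
  m2 <- read_model(f)
  v <- inst$X[7, ]
  expect_equal(predict_proba(m2, v), predict_proba(cv$model, v),
               tolerance = 1e-12)
})

test_that("the path agrees with an established penalized-GLM fitter", {
  skip_if_not_installed("glmnet")
  inst <- logistic_instance(n = 120, p = 8, k_true = 2, effect = 1.5,
                            seed = 55)
  path <- fit_l1_path(inst$X, inst$y, nlambda = 20,
                      lambda_min_ratio = 0.05)
  g <- glmnet::glmnet(inst$X, inst$y, family = "binomial",
                      lambda = path$lambda, standardize = TRUE,
                      thresh = 1e-12)
  for (l in c(5L, 10L, 15L)) {
    expect_equal(unname(path$beta[, l]),
                 unname(as.numeric(g$beta[, l])), tolerance = 1e-4)
    expect_equal(path$a0[l], unname(g$a0[l]), tolerance = 1e-4)
  }
})
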