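#' L1-penalized Bernoulli log-likelihood
#'
#' The objective maximized by the sparse aggregation model (intercept
#' unpenalized):
#' `sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)] - lambda * sum_j |beta_j|`
#' with `p_i = plogis(beta0 + x_i' beta)`.  Probabilities are clamped at
#' `1e-12` before taking logs.
#'
#' Note the penalty here multiplies the *summed* log-likelihood; the path
#' fitter's `lambda` is on the mean-log-likelihood scale (divide by `n`
#' to convert), following the coordinate-descent convention.
#'
#' @param beta0 Intercept.
#' @param beta Coefficient vector.
#' @param X Design matrix (rows = patients).
#' @param y Binary 0/1 response.
#' @param lambda Nonnegative penalty weight.
#' @return The penalized log-likelihood (a scalar).
#' @export
penalized_objective <- function(beta0, beta, X, y, lambda) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)), lambda >= 0)
  p <- stats::plogis(beta0 + drop(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p)) - lambda * sum(abs(beta))
}

# Fit at a single lambda by IRLS around the compiled coordinate-descent
# solver (warm-started).
.fit_one_lambda <- function(Xs, y, lambda, b0, beta, tol,
                            max_sweeps, max_irls = 100L) {
  sweeps <- 0L
  for (it in seq_len(max_irls)) {
    eta <- b0 + drop(Xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    b0_old <- b0
    beta_old <- beta
    fit <- .cd_wls_cpp(Xs, w, z, b0, beta, lambda, tol,
                       as.integer(max(max_sweeps - sweeps, 1L)))
    b0 <- fit$b0
    beta <- fit$beta
    sweeps <- sweeps + fit$sweeps
    if (max(abs(c(b0 - b0_old, beta - beta_old))) < tol ||
        sweeps >= max_sweeps) {
      break
    }
  }
  list(b0 = b0, beta = beta, sweeps = sweeps)
}

#' Fit the L1-regularized logistic regression path
#'
#' Coordinate-descent fit over a decreasing log-spaced penalty grid with
#' warm starts.  Predictors are standardized internally (location =
#' training mean, scale = population standard deviation); coefficients
#' are reported on both the standardized and the original scale.  The
#' grid starts at the smallest `lambda` with an all-zero solution,
#' `lambda_max = max_j |(1/n) sum_i xs_ij (y_i - ybar)|` (the KKT
#' activation threshold), and descends to
#' `lambda_max * lambda_min_ratio`.
#'
#' `lambda` is on the mean log-likelihood scale: the solution at
#' `lambda` maximizes `(1/n) loglik - lambda * sum |beta_std|`.
#'
#' @param X Feature matrix, rows = patients; column names become feature
#'   labels.
#' @param y Binary 0/1 response with both classes present (>= 2 each).
#' @param nlambda Number of grid points, default 100.
#' @param lambda_min_ratio Ratio of smallest to largest penalty, default
#'   `1e-3`.
#' @param lambda Optional explicit decreasing penalty sequence
#'   (overrides the automatic grid), e.g. to refit on a subset at the
#'   full-data grid during cross-validation.
#' @param tol Convergence tolerance on the maximum coefficient change,
#'   default `1e-8`.
#' @param max_sweeps Cap on total coordinate-descent sweeps per penalty
#'   value, default `1e5`.
#' @return Object of class `l1_logreg_path`: fields `lambda`, `labels`,
#'   `a0`/`beta` (original scale), `a0_std`/`beta_std` (standardized
#'   scale), `df` (support sizes), `l1_norm` (standardized L1 norms),
#'   `center`, `scale`, `ybar`, `n`.
#' @export
fit_l1_path <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-3,
                        lambda = NULL, tol = 1e-8, max_sweeps = 1e5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 patients per class to fit the model",
         call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("f", seq_len(p))
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2L, center)^2))
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  ybar <- mean(y)
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(Xs, y - ybar))) / n
    lambda <- exp(seq(log(lambda_max),
                      log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- as.numeric(lambda)
    stopifnot(all(diff(lambda) < 0) || length(lambda) == 1L)
  }
  nl <- length(lambda)
  a0_std <- numeric(nl)
  beta_std <- matrix(0, p, nl, dimnames = list(labels, NULL))
  b0 <- stats::qlogis(min(max(ybar, 1e-12), 1 - 1e-12))
  beta <- numeric(p)
  for (l in seq_len(nl)) {
    fit <- .fit_one_lambda(Xs, y, lambda[l], b0, beta, tol,
                           max_sweeps)
    b0 <- fit$b0
    beta <- fit$beta
    a0_std[l] <- b0
    beta_std[, l] <- beta
  }
  beta_orig <- beta_std / scale
  a0_orig <- a0_std - colSums(beta_std * (center / scale))
  structure(
    list(lambda = lambda, labels = labels,
         a0 = a0_orig, beta = beta_orig,
         a0_std = a0_std, beta_std = beta_std,
         df = colSums(beta_std != 0),
         l1_norm = colSums(abs(beta_std)),
         center = center, scale = scale, ybar = ybar, n = n,
         cv_error = NULL),
    class = "l1_logreg_path")
}

#' @export
print.l1_logreg_path <- function(x, ...) {
  cat("<l1_logreg_path> ", length(x$lambda), " penalties, ",
      length(x$labels), " features, df ", min(x$df), "-", max(x$df),
      if (!is.null(x$cv_error)) " (with CV errors)", "\n", sep = "")
  invisible(x)
}

#' Extract a single model from a path
#'
#' @param path An [fit_l1_path()] object.
#' @param lambda Penalty value; the nearest path point is used.
#' @param index Alternatively, the path index.
#' @return Object of class `l1_logreg` with fields `beta0`, `beta`
#'   (named, original scale), `beta_std`, `lambda`, `labels`, `center`,
#'   `scale`.
#' @export
path_model <- function(path, lambda = NULL, index = NULL) {
  stopifnot(inherits(path, "l1_logreg_path"))
  if (is.null(index)) {
    stopifnot(!is.null(lambda))
    index <- which.min(abs(path$lambda - lambda))
  }
  structure(
    list(beta0 = path$a0[index],
         beta = stats::setNames(path$beta[, index], path$labels),
         beta_std = stats::setNames(path$beta_std[, index], path$labels),
         lambda = path$lambda[index],
         labels = path$labels,
         center = path$center, scale = path$scale),
    class = "l1_logreg")
}

#' @export
print.l1_logreg <- function(x, ...) {
  nz <- which(x$beta != 0)
  cat("<l1_logreg> lambda=", signif(x$lambda, 4), ", ", length(nz),
      " of ", length(x$beta), " features active\n", sep = "")
  if (length(nz)) {
    print(signif(x$beta[nz], 4))
  }
  invisible(x)
}

#' Model support
#' @param model An `l1_logreg`.
#' @return Labels of the features with nonzero coefficients.
#' @export
model_support <- function(model) {
  names(model$beta)[model$beta != 0]
}

#' Predict AML confidence from a fitted sparse model
#'
#' @param model An `l1_logreg` (see [path_model()], [select_lambda_cv()]).
#' @param v Feature vector (named, matching the model's labels) or a
#'   matrix with matching column names.
#' @return Probability/ies in (0, 1) of the patient being AML-positive.
#' @export
predict_proba <- function(model, v) {
  stopifnot(inherits(model, "l1_logreg"))
  if (is.matrix(v)) {
    if (!identical(colnames(v), model$labels)) {
      stop("feature labels of the input do not match the model",
           call. = FALSE)
    }
    return(stats::plogis(model$beta0 + drop(v %*% model$beta)))
  }
  if (!is.null(names(v)) && !identical(names(v), model$labels)) {
    stop("feature labels of the input do not match the model",
         call. = FALSE)
  }
  stopifnot(length(v) == length(model$beta))
  stats::plogis(model$beta0 + sum(v * model$beta))
}

#' Select the penalty by stratified k-fold cross-validation
#'
#' The path is fit on the full data to fix the penalty grid, then refit
#' inside each training fold; the penalty minimizing the pooled
#' out-of-fold misclassification rate (at the 0.5 probability threshold)
#' is chosen, with ties broken toward the largest penalty (the sparsest
#' model).  The returned model is the full-data path point at the chosen
#' penalty.
#'
#' @param X,y As in [fit_l1_path()].
#' @param k Number of folds, default 10; must not exceed the minority
#'   class count.
#' @param seed Integer seed for the fold assignment.
#' @param ... Passed to [fit_l1_path()].
#' @return Object of class `cv_l1_logreg`: fields `lambda`, `model`
#'   (`l1_logreg`), `path` (with `cv_error` filled in), `cv_error` (at
#'   the selected penalty), `index`.
#' @export
select_lambda_cv <- function(X, y, k = 10L, seed = 1L, ...) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  path <- fit_l1_path(X, y, ...)
  folds <- .stratified_fold_ids(y, k, seed)
  nl <- length(path$lambda)
  miss <- numeric(nl)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_path <- fit_l1_path(X[tr, , drop = FALSE], y[tr],
                             lambda = path$lambda, ...)
    prob <- stats::plogis(
      matrix(fold_path$a0, sum(!tr), nl, byrow = TRUE) +
        X[!tr, , drop = FALSE] %*% fold_path$beta)
    miss <- miss + colSums((prob > 0.5) != y[!tr])
  }
  cv_error <- miss / length(y)
  path$cv_error <- cv_error
  idx <- which(cv_error == min(cv_error))[1L]   # largest lambda wins ties
  structure(
    list(lambda = path$lambda[idx], model = path_model(path, index = idx),
         path = path, cv_error = cv_error[idx], index = idx,
         k = k, seed = seed),
    class = "cv_l1_logreg")
}

#' @export
print.cv_l1_logreg <- function(x, ...) {
  cat("<cv_l1_logreg> lambda*=", signif(x$lambda, 4),
      " (index ", x$index, "), CV error ", signif(x$cv_error, 3),
      ", support ", sum(x$model$beta != 0), "\n", sep = "")
  invisible(x)
}

#' Maximum Karush-Kuhn-Tucker violation along a path
#'
#' At an exact solution, the mean-scale log-likelihood gradient on the
#' standardized features satisfies `|g_j| <= lambda` for zero
#' coefficients and `g_j = lambda * sign(beta_j)` for active ones.
#'
#' @param path An [fit_l1_path()] object.
#' @param X,y The data the path was fit on.
#' @return Numeric vector: the worst KKT violation at each path point.
#' @export
kkt_violation <- function(path, X, y) {
  stopifnot(inherits(path, "l1_logreg_path"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, path$center), 2L, path$scale, `/`)
  n <- nrow(Xs)
  vapply(seq_along(path$lambda), function(l) {
    mu <- stats::plogis(path$a0_std[l] + drop(Xs %*% path$beta_std[, l]))
    g <- drop(crossprod(Xs, y - mu)) / n
    b <- path$beta_std[, l]
    lam <- path$lambda[l]
    v_zero <- if (any(b == 0)) max(abs(g[b == 0]) - lam, 0) else 0
    v_act <- if (any(b != 0)) {
      max(abs(g[b != 0] - lam * sign(b[b != 0])))
    } else 0
    max(v_zero, v_act)
  }, numeric(1))
}

#' Best feature subsets of each size along the regularization path
#'
#' For every support size occurring on a cross-validated path, the path
#' point of that size with the smallest CV error (ties toward the larger
#' penalty); features are sorted by decreasing absolute standardized
#' coefficient, most important first.
#'
#' @param path An `l1_logreg_path` with `cv_error` filled in (see
#'   [select_lambda_cv()]).
#' @return A `data.frame` with one row per size: `size`, `lambda`,
#'   `l1_norm`, `cv_error`, and a list-column `markers` of ordered
#'   feature labels.
#' @export
best_subsets_report <- function(path) {
  stopifnot(inherits(path, "l1_logreg_path"))
  if (is.null(path$cv_error)) {
    stop("path has no CV errors; fit it via select_lambda_cv()",
         call. = FALSE)
  }
  sizes <- sort(unique(path$df))
  rows <- lapply(sizes, function(s) {
    cand <- which(path$df == s)
    best <- cand[which.min(path$cv_error[cand])]
    b <- path$beta_std[, best]
    nz <- which(b != 0)
    ord <- nz[order(abs(b[nz]), decreasing = TRUE)]
    data.frame(size = s, lambda = path$lambda[best],
               l1_norm = path$l1_norm[best],
               cv_error = path$cv_error[best],
               markers = I(list(path$labels[ord])))
  })
  do.call(rbind, rows)
}
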