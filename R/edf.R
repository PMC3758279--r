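#' Streaming mean/covariance accumulator
#'
#' Class moments of the 84-dimensional expanded event clouds are
#' accumulated one patient at a time (pairwise mean/centered-scatter
#' update), so the full expanded training data never needs to be held in
#' memory at once.
#'
#' @param d Feature dimensionality (84 for expanded tubes).
#' @return An object of class `streaming_moments` with `n = 0`.
#' @export
streaming_moments <- function(d = 84L) {
  structure(list(n = 0, mean = numeric(d), m2 = matrix(0, d, d)),
            class = "streaming_moments")
}

#' Accumulate one patient's expanded events into a moment accumulator
#'
#' @param acc A [streaming_moments()] accumulator.
#' @param x Numeric matrix of events x features, matching `acc`'s
#'   dimensionality.
#' @return The updated accumulator.
#' @export
accumulate_patient <- function(acc, x) {
  stopifnot(inherits(acc, "streaming_moments"))
  x <- as.matrix(x)
  if (ncol(x) != length(acc$mean)) {
    stop("dimension mismatch: accumulator has ", length(acc$mean),
         " features, batch has ", ncol(x), call. = FALSE)
  }
  nb <- nrow(x)
  if (nb == 0L) return(acc)
  mb <- colMeans(x)
  xc <- sweep(x, 2L, mb)
  sb <- crossprod(xc)
  if (acc$n == 0) {
    acc$n <- nb
    acc$mean <- mb
    acc$m2 <- sb
    return(acc)
  }
  delta <- mb - acc$mean
  n_new <- acc$n + nb
  acc$m2 <- acc$m2 + sb + tcrossprod(delta) * (acc$n * nb / n_new)
  acc$mean <- acc$mean + delta * (nb / n_new)
  acc$n <- n_new
  acc
}

#' Finalize a moment accumulator
#'
#' @param acc A [streaming_moments()] accumulator with `n >= 2`.
#' @return List with `n`, `mean`, and the sample covariance `cov`
#'   (denominator `n - 1`).
#' @export
finalize_moments <- function(acc) {
  stopifnot(inherits(acc, "streaming_moments"))
  if (acc$n < 2) {
    stop("covariance undefined: fewer than 2 events accumulated",
         call. = FALSE)
  }
  list(n = acc$n, mean = acc$mean, cov = acc$m2 / (acc$n - 1))
}

#' Fit the Fisher LDA projection direction for one tube
#'
#' Solves `(S_A + S_H + ridge * I) w = mu_A - mu_H`, where `S` and `mu`
#' are the class sample covariances and means of the expanded training
#' events.  The engineered features make the pooled covariance
#' ill-conditioned, so a ridge is escalated along a fixed relative ladder
#' (multiples of the mean covariance diagonal) until the solve is
#' numerically stable (finite solution, small relative residual).
#'
#' @param mom_a,mom_h Finalized class moments (see [finalize_moments()])
#'   for the AML and healthy class.
#' @param ridge_ladder Increasing relative ridge values tried in order.
#' @param tube_id Optional tube id stored for bookkeeping.
#' @return Object of class `lda_direction`: fields `w` (numeric vector),
#'   `ridge` (absolute value used), `tube_id`.
#' @export
fit_lda_direction <- function(mom_a, mom_h,
                              ridge_ladder = c(0, 1e-8, 1e-6, 1e-4,
                                               1e-2, 1),
                              tube_id = NA_integer_) {
  s <- mom_a$cov + mom_h$cov
  d <- mom_a$mean - mom_h$mean
  if (all(d == 0)) {
    return(structure(list(w = numeric(length(d)), ridge = 0,
                          tube_id = tube_id), class = "lda_direction"))
  }
  scale <- mean(diag(s))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  dn <- sqrt(sum(d^2))
  for (rel in ridge_ladder) {
    ridge <- rel * scale
    sr <- s
    diag(sr) <- diag(sr) + ridge
    w <- tryCatch(solve(sr, d), error = function(e) NULL)
    if (is.null(w) || !all(is.finite(w))) next
    resid <- sqrt(sum((sr %*% w - d)^2)) / dn
    if (resid < 1e-6) {
      return(structure(list(w = as.numeric(w), ridge = ridge,
                            tube_id = tube_id), class = "lda_direction"))
    }
  }
  stop("LDA system is singular even at the largest ridge", call. = FALSE)
}

#' Project expanded events onto an LDA direction
#'
#' @param x Events x features matrix.
#' @param direction An [fit_lda_direction()] object (or a bare numeric
#'   vector of weights).
#' @return Numeric vector, one projected value per event.
#' @export
project_events <- function(x, direction) {
  w <- if (inherits(direction, "lda_direction")) direction$w else direction
  x <- as.matrix(x)
  if (ncol(x) != length(w)) {
    stop("dimension mismatch: events have ", ncol(x),
         " features, direction has ", length(w), call. = FALSE)
  }
  drop(x %*% w)
}

#' Build the EDF evaluation grid
#'
#' `K` points uniformly spaced from the minimum to the maximum of the
#' pooled training projections, so the two class reference EDFs and any
#' test EDF share a common parametrization.
#'
#' @param values Pooled training projections (both classes) of one tube.
#' @param K Number of grid points, default 128.
#' @return Object of class `edf_grid` with fields `x1`, `delta`, `K`.
#' @export
build_edf_grid <- function(values, K = 128L) {
  stopifnot(K >= 2L)
  rng <- range(values)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("degenerate grid: training projections are constant",
         call. = FALSE)
  }
  structure(list(x1 = rng[1], delta = diff(rng) / (K - 1), K = as.integer(K)),
            class = "edf_grid")
}

#' Grid point locations
#' @param grid An [build_edf_grid()] object.
#' @return Numeric vector of the `K` grid points.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "edf_grid"))
  grid$x1 + (seq_len(grid$K) - 1L) * grid$delta
}

#' Evaluate an empirical distribution function on a grid
#'
#' The EDF value at grid point `g` is the fraction of sample values
#' `<= g`; the result is nondecreasing and lies in `[0, 1]`.
#'
#' @param values Nonempty numeric sample.
#' @param grid An [build_edf_grid()] object.
#' @return Numeric vector of `K` EDF values.
#' @export
edf_eval <- function(values, grid) {
  if (length(values) == 0L) {
    stop("cannot evaluate the EDF of an empty sample", call. = FALSE)
  }
  findInterval(grid_points(grid), sort(values)) / length(values)
}

#' Mean squared error between two gridded EDFs
#'
#' @param f_test,f_ref Numeric vectors of equal length `K`.
#' @return `mean((f_test - f_ref)^2)`, a nonnegative scalar.
#' @export
edf_mse <- function(f_test, f_ref) {
  if (length(f_test) != length(f_ref)) {
    stop("EDF length mismatch: ", length(f_test), " vs ", length(f_ref),
         call. = FALSE)
  }
  mean((f_test - f_ref)^2)
}

#' Train the per-tube LDA + reference-EDF models
#'
#' For each tube: class moments of the expanded events are accumulated
#' patient by patient and turned into a Fisher LDA direction; all training
#' events are then projected, a common grid is built from the pooled
#' projections of both classes, and one reference EDF per class is
#' computed.  By default the reference EDF of a class is the EDF of the
#' pooled events of all its training patients; `reference =
#' "per_patient"` instead averages the per-patient EDFs with equal
#' patient weight.
#'
#' @param cohort An `aml_cohort` with at least 2 labeled patients per
#'   class.
#' @param K Grid size, default 128.
#' @param eps Divisor clamp for [expand_features()].
#' @param reference `"pooled"` (default) or `"per_patient"`.
#' @param ridge_ladder Passed to [fit_lda_direction()].
#' @return Object of class `tube_models`: per tube a list with
#'   `direction`, `grid`, `ref_healthy`, `ref_aml`.
#' @export
train_tube_models <- function(cohort, K = 128L, eps = 1e-6,
                              reference = c("pooled", "per_patient"),
                              ridge_ladder = c(0, 1e-8, 1e-6, 1e-4,
                                               1e-2, 1)) {
  reference <- match.arg(reference)
  labels <- cohort_labels(cohort)
  if (sum(labels == 1, na.rm = TRUE) < 2 ||
      sum(labels == 0, na.rm = TRUE) < 2) {
    stop("training needs at least 2 labeled patients per class",
         call. = FALSE)
  }
  train <- cohort$patients[!is.na(labels)]
  labels <- labels[!is.na(labels)]
  models <- vector("list", 7L)
  for (t in 1:7) {
    tid <- as.character(t)
    acc_a <- streaming_moments(84L)
    acc_h <- streaming_moments(84L)
    for (i in seq_along(train)) {
      ex <- expand_features(train[[i]]$tubes[[tid]], eps = eps)
      if (labels[i] == 1) {
        acc_a <- accumulate_patient(acc_a, ex)
      } else {
        acc_h <- accumulate_patient(acc_h, ex)
      }
    }
    dir <- fit_lda_direction(finalize_moments(acc_a),
                             finalize_moments(acc_h),
                             ridge_ladder = ridge_ladder, tube_id = t)
    # second pass: projections per patient
    proj <- lapply(train, function(p) {
      project_events(expand_features(p$tubes[[tid]], eps = eps), dir)
    })
    grid <- build_edf_grid(unlist(proj, use.names = FALSE), K = K)
    ref_for <- function(class_label) {
      idx <- which(labels == class_label)
      if (reference == "pooled") {
        edf_eval(unlist(proj[idx], use.names = FALSE), grid)
      } else {
        rowMeans(vapply(proj[idx], edf_eval, numeric(grid$K),
                        grid = grid))
      }
    }
    models[[t]] <- list(direction = dir, grid = grid,
                        ref_healthy = ref_for(0), ref_aml = ref_for(1))
  }
  structure(list(tubes = models, K = as.integer(K), eps = eps,
                 reference = reference),
            class = "tube_models")
}

#' Compute the 14 EDF-MSE similarity scores for a patient
#'
#' Per tube, the patient's events are expanded, projected on the trained
#' LDA direction, summarized as an EDF on the trained grid, and compared
#' by mean squared error against the healthy and the AML reference EDFs.
#' The result is ordered `t1_healthy, t1_aml, ..., t7_healthy, t7_aml`.
#'
#' @param p A [patient_sample()] with all 7 tubes.
#' @param models A [train_tube_models()] fit.
#' @return Named numeric vector of 14 nonnegative raw scores.
#' @export
compute_tube_scores <- function(p, models) {
  stopifnot(inherits(models, "tube_models"))
  .require_tubes(p)
  out <- numeric(14L)
  nms <- character(14L)
  for (t in 1:7) {
    m <- models$tubes[[t]]
    f <- edf_eval(
      project_events(expand_features(p$tubes[[as.character(t)]],
                                     eps = models$eps), m$direction),
      m$grid)
    out[2L * t - 1L] <- edf_mse(f, m$ref_healthy)
    out[2L * t] <- edf_mse(f, m$ref_aml)
    nms[2L * t - 1L] <- paste0("t", t, "_healthy")
    nms[2L * t] <- paste0("t", t, "_aml")
  }
  names(out) <- nms
  out
}
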