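#' Define a scoring method for the CV benchmark
#'
#' A method bundles a training function (sub-cohort in, fitted model
#' out), a scoring function (model + patient in, confidence out, higher
#' = more AML-like) and a decision-threshold rule.
#'
#' @param name Method name.
#' @param train `function(cohort) -> model`.
#' @param score `function(model, patient) -> numeric`.
#' @param threshold `function(model) -> numeric`; defaults to the 0.5
#'   probability threshold.
#' @return Object of class `aml_method`.
#' @export
aml_method <- function(name, train, score,
                       threshold = function(model) 0.5) {
  structure(list(name = name, train = train, score = score,
                 threshold = threshold),
            class = "aml_method")
}

# Shared LASSO-on-patient-features trainer: features per patient,
# z-scored with training statistics, penalty by stratified CV.
.lasso_on_features <- function(cohort, extract, k, seed, ...) {
  labels <- cohort_labels(cohort)
  feats <- t(vapply(cohort$patients, extract,
                    extract(cohort$patients[[1]])))
  norm <- fit_normalizer(feats)
  k_use <- min(k, sum(labels == 1), sum(labels == 0))
  cv <- select_lambda_cv(apply_normalizer(norm, feats), labels,
                         k = k_use, seed = seed, ...)
  list(normalizer = norm, cv = cv, model = cv$model)
}

#' EDF-MSE / LR-LASSO: the full per-tube pipeline
#'
#' Trains the per-tube LDA + reference-EDF models, computes the 14
#' EDF-MSE similarity scores for each training patient, z-scores them,
#' and fits the sparse logistic aggregator with CV-selected penalty.
#'
#' @param K,eps,reference Passed to [train_tube_models()].
#' @param k,seed Cross-validation settings for the penalty search.
#' @param ... Passed to [fit_l1_path()].
#' @return An [aml_method()].
#' @export
method_edf_lasso <- function(K = 128L, eps = 1e-6, reference = "pooled",
                             k = 10L, seed = 1L, ...) {
  aml_method(
    name = "EDF-MSE/LR-LASSO",
    train = function(cohort) {
      tubes <- train_tube_models(cohort, K = K, eps = eps,
                                 reference = reference)
      fit <- .lasso_on_features(
        cohort, function(p) compute_tube_scores(p, tubes),
        k = k, seed = seed, ...)
      c(list(tubes = tubes), fit)
    },
    score = function(model, p) {
      raw <- compute_tube_scores(p, model$tubes)
      predict_proba(model$model, apply_normalizer(model$normalizer, raw))
    })
}

#' Mean / LR-LASSO: mean-intensity features with the sparse aggregator
#'
#' @inheritParams method_edf_lasso
#' @return An [aml_method()].
#' @export
method_mean_lasso <- function(k = 10L, seed = 1L, ...) {
  aml_method(
    name = "Mean/LR-LASSO",
    train = function(cohort) {
      .lasso_on_features(cohort, mean_features, k = k, seed = seed, ...)
    },
    score = function(model, p) {
      predict_proba(model$model,
                    apply_normalizer(model$normalizer, mean_features(p)))
    })
}

# Fisher LDA on per-patient feature vectors (patients are the samples
# here, unlike the per-event LDA of the tube pipeline).  Non-
# probabilistic: the decision threshold minimizes training error.
.lda_on_features <- function(cohort, extract) {
  labels <- cohort_labels(cohort)
  feats <- t(vapply(cohort$patients, extract,
                    extract(cohort$patients[[1]])))
  norm <- fit_normalizer(feats)
  z <- apply_normalizer(norm, feats)
  mom <- function(cls) {
    zc <- z[labels == cls, , drop = FALSE]
    list(n = nrow(zc), mean = colMeans(zc), cov = stats::cov(zc))
  }
  dir <- fit_lda_direction(mom(1), mom(0))
  scores <- drop(z %*% dir$w)
  list(normalizer = norm, direction = dir,
       threshold = min_error_threshold(scores, labels))
}

#' Mean / LDA baseline: Fisher LDA on the 49 mean-intensity features
#'
#' @return An [aml_method()]; scores are raw discriminant values and the
#'   decision threshold minimizes training error.
#' @export
method_mean_lda <- function() {
  aml_method(
    name = "Mean/LDA",
    train = function(cohort) .lda_on_features(cohort, mean_features),
    score = function(model, p) {
      sum(apply_normalizer(model$normalizer, mean_features(p)) *
            model$direction$w)
    },
    threshold = function(model) model$threshold)
}

#' Moment-feature reference: six moments per marker, LDA classifier
#'
#' Uses the 294 per-patient moment features (mean, sd, skewness,
#' kurtosis, median, IQR per channel and tube) with a Fisher LDA
#' discriminant; the decision threshold minimizes training error.
#'
#' @return An [aml_method()].
#' @export
method_biehl_features <- function() {
  aml_method(
    name = "Biehl-features/LDA",
    train = function(cohort) .lda_on_features(cohort, moment_features),
    score = function(model, p) {
      sum(apply_normalizer(model$normalizer, moment_features(p)) *
            model$direction$w)
    },
    threshold = function(model) model$threshold)
}

#' KL-histogram reference classifier
#'
#' @param alpha,gain Passed to [vilar_train()].
#' @return An [aml_method()].
#' @export
method_vilar <- function(alpha = 1e-6, gain = 1) {
  aml_method(
    name = "Vilar",
    train = function(cohort) {
      vilar_train(cohort, alpha = alpha, gain = gain)
    },
    score = function(model, p) vilar_score(p, model))
}

#' The method registry used by the command-line interface
#'
#' @param name One of `"edfmse-lasso"`, `"mean-lasso"`, `"mean-lda"`,
#'   `"vilar"`, `"biehl-features"`.
#' @param ... Passed to the method constructor.
#' @return An [aml_method()].
#' @export
get_method <- function(name, ...) {
  switch(name,
         "edfmse-lasso" = method_edf_lasso(...),
         "mean-lasso" = method_mean_lasso(...),
         "mean-lda" = method_mean_lda(...),
         "vilar" = method_vilar(...),
         "biehl-features" = method_biehl_features(...),
         stop("unknown method: ", name, call. = FALSE))
}
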