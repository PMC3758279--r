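# Stratified fold ids for one repeat: within each class, shuffled
# members get fold labels from a shuffled balanced sequence, so per-fold
# class counts differ by at most one from proportionality.
.stratified_fold_ids <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Build a stratified repeated k-fold cross-validation plan
#'
#' Every patient appears in exactly one test fold per repeat; per-fold
#' class counts are within one patient of exact proportionality.
#'
#' @param labels Binary 0/1 label vector.
#' @param k Folds; must not exceed the minority class count.
#' @param repeats Number of independent repetitions, default 1.
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: `folds` is a `length(labels) x
#'   repeats` matrix of fold ids.
#' @export
stratified_kfold <- function(labels, k = 10L, repeats = 1L, seed = 1L) {
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(0, 1)))
  n_min <- min(sum(labels == 1), sum(labels == 0))
  if (k > n_min) {
    stop("k = ", k, " exceeds the minority class count (", n_min, ")",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- vapply(seq_len(repeats),
                  function(r) .stratified_fold_ids(labels, k),
                  integer(length(labels)))
  structure(list(folds = folds, k = as.integer(k),
                 repeats = as.integer(repeats), seed = seed,
                 labels = labels),
            class = "cv_plan")
}

.check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' ROC AUC (Mann-Whitney form)
#'
#' The area under the ROC curve equals the probability that a random
#' positive outranks a random negative, with ties counted one half;
#' computed from midranks.
#'
#' @param scores Numeric confidence scores (higher = more AML-like).
#' @param labels Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  .check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC by step summation
#'
#' Interpolation-free: thresholds sweep the distinct score values in
#' decreasing order (tied scores enter together) and each recall
#' increment contributes the precision at that threshold.
#'
#' @inheritParams roc_auc
#' @return PR AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ends <- which(diff(c(s, -Inf)) != 0)  # last index of each tied group
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  n1 <- sum(y)
  rec <- tp / n1
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' ROC and PR curve points
#'
#' @inheritParams roc_auc
#' @return A `data.frame` with columns `threshold`, `tpr`, `fpr`,
#'   `precision`, `recall`, one row per distinct score (descending).
#' @export
performance_curves <- function(scores, labels) {
  labels <- as.numeric(labels)
  .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ends <- which(diff(c(s, -Inf)) != 0)
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  n1 <- sum(y)
  n0 <- length(y) - n1
  data.frame(threshold = s[ends],
             tpr = tp / n1, fpr = fp / n0,
             precision = tp / (tp + fp), recall = tp / n1)
}

#' Confusion matrix at a decision threshold
#'
#' Patients with `score > threshold` are called AML-positive.  The
#' default threshold for probabilistic outputs is 0.5, the canonical
#' logistic decision point.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold, default 0.5.
#' @return Named integer vector `c(tp, fp, tn, fn)` of class
#'   `confusion_matrix`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- scores > threshold
  structure(c(tp = sum(pred & labels == 1),
              fp = sum(pred & labels == 0),
              tn = sum(!pred & labels == 0),
              fn = sum(!pred & labels == 1)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fp", "fn", "tn")], 2, 2,
              dimnames = list(truth = c("AML", "healthy"),
                              predicted = c("AML", "healthy")))
  print(m)
  invisible(x)
}

#' Test equality of two correlated ROC AUCs
#'
#' Two-sided test that the AUCs of two scoring rules evaluated on the
#' same patients are equal (DeLong's method for paired ROC curves, the
#' operational form of the rank-based AUC comparison).
#'
#' @param scores_a,scores_b Two score vectors over the same patients.
#' @param labels Binary 0/1 labels.
#' @return Two-sided p-value.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  .check_two_classes(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (isTRUE(all.equal(rank(scores_a), rank(scores_b)))) {
    return(1)  # identical rankings: identical ROC curves
  }
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  as.numeric(pROC::roc.test(ra, rb, method = "delong",
                            paired = TRUE)$p.value)
}

#' Challenge separation score
#'
#' Negative log10 of the one-sided Mann-Whitney p-value that the
#' observed ranking separation between classes arose by chance (exact
#' p-value for small tie-free samples, otherwise the normal
#' approximation with tie correction).  Invariant to strictly monotone
#' transforms of the scores.
#'
#' @inheritParams roc_auc
#' @return Nonnegative score; higher means stronger separation.
#' @export
challenge_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  .check_two_classes(labels)
  p <- stats::wilcox.test(scores[labels == 1], scores[labels == 0],
                          alternative = "greater")$p.value
  -log10(max(p, .Machine$double.xmin))
}

#' Benchmark scoring methods by stratified repeated k-fold CV
#'
#' All training-derived quantities (LDA directions, reference EDFs,
#' histograms, normalizers, the penalty) are re-estimated inside each
#' training fold; out-of-fold scores are pooled across folds and
#' repeats.  A method failing in a fold is recorded and that fold
#' skipped for it.
#'
#' @param cohort An `aml_cohort` with labeled patients.
#' @param methods Named list of method objects (see [aml_method()]).
#' @param k,repeats,seed Cross-validation plan parameters.
#' @return Named list of `evaluation_report` objects, one per method:
#'   pooled `scores`/`labels`, `auc_roc`, `auc_pr`, curve points,
#'   `confusion` (at the method's threshold), `challenge_score`, and
#'   `failed_folds`.
#' @export
run_cv_benchmark <- function(cohort, methods, k = 10L, repeats = 1L,
                             seed = 1L) {
  stopifnot(is.list(methods), length(methods) > 0L)
  if (is.null(names(methods))) {
    names(methods) <- vapply(methods, `[[`, character(1), "name")
  }
  labels <- cohort_labels(cohort)
  stopifnot(!anyNA(labels))
  plan <- stratified_kfold(labels, k = k, repeats = repeats, seed = seed)
  n <- length(labels)
  out <- lapply(methods, function(m) {
    list(scores = numeric(0), labels = numeric(0),
         thresholds = numeric(0), failed = character(0))
  })
  for (r in seq_len(repeats)) {
    fold_ids <- plan$folds[, r]
    for (f in seq_len(k)) {
      test_idx <- which(fold_ids == f)
      train_cohort <- subset_cohort(cohort, which(fold_ids != f))
      for (mn in names(methods)) {
        meth <- methods[[mn]]
        res <- tryCatch({
          model <- meth$train(train_cohort)
          sc <- vapply(test_idx, function(i) {
            as.numeric(meth$score(model, cohort$patients[[i]]))
          }, numeric(1))
          list(scores = sc, threshold = meth$threshold(model))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          out[[mn]]$failed <- c(out[[mn]]$failed,
                                sprintf("repeat %d fold %d: %s", r, f,
                                        conditionMessage(res)))
          next
        }
        out[[mn]]$scores <- c(out[[mn]]$scores, res$scores)
        out[[mn]]$labels <- c(out[[mn]]$labels, labels[test_idx])
        out[[mn]]$thresholds <- c(out[[mn]]$thresholds, res$threshold)
      }
    }
  }
  reports <- lapply(names(methods), function(mn) {
    o <- out[[mn]]
    if (length(o$failed)) {
      warning("method ", mn, " failed in ", length(o$failed), " fold(s)",
              call. = FALSE)
    }
    thr <- stats::median(o$thresholds)
    structure(
      list(method = mn, scores = o$scores, labels = o$labels,
           auc_roc = roc_auc(o$scores, o$labels),
           auc_pr = pr_auc(o$scores, o$labels),
           curves = performance_curves(o$scores, o$labels),
           threshold = thr,
           confusion = confusion_at_threshold(o$scores, o$labels, thr),
           challenge_score = challenge_score(o$scores, o$labels),
           failed_folds = o$failed,
           k = k, repeats = repeats, seed = seed),
      class = "evaluation_report")
  })
  names(reports) <- names(methods)
  reports
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$method,
      ": ROC AUC ", signif(x$auc_roc, 3),
      ", PR AUC ", signif(x$auc_pr, 3),
      ", challenge score ", signif(x$challenge_score, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Pairwise AUC-difference p-values between benchmarked methods
#'
#' @param reports The list returned by [run_cv_benchmark()].  Reports
#'   must cover the same patients in the same order (no failed folds).
#' @return Symmetric matrix of two-sided DeLong p-values.
#' @export
compare_methods <- function(reports) {
  nm <- names(reports)
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) {
        p[i, j] <- p[j, i] <- compare_auc(reports[[i]]$scores,
                                          reports[[j]]$scores,
                                          reports[[i]]$labels)
      }
    }
  }
  p
}

#' Threshold minimizing training misclassification
#'
#' Decision rule used for scorers without a probability scale: candidate
#' thresholds are midpoints between consecutive distinct scores (plus
#' outer sentinels) and the one with minimal training error is chosen.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
min_error_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  err <- vapply(cand, function(thr) {
    sum((scores > thr) != labels)
  }, numeric(1))
  cand[which.min(err)]
}
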