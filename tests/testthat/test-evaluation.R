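test_that("stratified folds partition patients and preserve proportions", {
  labels <- c(rep(1, 43), rep(0, 316))
  plan <- stratified_kfold(labels, k = 10, repeats = 3, seed = 1)
  for (r in 1:3) {
    f <- plan$folds[, r]
    expect_equal(sort(unique(f)), 1:10)
    pos <- table(f[labels == 1])
    neg <- table(f[labels == 0])
    expect_true(all(pos %in% c(4L, 5L)))
    expect_true(all(neg %in% c(31L, 32L)))
  }
  # training splits realize the 39/284 composition of a 90% split
  f <- plan$folds[, 1]
  train_pos <- vapply(1:10, function(k) sum(labels == 1 & f != k),
                      numeric(1))
  train_neg <- vapply(1:10, function(k) sum(labels == 0 & f != k),
                      numeric(1))
  expect_equal(max(train_pos), 39)
  expect_true(284 %in% train_neg)

  # tiny case: one patient of each class per fold
  p2 <- stratified_kfold(c(1, 1, 0, 0), k = 2, seed = 5)
  f2 <- p2$folds[, 1]
  expect_equal(sort(f2[1:2]), 1:2)
  expect_equal(sort(f2[3:4]), 1:2)

  # reproducibility and guard rails
  expect_equal(stratified_kfold(labels, 10, seed = 9)$folds,
               stratified_kfold(labels, 10, seed = 9)$folds)
  expect_error(stratified_kfold(c(1, 0, 0, 0), k = 2), "minority")
})

test_that("ROC AUC equals the all-pairs Mann-Whitney statistic", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  set.seed(70)
  for (i in 1:20) {
    n <- 50
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    scores[1:5] <- scores[6:10]   # inject ties
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    u <- 0
    for (a in pos) for (b in neg) {
      u <- u + (a > b) + 0.5 * (a == b)
    }
    expect_equal(roc_auc(scores, labels), u / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC AUC is calibrated under the null", {
  set.seed(71)
  labels <- rbinom(1e4, 1, 0.5)
  scores <- rnorm(1e4)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.02)
})

test_that("PR AUC steps through thresholds without interpolation", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c(1, 0, 1, 0)
  # thresholds: recall 1/2 at precision 1, recall 1 at precision 3/4...
  # hand-computed: 0.5 * 1 + 0.5 * (2/3) -> recall steps at ranks 1 and 3
  expect_equal(pr_auc(scores, labels), 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(pr_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  # tied scores enter together
  expect_equal(pr_auc(c(1, 1), c(1, 0)), 0.5)
})

test_that("confusion matrices count the four cells", {
  expect_equal(unclass(confusion_at_threshold(c(0.9, 0.8), c(1, 1), 0.5)),
               c(tp = 2L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(unclass(confusion_at_threshold(c(0.9, 0.8), c(1, 0), Inf)),
               c(tp = 0L, fp = 0L, tn = 1L, fn = 1L))
  set.seed(72)
  scores <- runif(100)
  labels <- rbinom(100, 1, 0.4)
  cm <- confusion_at_threshold(scores, labels, 0.35)
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:100) {
    if (scores[i] > 0.35) {
      if (labels[i] == 1) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (labels[i] == 1) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  expect_equal(unclass(cm), c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(sum(cm), 100L)
})

test_that("AUC comparison behaves as a rank-based paired test", {
  set.seed(73)
  labels <- rbinom(200, 1, 0.3)
  labels[1:2] <- c(0, 1)
  s <- rnorm(200)
  expect_equal(compare_auc(s, s, labels), 1)
  # invariance to strictly monotone transforms
  s2 <- rnorm(200) + labels
  p1 <- compare_auc(s, s2, labels)
  p2 <- compare_auc(exp(s), 3 * s2 - 1, labels)
  expect_equal(p1, p2, tolerance = 1e-10)
  # a perfect scorer differs from a random one
  perfect <- labels + rnorm(200, sd = 0.01)
  rejected <- 0L
  for (i in 1:20) {
    set.seed(500 + i)
    lab <- rbinom(200, 1, 0.3)
    lab[1:2] <- c(0, 1)
    perf <- lab + rnorm(200, sd = 0.01)
    rand <- rnorm(200)
    if (compare_auc(perf, rand, lab) < 0.01) rejected <- rejected + 1L
  }
  expect_gte(rejected, 19L)
})

test_that("the challenge score measures ranking separation", {
  # perfect separation with n1 = n0 = 20: exact tail beyond 1e-8
  scores <- c(rnorm(20, 10), rnorm(20, 0))
  labels <- rep(c(1, 0), each = 20)
  expect_gt(challenge_score(scores, labels), 8)
  # monotone-transform invariance
  expect_equal(challenge_score(scores, labels),
               challenge_score(plogis(scores), labels))
  # null calibration: shuffled labels rarely exceed 2
  high <- 0L
  for (i in 1:40) {
    set.seed(600 + i)
    sc <- rnorm(100)
    lab <- sample(rep(c(1, 0), each = 50))
    if (challenge_score(sc, lab) >= 2) high <- high + 1L
  }
  expect_lte(high, 2L)
})

test_that("the CV benchmark pools out-of-fold scores without leakage", {
  co <- simulate_cohort(small_strong_spec(6L, 14L, events = c(60L, 100L)),
                        seed = 80)
  methods <- list(mean_lasso = method_mean_lasso(k = 5, seed = 1,
                                                 nlambda = 30),
                  mean_lda = method_mean_lda())
  reports <- run_cv_benchmark(co, methods, k = 3, repeats = 2, seed = 4)
  for (rep in reports) {
    expect_length(rep$scores, 20L * 2L)
    expect_equal(sum(rep$confusion), 40L)
    expect_true(rep$auc_roc >= 0 && rep$auc_roc <= 1)
  }
  # determinism under the same seed
  reports2 <- run_cv_benchmark(co, methods, k = 3, repeats = 2, seed = 4)
  expect_equal(reports$mean_lasso$scores, reports2$mean_lasso$scores)
  # pairwise comparison matrix is symmetric with unit diagonal gaps
  pm <- compare_methods(reports)
  expect_equal(pm["mean_lasso", "mean_lda"], pm["mean_lda", "mean_lasso"])

  # no leakage: removing a test-fold patient leaves that fold's trained
  # model unchanged
  labels <- cohort_labels(co)
  plan <- stratified_kfold(labels, k = 3, seed = 4)
  f <- plan$folds[, 1]
  train_ids <- which(f != 1)
  test_ids <- which(f == 1)
  m_full <- method_mean_lda()$train(subset_cohort(co, train_ids))
  co_drop <- subset_cohort(co, c(train_ids, test_ids[-1]))
  m_drop <- method_mean_lda()$train(
    subset_cohort(co_drop, seq_along(train_ids)))
  expect_identical(m_full$direction$w, m_drop$direction$w)
})

test_that("the training-error threshold rule is optimal on its data", {
  scores <- c(0.1, 0.2, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  thr <- min_error_threshold(scores, labels)
  expect_equal(sum((scores > thr) != labels), 0)
  set.seed(81)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5)
  thr2 <- min_error_threshold(sc, lab)
  err2 <- sum((sc > thr2) != lab)
  brute <- min(vapply(c(sc - 1e-9, max(sc) + 1),
                      function(t) sum((sc > t) != lab), numeric(1)))
  expect_equal(err2, brute)
})
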