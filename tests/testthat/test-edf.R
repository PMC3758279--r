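test_that("streaming moments equal two-pass batch statistics", {
  set.seed(10)
  batches <- lapply(c(5, 17, 40), function(n) {
    matrix(rnorm(n * 6, mean = 2, sd = 3), n, 6)
  })
  acc <- streaming_moments(6L)
  for (b in batches) acc <- accumulate_patient(acc, b)
  fin <- finalize_moments(acc)
  all_x <- do.call(rbind, batches)
  expect_equal(fin$n, nrow(all_x))
  expect_equal(fin$mean, colMeans(all_x), tolerance = 1e-8)
  expect_equal(fin$cov, cov(all_x), tolerance = 1e-8)

  # order invariance
  acc2 <- streaming_moments(6L)
  for (b in rev(batches)) acc2 <- accumulate_patient(acc2, b)
  fin2 <- finalize_moments(acc2)
  expect_equal(fin2$mean, fin$mean, tolerance = 1e-8)
  expect_equal(fin2$cov, fin$cov, tolerance = 1e-8)

  # one batch equals that batch's covariance
  one <- accumulate_patient(streaming_moments(6L), batches[[1]])
  expect_equal(finalize_moments(one)$cov, cov(batches[[1]]))

  # single event: covariance undefined
  single <- accumulate_patient(streaming_moments(6L),
                               matrix(rnorm(6), 1, 6))
  expect_error(finalize_moments(single), "fewer than 2")
  expect_error(accumulate_patient(acc, matrix(0, 3, 5)),
               "dimension mismatch")
})

test_that("the LDA direction solves the pooled-covariance system", {
  mk <- function(mean, cov, n = 10) list(n = n, mean = mean, cov = cov)
  # identical class means give the zero direction
  z <- fit_lda_direction(mk(c(1, 2), diag(2)), mk(c(1, 2), diag(2)))
  expect_equal(z$w, c(0, 0))

  # identity pooled covariance reproduces the mean difference
  d <- fit_lda_direction(mk(c(1, 0), diag(2) / 2),
                         mk(c(0, 0), diag(2) / 2))
  expect_equal(d$w, c(1, 0))
  expect_equal(d$ridge, 0)

  # random SPD 5-d instance vs a direct solve
  set.seed(11)
  a <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  h <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  mu_a <- rnorm(5)
  mu_h <- rnorm(5)
  got <- fit_lda_direction(mk(mu_a, a), mk(mu_h, h))
  expect_equal(got$w, drop(solve(a + h, mu_a - mu_h)),
               tolerance = 1e-10)

  # singular system escalates the ridge rather than failing
  s1 <- matrix(1, 3, 3)
  got2 <- fit_lda_direction(mk(c(1, 0, 0), s1), mk(c(0, 0, 0), s1))
  expect_gt(got2$ridge, 0)
  expect_true(all(is.finite(got2$w)))
})

test_that("projection is the plain linear map", {
  set.seed(12)
  x <- matrix(rnorm(30), 10, 3)
  w <- c(0, 1, 0)
  expect_equal(project_events(x, w), x[, 2])
  expect_equal(project_events(x, 2 * w), 2 * project_events(x, w))
  wr <- rnorm(3)
  loop <- vapply(1:10, function(i) sum(x[i, ] * wr), numeric(1))
  expect_equal(project_events(x, wr), loop, tolerance = 1e-12)
  expect_error(project_events(x, rnorm(4)), "dimension mismatch")
})

test_that("the EDF grid spans the training range uniformly", {
  g <- build_edf_grid(c(0, 1), K = 128L)
  expect_equal(g$x1, 0)
  expect_equal(g$delta, 1 / 127)
  expect_equal(length(grid_points(g)), 128L)
  expect_equal(max(grid_points(g)), 1)

  g2 <- build_edf_grid(c(-3, 5), K = 5L)
  expect_equal(grid_points(g2), c(-3, -1, 1, 3, 5))
  expect_error(build_edf_grid(rep(2, 10)), "degenerate")
  # default K = 128 in the tube trainer
  expect_equal(formals(train_tube_models)$K, 128L)
})

test_that("EDF evaluation counts correctly and is monotone in [0,1]", {
  g <- structure(list(x1 = 0.5, delta = 1, K = 4L), class = "edf_grid")
  expect_equal(edf_eval(c(1, 2, 3), g), c(0, 1 / 3, 2 / 3, 1))

  # all sample values below the grid: EDF is 1 everywhere
  expect_equal(edf_eval(c(-5, -4), g), rep(1, 4))
  expect_error(edf_eval(numeric(0), g), "empty")

  set.seed(13)
  v <- rnorm(200)
  grid <- build_edf_grid(v, K = 64L)
  f <- edf_eval(v, grid)
  pts <- grid_points(grid)
  naive <- vapply(pts, function(gp) sum(v <= gp) / length(v),
                  numeric(1))
  expect_identical(f, naive)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("EDF MSE is the mean squared difference", {
  expect_equal(edf_mse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(edf_mse(rep(0, 128), rep(1, 128)), 1)
  set.seed(14)
  a <- runif(128)
  b <- runif(128)
  expect_equal(edf_mse(a, b), sum((a - b)^2) / 128, tolerance = 1e-15)
  expect_equal(edf_mse(a, b), edf_mse(b, a))
  expect_error(edf_mse(a, b[-1]), "length mismatch")
})

test_that("trained tube models score patients with 14 ordered scores", {
  co <- simulate_cohort(small_strong_spec(4L, 6L, events = c(80L, 120L)),
                        seed = 21)
  tm <- train_tube_models(co)
  sc <- compute_tube_scores(co$patients[[1]], tm)
  expect_length(sc, 14L)
  expect_equal(names(sc)[1:3], c("t1_healthy", "t1_aml", "t2_healthy"))
  expect_true(all(sc >= 0))

  # training healthy patients sit nearer the healthy reference where the
  # classes differ (tube 4 carries the blast signal)
  healthy_sc <- vapply(co$patients[cohort_labels(co) == 0],
                       compute_tube_scores, numeric(14L), models = tm)
  expect_lt(mean(healthy_sc["t4_healthy", ]),
            mean(healthy_sc["t4_aml", ]))

  expect_error(
    train_tube_models(subset_cohort(co, which(cohort_labels(co) == 0))),
    "per class")
})

test_that("only the informative tube separates a tube-4-only cohort", {
  co <- simulate_cohort(tube4_only_spec(6L, 10L, events = c(80L, 120L)),
                        seed = 31)
  tm <- train_tube_models(co)
  sc <- vapply(co$patients, compute_tube_scores, numeric(14L),
               models = tm)
  lab <- cohort_labels(co)
  gap <- vapply(1:7, function(t) {
    d <- sc[2 * t - 1, ] - sc[2 * t, ]   # s_healthy - s_aml
    mean(d[lab == 1]) - mean(d[lab == 0])
  }, numeric(1))
  expect_equal(which.max(abs(gap)), 4L)
})

test_that("per-patient reference EDFs are a valid alternative", {
  co <- simulate_cohort(small_strong_spec(3L, 4L, events = c(50L, 80L)),
                        seed = 41)
  tm <- train_tube_models(co, reference = "per_patient")
  ref <- tm$tubes[[1]]$ref_healthy
  expect_true(all(diff(ref) >= 0))
  expect_true(all(ref >= 0 & ref <= 1))
  expect_length(compute_tube_scores(co$patients[[1]], tm), 14L)
})

test_that("tube models survive a JSON round trip", {
  co <- simulate_cohort(small_strong_spec(3L, 4L, events = c(40L, 60L)),
                        seed = 51)
  tm <- train_tube_models(co)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(tm, f)
  tm2 <- read_model(f)
  s1 <- compute_tube_scores(co$patients[[2]], tm)
  s2 <- compute_tube_scores(co$patients[[2]], tm2)
  expect_equal(s1, s2, tolerance = 1e-12)
})
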