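# Evaluation protocol: SROCC, logistic remapping, PLCC/RMSE, repeated
# splits, and the corrected resampled paired t-test.

test_that("SROCC matches the midrank brute-force oracle", {
  expect_equal(srocc(1:10, 1:10), 1)
  expect_equal(srocc(1:10, 10:1), -1)
  expect_equal(srocc(c(1, 2, 3, 5, 4), c(1, 2, 3, 4, 5)), 0.9)
  expect_equal(oracle_srocc(c(1, 2, 3, 5, 4), c(1, 2, 3, 4, 5)), 0.9)
  for (s in 1:10) {
    set.seed(500 + s)
    a <- sample(1:8, 12, replace = TRUE)   # ties exercised via midranks
    b <- sample(1:8, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(srocc(a, b), oracle_srocc(a, b))
  }
  expect_error(srocc(rep(1, 5), 1:5), "constant")
  expect_error(srocc(1:2, 1:2), "length >= 3")
})

test_that("the logistic family absorbs identity, affine, and reversed maps", {
  set.seed(1)
  pred <- runif(40, 1, 5)
  f_id <- logistic_fit(pred, pred)
  expect_true(f_id$converged)
  expect_lt(max(abs(predict_logistic(f_id, pred) - pred)), 1e-6)
  f_aff <- logistic_fit(pred, 2 * pred + 1)
  expect_lt(max(abs(predict_logistic(f_aff, pred) - (2 * pred + 1))), 1e-6)
  # decreasing relation: the linear term flips sign
  pr <- plcc_rmse(pred, -pred)
  expect_equal(pr$plcc, 1)
  expect_lt(pr$rmse, 1e-6)
})

test_that("known logistic parameters are recovered within fit tolerance", {
  set.seed(2)
  x <- seq(0, 10, length.out = 80)
  truth <- function(x) 3 * (0.5 - plogis(-1.2 * (x - 5))) + 0.1 * x + 2
  mos <- truth(x) + rnorm(80, 0, 0.01)
  fit <- logistic_fit(x, mos)
  expect_true(fit$converged)
  expect_lt(max(abs(predict_logistic(fit, x) - truth(x))), 0.05)
})

test_that("PLCC and RMSE behave at the anchors and under pure noise", {
  set.seed(3)
  pred <- runif(50, 1, 5)
  pr <- plcc_rmse(pred, pred)
  expect_equal(pr$plcc, 1)
  expect_lt(pr$rmse, 1e-6)
  set.seed(4)
  noise_pred <- rnorm(1000); noise_mos <- rnorm(1000)
  pr0 <- plcc_rmse(noise_pred, noise_mos)
  expect_lt(abs(pr0$plcc), 0.1)
  expect_error(logistic_fit(rep(1, 10), 1:10), "constant")
})

test_that("metrics degrade together as prediction noise grows", {
  set.seed(5)
  mos <- runif(100, 1, 5)
  levels <- c(0.05, 0.3, 1, 3)
  avg <- sapply(levels, function(s) {
    m <- sapply(1:20, function(r) {
      set.seed(1000 * s + r)
      p <- mos + rnorm(100, 0, s)
      pr <- plcc_rmse(p, mos)
      c(srocc = srocc(p, mos), plcc = pr$plcc, rmse = pr$rmse)
    })
    rowMeans(m)
  })
  expect_true(all(diff(avg["srocc", ]) < 0))
  expect_true(all(diff(avg["plcc", ]) < 0))
  expect_true(all(diff(avg["rmse", ]) > 0))
})

test_that("repeated splits are replayable, sized correctly, and summarized", {
  toy_grid <- ceiqa_grid(cost = 10, gamma = 0.05, k = 2)
  set.seed(6)
  X <- matrix(rnorm(642 * 4), 642, 4)
  y <- X[, 1] + rnorm(642, 0, 0.2)
  ev <- repeated_split_eval(X, y, n_repeats = 2, seed = 9, grid = toy_grid)
  expect_equal(ev$n_train, 513L)      # floor(0.8 * 642)
  expect_equal(ev$n_test, 129L)       # the held-out remainder
  ev2 <- repeated_split_eval(X, y, n_repeats = 2, seed = 9, grid = toy_grid)
  expect_identical(ev$srocc, ev2$srocc)
  expect_identical(ev$splits, ev2$splits)
  # summaries reproduce from the stored per-repeat vectors
  expect_equal(unname(ev$median["srocc"]), median(ev$srocc))
  expect_equal(unname(ev$sd["rmse"]), sd(ev$rmse))
  expect_output(print(ev), "SROCC")
  expect_error(repeated_split_eval(X[1:8, ], y[1:8], n_repeats = 1,
                                   grid = toy_grid), "too few")
})

test_that("evaluation reports round-trip their per-repeat vectors", {
  toy_grid <- ceiqa_grid(cost = 10, gamma = 0.05, k = 2)
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3)
  ev <- repeated_split_eval(X, X[, 1] + rnorm(40, 0, 0.1), n_repeats = 3,
                            seed = 2, grid = toy_grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(ev, path)
  expect_match(readLines(path, n = 1L), "^# ceiqa .*repeats=3")
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$srocc, unname(ev$srocc))
})

test_that("the corrected resampled t-test matches its scalar oracle", {
  # identical methods: zero decision
  a <- c(0.8, 0.82, 0.81, 0.79)
  expect_identical(as.integer(corrected_resampled_ttest(a, a, 80, 20)), 0L)
  # constant advantage with tiny jitter, K = 10, n_test/n_train = 0.25
  set.seed(8)
  d <- 0.05 + rnorm(10, 0, 0.001)
  b <- runif(10, 0.7, 0.8)
  v <- corrected_resampled_ttest(b + d, b, 80, 20)
  expect_identical(as.integer(v), oracle_corrected_t(b + d, b, 80, 20))
  expect_equal(attr(v, "statistic"),
               mean(d) / sqrt(var(d) * (1 / 10 + 20 / 80)))
  # randomized oracle agreement and argument-swap antisymmetry
  for (s in 1:20) {
    set.seed(900 + s)
    x <- runif(12, 0.6, 0.9); yv <- x + rnorm(12, 0.01, 0.03)
    expect_identical(as.integer(corrected_resampled_ttest(x, yv, 100, 25)),
                     oracle_corrected_t(x, yv, 100, 25))
    expect_identical(as.integer(corrected_resampled_ttest(x, yv, 100, 25)),
                     -as.integer(corrected_resampled_ttest(yv, x, 100, 25)))
  }
  expect_error(corrected_resampled_ttest(1:3, 1:4, 10, 2), "paired")
})

test_that("the correction never increases the t statistic magnitude", {
  for (s in 1:10) {
    set.seed(700 + s)
    a <- runif(15, 0.6, 0.9); b <- a + rnorm(15, 0, 0.05)
    d <- a - b
    t_plain <- mean(d) / sqrt(var(d) / length(d))
    t_corr <- attr(corrected_resampled_ttest(a, b, 60, 20), "statistic")
    expect_lte(abs(t_corr), abs(t_plain))
  }
})

test_that("significance matrices are antisymmetric with transitive dominance", {
  set.seed(9)
  base <- runif(30, 0.5, 0.55)
  scores <- list(best = base + 0.3, mid = base + 0.15, worst = base)
  m <- significance_matrix(scores, 80, 20)
  expect_identical(m, -t(m))
  expect_true(all(diag(m) == 0L))
  expect_identical(m["best", "mid"], 1L)
  expect_identical(m["best", "worst"], 1L)
  expect_identical(m["mid", "worst"], 1L)
  # identical methods: all-zero matrix
  m0 <- significance_matrix(list(a = base, b = base), 80, 20)
  expect_true(all(m0 == 0L))
  expect_error(significance_matrix(list(a = 1:3, b = 1:4), 10, 2),
               "differ in length")
})
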