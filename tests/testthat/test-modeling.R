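test_that("an overwhelming penalty shrinks every weight to zero, leaving the mean as intercept", {
  set.seed(5)
  ds <- toy_dataset(matrix(rnorm(60), 12, 5), y = rnorm(12, 10))
  fit <- fit_lasso(ds, lambda = 1e6)
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, mean(ds$y), tolerance = 1e-8)
  expect_length(fit$selected, 0)
})

test_that("with no penalty and n > p the LASSO matches the normal-equation OLS oracle", {
  set.seed(6)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + 1.5 * x[, 1] - 0.7 * x[, 3] + rnorm(40, 0, 0.1)
  fit <- fit_lasso(toy_dataset(x, y), lambda = 0)
  beta <- ols_oracle(x, y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-3)
  expect_equal(unname(fit$weights), beta[-1], tolerance = 1e-3)
})

test_that("the LASSO recovers the true support on a noiseless two-parameter cohort", {
  coupling <- data.frame(descriptor = c("Correlation", "Length"),
                         statistic = c("SD", "SD"),
                         time_h = 6, coefficient = c(0.008, -1.2))
  sp <- cohort_spec(n_clones = 10, cells_per_well_range = c(50, 2000),
                    time_points = c(6, 12), n_fov = 8, coupling = coupling,
                    noise_sd = 0, seed = 11)
  co <- generate_cohort(sp)
  ds <- profile_dataset(cohort_profiles(co), co$labels)
  fit <- fit_lasso(ds)
  truth <- c("Correlation_SD (6 h)", "Length_SD (6 h)")
  expect_gt(length(fit$selected), 0)
  expect_true(all(fit$selected %in% truth))
})

test_that("nonzero-coefficient count is non-increasing in the penalty", {
  set.seed(8)
  x <- matrix(rnorm(200), 20, 10)
  y <- x %*% rnorm(10) + rnorm(20, 0, 0.5)
  ds <- toy_dataset(x, as.numeric(y))
  nnz <- vapply(c(0.01, 0.05, 0.2, 0.5, 2),
                function(l) length(fit_lasso(ds, lambda = l)$selected), 1L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("random forests are seed-reproducible and rank a dominant predictor first", {
  set.seed(9)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("p", 1:10)))
  y <- 5 * x[, 4] + rnorm(30, 0, 0.2)
  ds <- toy_dataset(x, y)
  f1 <- fit_rf(ds, seed = 3)
  f2 <- fit_rf(ds, seed = 3)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_equal(names(which.max(f1$importances)), "p4")
})

test_that("on a pure-noise target the forest cannot beat the mean predictor by much", {
  set.seed(10)
  x <- matrix(rnorm(15 * 20), 15, 20)
  y <- rnorm(15, 10)
  ds <- toy_dataset(x, y)
  cv <- loocv(ds, list(kind = "rf", seed = 2))
  mean_rmse <- rmse_of(y, vapply(seq_along(y), function(i) mean(y[-i]), numeric(1)))
  expect_gte(cv$rmse, mean_rmse - 0.5)
})

test_that("RMSE follows its definition on held-out predictions", {
  y <- c(7, 9, 11, 13)
  expect_equal(rmse_of(y, y), 0)
  expect_equal(rmse_of(y, y + 1), 1)
})

test_that("grouped LOOCV makes one fold per clone and never leaks replicates", {
  co <- default_cohort()
  reduced <- lapply(co$clones, function(cl)
    bootstrap_profiles(cl$cells, 12, k = 64, B = 3, seed = 5,
                       time_points = c(6, 12)))
  ds <- profile_dataset(unlist(reduced, recursive = FALSE), co$labels)
  expect_equal(nrow(ds$x), 45)
  cv <- loocv(ds, list(kind = "lasso"))
  expect_equal(cv$n_folds, 15)
  # every clone's 3 replicates are predicted together, once each
  tab <- table(cv$predictions$clone)
  expect_true(all(tab == 3))
  expect_equal(nrow(cv$predictions), 45)
})

test_that("LOOCV errors usefully on degenerate fold structures", {
  set.seed(11)
  x <- matrix(rnorm(20), 2, 10)
  expect_error(loocv(toy_dataset(x, c(1, 2))), ">= 3 clones")
  x3 <- matrix(rnorm(30), 3, 10)
  ds3 <- toy_dataset(x3, c(7, 9, 11))
  expect_error(fit_lasso(toy_dataset(x3[1:2, ], c(7, 7))), ">= 3")
})

test_that("LASSO LOOCV error vanishes as generator noise goes to zero", {
  sp0 <- cohort_spec(n_clones = 10, cells_per_well_range = c(50, 2000),
                     time_points = c(6, 12, 18), n_fov = 8, noise_sd = 0, seed = 21)
  co0 <- generate_cohort(sp0)
  ds0 <- profile_dataset(cohort_profiles(co0), co0$labels)
  cv0 <- loocv(ds0, list(kind = "lasso"))
  expect_lt(cv0$rmse, 0.2)
  sp1 <- cohort_spec(n_clones = 10, cells_per_well_range = c(50, 2000),
                     time_points = c(6, 12, 18), n_fov = 8, noise_sd = 1, seed = 21)
  co1 <- generate_cohort(sp1)
  ds1 <- profile_dataset(cohort_profiles(co1), co1$labels)
  expect_lt(cv0$rmse, loocv(ds1, list(kind = "lasso"))$rmse)
})

test_that("the data-usage grid fills every window x FOV-count cell with finite RMSE", {
  co <- small_cohort()
  g <- data_usage_grid(co, windows = c(6, 18), fov_counts = c(3, 8),
                       model_spec = list(kind = "lasso"), seed = 2)
  expect_equal(nrow(g$grid), 4)
  expect_true(all(is.finite(g$grid$rmse)))
  expect_identical(g$grid$pass, g$grid$rmse < 1.0)
  expect_error(data_usage_grid(co, windows = 18, fov_counts = 99), "1..8")
  expect_error(data_usage_grid(co, windows = 24, fov_counts = 2), "time points")
})

test_that("using the full window and all FOVs does not do worse than the minimal data cell", {
  co <- default_cohort()
  g <- data_usage_grid(co, windows = c(6, 90), fov_counts = c(2, 64),
                       model_spec = list(kind = "lasso"), seed = 3)
  full <- g$grid$rmse[g$grid$window_end_h == 90 & g$grid$fov_count == 64]
  minimal <- g$grid$rmse[g$grid$window_end_h == 6 & g$grid$fov_count == 2]
  expect_lte(full, minimal + 0.5)
  # an undersampled draw with no cells at a time point is recorded, not fatal
  g1 <- data_usage_grid(co, windows = 6, fov_counts = 1,
                        model_spec = list(kind = "lasso"), seed = 3)
  expect_equal(nrow(g1$grid), 1)
  expect_true(is.finite(g1$grid$rmse) || !is.na(g1$grid$error))
})

test_that("model-structure correlation is 1 against itself and -1 against its negation", {
  w <- c(a = 0.5, b = -1.2, c = 0, d = 2)
  f <- structure(list(kind = "lasso", weights = w), class = "model_fit")
  g <- structure(list(kind = "lasso", weights = -w), class = "model_fit")
  cm <- model_structure_correlation(list(self = f, neg = g, again = f))
  expect_equal(unname(cm["self", "self"]), 1)
  expect_equal(unname(cm["self", "again"]), 1)
  expect_equal(unname(cm["self", "neg"]), -1)
  expect_true(isSymmetric(cm))
  zero <- structure(list(kind = "lasso", weights = w * 0), class = "model_fit")
  expect_warning(cm2 <- model_structure_correlation(list(f, zero)), "zero-variance")
  expect_true(is.na(cm2[1, 2]))
})

test_that("LASSO fits on bootstrap re-draws of one cohort share their model structure", {
  co <- default_cohort()
  fits <- lapply(c(31, 32), function(s) {
    bp <- unlist(lapply(co$clones, function(cl)
      bootstrap_profiles(cl$cells, 18, k = 64, B = 5, seed = s,
                         time_points = c(6, 12, 18))), recursive = FALSE)
    fit_lasso(profile_dataset(bp, co$labels))
  })
  cm <- model_structure_correlation(fits)
  expect_gt(cm[1, 2], 0.7)
})
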