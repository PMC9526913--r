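# Minimal cell table with given values for one descriptor, constants elsewhere.
cells_with <- function(descriptor, values, time_h = 6, fov = 1) {
  base <- as.data.frame(matrix(1, length(values), 12,
                               dimnames = list(NULL, descriptor_names())))
  base[[descriptor]] <- values
  cbind(data.frame(clone_id = "cX", time_h = time_h, fov = fov,
                   cell_id = seq_along(values)), base)
}

test_that("population summary uses the pooled sample SD (n - 1) convention", {
  s <- summarize_population(cells_with("Area", c(100, 300)))
  expect_equal(unname(s["Area_mean"]), 200)
  expect_equal(unname(s["Area_SD"]), 141.42, tolerance = 1e-4)
  same <- summarize_population(cells_with("Area", rep(250, 5)))
  expect_equal(unname(same["Area_SD"]), 0)
  expect_length(s, 24)
})

test_that("summaries of large draws recover the generating parameters", {
  set.seed(77)
  v <- rnorm(1e4, mean = 100, sd = 20)
  s <- summarize_population(cells_with("Area", v))
  expect_lt(abs(s[["Area_mean"]] - 100), 3 * 20 / sqrt(1e4))
  expect_lt(abs(s[["Area_SD"]] - 20), 3 * 20 / sqrt(2 * 1e4))
})

test_that("0 or 1 usable records is an insufficient-population error naming the clone", {
  expect_error(summarize_population(cells_with("Area", 100)), "insufficient.*cX")
  one <- cells_with("Area", c(100, 200)); one$degenerate <- c(FALSE, TRUE)
  expect_error(summarize_population(one), "insufficient")
})

test_that("profile dimensionality follows 12 x 2 x time points", {
  co <- default_cohort()
  cl <- co$clones[[1]]
  full <- build_profile(cl$cells, 90, 1:64)
  expect_length(full$values, 360)
  single <- build_profile(cl$cells, 6, 1:64)
  expect_length(single$values, 24)
  mid <- build_profile(cl$cells, 30, 1:64)
  expect_length(mid$values, 120)
  expect_true("Correlation_SD (18 h)" %in% names(full$values))
  expect_identical(names(full$values), profile_parameter_names(seq(6, 90, 6)))
})

test_that("window parameter sets nest: shorter windows are prefixes of longer ones", {
  co <- small_cohort()
  cl <- co$clones[[1]]
  p12 <- build_profile(cl$cells, 12, 1:8, time_points = c(6, 12))
  p18 <- build_profile(cl$cells, 18, 1:8, time_points = c(6, 12, 18))
  expect_identical(names(p12$values), names(p18$values)[seq_along(p12$values)])
  expect_equal(p12$values, p18$values[seq_along(p12$values)])
})

test_that("profiles are invariant to FOV id order and match pooled concatenation", {
  co <- small_cohort()
  cl <- co$clones[[2]]
  a <- build_profile(cl$cells, 18, c(1, 2, 5), time_points = c(6, 12, 18))
  b <- build_profile(cl$cells, 18, c(5, 1, 2), time_points = c(6, 12, 18))
  expect_equal(a$values, b$values)
  # pooling identity: union of FOVs == concatenated records, no pre-averaging
  rec <- cl$cells[cl$cells$fov %in% c(1, 2, 5) & cl$cells$time_h == 6, ]
  s <- summarize_population(rec)
  expect_equal(unname(a$values["Area_SD (6 h)"]), unname(s["Area_SD"]))
})

test_that("a missing time point raises a missing-time-point error", {
  co <- small_cohort()
  cl <- co$clones[[1]]
  expect_error(build_profile(cl$cells, 24, 1:8, time_points = c(6, 12, 18, 24)),
               "missing time point")
  expect_error(build_profile(cl$cells, 18, integer(0)), "fov_ids")
})

test_that("FOV subsampling is uniform, without replacement and seed-reproducible", {
  full <- subsample_fovs(1:64, 64, seed = 1)
  expect_setequal(full, 1:64)
  one <- subsample_fovs(1:64, 1, seed = 2)
  expect_length(one, 1)
  expect_identical(subsample_fovs(1:64, 10, seed = 3), subsample_fovs(1:64, 10, seed = 3))
  expect_error(subsample_fovs(1:64, 0), "between")
  expect_error(subsample_fovs(1:64, 65), "between")
})

test_that("bootstrap draws FOVs with replacement and the forced identity draw equals the raw profile", {
  co <- small_cohort()
  cl <- co$clones[[3]]
  B <- 6
  bp <- bootstrap_profiles(cl$cells, 18, k = 8, B = B, seed = 4,
                           available = 1:8, time_points = c(6, 12, 18))
  expect_length(bp, B)
  expect_equal(vapply(bp, `[[`, 0L, "replicate_id"), 1:B)
  expect_true(any(vapply(bp, function(p) anyDuplicated(p$fov_ids) > 0, logical(1))))
  # forcing the identity draw (single available FOV) reproduces the raw profile
  raw <- build_profile(cl$cells[cl$cells$fov == 2, ], 18, 2, time_points = c(6, 12, 18))
  ident <- bootstrap_profiles(cl$cells, 18, k = 1, B = 1, seed = 9,
                              available = 2, time_points = c(6, 12, 18))
  expect_equal(unname(ident[[1]]$values), unname(raw$values))
})

test_that("bootstrap spread of a profile parameter shrinks as the FOV count grows", {
  co <- small_cohort()
  cl <- co$clones[[1]]
  spread <- function(k) {
    bp <- bootstrap_profiles(cl$cells, 6, k = k, B = 50, seed = 10,
                             available = 1:8, time_points = 6)
    stats::sd(vapply(bp, function(p) p$values[["Area_mean (6 h)"]], numeric(1)))
  }
  expect_lt(spread(8), spread(2))
})

test_that("growth rate is the fold-change of counts and matches the generator ground truth", {
  expect_equal(growth_rate(c(`6` = 300, `90` = 1500)), 5)
  expect_equal(growth_rate(c(10, 10, 10)), 1)
  expect_error(growth_rate(c(0, 50)), "zero")
  expect_error(growth_rate(300), "2 time points")
  co <- default_cohort()
  for (cl in co$clones[1:5])
    expect_equal(growth_rate(cl$counts), cl$growth_rate, tolerance = 0.15)
})

test_that("datasets align profiles with labels and reject inconsistent input", {
  co <- small_cohort()
  prof <- cohort_profiles(co)
  ds <- profile_dataset(prof, co$labels)
  expect_equal(dim(ds$x), c(6, 72))
  expect_equal(ds$y, co$labels$potency)
  short <- build_profile(co$clones[[1]]$cells, 12, 1:8, time_points = c(6, 12))
  expect_error(profile_dataset(c(prof[1:2], list(short)), co$labels), "parameter name")
  expect_error(profile_dataset(prof, co$labels[c(1, 1:5), ]), "one row per clone")
})

test_that("profile tables round-trip through CSV", {
  co <- small_cohort()
  prof <- cohort_profiles(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(prof, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$clone_id, co$labels$clone_id)
  expect_equal(tab[["Area_mean (6 h)"]],
               vapply(prof, function(p) p$values[["Area_mean (6 h)"]], numeric(1)))
})
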