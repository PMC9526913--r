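test_that("default cohort has 15 clones with potencies spanning the 7-13 range", {
  co <- default_cohort()
  expect_length(co$clones, 15)
  expect_true(all(co$labels$potency %in% 7:13))
  expect_gte(length(unique(co$labels$potency)), 2)
  # round-robin assignment covers the whole range with 15 clones
  expect_setequal(unique(co$labels$potency), 7:13)
})

test_that("invalid cohort specs fail with the offending field named", {
  expect_error(cohort_spec(n_clones = 0), "n_clones")
  expect_error(cohort_spec(potency_range = c(13, 7)), "potency_range")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(cells_per_well_range = c(0, 10)), "cells_per_well_range")
  bad <- default_coupling(); bad$coefficient[1] <- Inf
  expect_error(cohort_spec(coupling = bad), "coupling")
})

test_that("identical spec and seed give a bit-identical cohort", {
  sp <- cohort_spec(n_clones = 4, cells_per_well_range = c(20, 500),
                    time_points = c(6, 12), n_fov = 4, seed = 13)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$labels, b$labels)
  expect_identical(a$clones[[2]]$cells, b$clones[[2]]$cells)
})

test_that("noiseless coupled population statistics are exact affine functions of potency", {
  sp <- cohort_spec(n_clones = 8, cells_per_well_range = c(50, 2000),
                    time_points = c(6, 12), n_fov = 4, noise_sd = 0, seed = 3)
  co <- generate_cohort(sp)
  stat <- vapply(co$clones, function(cl)
    summarize_population(cl$cells[cl$cells$time_h == 6, ])[["Correlation_SD"]],
    numeric(1))
  q <- co$labels$potency
  fit <- stats::lm(stat ~ q)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  expect_equal(unname(stats::coef(fit)[2]), 0.008, tolerance = 1e-8)
})

test_that("increasing potency at zero noise shifts each coupled statistic in its coefficient's sign", {
  sp <- cohort_spec(n_clones = 7, cells_per_well_range = c(50, 2000),
                    time_points = c(6, 12), n_fov = 4, noise_sd = 0, seed = 3)
  co <- generate_cohort(sp)
  q <- co$labels$potency
  ord <- order(q)
  cp <- unique(sp$coupling[, c("descriptor", "statistic", "coefficient")])
  for (r in seq_len(nrow(cp))) {
    stat_name <- paste0(cp$descriptor[r], "_", cp$statistic[r])
    v <- vapply(co$clones, function(cl)
      summarize_population(cl$cells[cl$cells$time_h == 6, ])[[stat_name]],
      numeric(1))
    d <- diff(v[ord])
    if (cp$coefficient[r] > 0) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
})

test_that("generated growth rates reproduce the weak growth/potency association", {
  co <- cached("r2_cohort", generate_cohort(
    cohort_spec(n_clones = 200, cells_per_well_range = c(10, 1000),
                time_points = c(6, 90), n_fov = 2, seed = 7)))
  r2 <- scalar_r2(co$labels$growth_rate, co$labels$potency)
  expect_lt(abs(r2 - 0.09), 0.05)
})

test_that("cell counts are non-decreasing and stay inside the per-well range", {
  co <- small_cohort()
  for (cl in co$clones) {
    expect_true(all(diff(cl$counts) >= 0))
    expect_true(all(cl$counts >= 2))
    expect_true(all(cl$counts <= co$spec$cells_per_well_range[2]))
    expect_true(cl$potency >= co$spec$potency_range[1] &&
                  cl$potency <= co$spec$potency_range[2])
  }
})

test_that("rendering an empty time point gives a blank frame and empty mask", {
  co <- render_cohort()
  cl <- co$clones[[1]]
  # restrict the clone to FOV 1 so FOV 2 is guaranteed empty
  cl$cells <- cl$cells[cl$cells$fov == 1, ]
  fr <- render_frame(cl, 6, 2, render_spec(image_size = 256))
  expect_equal(n_objects(fr$mask), 0)
  expect_equal(nrow(fr$truth), 0)
  expect_true(all(fr$frame$intensity >= 0 & fr$frame$intensity <= 1))
})

test_that("every rendered cell is one connected labelled region, reproducibly", {
  co <- render_cohort()
  cl <- co$clones[[1]]
  rs <- render_spec(image_size = 400, allow_border = FALSE)
  fr <- render_frame(cl, 6, 1, rs, seed = 21)
  expect_equal(n_objects(fr$mask), nrow(fr$truth))
  expect_true(all(fr$truth$area_px > 0))
  expect_false(any(fr$truth$border_touching))
  # connectivity: labels survive 8-connectivity relabelling unchanged in count
  lab <- EBImage::bwlabel(fr$mask > 0)
  expect_equal(max(lab), nrow(fr$truth))
  fr2 <- render_frame(cl, 6, 1, rs, seed = 21)
  expect_identical(fr$frame$intensity, fr2$frame$intensity)
  expect_identical(fr$mask, fr2$mask)
})

test_that("descriptors measured from the ground-truth render agree with the generating table", {
  co <- render_cohort()
  cl <- co$clones[[1]]
  rs <- render_spec(image_size = 400, allow_border = FALSE)
  fr <- render_frame(cl, 6, 1, rs, seed = 21)
  rec <- measure_frame(fr$frame, fr$mask)
  tab <- cl$cells[cl$cells$time_h == 6 & cl$cells$fov == 1, ]
  gen_area <- tab$Area[match(fr$truth$cell_id, tab$cell_id)]
  ratio <- rec$Area[fr$truth$label] / pmax(gen_area, 50)
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("overly dense scenes raise a density error", {
  co <- render_cohort()
  cl <- co$clones[[2]]
  expect_error(render_frame(cl, 12, which.max(tabulate(cl$cells$fov[cl$cells$time_h == 12])),
                            render_spec(image_size = 64, max_place_tries = 5)),
               "density|too large")
})

test_that("cohorts round-trip to delimited files with a spec sidecar", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(lab$potency, co$labels$potency)
  cells <- read.csv(file.path(dir, "clone01_cells.csv"), check.names = FALSE)
  expect_equal(nrow(cells), nrow(co$clones[[1]]$cells))
  expect_true(all(descriptor_names() %in% names(cells)))
})
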