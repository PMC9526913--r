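#' Baseline per-cell descriptor distributions
#'
#' Baseline population mean and within-population SD for each of the 12
#' descriptors, representing a clone of intermediate potency. Units follow the
#' descriptor definitions (Area in um^2, Perimeter/Length/Breadth in um,
#' intensities in arbitrary units on a 0--1 scale, texture and shape ratios
#' dimensionless). Values are chosen to emulate small, fairly homogeneous
#' clone-derived mesenchymal stromal cells imaged at 4x phase contrast
#' (median spread-cell area a few hundred um^2).
#'
#' @return A data.frame with columns \code{descriptor}, \code{base_mean},
#'   \code{base_sd}.
#' @export
baseline_descriptor_table <- function() {
  data.frame(
    descriptor = descriptor_names(),
    base_mean = c(360, 90, 35, 15, 2.4, 2.0, 0.55, 0.85, 0.50, 0.08, 0.55, 0.15),
    base_sd   = c(150, 30, 18,  5, 0.9, 0.8, 0.18, 0.08, 0.10, 0.03, 0.12, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Default descriptor-statistic coupling to serial-passage potency
#'
#' Affine coupling between clone potency and selected population statistics at
#' the early time points (6--18 h): the SD of the texture descriptors
#' (Correlation, Energy) increases with potency, reflecting a larger
#' proliferating (round, bright) subpopulation, while the SD of Length and
#' Compactness and the mean of Correlation decrease, reflecting a more
#' homogeneous, less elongation-dominated population in high-potency clones.
#' Coefficients are per passage of potency, in the descriptor's own units.
#'
#' @param time_points Time grid of the cohort (hours); coupling is applied at
#'   the intersection with \code{c(6, 12, 18)}.
#' @return A data.frame with columns \code{descriptor}, \code{statistic}
#'   (\code{"mean"} or \code{"SD"}), \code{time_h}, \code{coefficient}.
#' @export
default_coupling <- function(time_points = default_time_points()) {
  tps <- intersect(c(6, 12, 18), time_points)
  base <- data.frame(
    descriptor = c("Correlation", "Energy", "Length", "Compactness", "Correlation"),
    statistic = c("SD", "SD", "SD", "SD", "mean"),
    coefficient = c(+0.008, +0.004, -1.2, -0.05, -0.012),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(tps, function(tp) transform(base, time_h = tp)))
  out[, c("descriptor", "statistic", "time_h", "coefficient")]
}

#' Specification of a synthetic clone cohort
#'
#' Defines the conditions under which a cohort of single-cell-derived clones is
#' simulated: 15 clones with serial-passage potencies spanning 7--13, wells
#' holding from ~300 cells at seeding up to (at most) 100,000 cells across the
#' 6--90 h time course, and population statistics of selected descriptors
#' coupled affinely to potency (see [default_coupling()]).
#'
#' `noise_sd` scales the clone-level jitter applied to every population
#' parameter beyond what potency explains: a coupled parameter receives jitter
#' with SD `noise_sd * 2 * |coefficient|` (potency itself contributes SD
#' `2 * |coefficient|` across a 7--13 cohort, so the default `noise_sd = 0.5`
#' sets the per-parameter signal-to-noise ratio to 2 — the frozen calibration
#' under which a well-fit linear model reaches the sub-passage error regime),
#' and an uncoupled parameter receives jitter with SD
#' `noise_sd * 0.1 * base_sd`.
#'
#' `growth_potency_r2_target` calibrates the weak coupling between growth rate
#' and potency: log2 fold-change is drawn as
#' `2.5 + 0.1 (q - 10) + N(0, s)` with `s` solved so the expected coefficient
#' of determination equals the target (0.09 by default — growth rate alone
#' cannot predict potency).
#'
#' @param n_clones Number of clones (default 15).
#' @param potency_range Integer interval of serial-passage limitation numbers
#'   (default c(7, 13)).
#' @param cells_per_well_range Admissible per-well cell count interval across
#'   the time course (default c(300, 100000)); seeding counts are drawn near
#'   its lower end.
#' @param time_points Acquisition time grid in hours (default 6, 12, ..., 90).
#' @param n_fov Number of fields of view tiling the well (default 64).
#' @param coupling Coupling table as returned by [default_coupling()].
#' @param noise_sd Scalar jitter scale (>= 0, default 0.5).
#' @param growth_potency_r2_target Target R^2 between growth rate and potency
#'   (default 0.09).
#' @param seed Integer seed; the same spec and seed give a bit-identical cohort.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_clones = 15,
                        potency_range = c(7, 13),
                        cells_per_well_range = c(300, 100000),
                        time_points = default_time_points(),
                        n_fov = 64,
                        coupling = default_coupling(time_points),
                        noise_sd = 0.5,
                        growth_potency_r2_target = 0.09,
                        seed = 1) {
  if (!is.numeric(n_clones) || length(n_clones) != 1 || n_clones < 1 ||
      n_clones != round(n_clones))
    stopf("invalid cohort spec: 'n_clones' must be a positive integer")
  if (length(potency_range) != 2 || any(!is.finite(potency_range)) ||
      potency_range[1] > potency_range[2] ||
      any(potency_range != round(potency_range)) || potency_range[1] < 3)
    stopf("invalid cohort spec: 'potency_range' must be an integer interval with lower bound >= 3")
  if (length(cells_per_well_range) != 2 || cells_per_well_range[1] < 2 ||
      cells_per_well_range[1] > cells_per_well_range[2])
    stopf("invalid cohort spec: 'cells_per_well_range' must be an interval with lower bound >= 2")
  if (length(time_points) < 1 || any(!is.finite(time_points)) ||
      any(time_points <= 0) || is.unsorted(time_points, strictly = TRUE))
    stopf("invalid cohort spec: 'time_points' must be strictly increasing positive hours")
  if (!is.numeric(n_fov) || n_fov < 1) stopf("invalid cohort spec: 'n_fov' must be >= 1")
  req <- c("descriptor", "statistic", "time_h", "coefficient")
  if (!is.data.frame(coupling) || !all(req %in% names(coupling)))
    stopf("invalid cohort spec: 'coupling' must have columns %s", paste(req, collapse = ", "))
  if (nrow(coupling) > 0) {
    if (any(!is.finite(coupling$coefficient)))
      stopf("invalid cohort spec: 'coupling' coefficients must all be finite")
    if (!all(coupling$descriptor %in% descriptor_names()))
      stopf("invalid cohort spec: 'coupling' names unknown descriptors")
    if (!all(coupling$statistic %in% c("mean", "SD")))
      stopf("invalid cohort spec: 'coupling' statistic must be 'mean' or 'SD'")
    if (!all(coupling$time_h %in% time_points))
      stopf("invalid cohort spec: 'coupling' refers to time points outside 'time_points'")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || !is.finite(noise_sd) || noise_sd < 0)
    stopf("invalid cohort spec: 'noise_sd' must be a finite scalar >= 0")
  if (!is.numeric(growth_potency_r2_target) || growth_potency_r2_target < 0 ||
      growth_potency_r2_target >= 1)
    stopf("invalid cohort spec: 'growth_potency_r2_target' must be in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stopf("invalid cohort spec: 'seed' must be a finite integer")
  structure(list(
    n_clones = as.integer(n_clones),
    potency_range = as.integer(potency_range),
    cells_per_well_range = as.numeric(cells_per_well_range),
    time_points = as.numeric(time_points),
    n_fov = as.integer(n_fov),
    coupling = coupling,
    noise_sd = noise_sd,
    growth_potency_r2_target = growth_potency_r2_target,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Round-robin potency assignment over the range, then shuffled: guarantees the
# full range is covered whenever n_clones >= range width (e.g. 15 clones over
# 7..13) and >= 2 distinct values whenever n_clones >= 2.
assign_potencies <- function(spec) {
  vals <- seq(spec$potency_range[1], spec$potency_range[2])
  q <- rep(vals, length.out = spec$n_clones)
  if (spec$n_clones > 1) q <- sample(q) else q <- q[1]
  as.integer(q)
}

# Draw an n x 12 per-cell descriptor matrix whose pooled sample mean and
# sample SD (n - 1) equal mu/sigma exactly: standard-normal draws are
# re-standardised column-wise before scaling. This makes clone-level
# population statistics exact functions of the generating parameters, so the
# noiseless cohort is exactly affine in potency on the coupled parameters.
draw_exact_cells <- function(n, mu, sigma) {
  k <- length(mu)
  z <- matrix(stats::rnorm(n * k), n, k)
  z <- sweep(z, 2, colMeans(z))
  s <- apply(z, 2, stats::sd)
  s[s == 0] <- 1
  z <- sweep(z, 2, s, "/")
  x <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
  colnames(x) <- descriptor_names()
  x
}

#' Generate a synthetic clone cohort
#'
#' Simulates \code{spec$n_clones} single-cell-derived clones. For each clone a
#' potency is assigned (round-robin over the range, shuffled), a growth curve
#' is drawn (log2 fold-change weakly coupled to potency, calibrated to the
#' spec's growth/potency R^2 target), and per-cell descriptor tables are drawn
#' at every time point. Population mean and SD of each coupled
#' descriptor-statistic equal
#' \code{baseline + coefficient * (potency - midrange) + jitter}, with jitter
#' scaled by \code{spec$noise_sd} (exactly affine in potency when
#' \code{noise_sd = 0}). Cells are spread uniformly over the well's fields of
#' view, and each cell carries a \code{proliferating} flag (round/bright
#' phenotype) whose prevalence increases with potency; the flag drives image
#' rendering only.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class \code{synthetic_cohort}: a list with
#'   \code{spec}, \code{clones} (list of \code{synthetic_clone}, each holding
#'   \code{clone_id}, \code{potency}, \code{growth_rate}, per-time-point
#'   \code{counts} and the per-cell \code{cells} table), and \code{labels}
#'   (data.frame \code{clone_id}, \code{potency}, \code{growth_rate}).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  base <- baseline_descriptor_table()
  tps <- spec$time_points
  qmid <- mean(spec$potency_range)

  with_seed(spec$seed, {
    potencies <- assign_potencies(spec)

    # growth calibration: R2 = b^2 Var(q) / (b^2 Var(q) + s^2)
    b <- 0.1
    vq <- mean((potencies - mean(potencies))^2)
    r2 <- spec$growth_potency_r2_target
    s_e <- if (r2 > 0 && vq > 0) b * sqrt(vq) * sqrt(1 / r2 - 1) else 0.636
    if (r2 == 0) b <- 0
    log2fold <- 2.5 + b * (potencies - qmid) + stats::rnorm(spec$n_clones, 0, s_e)
    fold <- pmax(2^log2fold, 1.05)

    clones <- vector("list", spec$n_clones)
    for (i in seq_len(spec$n_clones)) {
      q <- potencies[i]
      n0 <- round(stats::runif(1, spec$cells_per_well_range[1],
                               min(spec$cells_per_well_range[1] * 5 / 3,
                                   spec$cells_per_well_range[2])))
      if (length(tps) > 1) {
        frac <- (tps - tps[1]) / (tps[length(tps)] - tps[1])
        counts <- cummax(round(n0 * fold[i]^frac))
      } else counts <- n0
      counts <- pmin(counts, spec$cells_per_well_range[2])

      p_round <- min(max(0.15 + 0.02 * (q - qmid), 0.02), 0.6)
      tables <- vector("list", length(tps))
      for (j in seq_along(tps)) {
        tp <- tps[j]
        mu <- base$base_mean
        sigma <- base$base_sd
        names(mu) <- names(sigma) <- base$descriptor
        cp <- spec$coupling[spec$coupling$time_h == tp, , drop = FALSE]
        jit_mu <- 0.1 * sigma
        jit_sd <- 0.1 * sigma
        if (nrow(cp) > 0) for (r in seq_len(nrow(cp))) {
          d <- cp$descriptor[r]; cf <- cp$coefficient[r]
          if (cp$statistic[r] == "mean") {
            mu[d] <- mu[d] + cf * (q - qmid)
            jit_mu[d] <- 2 * abs(cf)
          } else {
            sigma[d] <- sigma[d] + cf * (q - qmid)
            jit_sd[d] <- 2 * abs(cf)
          }
        }
        mu <- mu + spec$noise_sd * jit_mu * stats::rnorm(length(mu))
        sigma <- pmax(sigma + spec$noise_sd * jit_sd * stats::rnorm(length(sigma)),
                      0.05 * base$base_sd)
        n <- counts[j]
        x <- draw_exact_cells(n, mu, sigma)
        tables[[j]] <- data.frame(
          clone_id = sprintf("clone%02d", i),
          time_h = tp,
          fov = sample.int(spec$n_fov, n, replace = TRUE),
          cell_id = seq_len(n),
          x,
          proliferating = stats::runif(n) < p_round,
          stringsAsFactors = FALSE, check.names = FALSE
        )
      }
      cells <- do.call(rbind, tables)
      rownames(cells) <- NULL
      clones[[i]] <- structure(list(
        clone_id = sprintf("clone%02d", i),
        potency = q,
        growth_rate = fold[i],
        counts = stats::setNames(counts, tps),
        cells = cells,
        seed = derive_seed(spec$seed, i)
      ), class = "synthetic_clone")
    }

    labels <- data.frame(
      clone_id = vapply(clones, `[[`, "", "clone_id"),
      potency = potencies,
      growth_rate = fold,
      stringsAsFactors = FALSE
    )
    structure(list(spec = spec, clones = clones, labels = labels),
              class = "synthetic_cohort")
  })
}

#' Pool all per-cell tables of a cohort
#'
#' @param cohort A \code{synthetic_cohort}.
#' @return One data.frame with all clones' cell records.
#' @export
cohort_cells <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$clones, `[[`, "cells"))
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d clones, potencies %d-%d, %d time points, %d FOVs/well\n",
              length(x$clones), min(x$labels$potency), max(x$labels$potency),
              length(x$spec$time_points), x$spec$n_fov))
  invisible(x)
}

#' Rendering parameters for synthetic phase-contrast frames
#'
#' Defaults emulate one 4x phase-contrast field of view: a 1000 x 1000 px frame
#' at 0.5 um/px (64 such frames tile a 16 mm^2 well, i.e. 0.25 mm^2 each), a
#' mid-grey background with mild vignetting and fine granularity, spread cells
#' drawn as textured ellipses with a bright halo rim, and proliferating cells
#' as small bright disks.
#'
#' @param image_size Frame size in pixels, length-2 (rows, cols) or scalar.
#' @param pixel_size Pixel size in um/px.
#' @param bg_level Background grey level in [0, 1].
#' @param vignette_amplitude Amplitude of the radial vignetting.
#' @param bg_noise_sd SD of the background granularity.
#' @param cell_fill_delta Spread-cell interior offset from background.
#' @param cell_texture_sd SD of intra-cell intensity texture.
#' @param rim_brightness Added brightness of the phase-halo rim.
#' @param round_brightness Grey level of proliferating (round) cells.
#' @param round_texture_sd SD of intensity texture inside round cells.
#' @param allow_border If TRUE cells may straddle the frame border (flagged in
#'   the ground truth); if FALSE all cells are placed fully interior.
#' @param max_place_tries Rejection-sampling attempts per cell before a
#'   density error is raised.
#' @return An object of class \code{render_spec}.
#' @export
render_spec <- function(image_size = c(1000, 1000), pixel_size = 0.5,
                        bg_level = 0.45, vignette_amplitude = 0.03,
                        bg_noise_sd = 0.01, cell_fill_delta = -0.05,
                        cell_texture_sd = 0.08, rim_brightness = 0.15,
                        round_brightness = 0.85, round_texture_sd = 0.05,
                        allow_border = TRUE, max_place_tries = 500) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (any(image_size < 64)) stopf("invalid render spec: 'image_size' must be >= 64 px")
  if (pixel_size <= 0) stopf("invalid render spec: 'pixel_size' must be positive")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 bg_level = bg_level, vignette_amplitude = vignette_amplitude,
                 bg_noise_sd = bg_noise_sd, cell_fill_delta = cell_fill_delta,
                 cell_texture_sd = cell_texture_sd, rim_brightness = rim_brightness,
                 round_brightness = round_brightness, round_texture_sd = round_texture_sd,
                 allow_border = allow_border, max_place_tries = max_place_tries),
            class = "render_spec")
}

#' Render one synthetic field of view with its ground truth
#'
#' Rasterises the cells of one clone / time point / FOV into a grayscale
#' phase-contrast-like frame together with a labelled ground-truth mask.
#' Spread cells are ellipses (axes derived from each cell's Area and
#' AspectRatio) with interior texture and a bright rim; proliferating cells
#' are bright disks. Placement is non-overlapping rejection sampling;
#' rendering is deterministic given the seed.
#'
#' @param clone A \code{synthetic_clone}.
#' @param time_point Time point in hours; must exist in the clone's table.
#' @param fov_index FOV number (1-based) whose cells are rendered.
#' @param render A [render_spec()].
#' @param seed Integer seed; defaults to a seed derived from the clone's own
#'   seed, the time point and the FOV index.
#' @return A list with \code{frame} (an [image_frame()]), \code{mask} (integer
#'   label matrix, 0 = background), and \code{truth} (data.frame with
#'   \code{cell_id}, \code{label}, \code{x}, \code{y}, \code{area_px},
#'   \code{proliferating}, \code{border_touching}).
#' @export
render_frame <- function(clone, time_point, fov_index, render = render_spec(),
                         seed = NULL) {
  if (!time_point %in% clone$cells$time_h)
    stopf("time point %s h not present in clone '%s'", time_point, clone$clone_id)
  if (is.null(seed)) seed <- derive_seed(clone$seed, round(time_point * 10), fov_index)
  cells <- clone$cells[clone$cells$time_h == time_point &
                         clone$cells$fov == fov_index, , drop = FALSE]
  h <- render$image_size[1]; w <- render$image_size[2]

  with_seed(seed, {
    # background with vignetting + granularity
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    rad2 <- ((rr - (h + 1) / 2) / (h / 2))^2 + ((cc - (w + 1) / 2) / (w / 2))^2
    img <- render$bg_level - render$vignette_amplitude * (rad2 - 0.5) +
      matrix(stats::rnorm(h * w, 0, render$bg_noise_sd), h, w)
    mask <- matrix(0L, h, w)
    truth <- data.frame(cell_id = integer(), label = integer(), x = numeric(),
                        y = numeric(), area_px = integer(),
                        proliferating = logical(), border_touching = logical())
    if (nrow(cells) == 0) {
      return(list(frame = image_frame(pmin(pmax(img, 0), 1), clone$clone_id,
                                      fov_index, time_point, render$pixel_size),
                  mask = mask, truth = truth))
    }

    area_px <- pmax(cells$Area, 50) / render$pixel_size^2
    ar <- pmin(pmax(cells$AspectRatio, 1), 6)
    is_round <- cells$proliferating
    bsemi <- sqrt(area_px / (pi * ar))
    asemi <- ar * bsemi
    asemi[is_round] <- bsemi[is_round] <- pmax(sqrt(area_px[is_round] / pi), 4)
    theta <- stats::runif(nrow(cells), 0, pi)

    # non-overlapping placement
    cx <- cy <- numeric(nrow(cells))
    reach <- asemi + 2
    for (i in seq_len(nrow(cells))) {
      lo_r <- if (render$allow_border) 1 else reach[i] + 1
      hi_r <- if (render$allow_border) h else h - reach[i] - 1
      lo_c <- if (render$allow_border) 1 else reach[i] + 1
      hi_c <- if (render$allow_border) w else w - reach[i] - 1
      if (hi_r <= lo_r || hi_c <= lo_c)
        stopf("cell %d too large for the frame at the requested density", i)
      ok <- FALSE
      for (try in seq_len(render$max_place_tries)) {
        y0 <- stats::runif(1, lo_r, hi_r); x0 <- stats::runif(1, lo_c, hi_c)
        if (i == 1 || all(sqrt((cx[seq_len(i - 1)] - x0)^2 +
                               (cy[seq_len(i - 1)] - y0)^2) >
                          reach[i] + reach[seq_len(i - 1)])) {
          cx[i] <- x0; cy[i] <- y0; ok <- TRUE; break
        }
      }
      if (!ok) stopf("could not place %d cells without overlap: density too high for %dx%d frame",
                     nrow(cells), h, w)
    }

    for (i in seq_len(nrow(cells))) {
      r0 <- max(1L, floor(cy[i] - reach[i])); r1 <- min(h, ceiling(cy[i] + reach[i]))
      c0 <- max(1L, floor(cx[i] - reach[i])); c1 <- min(w, ceiling(cx[i] + reach[i]))
      sub_r <- r0:r1; sub_c <- c0:c1
      dy <- matrix(sub_r - cy[i], length(sub_r), length(sub_c))
      dx <- matrix(sub_c - cx[i], length(sub_r), length(sub_c), byrow = TRUE)
      u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / asemi[i]
      v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / bsemi[i]
      m2 <- u^2 + v^2
      inside <- m2 <= 1
      npx <- sum(inside)
      if (npx == 0) next
      if (is_round[i]) {
        vals <- render$round_brightness +
          stats::rnorm(npx, 0, render$round_texture_sd)
      } else {
        vals <- render$bg_level + render$cell_fill_delta +
          stats::rnorm(npx, 0, render$cell_texture_sd)
        vals[m2[inside] > 0.72] <- vals[m2[inside] > 0.72] + render$rim_brightness
      }
      block_i <- img[sub_r, sub_c]; block_m <- mask[sub_r, sub_c]
      block_i[inside] <- vals
      block_m[inside] <- i
      img[sub_r, sub_c] <- block_i
      mask[sub_r, sub_c] <- block_m
    }

    border <- vapply(seq_len(nrow(cells)), function(i) {
      any(mask[1, ] == i) || any(mask[h, ] == i) ||
        any(mask[, 1] == i) || any(mask[, w] == i)
    }, logical(1))
    truth <- data.frame(cell_id = cells$cell_id, label = seq_len(nrow(cells)),
                        x = cx, y = cy,
                        area_px = as.integer(tabulate(mask[mask > 0], nrow(cells))),
                        proliferating = is_round, border_touching = border)
    list(frame = image_frame(pmin(pmax(img, 0), 1), clone$clone_id, fov_index,
                             time_point, render$pixel_size),
         mask = mask, truth = truth)
  })
}

#' Write a cohort to delimited files
#'
#' Writes one per-clone cell table (\code{<clone>_cells.csv}), a labels table
#' (\code{labels.csv}: clone_id, potency, growth_rate) and a JSON sidecar
#' echoing the generating spec and seed. Optionally renders and writes 16-bit
#' grayscale TIFF frames named \code{<clone>_t<HH>_fov<NN>.tif} (requires the
#' \pkg{tiff} package).
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if missing).
#' @param render NULL (no images) or a [render_spec()].
#' @param render_fovs,render_times FOV indices / time points to render when
#'   \code{render} is given (defaults: FOV 1, first time point).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, render = NULL,
                         render_fovs = 1, render_times = cohort$spec$time_points[1]) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in cohort$clones)
    utils::write.csv(cl$cells, file.path(dir, paste0(cl$clone_id, "_cells.csv")),
                     row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  spec <- cohort$spec
  sidecar <- c(
    sprintf('"n_clones": %d', spec$n_clones),
    sprintf('"potency_range": [%d, %d]', spec$potency_range[1], spec$potency_range[2]),
    sprintf('"time_points": [%s]', paste(spec$time_points, collapse = ", ")),
    sprintf('"n_fov": %d', spec$n_fov),
    sprintf('"noise_sd": %g', spec$noise_sd),
    sprintf('"growth_potency_r2_target": %g', spec$growth_potency_r2_target),
    sprintf('"seed": %d', spec$seed)
  )
  writeLines(paste0("{\n  ", paste(sidecar, collapse = ",\n  "), "\n}"),
             file.path(dir, "cohort_spec.json"))
  if (!is.null(render)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("writing rendered frames requires the 'tiff' package")
    for (cl in cohort$clones) for (tp in render_times) for (fv in render_fovs) {
      fr <- render_frame(cl, tp, fv, render)
      tiff::writeTIFF(fr$frame$intensity,
                      file.path(dir, sprintf("%s_t%02d_fov%02d.tif", cl$clone_id, tp, fv)),
                      bits.per.sample = 16)
    }
  }
  invisible(dir)
}
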