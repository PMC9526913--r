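# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The default study-condition cohort: 15 clones, potencies 7-13, 6-90 h,
# 64 FOVs, calibrated coupling and noise.
default_cohort <- function() cached("default_cohort", {
  generate_cohort(cohort_spec(seed = 1))
})

default_dataset <- function() cached("default_dataset", {
  co <- default_cohort()
  profile_dataset(cohort_profiles(co), co$labels)
})

# A light cohort for structural tests: 6 clones, 3 time points, 8 FOVs.
small_cohort <- function() cached("small_cohort", {
  generate_cohort(cohort_spec(n_clones = 6, cells_per_well_range = c(60, 2000),
                              time_points = c(6, 12, 18), n_fov = 8, seed = 7))
})

# A sparse image-tier cohort: few cells per FOV so frames render cleanly.
render_cohort <- function() cached("render_cohort", {
  generate_cohort(cohort_spec(n_clones = 2, cells_per_well_range = c(40, 800),
                              time_points = c(6, 12), n_fov = 8, seed = 5))
})

# ---- binary shape builders (row, col conventions as in masks) ----

disk_mask <- function(r, size = 2 * r + 21, cx = (size + 1) / 2, cy = cx) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  matrix(as.integer((rr - cy)^2 + (cc - cx)^2 <= r^2), size, size)
}

square_mask <- function(side, size = side + 20, at = 11) {
  m <- matrix(0L, size, size)
  m[at:(at + side - 1), at:(at + side - 1)] <- 1L
  m
}

annulus_mask <- function(r_out, r_in, size = 2 * r_out + 21) {
  c0 <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size); cc <- t(rr)
  d2 <- (rr - c0)^2 + (cc - c0)^2
  matrix(as.integer(d2 <= r_out^2 & d2 >= r_in^2), size, size)
}

# Wrap a matrix as a frame, padding to the 64-px minimum if needed.
as_frame <- function(intensity, pixel_size = 0.5, time_h = 6) {
  if (any(dim(intensity) < 64)) {
    out <- matrix(0, max(64, nrow(intensity)), max(64, ncol(intensity)))
    out[seq_len(nrow(intensity)), seq_len(ncol(intensity))] <- intensity
    intensity <- out
  }
  image_frame(intensity, clone_id = "fixture", fov_index = 1L,
              time_h = time_h, pixel_size = pixel_size)
}

pad_mask <- function(mask) {
  if (all(dim(mask) >= 64)) return(mask)
  out <- matrix(0L, max(64, nrow(mask)), max(64, ncol(mask)))
  out[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  out
}

# ---- independent oracles ----

# O(n^2)-style brute-force GLCM: enumerate every in-mask pixel pair at the
# offset, count symmetrically, normalise.
glcm_oracle <- function(patch, mask, offset, gray_levels) {
  vals <- patch[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(patch), ncol(patch))
  q[mask] <- if (diff(rng) == 0) 0L else
    pmin(as.integer(floor((patch[mask] - rng[1]) / diff(rng) * gray_levels)),
         gray_levels - 1L)
  P <- matrix(0, gray_levels, gray_levels)
  for (r in seq_len(nrow(patch))) for (c in seq_len(ncol(patch))) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nrow(patch) || c2 < 1 || c2 > ncol(patch)) next
    if (is.na(q[r, c]) || is.na(q[r2, c2])) next
    i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  P / sum(P)
}

glcm_oracle_features <- function(P) {
  lev <- seq_len(nrow(P)) - 1
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(lev * pi_m); mu_j <- sum(lev * pj_m)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_m)); sd_j <- sqrt(sum((lev - mu_j)^2 * pj_m))
  list(Energy = sum(P^2),
       Correlation = sum(outer(lev - mu_i, lev - mu_j) * P) / (sd_i * sd_j))
}

# Flood-fill from the border: pixels not reachable from outside the object
# belong to the filled object (the hole-filling oracle).
flood_fill_area_oracle <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  outside <- matrix(FALSE, h, w)
  queue <- cbind(c(rep(1, w), rep(h, w), seq_len(h), seq_len(h)),
                 c(seq_len(w), seq_len(w), rep(1, h), rep(w, h)))
  queue <- queue[bin[queue] == 0, , drop = FALSE]
  outside[queue] <- TRUE
  queue <- split(queue, seq_len(nrow(queue)))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r < 1 || r > h || c < 1 || c > w) next
      if (!outside[r, c] && bin[r, c] == 0) {
        outside[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  sum(!outside)
}

# Ordinary least squares by the normal equations.
ols_oracle <- function(x, y) {
  xx <- cbind(1, x)
  as.numeric(solve(t(xx) %*% xx, t(xx) %*% y))
}

# Build a minimal cohort_dataset from raw pieces.
toy_dataset <- function(x, y, clone = paste0("c", seq_along(y)),
                        replicate = rep(0L, length(y))) {
  colnames(x) <- colnames(x) %||% paste0("p", seq_len(ncol(x)))
  structure(list(x = x, y = y, clone = clone, replicate = replicate,
                 parameter_names = colnames(x)),
            class = "cohort_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmse_of <- function(truth, pred) sqrt(mean((truth - pred)^2))
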