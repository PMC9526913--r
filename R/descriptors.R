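#' GLCM parameters
#'
#' Gray-level co-occurrence settings for the texture descriptors. Intensities
#' inside the cell region are quantised to \code{gray_levels} equal-width bins
#' over the patch's own min--max range; co-occurrences are counted at the
#' given pixel offsets, symmetrised, normalised, and the normalised matrices
#' averaged over offsets before computing features.
#'
#' @param gray_levels Number of quantisation levels (>= 2, default 32).
#' @param offsets Matrix of (row, col) pixel displacements, one per row.
#'   Default: distance 1 at 0, 45, 90 and 135 degrees.
#' @param symmetric Count each pair in both directions (default TRUE).
#' @return An object of class \code{glcm_params}.
#' @export
glcm_params <- function(gray_levels = 32,
                        offsets = rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                        symmetric = TRUE) {
  if (gray_levels < 2) stopf("'gray_levels' must be >= 2")
  offsets <- rbind(offsets)
  if (nrow(offsets) < 1 || ncol(offsets) != 2)
    stopf("'offsets' must be a matrix with columns (row, col) and >= 1 row")
  structure(list(gray_levels = as.integer(gray_levels), offsets = offsets,
                 symmetric = isTRUE(symmetric)), class = "glcm_params")
}

# Quantise intensities to 0..(G-1) over their own min-max range.
quantize_gray <- function(vals, gray_levels) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rep(0L, length(vals)))
  pmin(as.integer(floor((vals - rng[1]) / diff(rng) * gray_levels)),
       gray_levels - 1L)
}

# Accumulate the co-occurrence matrix for one offset over in-mask pixel pairs.
glcm_accumulate <- function(q, inmask, offset, gray_levels) {
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1, 1 - dr); r1 <- min(h, h - dr)
  c0 <- max(1, 1 - dc); c1 <- min(w, w - dc)
  if (r1 < r0 || c1 < c0) return(matrix(0, gray_levels, gray_levels))
  a_ok <- inmask[r0:r1, c0:c1, drop = FALSE]
  b_ok <- inmask[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  ok <- a_ok & b_ok
  i <- q[r0:r1, c0:c1, drop = FALSE][ok]
  j <- q[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE][ok]
  if (!length(i)) return(matrix(0, gray_levels, gray_levels))
  m <- matrix(0, gray_levels, gray_levels)
  tab <- table(factor(i, levels = 0:(gray_levels - 1)),
               factor(j, levels = 0:(gray_levels - 1)))
  m + as.matrix(tab)
}

#' GLCM texture features of a masked intensity patch
#'
#' Computes the two texture descriptors on the normalised co-occurrence
#' matrix P averaged over offsets:
#' Energy = sum(P^2) and
#' Correlation = sum((i - mu_i)(j - mu_j) P) / (sd_i sd_j),
#' where mu/sd are the marginal means/SDs of P. A patch with zero intensity
#' variance (a single occupied co-occurrence cell) has Energy 1; a degenerate
#' marginal yields Correlation 0, flagged.
#'
#' @param patch Numeric intensity matrix.
#' @param mask Logical matrix of in-region pixels (default: all).
#' @param glcm A [glcm_params()].
#' @return Named list: \code{Correlation}, \code{Energy}, \code{degenerate}.
#' @export
glcm_features <- function(patch, mask = NULL, glcm = glcm_params()) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  stopifnot(all(dim(mask) == dim(patch)))
  G <- glcm$gray_levels
  qfull <- matrix(0L, nrow(patch), ncol(patch))
  qfull[mask] <- quantize_gray(patch[mask], G)
  total <- matrix(0, G, G)
  n_off <- 0
  for (k in seq_len(nrow(glcm$offsets))) {
    m <- glcm_accumulate(qfull, mask, glcm$offsets[k, ], G)
    if (glcm$symmetric) m <- m + t(m)
    s <- sum(m)
    if (s > 0) {
      total <- total + m / s
      n_off <- n_off + 1
    }
  }
  if (n_off == 0)
    return(list(Correlation = 0, Energy = 1, degenerate = TRUE))
  P <- total / n_off
  energy <- sum(P^2)
  lev <- 0:(G - 1)
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(lev * pi_m); mu_j <- sum(lev * pj_m)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((lev - mu_j)^2 * pj_m))
  if (sd_i == 0 || sd_j == 0)
    return(list(Correlation = 0, Energy = energy, degenerate = TRUE))
  corr <- sum(outer(lev - mu_i, lev - mu_j) * P) / (sd_i * sd_j)
  list(Correlation = corr, Energy = energy, degenerate = FALSE)
}

# Perimeter from the ordered boundary contour, with the classical corrected
# step weights (0.948 per isothetic step, 1.340 per diagonal step) that make
# digital-circle perimeters accurate to ~1%.
region_perimeter_px <- function(bin) {
  oc <- EBImage::ocontour(EBImage::Image(bin))
  if (!length(oc)) return(0)
  sum(vapply(oc, function(p) {
    if (nrow(p) < 2) return(4 * 0.948)  # isolated pixel: unit-square boundary
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    step <- sqrt(rowSums((p - nxt)^2))
    sum(ifelse(step <= 1 + 1e-9, 0.948 * step, 1.340 * step / sqrt(2)))
  }, numeric(1)))
}

# Convex hull area of a pixel set, using all four pixel corners so a filled
# rectangle has hull area exactly equal to its pixel count.
convex_hull_area_px <- function(rows, cols) {
  corners <- cbind(c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
                   c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5))
  h <- grDevices::chull(corners)
  pts <- corners[h, , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(length(rows))
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Measure the 12 morphological descriptors of one cell region
#'
#' Shape descriptors are computed on the binary region: Area (pixel count x
#' pixel_size^2, um^2), Perimeter (corrected boundary-chain length, um),
#' Length/Breadth (major/minor axis of the moment-equivalent ellipse, um),
#' AspectRatio = Length/Breadth, Compactness = Perimeter^2 / (4 pi Area)
#' (1 for a disk), Roundness = its reciprocal, Solidity = Area / convex hull
#' area. Intensity and texture descriptors use the masked intensity patch:
#' IntensityMean, IntensitySD (sample SD), and the GLCM Correlation and
#' Energy. Regions of one pixel or zero intensity variance get the degenerate
#' texture values Energy = 1, Correlation = 0 and are flagged.
#'
#' @param frame An [image_frame()].
#' @param mask Integer label matrix aligned with the frame.
#' @param label Label id present in the mask.
#' @param glcm A [glcm_params()].
#' @return One-row data.frame: provenance columns, \code{area_px}, the 12
#'   descriptors, and a \code{degenerate} flag.
#' @export
measure_cell <- function(frame, mask, label, glcm = glcm_params()) {
  stopifnot(inherits(frame, "image_frame"))
  if (!any(mask == label)) stopf("label %s not present in mask", label)
  px <- frame$pixel_size
  bin <- matrix(0L, nrow(mask), ncol(mask))
  bin[mask == label] <- 1L
  idx <- which(bin == 1L, arr.ind = TRUE)
  area_px <- nrow(idx)
  area <- area_px * px^2
  perim <- region_perimeter_px(bin) * px

  mom <- EBImage::computeFeatures.moment(bin, frame$intensity)
  length_um <- mom[1, "m.majoraxis"] * px
  ecc <- mom[1, "m.eccentricity"]
  breadth_um <- length_um * sqrt(max(1 - ecc^2, 0))
  if (breadth_um == 0) breadth_um <- px  # 1-px-wide line: one pixel of breadth
  aspect <- length_um / breadth_um
  compact <- if (area > 0 && perim > 0) perim^2 / (4 * pi * area) else NA_real_
  roundness <- 1 / compact
  solidity <- min(area_px / convex_hull_area_px(idx[, 1], idx[, 2]), 1)

  vals <- frame$intensity[bin == 1L]
  imean <- mean(vals)
  isd <- if (area_px > 1) sample_sd(vals) else 0
  degenerate <- area_px < 2 || isd == 0
  if (degenerate) {
    tex <- list(Correlation = 0, Energy = 1, degenerate = TRUE)
  } else {
    tex <- glcm_features(frame$intensity, bin == 1L, glcm)
    degenerate <- tex$degenerate
  }

  data.frame(clone_id = frame$clone_id, time_h = frame$time_h,
             fov = frame$fov_index, cell_id = as.integer(label),
             area_px = area_px,
             Area = area, Perimeter = perim, Length = length_um,
             Breadth = breadth_um, AspectRatio = aspect,
             Compactness = compact, Roundness = roundness,
             Solidity = solidity, IntensityMean = imean, IntensitySD = isd,
             Correlation = tex$Correlation, Energy = tex$Energy,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Measure every cell in a frame
#'
#' @param frame An [image_frame()].
#' @param mask Integer label matrix aligned with the frame (labels 1..n).
#' @param glcm A [glcm_params()].
#' @return data.frame with one row per label, in label order (zero rows for an
#'   empty mask).
#' @export
measure_frame <- function(frame, mask, glcm = glcm_params()) {
  stopifnot(inherits(frame, "image_frame"))
  if (!all(dim(mask) == dim(frame$intensity)))
    stopf("mask shape %s does not match frame shape %s",
          paste(dim(mask), collapse = "x"),
          paste(dim(frame$intensity), collapse = "x"))
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    out <- measure_cell_template()
    return(out)
  }
  do.call(rbind, lapply(labs, function(l) measure_cell(frame, mask, l, glcm)))
}

measure_cell_template <- function() {
  data.frame(clone_id = character(), time_h = numeric(), fov = integer(),
             cell_id = integer(), area_px = integer(), Area = numeric(),
             Perimeter = numeric(), Length = numeric(), Breadth = numeric(),
             AspectRatio = numeric(), Compactness = numeric(),
             Roundness = numeric(), Solidity = numeric(),
             IntensityMean = numeric(), IntensitySD = numeric(),
             Correlation = numeric(), Energy = numeric(),
             degenerate = logical(), stringsAsFactors = FALSE)
}
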