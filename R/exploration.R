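#' Kernel density estimate of the log10 cell-area distribution
#'
#' Gaussian KDE of log10(area_px) over cells whose pixel area exceeds
#' \code{min_area_px} (200 px by default: smaller objects are mostly round
#' proliferating cells, which would blur the spread-cell size discussion).
#' Bandwidth follows Silverman's rule on the log10 data; the grid spans the
#' data range plus 3 bandwidths with 512 points. The median area of the
#' surviving cells is reported in um^2 alongside.
#'
#' @param records data.frame with an \code{area_px} column.
#' @param min_area_px Pixel-area filter (exclusive, default 200).
#' @param pixel_size um/px used for the um^2 median (default 0.5).
#' @return An object of class \code{density_estimate}: list with \code{grid},
#'   \code{density}, \code{bandwidth}, \code{n_used}, \code{n_filtered},
#'   \code{min_area_px}, \code{median_area_um2}.
#' @export
kde_log_area <- function(records, min_area_px = 200, pixel_size = 0.5) {
  if (is.null(records$area_px)) {
    if (is.null(records$Area)) stopf("records need an 'area_px' (or 'Area') column")
    records$area_px <- records$Area / pixel_size^2
  }
  keep <- records$area_px > min_area_px
  n_used <- sum(keep)
  if (n_used == 0)
    stopf("empty population: all %d record(s) at or below the %d px area filter",
          nrow(records), min_area_px)
  if (n_used < 10)
    stopf("insufficient population: only %d record(s) above the area filter; need >= 10",
          n_used)
  la <- log10(records$area_px[keep])
  d <- stats::density(la, bw = "nrd0", n = 512, cut = 3)
  structure(list(grid = d$x, density = d$y, bandwidth = d$bw,
                 n_used = n_used, n_filtered = nrow(records) - n_used,
                 min_area_px = min_area_px,
                 median_area_um2 = stats::median(records$area_px[keep]) * pixel_size^2),
            class = "density_estimate")
}

#' PCA of morphological profiles
#'
#' Standardises the parameters (z-score; constant columns are dropped with a
#' warning) and decomposes with [stats::prcomp()]. The component sign
#' convention fixes the largest-magnitude loading of each component to be
#' positive, so identical inputs give identical scores. The returned object
#' can project further profiles onto the fixed axes via [project_profiles()]
#' (used to overlay per-FOV-usage subsets, or bootstrap replicate clouds, on
#' components fitted to the merged data).
#'
#' @param x Numeric matrix, rows = profiles, columns = named parameters (or a
#'   \code{cohort_dataset}, whose \code{x} is used).
#' @return An object of class \code{pca_result}: \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions, non-increasing),
#'   \code{center}, \code{scale}, \code{dropped} (constant columns).
#' @export
pca_profiles <- function(x) {
  if (inherits(x, "cohort_dataset")) x <- x$x
  if (nrow(x) < 3) stopf("need >= 3 profiles for PCA")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant parameter column(s)", length(dropped)))
    x <- x[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive in every component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x, loadings = p$rotation,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 center = p$center, scale = p$scale, dropped = dropped),
            class = "pca_result")
}

#' Project profiles onto fixed PCA axes
#'
#' @param pca A \code{pca_result}.
#' @param x Matrix of profiles sharing the parameter columns the PCA was
#'   fitted on.
#' @return Score matrix on the fitted components.
#' @export
project_profiles <- function(pca, x) {
  if (inherits(x, "cohort_dataset")) x <- x$x
  x <- x[, rownames(pca$loadings), drop = FALSE]
  scale(x, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Coefficient of determination between a per-clone scalar and potency
#'
#' Squared Pearson correlation, as used to show that growth rate alone cannot
#' predict serial-passage potency.
#'
#' @param x Per-clone scalar (e.g. growth rate).
#' @param y Per-clone potency.
#' @return R^2 in [0, 1].
#' @export
scalar_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("need >= 3 paired clone values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("undefined R^2: zero variance in x or y")
  stats::cor(x, y)^2
}

#' Two-sample comparison of a descriptor between cohorts
#'
#' Student's t-test (equal-variance) on one descriptor between two groups of
#' cell records.
#'
#' @param a,b data.frames of cell records.
#' @param descriptor Descriptor column name.
#' @param var_equal Use the classical equal-variance statistic (default TRUE).
#' @return List with \code{statistic}, \code{p_value}, \code{df},
#'   \code{mean_a}, \code{mean_b}.
#' @export
compare_distributions <- function(a, b, descriptor, var_equal = TRUE) {
  va <- a[[descriptor]]; vb <- b[[descriptor]]
  if (is.null(va) || is.null(vb)) stopf("descriptor '%s' not found in both groups", descriptor)
  if (length(va) < 2 || length(vb) < 2) stopf("each group needs >= 2 records")
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    if (mean(va) == mean(vb))
      return(list(statistic = 0, p_value = 1, df = length(va) + length(vb) - 2,
                  mean_a = mean(va), mean_b = mean(vb)))
    stopf("undefined test: zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(va, vb, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(va), mean_b = mean(vb))
}
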