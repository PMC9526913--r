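#' An acquired phase-contrast frame
#'
#' Container for one field of view: a grayscale intensity grid plus
#' acquisition metadata. Intensities must be finite; the frame at least
#' 64 x 64 px; the time point a positive multiple of the 6-h acquisition
#' interval.
#'
#' @param intensity Numeric matrix (rows x cols) of grayscale intensities.
#' @param clone_id Clone identifier.
#' @param fov_index Field-of-view index.
#' @param time_h Hours post-seeding (multiple of 6).
#' @param pixel_size Pixel size in um/px.
#' @return An object of class \code{image_frame}.
#' @export
image_frame <- function(intensity, clone_id = NA_character_, fov_index = NA_integer_,
                        time_h = 6, pixel_size = 0.5) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stopf("'intensity' must be a numeric matrix")
  if (any(dim(intensity) < 64)) stopf("frame dimensions must be >= 64 x 64 px")
  if (any(!is.finite(intensity))) stopf("frame intensities must all be finite")
  if (!is.finite(time_h) || time_h <= 0 || time_h %% 6 != 0)
    stopf("'time_h' must be a positive multiple of 6 h")
  if (pixel_size <= 0) stopf("'pixel_size' must be positive")
  structure(list(intensity = intensity, clone_id = clone_id,
                 fov_index = fov_index, time_h = time_h,
                 pixel_size = pixel_size), class = "image_frame")
}

#' Read a grayscale frame from TIFF or PNG
#'
#' Reads an 8/16-bit grayscale image (first channel of multi-channel files)
#' into an [image_frame()].
#'
#' @param path File path (.tif/.tiff/.png).
#' @inheritParams image_frame
#' @return An \code{image_frame}.
#' @export
read_frame <- function(path, clone_id = NA_character_, fov_index = NA_integer_,
                       time_h = 6, pixel_size = 0.5) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    png = png::readPNG(path),
    stopf("unsupported image format '%s'", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  image_frame(img, clone_id, fov_index, time_h, pixel_size)
}

#' Segmentation pipeline parameters
#'
#' Parameters of the eight-step pipeline (see [segment_frame()]). Exact
#' operator settings are configuration, not fixed constants: any published or
#' tuned value can be substituted.
#'
#' @param background_kernel_px Side of the local-median window used for
#'   background adjustment (odd, default 101).
#' @param texture_window_px Side of the local-SD window used for texture
#'   enhancement (odd, default 7).
#' @param threshold_method Currently \code{"otsu"}.
#' @param threshold_offset Additive offset on the threshold (on the
#'   0--1-normalised enhanced image).
#' @param min_object_area_px Minimum object area for the first small-object
#'   removal (step 4), default 64 px.
#' @param min_object_area_px2 Minimum area for the second removal (step 6);
#'   defaults to \code{min_object_area_px}.
#' @param erosion_radius_px Radius of the disc structuring element (step 5).
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(background_kernel_px = 101,
                                texture_window_px = 7,
                                threshold_method = "otsu",
                                threshold_offset = 0,
                                min_object_area_px = 64,
                                min_object_area_px2 = min_object_area_px,
                                erosion_radius_px = 1) {
  if (background_kernel_px < 3 || texture_window_px < 3)
    stopf("kernel/window sizes must be >= 3 px")
  if (min_object_area_px < 1 || min_object_area_px2 < 1)
    stopf("'min_object_area_px' must be >= 1")
  if (erosion_radius_px < 0) stopf("'erosion_radius_px' must be >= 0")
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(list(background_kernel_px = as.integer(background_kernel_px),
                 texture_window_px = as.integer(texture_window_px),
                 threshold_method = threshold_method,
                 threshold_offset = threshold_offset,
                 min_object_area_px = as.integer(min_object_area_px),
                 min_object_area_px2 = as.integer(min_object_area_px2),
                 erosion_radius_px = as.integer(erosion_radius_px)),
            class = "segmentation_params")
}

# Relabel a label matrix so surviving labels are consecutive 1..n, preserving
# the original label order.
relabel_consecutive <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) return(mask)
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- mask
  out[out > 0] <- lut[out[out > 0]]
  out
}

# Local standard deviation via box-mean filters of x and x^2.
local_sd <- function(x, window) {
  k <- matrix(1 / (window * window), window, window)
  m <- as.matrix(EBImage::imageData(EBImage::filter2(x, k, boundary = "replicate")))
  m2 <- as.matrix(EBImage::imageData(EBImage::filter2(x * x, k, boundary = "replicate")))
  matrix(sqrt(pmax(m2 - m * m, 0)), nrow(x), ncol(x))
}

#' Segment a phase-contrast frame into labelled cell regions
#'
#' Eight sequential processes: (1) background adjustment — subtraction of a
#' large-window local median; (2) texture enhancement — local-SD filtering,
#' which turns the textured, halo-rimmed cells bright against the flat
#' background; (3) binarisation — Otsu threshold on the enhanced image;
#' (4) removal of small objects; (5) erosion with a disc; (6) removal of small
#' objects again; (7) hole filling; (8) removal of frame-touching objects.
#' The pipeline contains no randomness: the same frame and parameters always
#' give the identical mask.
#'
#' @param frame An [image_frame()].
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background, 1..n cells, 8-connectivity),
#'   with attribute \code{provenance} recording the frame metadata.
#' @export
segment_frame <- function(frame, params = segmentation_params()) {
  stopifnot(inherits(frame, "image_frame"))
  img <- frame$intensity
  if (diff(range(img)) == 0) {
    warning("degenerate frame (constant intensity): returning empty mask")
    return(empty_mask(img, frame))
  }
  img <- (img - min(img)) / diff(range(img))
  # (1) background adjustment
  bg <- EBImage::medianFilter(EBImage::Image(img),
                              size = max(1L, params$background_kernel_px %/% 2L))
  adj <- img - as.matrix(EBImage::imageData(bg))
  # (2) texture enhancement
  enh <- local_sd(adj, params$texture_window_px)
  rng <- range(enh)
  if (diff(rng) == 0) {
    warning("degenerate frame (no local texture): returning empty mask")
    return(empty_mask(img, frame))
  }
  enh <- (enh - rng[1]) / diff(rng)
  # (3) binarisation
  th <- EBImage::otsu(EBImage::Image(enh), range = c(0, 1)) + params$threshold_offset
  bin <- enh > th
  mask <- EBImage::bwlabel(bin)
  mask <- matrix(as.integer(EBImage::imageData(mask)), nrow(img), ncol(img))
  # (4) removal of small objects
  mask <- remove_small_objects(mask, params$min_object_area_px)
  # (5) erosion
  if (params$erosion_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * params$erosion_radius_px + 1L, "disc")
    er <- EBImage::erode(mask > 0, brush)
    mask[!(er > 0)] <- 0L
    # erosion can split a component; relabel so labels stay connected
    mask <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask > 0))),
                   nrow(img), ncol(img))
  }
  # (6) removal of small objects
  mask <- remove_small_objects(mask, params$min_object_area_px2)
  # (7) fill hole
  mask <- fill_holes(mask)
  # (8) removal of frame-touching objects
  mask <- remove_border_touching(mask)
  attr(mask, "provenance") <- list(clone_id = frame$clone_id,
                                   fov_index = frame$fov_index,
                                   time_h = frame$time_h,
                                   pixel_size = frame$pixel_size,
                                   params = params)
  mask
}

empty_mask <- function(img, frame) {
  m <- matrix(0L, nrow(img), ncol(img))
  attr(m, "provenance") <- list(clone_id = frame$clone_id,
                                fov_index = frame$fov_index,
                                time_h = frame$time_h,
                                pixel_size = frame$pixel_size)
  m
}

#' Remove labelled objects below an area threshold
#'
#' Every surviving component has pixel area >= \code{min_area_px}; survivors
#' are relabelled consecutively 1..n (original order preserved). Idempotent.
#'
#' @param mask Integer label matrix.
#' @param min_area_px Minimum pixel area (>= 1).
#' @return Relabelled integer label matrix.
#' @export
remove_small_objects <- function(mask, min_area_px) {
  if (min_area_px < 1) stopf("'min_area_px' must be >= 1")
  if (!any(mask > 0)) return(mask)
  areas <- tabulate(mask[mask > 0])
  drop <- which(areas > 0 & areas < min_area_px)
  if (length(drop)) mask[mask %in% drop] <- 0L
  relabel_consecutive(mask)
}

#' Fill holes enclosed by labelled objects
#'
#' Background regions fully enclosed by a single label are filled with that
#' label; object areas are non-decreasing. Idempotent.
#'
#' @param mask Integer label matrix.
#' @return Integer label matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!any(mask > 0)) return(mask)
  out <- EBImage::fillHull(EBImage::Image(mask))
  m <- matrix(as.integer(EBImage::imageData(out)), nrow(mask), ncol(mask))
  attributes(m) <- attributes(mask)
  m
}

#' Remove objects touching the frame border
#'
#' Drops every label with a pixel on the outermost 1-px ring and relabels the
#' survivors consecutively. Idempotent.
#'
#' @param mask Integer label matrix.
#' @return Relabelled integer label matrix.
#' @export
remove_border_touching <- function(mask) {
  if (!any(mask > 0)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  edge <- unique(c(mask[1, ], mask[h, ], mask[, 1], mask[, w]))
  edge <- edge[edge > 0]
  if (length(edge)) mask[mask %in% edge] <- 0L
  relabel_consecutive(mask)
}

#' Number of labelled objects in a mask
#' @param mask Integer label matrix.
#' @return Integer count.
#' @export
n_objects <- function(mask) {
  if (!any(mask > 0)) return(0L)
  length(unique(mask[mask > 0]))
}

#' Match segmented objects to a ground-truth mask
#'
#' Greedily matches each ground-truth label to the segmented label of maximal
#' overlap and scores the match by intersection-over-union. Used to evaluate
#' segmentation recall/precision against rendered ground truth.
#'
#' @param segmented,truth_mask Integer label matrices of identical shape.
#' @param iou_min Minimum IoU for a match (default 0.5).
#' @return List with \code{matches} (data.frame truth_label, seg_label, iou),
#'   \code{recall} and \code{precision}.
#' @export
match_to_truth <- function(segmented, truth_mask, iou_min = 0.5) {
  stopifnot(all(dim(segmented) == dim(truth_mask)))
  tl <- sort(unique(truth_mask[truth_mask > 0]))
  sl <- sort(unique(segmented[segmented > 0]))
  rows <- lapply(tl, function(t) {
    tpix <- truth_mask == t
    cand <- segmented[tpix]
    cand <- cand[cand > 0]
    if (!length(cand)) return(data.frame(truth_label = t, seg_label = NA_integer_, iou = 0))
    s <- as.integer(names(which.max(table(cand))))
    inter <- sum(tpix & segmented == s)
    union <- sum(tpix | segmented == s)
    data.frame(truth_label = t, seg_label = s, iou = inter / union)
  })
  matches <- do.call(rbind, rows)
  hit <- matches[!is.na(matches$seg_label) & matches$iou >= iou_min, , drop = FALSE]
  hit <- hit[!duplicated(hit$seg_label), , drop = FALSE]
  list(matches = matches,
       recall = if (length(tl)) nrow(hit) / length(tl) else NA_real_,
       precision = if (length(sl)) nrow(hit) / length(sl) else NA_real_)
}
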