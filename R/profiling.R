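#' Population summary of per-cell descriptor records
#'
#' Pools all records (across FOVs — no per-FOV pre-averaging) and returns the
#' mean and sample SD (n - 1 denominator) of each of the 12 descriptors.
#' Records flagged degenerate are excluded before summarising.
#'
#' @param records data.frame of cell records with the 12 descriptor columns.
#' @return Named numeric vector of 24 values, \code{<Descriptor>_mean} and
#'   \code{<Descriptor>_SD} for each descriptor.
#' @export
summarize_population <- function(records) {
  if (!is.null(records$degenerate)) records <- records[!records$degenerate, , drop = FALSE]
  if (nrow(records) < 2) {
    who <- if (nrow(records) && !is.null(records$clone_id))
      sprintf(" (clone %s, %s h)", records$clone_id[1], records$time_h[1]) else ""
    stopf("insufficient population: %d usable cell record(s)%s; need >= 2 for SD",
          nrow(records), who)
  }
  desc <- descriptor_names()
  missing <- setdiff(desc, names(records))
  if (length(missing)) stopf("records lack descriptor column(s): %s",
                             paste(missing, collapse = ", "))
  out <- numeric(0)
  for (d in desc) {
    v <- records[[d]]
    out <- c(out, stats::setNames(c(mean(v), sample_sd(v)),
                                  paste0(d, c("_mean", "_SD"))))
  }
  out
}

#' Build a clone's morphological profile
#'
#' Accumulates the per-time-point population summaries into one named
#' parameter vector over the time window [6 h, \code{window_end_h}], using
#' only cells from the given FOVs. Parameter names follow
#' \code{"<Descriptor>_<mean|SD> (<T> h)"}, ordered time-major then descriptor
#' then statistic, so the full 15-point window yields 360 parameters and a
#' single time point 24.
#'
#' @param cells data.frame of cell records (columns \code{clone_id},
#'   \code{time_h}, \code{fov}, descriptors) for one clone.
#' @param window_end_h Last time point of the window (hours).
#' @param fov_ids FOV indices whose cells contribute; duplicated ids count
#'   their cells once here (use [bootstrap_profiles()] for multiset draws).
#' @param time_points Time grid expected within the window (default the 6-h
#'   grid up to \code{window_end_h}).
#' @return An object of class \code{morphological_profile}: list with
#'   \code{clone_id}, \code{replicate_id} (0 = raw), \code{values} (named
#'   vector), \code{window}, \code{fov_count}, \code{fov_ids}.
#' @export
build_profile <- function(cells, window_end_h, fov_ids,
                          time_points = NULL) {
  if (length(fov_ids) < 1) stopf("'fov_ids' must be a nonempty set of FOV indices")
  if (is.null(time_points)) time_points <- seq(6, window_end_h, by = 6)
  time_points <- time_points[time_points <= window_end_h]
  if (!length(time_points)) stopf("empty time window ending at %s h", window_end_h)
  sel <- cells[cells$fov %in% unique(fov_ids), , drop = FALSE]
  vals <- numeric(0)
  for (tp in time_points) {
    rec <- sel[sel$time_h == tp, , drop = FALSE]
    if (nrow(rec) == 0)
      stopf("missing time point: no cell records at %s h within the requested window", tp)
    s <- summarize_population(rec)
    names(s) <- paste0(names(s), " (", format(tp, trim = TRUE), " h)")
    vals <- c(vals, s)
  }
  structure(list(clone_id = cells$clone_id[1], replicate_id = 0L,
                 values = vals, window = c(start = 6, end = window_end_h),
                 fov_count = length(unique(fov_ids)),
                 fov_ids = unique(fov_ids)),
            class = "morphological_profile")
}

#' Randomly subsample FOV indices
#'
#' Uniform draw of k distinct FOVs without replacement, reproducible by seed.
#'
#' @param available Vector of available FOV indices.
#' @param k Number to draw (1 <= k <= length(available)).
#' @param seed Integer seed (NULL = current RNG state).
#' @return Vector of k distinct FOV indices.
#' @export
subsample_fovs <- function(available, k, seed = NULL) {
  if (k < 1 || k > length(available))
    stopf("'k' must be between 1 and %d", length(available))
  with_seed(seed, {
    if (k == length(available)) available
    else available[sample.int(length(available), k)]
  })
}

# Per-(fov, time, descriptor) sufficient statistics (count, sum, sum of
# squares) laid out as matrices indexed fov x (time, descriptor). Pooling
# these over a FOV multiset is exactly equivalent to summarising the
# concatenated records — a duplicated FOV contributes its cells once per
# occurrence — which makes 50-repeat bootstraps one matrix product per draw.
fov_sufficient_stats <- function(cells, available, time_points) {
  if (!is.null(cells$degenerate)) cells <- cells[!cells$degenerate, , drop = FALSE]
  desc <- descriptor_names()
  nf <- length(available); nt <- length(time_points); nd <- length(desc)
  fi <- match(cells$fov, available)
  ti <- match(cells$time_h, time_points)
  keep <- !is.na(fi) & !is.na(ti)
  cells <- cells[keep, , drop = FALSE]; fi <- fi[keep]; ti <- ti[keep]
  m <- as.matrix(cells[, desc, drop = FALSE])
  N <- matrix(0, nf, nt)
  S <- matrix(0, nf, nt * nd)
  SS <- matrix(0, nf, nt * nd)
  cnt <- table(factor(fi, levels = seq_len(nf)), factor(ti, levels = seq_len(nt)))
  N[] <- as.numeric(cnt)
  grp <- (ti - 1L) * nf + fi  # row index within a (fov, time) cell
  for (d in seq_len(nd)) {
    col0 <- (seq_len(nt) - 1L) * nd + d
    s <- rowsum(m[, d], grp)
    ss <- rowsum(m[, d]^2, grp)
    gi <- as.integer(rownames(s))
    fov_i <- (gi - 1L) %% nf + 1L
    tp_i <- (gi - 1L) %/% nf + 1L
    S[cbind(fov_i, col0[tp_i])] <- s
    SS[cbind(fov_i, col0[tp_i])] <- ss
  }
  list(N = N, S = S, SS = SS, nf = nf, nt = nt, nd = nd,
       time_points = time_points, desc = desc)
}

# Pooled 24-per-time-point summary for one FOV multiset (weights = draw
# multiplicities), in time-major, descriptor, mean-then-SD order.
pooled_profile_values <- function(suff, fov_weights) {
  n_tp <- as.numeric(fov_weights %*% suff$N)
  bad <- which(n_tp < 2)
  if (length(bad))
    stopf("insufficient population: %d cell record(s) at %s h for the drawn FOV set",
          n_tp[bad[1]], suff$time_points[bad[1]])
  s <- as.numeric(fov_weights %*% suff$S)
  ss <- as.numeric(fov_weights %*% suff$SS)
  nrep <- rep(n_tp, each = suff$nd)
  mu <- s / nrep
  sdv <- sqrt(pmax((ss - nrep * mu^2) / (nrep - 1), 0))
  vals <- as.numeric(rbind(mu, sdv))  # interleave mean, SD per descriptor
  names(vals) <- unlist(lapply(suff$time_points, function(tp)
    paste0(rep(suff$desc, each = 2), "_", c("mean", "SD"),
           " (", format(tp, trim = TRUE), " h)")))
  vals
}

#' Bootstrap FOV-resampled profiles for one clone
#'
#' Draws B FOV multisets of size k with replacement (overlaps allowed) from
#' the available FOVs and builds one profile per draw; duplicated FOVs
#' contribute their cells once per occurrence. With 15 clones and B = 50 this
#' expands a cohort from 15 to 750 samples.
#'
#' @param cells Cell records of one clone.
#' @param window_end_h Window end (hours).
#' @param k FOVs drawn per repeat (>= 1).
#' @param B Number of bootstrap repeats (>= 1).
#' @param seed Integer seed.
#' @param available Available FOV ids (default 1..64).
#' @param time_points Optional explicit time grid (see [build_profile()]).
#' @return List of B \code{morphological_profile}s with replicate_id 1..B.
#' @export
bootstrap_profiles <- function(cells, window_end_h, k, B, seed = NULL,
                               available = 1:64, time_points = NULL) {
  if (B < 1) stopf("'B' must be >= 1")
  if (k < 1) stopf("'k' must be >= 1")
  if (is.null(time_points)) time_points <- seq(6, window_end_h, by = 6)
  time_points <- time_points[time_points <= window_end_h]
  suff <- fov_sufficient_stats(cells, available, time_points)
  clone <- cells$clone_id[1]
  with_seed(seed, {
    lapply(seq_len(B), function(b) {
      draw <- available[sample.int(length(available), k, replace = TRUE)]
      w <- tabulate(match(draw, available), nbins = length(available))
      vals <- pooled_profile_values(suff, w)
      structure(list(clone_id = clone, replicate_id = b, values = vals,
                     window = c(start = 6, end = window_end_h),
                     fov_count = k, fov_ids = draw),
                class = "morphological_profile")
    })
  })
}

#' Fold-change growth rate over a time window
#'
#' @param counts Named numeric vector of cell counts, names = time points in
#'   hours (or a plain vector in time order).
#' @return count(end) / count(start).
#' @export
growth_rate <- function(counts) {
  if (length(counts) < 2) stopf("need counts at >= 2 time points")
  if (counts[1] <= 0) stopf("undefined growth rate: zero cell count at the first time point")
  as.numeric(counts[length(counts)] / counts[1])
}

#' Assemble profiles into a model-ready dataset
#'
#' Binds profiles (rows) into a parameter matrix with aligned names, joined to
#' clone labels. All profiles must share the identical parameter name vector.
#'
#' @param profiles List of \code{morphological_profile}s.
#' @param labels data.frame with \code{clone_id} and \code{potency} (and
#'   optionally \code{growth_rate}).
#' @return An object of class \code{cohort_dataset}: list with \code{x}
#'   (matrix, rows = profiles), \code{y} (potency per row), \code{clone}
#'   (clone id per row), \code{replicate} (replicate id per row),
#'   \code{parameter_names}.
#' @export
profile_dataset <- function(profiles, labels) {
  stopifnot(length(profiles) >= 1)
  pn <- names(profiles[[1]]$values)
  for (p in profiles)
    if (!identical(names(p$values), pn))
      stopf("profiles do not share an identical parameter name vector")
  x <- do.call(rbind, lapply(profiles, function(p) p$values))
  rownames(x) <- NULL
  clone <- vapply(profiles, `[[`, "", "clone_id")
  if (anyDuplicated(labels$clone_id)) stopf("labels must contain one row per clone")
  ix <- match(clone, labels$clone_id)
  if (any(is.na(ix))) stopf("missing label for clone(s): %s",
                            paste(unique(clone[is.na(ix)]), collapse = ", "))
  structure(list(x = x, y = labels$potency[ix], clone = clone,
                 replicate = vapply(profiles, `[[`, 0L, "replicate_id"),
                 parameter_names = pn),
            class = "cohort_dataset")
}

#' Raw (all-FOV or subsampled) profiles for every clone of a cohort
#'
#' Convenience wrapper: builds one replicate-0 profile per clone from the
#' given FOV set and window.
#'
#' @param cohort A \code{synthetic_cohort} (or any list of clones with
#'   \code{cells}).
#' @param window_end_h Window end (hours).
#' @param fov_ids FOV ids to use (default all FOVs of the cohort spec).
#' @return List of \code{morphological_profile}s, one per clone.
#' @export
cohort_profiles <- function(cohort, window_end_h = max(cohort$spec$time_points),
                            fov_ids = seq_len(cohort$spec$n_fov)) {
  lapply(cohort$clones, function(cl)
    build_profile(cl$cells, window_end_h, fov_ids,
                  time_points = cohort$spec$time_points[
                    cohort$spec$time_points <= window_end_h]))
}

#' Write / read profile tables
#'
#' Profiles are serialised as a wide delimited table: one row per clone x
#' replicate, columns \code{clone_id}, \code{replicate_id}, then the named
#' parameters.
#'
#' @param profiles List of \code{morphological_profile}s.
#' @param path CSV path.
#' @return \code{write_profiles}: invisibly, the path.
#' @export
write_profiles <- function(profiles, path) {
  x <- do.call(rbind, lapply(profiles, function(p) p$values))
  df <- data.frame(clone_id = vapply(profiles, `[[`, "", "clone_id"),
                   replicate_id = vapply(profiles, `[[`, 0L, "replicate_id"),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
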