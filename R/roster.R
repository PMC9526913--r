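#' Morphological descriptor roster
#'
#' The twelve per-cell morphological descriptors measured on each segmented
#' cell region, in their fixed canonical order. Shape descriptors (Area through
#' Solidity) are computed on the binary region; intensity and texture
#' descriptors (IntensityMean through Energy) on the masked intensity patch.
#'
#' @return Character vector of the 12 descriptor names.
#' @export
descriptor_names <- function() {
  c("Area", "Perimeter", "Length", "Breadth", "AspectRatio", "Compactness",
    "Roundness", "Solidity", "IntensityMean", "IntensitySD", "Correlation",
    "Energy")
}

#' Profile parameter names for a time window
#'
#' Builds the canonical parameter name vector of a morphological profile:
#' \code{"<Descriptor>_<mean|SD> (<T> h)"}, ordered time-major, then
#' descriptor, then statistic. A full 6--90 h window (15 time points) yields
#' 12 x 2 x 15 = 360 parameters; a single time point yields 24.
#'
#' @param time_points Numeric vector of time points (hours), ascending.
#' @param descriptors Character vector of descriptor names.
#' @return Character vector of parameter names.
#' @export
profile_parameter_names <- function(time_points, descriptors = descriptor_names()) {
  unlist(lapply(time_points, function(tp) {
    unlist(lapply(descriptors, function(d) {
      paste0(d, "_", c("mean", "SD"), " (", format(tp, trim = TRUE), " h)")
    }))
  }))
}

#' Default acquisition time grid
#'
#' Imaging time points: every 6 h from 6 h to 90 h post-seeding (15 points).
#' @return Numeric vector of hours.
#' @export
default_time_points <- function() seq(6, 90, by = 6)

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a master seed and integer tags,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) x <- (x * 69069 + as.double(t) * 2654435761) %% 2147483647
  as.integer(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Sample standard deviation (n - 1 denominator); the package-wide convention.
sample_sd <- function(x) stats::sd(x)
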