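#' Algorithm parameters
#'
#' Bundles the tuning constants shared by [vibe()], [vibe1d()] and [devb()].
#' The defaults are the standard operating point for this family of
#' segmenters: `n_samples = 20` stored background samples per pixel, matching
#' radius `radius = 20` (Euclidean distance in 8-bit pixel-value units),
#' `min_matches = 2` samples within the radius to call a pixel background,
#' and time-subsampling factor `subsample_factor = 16` (a background pixel
#' has one chance in 16 of updating its model on any given frame).
#'
#' `ghost_threshold` is the depth-model test threshold used only by [devb()]:
#' a foreground pixel whose stored proximity exceeds the currently observed
#' proximity by more than this amount (on the 8-bit proximity scale, 0 =
#' farthest, 255 = closest) is reclassified as a ghost. Small values in the
#' 1-3 range work well; the default is 2.
#'
#' @param n_samples Number of background samples kept per pixel (N).
#' @param radius Euclidean matching radius R in pixel-value units.
#' @param min_matches Minimum number of samples within `radius` for a
#'   background classification (lambda).
#' @param subsample_factor Time subsampling factor phi; each background pixel
#'   updates its model with probability `1/subsample_factor`.
#' @param ghost_threshold Ghost-test threshold tau on the 8-bit proximity
#'   scale ([devb()] only).
#' @param seed Integer seed for the pseudo-random stream; identical seed and
#'   inputs give a bit-identical trajectory.
#' @return An object of class `"devb_params"` (a named list).
#' @examples
#' p <- devb_params()
#' p$n_samples
#' @export
devb_params <- function(n_samples = 20L, radius = 20, min_matches = 2L,
                        subsample_factor = 16L, ghost_threshold = 2,
                        seed = 0L) {
  n_samples <- as.integer(n_samples)
  min_matches <- as.integer(min_matches)
  subsample_factor <- as.integer(subsample_factor)
  seed <- as.integer(seed)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be a positive integer")
  if (is.na(radius) || radius < 0) stop("radius must be non-negative")
  if (is.na(min_matches) || min_matches < 1L) stop("min_matches must be a positive integer")
  if (min_matches > n_samples) stop("min_matches must not exceed n_samples")
  if (is.na(subsample_factor) || subsample_factor < 1L)
    stop("subsample_factor must be a positive integer")
  if (is.na(ghost_threshold) || ghost_threshold < 0)
    stop("ghost_threshold must be non-negative")
  structure(list(n_samples = n_samples, radius = radius,
                 min_matches = min_matches, subsample_factor = subsample_factor,
                 ghost_threshold = ghost_threshold, seed = seed),
            class = "devb_params")
}

#' @export
print.devb_params <- function(x, ...) {
  cat("Background-model parameters\n")
  cat(sprintf("  n_samples (N):          %d\n", x$n_samples))
  cat(sprintf("  radius (R):             %g\n", x$radius))
  cat(sprintf("  min_matches (lambda):   %d\n", x$min_matches))
  cat(sprintf("  subsample_factor (phi): %d\n", x$subsample_factor))
  cat(sprintf("  ghost_threshold (tau):  %g\n", x$ghost_threshold))
  cat(sprintf("  seed:                   %d\n", x$seed))
  invisible(x)
}

as_devb_params <- function(x) {
  if (inherits(x, "devb_params")) return(x)
  if (is.list(x)) return(do.call(devb_params, x))
  stop("params must be a devb_params object or a named list")
}
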