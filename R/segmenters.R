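#' One RGB-D time step
#'
#' Bundles a color frame, a depth frame, and an optional ground-truth mask,
#' all sharing the same height and width.
#'
#' @param color Numeric array `H x W x 3`, 8-bit values (0-255).
#' @param depth Integer/numeric matrix `H x W`, millimeters; 0 marks holes.
#' @param gt Optional logical matrix `H x W` (TRUE = foreground).
#' @return A list of class `"frame_triplet"`.
#' @export
frame_triplet <- function(color, depth, gt = NULL) {
  color <- as_frame_array(color)
  if (dim(color)[3] != 3L) stop("color must have 3 channels")
  if (!is.matrix(depth)) stop("depth must be a matrix")
  if (!identical(dim(color)[1:2], dim(depth))) stop("color and depth shapes must match")
  if (!is.null(gt)) {
    if (!is.matrix(gt) || !identical(dim(gt), dim(depth)))
      stop("ground truth shape must match the frames")
    gt <- gt != 0
  }
  structure(list(color = color, depth = depth, gt = gt), class = "frame_triplet")
}

#' Construct an RGB-D sequence from frame triplets
#'
#' @param frames List of [frame_triplet()] objects with identical shapes.
#' @param frame_names Optional character vector of frame names (used when
#'   writing masks to disk).
#' @return A list of class `"rgbd_sequence"`.
#' @export
rgbd_sequence <- function(frames, frame_names = NULL) {
  if (length(frames) < 1L) stop("at least one frame is required")
  if (!all(vapply(frames, inherits, logical(1), "frame_triplet")))
    stop("frames must be frame_triplet objects")
  d0 <- dim(frames[[1]]$depth)
  if (!all(vapply(frames, function(f) identical(dim(f$depth), d0), logical(1))))
    stop("all frames must share the same shape")
  if (is.null(frame_names)) frame_names <- sprintf("frame_%04d", seq_along(frames))
  structure(frames, class = "rgbd_sequence", frame_names = frame_names)
}

#' @export
print.rgbd_sequence <- function(x, ...) {
  d <- dim(x[[1]]$depth)
  cat(sprintf("RGB-D sequence: %d frames of %d x %d, ground truth %s\n",
              length(x), d[1], d[2],
              if (is.null(x[[1]]$gt)) "absent" else "present"))
  invisible(x)
}

new_segmentation <- function(res, algorithm, params, frame_names) {
  structure(list(masks = lapply(res$masks, identity),
                 ghost_reclassified = as.integer(res$ghost_reclassified),
                 params = params, algorithm = algorithm,
                 frame_names = frame_names,
                 model = res$model, depth_model = res$depth_model),
            class = "segmentation")
}

check_frames_list <- function(frames) {
  if (length(frames) < 1L) stop("at least one frame is required")
  frames <- lapply(frames, as_frame_array)
  d0 <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d0), logical(1))))
    stop("all frames must share the same shape")
  frames
}

#' Color-only sample-based background subtraction (ViBe)
#'
#' Initializes the per-pixel sample model from the first frame's
#' 8-neighborhoods, then classifies every frame pixel by pixel in raster
#' order: a pixel is background when at least `min_matches` of its
#' `n_samples` stored samples lie within `radius` (Euclidean distance in the
#' value space); background pixels stochastically refresh their own model and
#' a random neighbor's with probability `1/subsample_factor` each. The
#' first frame's mask is produced by classifying it against its own
#' just-initialized model.
#'
#' @param frames List of numeric `H x W x k` arrays (k = 3 for color, k = 1
#'   for single-channel input) on a 0-255 scale, or an
#'   `rgbd_sequence` (its color frames are used).
#' @param params A [devb_params()] object.
#' @param seed Seed for the run; defaults to `params$seed`.
#' @return An object of class `"segmentation"`: `masks` (list of logical
#'   matrices, TRUE = foreground), `ghost_reclassified` (all zero for this
#'   algorithm), `params`, `algorithm`, and the final sample model.
#' @examples
#' frames <- replicate(5, array(50, c(8, 8, 3)), simplify = FALSE)
#' seg <- vibe(frames, devb_params(seed = 1))
#' sum(seg$masks[[5]])  # static scene: no foreground
#' @export
vibe <- function(frames, params = devb_params(), seed = params$seed) {
  params <- as_devb_params(params)
  frame_names <- NULL
  if (inherits(frames, "rgbd_sequence")) {
    frame_names <- attr(frames, "frame_names")
    frames <- lapply(frames, function(f) f$color)
  }
  frames <- check_frames_list(frames)
  if (is.null(frame_names)) frame_names <- sprintf("frame_%04d", seq_along(frames))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_vibe(frames, params$n_samples, params$radius,
                      params$min_matches, params$subsample_factor)
  new_segmentation(res, "vibe", params, frame_names)
}

#' Depth-only baseline (ViBe on one proximity channel)
#'
#' Runs the sample-based segmenter on single-channel depth alone. Input
#' proximity frames in `[0, 1]` are placed on the 8-bit proximity scale
#' (multiplied by 255) so the default `radius` keeps its magnitude. Depth
#' holes (proximity 0) are classified like any other value, which is exactly
#' why this baseline is noisy around flickering holes.
#'
#' @param proximity_frames List of numeric `H x W` matrices in `[0, 1]`
#'   (see [to_proximity()]), or an `rgbd_sequence` (depth converted with
#'   `max_range_mm`).
#' @param params A [devb_params()] object.
#' @param max_range_mm Used only when an `rgbd_sequence` is supplied.
#' @param seed Seed for the run.
#' @return A `"segmentation"` object.
#' @export
vibe1d <- function(proximity_frames, params = devb_params(),
                   max_range_mm = 8000, seed = params$seed) {
  frame_names <- NULL
  if (inherits(proximity_frames, "rgbd_sequence")) {
    frame_names <- attr(proximity_frames, "frame_names")
    proximity_frames <- lapply(proximity_frames,
                               function(f) to_proximity(f$depth, max_range_mm))
  }
  frames <- lapply(proximity_frames, function(p) {
    if (!is.matrix(p)) stop("proximity frames must be matrices")
    if (any(p < 0 | p > 1)) stop("proximity values must lie in [0, 1]")
    p * 255
  })
  seg <- vibe(frames, params, seed)
  if (!is.null(frame_names)) seg$frame_names <- frame_names
  seg$algorithm <- "vibe1d"
  seg
}

#' Depth-extended background subtraction (DEVB)
#'
#' For every frame the depth is mapped to the proximity scale, the
#' uncertainty `sigma = 1 - proximity` is computed, and color and proximity
#' are fused per channel ([fuse()]) onto the 8-bit working scale before any
#' pixel is classified. Classification and model updates then follow the
#' color machinery on the fused values, with two depth additions: a per-pixel
#' depth model (initialized from the first depth frame) is refreshed on the
#' background branch's update coin, and foreground pixels whose stored
#' proximity exceeds the observed one by more than `ghost_threshold` (8-bit
#' proximity scale) are reclassified as background ghosts — their mask entry
#' is background and their sample model adapts, but the depth model keeps its
#' value until the color model has genuinely caught up. This removes the
#' ghost at the initial position of a departed object within a frame or two,
#' while an object *approaching* the camera can never be reclassified, so
#' black shadows (a new object crossing an old target's footprint with
#' similar colors) stay foreground.
#'
#' @param frames An `rgbd_sequence`, or a list of [frame_triplet()] objects.
#' @param params A [devb_params()] object (`ghost_threshold` is tau).
#' @param max_range_mm Depth normalization range for [to_proximity()].
#' @param seed Seed for the run.
#' @return A `"segmentation"` object; `ghost_reclassified` holds the
#'   per-frame count of pixels flipped by the ghost test, and `depth_model`
#'   the final depth model (8-bit proximity scale).
#' @examples
#' seq <- ghost_scenario(height = 24, width = 24, n_frames = 8, seed = 1)
#' seg <- devb(seq, devb_params(seed = 1))
#' seg$ghost_reclassified
#' @export
devb <- function(frames, params = devb_params(), max_range_mm = 8000,
                 seed = params$seed) {
  params <- as_devb_params(params)
  if (!inherits(frames, "rgbd_sequence")) frames <- rgbd_sequence(frames)
  frame_names <- attr(frames, "frame_names")
  prox <- lapply(frames, function(f) to_proximity(f$depth, max_range_mm))
  fused <- vector("list", length(frames))
  for (t in seq_along(frames))
    fused[[t]] <- fuse_working(frames[[t]]$color, prox[[t]])
  prox8 <- lapply(prox, function(p) p * 255)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_devb(fused, prox8, params$n_samples, params$radius,
                      params$min_matches, params$subsample_factor,
                      params$ghost_threshold)
  new_segmentation(res, "devb", params, frame_names)
}

#' @export
print.segmentation <- function(x, ...) {
  d <- dim(x$masks[[1]])
  fg <- mean(vapply(x$masks, mean, numeric(1)))
  cat(sprintf("%s segmentation: %d frames of %d x %d\n",
              x$algorithm, length(x$masks), d[1], d[2]))
  cat(sprintf("  mean foreground fraction: %.4f\n", fg))
  if (x$algorithm == "devb")
    cat(sprintf("  ghost-reclassified pixels (total): %d\n",
                sum(x$ghost_reclassified)))
  invisible(x)
}

#' @export
summary.segmentation <- function(object, ...) {
  df <- data.frame(frame_index = seq_along(object$masks),
                   foreground_pixels = vapply(object$masks, sum, integer(1)),
                   foreground_fraction = vapply(object$masks, mean, numeric(1)),
                   ghost_reclassified = object$ghost_reclassified)
  structure(list(algorithm = object$algorithm, params = object$params,
                 per_frame = df),
            class = "summary.segmentation")
}

#' @export
print.summary.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation summary (%s)\n", x$algorithm))
  print(x$params)
  n <- nrow(x$per_frame)
  show <- if (n > 10) x$per_frame[c(1:5, (n - 4):n), ] else x$per_frame
  print(show, row.names = FALSE)
  if (n > 10) cat(sprintf("  (%d frames in total)\n", n))
  invisible(x)
}

#' Display one frame's foreground mask
#'
#' @param x A `"segmentation"` object.
#' @param frame 1-based frame index to display.
#' @param ... Passed to [graphics::image()].
#' @export
plot.segmentation <- function(x, frame = length(x$masks), ...) {
  m <- x$masks[[frame]]
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = c("black", "white"),
                  axes = FALSE, asp = nrow(m) / ncol(m),
                  main = sprintf("%s mask, frame %d", x$algorithm, frame), ...)
  invisible(x)
}
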