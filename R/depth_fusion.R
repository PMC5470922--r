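#' Convert a millimeter depth frame to the proximity (brightness) scale
#'
#' Depth cameras report range in millimeters with 0 meaning "no reading" (a
#' hole). On the proximity scale larger means closer to the camera, the way a
#' depth image looks when displayed: `clip((max_range_mm - depth) /
#' max_range_mm, 0, 1)` for valid pixels, 0 for holes. The map is strictly
#' decreasing in depth over `(0, max_range_mm)`.
#'
#' @param depth Integer/numeric matrix of depths in mm; 0 marks holes.
#' @param max_range_mm Sensor range used for normalization (default 8000 mm,
#'   the practical limit of consumer structured-light sensors).
#' @return Numeric matrix in `[0, 1]`; holes map exactly to 0.
#' @examples
#' to_proximity(matrix(c(0L, 2000L, 8000L, 500L), 2), 8000)
#' @export
to_proximity <- function(depth, max_range_mm = 8000) {
  if (!is.matrix(depth)) stop("depth must be a matrix of millimeter values")
  if (max_range_mm <= 0) stop("max_range_mm must be positive")
  p <- pmin(pmax((max_range_mm - depth) / max_range_mm, 0), 1)
  p[depth == 0] <- 0
  p
}

#' Normalized depth uncertainty
#'
#' The inverted, \[0,1\]-normalized depth used to weight depth against color:
#' `sigma = 1 - proximity`. Close, reliable measurements get sigma near 0;
#' holes (proximity 0) get sigma exactly 1, so fusion there falls back on
#' color alone.
#'
#' @param proximity Numeric matrix in `[0, 1]` from [to_proximity()].
#' @return Numeric matrix in `[0, 1]`, the exact complement of `proximity`.
#' @export
compute_sigma <- function(proximity) {
  if (!is.matrix(proximity)) stop("proximity must be a matrix")
  if (any(proximity < 0 | proximity > 1)) stop("proximity must lie in [0, 1]")
  1 - proximity
}

#' Uncertainty-weighted fusion of normalized color and proximity
#'
#' Per channel: `w_d = (1 - sigma) * d`, `w_c = (1 + sigma) * c`, fused value
#' `(w_d + w_c) / 2`. Where depth is certain (sigma = 0) the result is the
#' average of proximity and color; where it is a hole (sigma = 1) the result
#' is exactly the color channel. Outputs lie in `[0, 1.5]`.
#'
#' @param color_norm Numeric array `H x W x 3`, color normalized to `[0, 1]`.
#' @param proximity Numeric matrix `H x W` in `[0, 1]`.
#' @param sigma Numeric matrix `H x W` in `[0, 1]`; defaults to
#'   `compute_sigma(proximity)`.
#' @return Numeric array `H x W x 3` in `[0, 1.5]` (the pre-rescale fused
#'   image; see [fuse_working()] for the 8-bit working scale).
#' @examples
#' fuse(array(0.4, c(1, 1, 3)), matrix(0.8), matrix(0))  # (0.8+0.4)/2 = 0.6
#' @export
fuse <- function(color_norm, proximity, sigma = compute_sigma(proximity)) {
  if (!is.array(color_norm) || length(dim(color_norm)) != 3L || dim(color_norm)[3] != 3L)
    stop("color_norm must be an H x W x 3 array")
  d <- dim(color_norm)[1:2]
  if (!identical(dim(proximity), d) || !identical(dim(sigma), d))
    stop("color, proximity and sigma shapes must match")
  if (any(color_norm < 0 | color_norm > 1)) stop("color_norm must lie in [0, 1]")
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  wd <- (1 - sigma) * proximity
  out <- color_norm
  for (ch in 1:3) out[, , ch] <- 0.5 * (wd + (1 + sigma) * color_norm[, , ch])
  out
}

# Fused frame on the 8-bit working scale: [0,1.5] * 170 -> [0,255], so the
# default matching radius keeps its usual magnitude after fusion.
fuse_working <- function(color, proximity, sigma = compute_sigma(proximity)) {
  fuse(color / 255, proximity, sigma) * 170
}

#' Ghost test against the depth model
#'
#' A foreground pixel is a ghost when the proximity stored in the depth model
#' exceeds the currently observed proximity by more than `tau`: the object
#' that stamped the model has departed, so the sensor now sees something
#' farther away. The difference is signed — an object moving *closer*
#' (current above model) is never a ghost.
#'
#' @param model_value Stored depth-model proximity (vectorized).
#' @param current_value Currently observed proximity on the same scale.
#' @param tau Non-negative threshold on that scale (the segmenters use the
#'   8-bit proximity scale, where values 1-3 are sensible).
#' @return Logical: `TRUE` where `model_value - current_value > tau`.
#' @examples
#' is_ghost(200, 50, tau = 2)   # TRUE: the surface receded
#' is_ghost(0.1, 0.9, tau = 0.05)  # FALSE: approaching object
#' @export
is_ghost <- function(model_value, current_value, tau) {
  if (any(tau < 0)) stop("tau must be non-negative")
  (model_value - current_value) > tau
}

#' Stochastic depth-model update for one background-classified pixel
#'
#' With probability `1/subsample_factor` the stored proximity at the position
#' is replaced by the currently observed one; otherwise the model is
#' unchanged. Inside [devb()]'s frame loop this replacement rides the same
#' coin as the pixel's own background-sample update.
#'
#' @param model Numeric matrix: the depth model grid (proximity scale).
#' @param row,col 1-based position.
#' @param value Observed proximity at the position.
#' @param params A [devb_params()] object; `subsample_factor` is used.
#' @return The updated depth model (a copy).
#' @export
update_depth_model <- function(model, row, col, value, params = devb_params()) {
  params <- as_devb_params(params)
  if (!is.matrix(model)) stop("depth model must be a matrix")
  if (row < 1 || row > nrow(model) || col < 1 || col > ncol(model))
    stop("position out of bounds")
  if (runif(1) < 1 / params$subsample_factor) model[row, col] <- value
  model
}
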