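#' Initialize the per-pixel sample model from a first frame
#'
#' Builds the background model M(x): for every pixel, `n_samples` values are
#' drawn uniformly at random (with replacement) from the pixel's 8-neighborhood
#' plus the pixel itself in the first frame, so the model is classifiable from
#' frame 1. Border pixels use their in-bounds neighborhood.
#'
#' @param frame Numeric array `H x W x k` (or an `H x W` matrix, treated as
#'   `k = 1`) of pixel values on the working scale (0-255 for 8-bit input).
#' @param params A [devb_params()] object; `n_samples` and `seed` are used.
#' @param seed Optional override of `params$seed`; `NULL` leaves the current
#'   RNG state untouched (useful when the caller manages the stream).
#' @return Numeric array `H x W x k x n_samples`: the sample model grid.
#' @examples
#' m <- init_model(array(50, c(4, 4, 3)), devb_params(n_samples = 5))
#' dim(m)
#' @export
init_model <- function(frame, params = devb_params(), seed = params$seed) {
  params <- as_devb_params(params)
  frame <- as_frame_array(frame)
  if (!is.null(seed)) set.seed(seed)
  cpp_init_model(frame, params$n_samples)
}

# coerce matrix -> H x W x 1 array; validate
as_frame_array <- function(frame) {
  if (is.matrix(frame)) dim(frame) <- c(dim(frame), 1L)
  if (!is.array(frame) || length(dim(frame)) != 3L)
    stop("frame must be an H x W x k array or an H x W matrix")
  if (any(dim(frame) == 0L)) stop("frame must be non-empty")
  storage.mode(frame) <- "double"
  frame
}

#' Count model samples within the matching radius
#'
#' Computes N_R(x), the number of stored samples at strict Euclidean distance
#' less than `radius` from the observed value, in the k-dimensional value
#' space.
#'
#' @param value Numeric vector of length k (one pixel value).
#' @param samples Numeric matrix `n x k` (one sample per row), or a numeric
#'   vector when `k = 1`.
#' @param radius Non-negative matching radius.
#' @return Integer count in `[0, n]`.
#' @examples
#' count_matches(c(10, 10, 10), matrix(10, 20, 3), radius = 20)
#' @export
count_matches <- function(value, samples, radius) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  if (length(value) != ncol(samples))
    stop("value and samples disagree on dimensionality")
  if (radius < 0) stop("radius must be non-negative")
  cpp_count_matches(as.numeric(value), samples, radius)
}

#' Classify one pixel value against its sample model
#'
#' Background if and only if at least `min_matches` samples lie within
#' `radius` of the value (the `matches >= lambda` rule).
#'
#' @inheritParams count_matches
#' @param params A [devb_params()] object supplying `radius` and
#'   `min_matches`.
#' @return `"background"` or `"foreground"`.
#' @examples
#' classify_pixel(c(10, 10, 10), matrix(10, 20, 3), devb_params())
#' @export
classify_pixel <- function(value, samples, params = devb_params()) {
  params <- as_devb_params(params)
  n <- count_matches(value, samples, params$radius)
  if (n >= params$min_matches) "background" else "foreground"
}

#' Stochastic background-model update for one background-classified pixel
#'
#' With probability `1/subsample_factor` one uniformly chosen sample of the
#' pixel's own model is replaced by `value`; independently, with probability
#' `1/subsample_factor`, one uniformly chosen sample of one uniformly chosen
#' in-bounds 8-neighbor's model is replaced by `value` (spatial diffusion of
#' the current observation). Sample counts are conserved. Draws come from R's
#' global RNG stream in the fixed order (self coin, self slot, neighbor coin,
#' neighbor index, neighbor slot), so `set.seed()` makes call sequences
#' reproducible.
#'
#' @param model Sample model array `H x W x k x N` from [init_model()].
#' @param row,col 1-based pixel position.
#' @param value Numeric vector of length k: the observed value.
#' @param params A [devb_params()] object; `subsample_factor` is used.
#' @return The updated model array (a copy; the input is not modified).
#' @export
stochastic_update <- function(model, row, col, value, params = devb_params()) {
  params <- as_devb_params(params)
  d <- dim(model)
  if (length(d) != 4L) stop("model must be an H x W x k x N array")
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop("position out of bounds")
  if (length(value) != d[3]) stop("value dimensionality does not match model")
  cpp_stochastic_update(model, as.integer(row) - 1L, as.integer(col) - 1L,
                        as.numeric(value), params$subsample_factor)
}

#' Expected sample survival probability under random subsampling
#'
#' Probability that a sample present in a pixel's model is still there after
#' `dt` update events, `((N - 1) / N)^dt`, equivalently
#' `exp(-log(N / (N - 1)) * dt)`: the memoryless exponential-lifespan law of
#' the random-subsampling update. `dt` counts update events (frames at which
#' the pixel was background-classified *and* the `1/phi` coin fired); folding
#' the coin in gives the per-frame law `(1 - 1/(N * phi))^T` that
#' [lifespan_experiment()] measures empirically.
#'
#' @param n_samples Model size N (at least 2).
#' @param dt Non-negative elapsed update events (vectorized).
#' @param form `"power"` for `((N-1)/N)^dt` or `"exponential"` for the
#'   `exp(-log(N/(N-1)) dt)` rewrite; the two agree to floating tolerance.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' survival_probability(20, 1)   # 0.95
#' survival_probability(20, 50)
#' @export
survival_probability <- function(n_samples, dt, form = c("power", "exponential")) {
  form <- match.arg(form)
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (any(dt < 0)) stop("dt must be non-negative")
  if (form == "power") ((n_samples - 1) / n_samples)^dt
  else exp(-log(n_samples / (n_samples - 1)) * dt)
}

#' Empirical sample-lifespan experiment
#'
#' Tags every sample of every pixel of a static scene at frame 1, runs the
#' in-place random-subsampling update (each frame each pixel fires the
#' `1/phi` coin; when it fires, a uniformly chosen slot is replaced and loses
#' its tag) for `n_frames` frames, and reports the surviving-tag fraction
#' next to the closed-form expectation `(1 - 1/(N * phi))^n_frames`. This
#' isolates the update channel the exponential law describes; the neighbor
#' diffusion of the full segmentation loop is a second, independent
#' replacement channel and is not part of the law.
#'
#' @param height,width Scene size in pixels.
#' @param params A [devb_params()] object (`n_samples`, `subsample_factor`,
#'   `seed`).
#' @param n_frames Number of update opportunities T.
#' @param seed Optional seed override.
#' @return A list with `surviving_fraction`, `expected_fraction`, `n_tags`,
#'   and `mc_sd` (the binomial Monte-Carlo standard deviation of the
#'   surviving fraction).
#' @examples
#' lifespan_experiment(20, 20, devb_params(), n_frames = 32)
#' @export
lifespan_experiment <- function(height, width, params = devb_params(),
                                n_frames = 320L, seed = params$seed) {
  params <- as_devb_params(params)
  if (height < 1 || width < 1) stop("scene must be non-empty")
  if (n_frames < 0) stop("n_frames must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  frac <- cpp_lifespan_survival(as.integer(height), as.integer(width),
                                params$n_samples, params$subsample_factor,
                                as.integer(n_frames))
  p <- (1 - 1 / (params$n_samples * params$subsample_factor))^n_frames
  n_tags <- as.numeric(height) * width * params$n_samples
  list(surviving_fraction = frac,
       expected_fraction = p,
       n_tags = n_tags,
       mc_sd = sqrt(p * (1 - p) / n_tags))
}
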