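#' Specify a synthetic RGB-D scene
#'
#' Describes a static textured background at a fixed depth with zero or more
#' moving objects in front of it, plus the two depth-sensor artifacts that
#' matter for segmentation: holes (pixels with no reading, value 0, re-drawn
#' independently every frame) and illumination flicker (a per-frame global
#' brightness offset; when active, the background texture noise is also
#' re-drawn per frame instead of being frozen at frame 1).
#'
#' Each object is a list with elements `color` (RGB triple, 0-255),
#' `depth_mm` (must be closer than the background), `shape` (`"rectangle"`
#' or `"ellipse"`), `size` (c(height, width) in pixels), either `position`
#' (c(row, col) of the top-left corner, static) or `traj` (a function of the
#' frame index returning that corner), and optional `first_frame` /
#' `last_frame` limiting when it is visible.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames.
#' @param bg_color RGB triple of the background (0-255).
#' @param bg_noise Texture noise amplitude: i.i.d. uniform on
#'   `[-bg_noise, bg_noise]` per pixel per channel.
#' @param bg_depth_mm Background depth in millimeters.
#' @param objects List of object specifications (see Details).
#' @param hole_rate Per-pixel per-frame probability of a depth hole.
#' @param flicker_amplitude Global brightness flicker amplitude (0 = off).
#' @param seed Seed; the generated sequence is fully determined by the spec.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(height, width, n_frames, bg_color = c(96, 96, 96),
                       bg_noise = 3, bg_depth_mm = 4000, objects = list(),
                       hole_rate = 0, flicker_amplitude = 0, seed = 0L) {
  if (height < 1 || width < 1 || n_frames < 1)
    stop("height, width and n_frames must be positive")
  if (hole_rate < 0 || hole_rate > 1) stop("hole_rate must lie in [0, 1]")
  if (flicker_amplitude < 0) stop("flicker_amplitude must be non-negative")
  for (ob in objects) {
    if (is.null(ob$color) || is.null(ob$depth_mm) || is.null(ob$size))
      stop("each object needs color, depth_mm and size")
    if (ob$depth_mm >= bg_depth_mm)
      stop("objects must be closer than the background (depth_mm smaller)")
  }
  structure(list(height = height, width = width, n_frames = n_frames,
                 bg_color = bg_color, bg_noise = bg_noise,
                 bg_depth_mm = bg_depth_mm, objects = objects,
                 hole_rate = hole_rate, flicker_amplitude = flicker_amplitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run expr under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

object_footprint <- function(ob, t, height, width) {
  alive <- (is.null(ob$first_frame) || t >= ob$first_frame) &&
           (is.null(ob$last_frame) || t <= ob$last_frame)
  if (!alive) return(NULL)
  tl <- if (!is.null(ob$traj)) ob$traj(t) else ob$position
  h <- ob$size[1]; w <- ob$size[2]
  if (tl[1] < 1 || tl[2] < 1 || tl[1] + h - 1 > height || tl[2] + w - 1 > width)
    stop(sprintf("object trajectory out of bounds at frame %d", t))
  mask <- matrix(FALSE, height, width)
  rows <- tl[1]:(tl[1] + h - 1); cols <- tl[2]:(tl[2] + w - 1)
  if (identical(ob$shape, "ellipse")) {
    cr <- tl[1] + (h - 1) / 2; cc <- tl[2] + (w - 1) / 2
    sub <- outer(rows, cols, function(r, co)
      ((r - cr) / (h / 2))^2 + ((co - cc) / (w / 2))^2 <= 1)
    mask[rows, cols] <- sub
  } else {
    mask[rows, cols] <- TRUE
  }
  mask
}

#' Generate a synthetic RGB-D sequence with ground truth
#'
#' Color frames are the noisy background texture with the objects stamped on
#' top (later objects occlude earlier ones) and any flicker offset added;
#' depth frames carry the background depth with object depths stamped and
#' holes (value 0) placed by an independent per-pixel coin at `hole_rate`
#' each frame; ground truth marks exactly the stamped object pixels. The
#' output is fully determined by the spec (including its seed) and the
#' caller's RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return An `rgbd_sequence` with ground-truth masks.
#' @examples
#' seq <- generate_scene(scene_spec(16, 16, 3))
#' sum(seq[[1]]$gt)
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    draw_texture <- function()
      round(array(runif(H * W * 3, -spec$bg_noise, spec$bg_noise), c(H, W, 3)))
    texture <- draw_texture()
    frames <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames)) {
      offset <- 0
      if (spec$flicker_amplitude > 0) {
        texture <- draw_texture()
        offset <- round(runif(1, -spec$flicker_amplitude, spec$flicker_amplitude))
      }
      color <- texture
      for (ch in 1:3) color[, , ch] <- color[, , ch] + spec$bg_color[ch]
      depth <- matrix(spec$bg_depth_mm, H, W)
      gt <- matrix(FALSE, H, W)
      for (ob in spec$objects) {
        fp <- object_footprint(ob, t, H, W)
        if (is.null(fp)) next
        for (ch in 1:3) {
          pl <- color[, , ch]; pl[fp] <- ob$color[ch]; color[, , ch] <- pl
        }
        depth[fp] <- ob$depth_mm
        gt <- gt | fp
      }
      color <- pmin(pmax(color + offset, 0), 255)
      if (spec$hole_rate > 0)
        depth[matrix(runif(H * W) < spec$hole_rate, H, W)] <- 0L
      storage.mode(depth) <- "integer"
      frames[[t]] <- frame_triplet(color, depth, gt)
    }
    rgbd_sequence(frames)
  })
}

centered_box <- function(height, width, size) {
  c(floor((height - size) / 2) + 1L, floor((width - size) / 2) + 1L)
}

#' Canonical ghost fixture
#'
#' An object is present in frame 1 only and departs from frame 2 onward: the
#' background model is built with the object in place, so a color-only
#' segmenter leaves a ghost — persistent false foreground — at the initial
#' footprint, while the depth model sees that the surface has receded and a
#' depth-aware segmenter can reclassify it. The object's frame-1 footprint is
#' attached as attribute `"ghost_region"` (a logical matrix) for targeted
#' false-positive measurement.
#'
#' @param height,width Frame size (default 64 x 64).
#' @param n_frames Number of frames (at least 3; default 60).
#' @param seed Generator seed.
#' @return An `rgbd_sequence` with attribute `"ghost_region"`.
#' @export
ghost_scenario <- function(height = 64, width = 64, n_frames = 60, seed = 0L) {
  if (n_frames < 3) stop("n_frames must be at least 3")
  s <- max(4L, min(height, width) %/% 4L)
  tl <- centered_box(height, width, s)
  ob <- list(color = c(200, 80, 60), depth_mm = 1500, shape = "rectangle",
             size = c(s, s), position = tl, first_frame = 1, last_frame = 1)
  spec <- scene_spec(height, width, n_frames, bg_color = c(70, 70, 190),
                     bg_noise = 3, bg_depth_mm = 4000, objects = list(ob),
                     hole_rate = 0.005, seed = seed)
  seq <- generate_scene(spec)
  region <- matrix(FALSE, height, width)
  region[tl[1]:(tl[1] + s - 1), tl[2]:(tl[2] + s - 1)] <- TRUE
  attr(seq, "ghost_region") <- region
  seq
}

#' Black-shadow fixture
#'
#' Object A occupies a central region Q in frame 1 and then leaves; object B,
#' with a nearly identical color but much closer to the camera, later crosses
#' Q. Color-only models hold A's colors at Q, so B matches them and is
#' swallowed as background (a black shadow); B's higher proximity lets a
#' depth-aware segmenter keep it foreground. Ground truth marks B (and A in
#' frame 1) as foreground. Attributes: `"old_footprint"` (logical matrix Q)
#' and `"crossing_masks"` (per-frame logical footprints of B).
#'
#' @param height,width Frame size (default 64 x 64).
#' @param n_frames Number of frames (at least 10; default 60).
#' @param seed Generator seed.
#' @return An `rgbd_sequence` with the attributes above.
#' @export
black_shadow_scenario <- function(height = 64, width = 64, n_frames = 60,
                                  seed = 0L) {
  if (n_frames < 10) stop("n_frames must be at least 10")
  s <- max(6L, min(height, width) %/% 4L)
  qtl <- centered_box(height, width, s)
  first_b <- 6L
  last_b <- min(n_frames, first_b + (width - s) %/% 2L)
  traj_b <- function(t) c(qtl[1], 1L + 2L * (t - first_b))
  a <- list(color = c(180, 60, 60), depth_mm = 2500, shape = "rectangle",
            size = c(s, s), position = qtl, first_frame = 1, last_frame = 1)
  b <- list(color = c(185, 65, 65), depth_mm = 800, shape = "rectangle",
            size = c(s, s), traj = traj_b, first_frame = first_b,
            last_frame = last_b)
  spec <- scene_spec(height, width, n_frames, bg_color = c(120, 120, 120),
                     bg_noise = 3, bg_depth_mm = 5000, objects = list(a, b),
                     hole_rate = 0, seed = seed)
  seq <- generate_scene(spec)
  q <- matrix(FALSE, height, width)
  q[qtl[1]:(qtl[1] + s - 1), qtl[2]:(qtl[2] + s - 1)] <- TRUE
  crossing <- lapply(seq_len(n_frames), function(t) {
    fp <- object_footprint(b, t, height, width)
    if (is.null(fp)) matrix(FALSE, height, width) else fp
  })
  attr(seq, "old_footprint") <- q
  attr(seq, "crossing_masks") <- crossing
  seq
}

#' Depth-hole stress fixture
#'
#' A moving object over a static background, with a substantial rate of
#' flickering depth holes — the condition under which a depth-only segmenter
#' produces heavy false-positive noise.
#'
#' @inheritParams ghost_scenario
#' @param hole_rate Per-pixel per-frame hole probability (default 0.05).
#' @return An `rgbd_sequence`.
#' @export
holes_scenario <- function(height = 64, width = 64, n_frames = 30,
                           hole_rate = 0.05, seed = 0L) {
  s <- max(4L, min(height, width) %/% 5L)
  row <- centered_box(height, width, s)[1]
  last <- min(n_frames, 1L + (width - s) %/% 2L)
  ob <- list(color = c(210, 200, 70), depth_mm = 1200, shape = "ellipse",
             size = c(s, s), traj = function(t) c(row, 1L + 2L * (t - 1L)),
             first_frame = 1, last_frame = last)
  generate_scene(scene_spec(height, width, n_frames, bg_color = c(90, 110, 90),
                            bg_noise = 3, bg_depth_mm = 3000,
                            objects = list(ob), hole_rate = hole_rate,
                            seed = seed))
}

#' Illumination-flicker fixture
#'
#' A static scene whose global brightness flickers frame to frame (and whose
#' texture noise is re-drawn each frame), stressing color-only segmentation.
#'
#' @inheritParams ghost_scenario
#' @param flicker_amplitude Brightness flicker amplitude (default 12).
#' @return An `rgbd_sequence`.
#' @export
flicker_scenario <- function(height = 64, width = 64, n_frames = 30,
                             flicker_amplitude = 12, seed = 0L) {
  generate_scene(scene_spec(height, width, n_frames, bg_color = c(110, 100, 80),
                            bg_noise = 3, bg_depth_mm = 3500,
                            flicker_amplitude = flicker_amplitude, seed = seed))
}

#' Fully static fixture
#'
#' No objects, frozen texture, no holes, no flicker: every frame is
#' identical and the ground truth is empty.
#'
#' @inheritParams ghost_scenario
#' @return An `rgbd_sequence`.
#' @export
static_scenario <- function(height = 64, width = 64, n_frames = 30, seed = 0L) {
  generate_scene(scene_spec(height, width, n_frames, bg_color = c(100, 100, 140),
                            bg_noise = 3, bg_depth_mm = 3500, seed = seed))
}
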