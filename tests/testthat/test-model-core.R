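test_that("initialization draws every sample from the frame-1 neighborhood", {
  # uniform frame: only one value available anywhere
  m <- init_model(array(50, c(6, 6, 3)), devb_params(), seed = 1)
  expect_true(all(m == 50))
  expect_identical(dim(m), c(6L, 6L, 3L, 20L))

  # 1 x 1 frame: degenerate neighborhood
  m1 <- init_model(array(c(7, 8, 9), c(1, 1, 3)), devb_params(), seed = 1)
  expect_true(all(m1[1, 1, 1, ] == 7 & m1[1, 1, 2, ] == 8 & m1[1, 1, 3, ] == 9))

  # 3 x 3 frame of 9 distinct values: center-pixel samples are members of the set
  f <- array(matrix(1:9, 3, 3), c(3, 3, 1))
  m9 <- init_model(f, devb_params(n_samples = 200), seed = 3)
  expect_true(all(m9[2, 2, 1, ] %in% 1:9))
  # a corner pixel only sees its clipped 2 x 2 neighborhood
  expect_true(all(m9[1, 1, 1, ] %in% c(1, 2, 4, 5)))

  expect_error(init_model(array(0, c(0, 3, 3))), "non-empty")
})

test_that("count_matches equals the brute-force distance oracle", {
  expect_identical(count_matches(c(10, 10, 10), matrix(10, 20, 3), 20), 20L)
  expect_identical(count_matches(c(100, 100, 100), matrix(10, 20, 3), 20), 0L)

  set.seed(7)
  for (rep in 1:20) {
    value <- runif(3, 0, 255)
    samples <- matrix(runif(60, 0, 255), 20, 3)
    r <- runif(1, 5, 200)
    expect_identical(count_matches(value, samples, r),
                     oracle_count(value, samples, r))
  }
  expect_error(count_matches(c(1, 2), matrix(0, 5, 3), 10), "dimensionality")
})

test_that("matching uses a strict inequality at the radius boundary", {
  samples <- matrix(c(10, 10, 10), 1, 3)
  expect_identical(count_matches(c(30, 10, 10), samples, 20), 0L)  # dist == R
  expect_identical(count_matches(c(30 - 1e-9, 10, 10), samples, 20), 1L)
})

test_that("classification is (match count >= min_matches) on random instances", {
  p <- devb_params()
  # exactly min_matches samples within the radius -> background
  samples <- rbind(matrix(10, 2, 3), matrix(200, 18, 3))
  expect_identical(classify_pixel(c(10, 10, 10), samples, p), "background")
  expect_identical(classify_pixel(c(10, 10, 10), matrix(200, 20, 3), p),
                   "foreground")

  set.seed(11)
  for (rep in 1:500) {
    value <- runif(3, 0, 255)
    samples <- matrix(runif(60, 0, 255), 20, 3)
    want <- if (oracle_count(value, samples, p$radius) >= p$min_matches)
      "background" else "foreground"
    expect_identical(classify_pixel(value, samples, p), want)
  }
})

test_that("stochastic update respects the subsampling probability", {
  model <- init_model(array(0, c(3, 3, 3)), devb_params(n_samples = 20), seed = 1)

  # phi = 1: the pixel's own model certainly receives the value
  set.seed(2)
  up <- stochastic_update(model, 2, 2, c(9, 9, 9), devb_params(subsample_factor = 1))
  expect_identical(sum(up[2, 2, 1, ] == 9), 1L)

  # effectively infinite phi: nothing ever changes
  set.seed(3)
  big <- devb_params(subsample_factor = .Machine$integer.max)
  for (rep in 1:200) model2 <- stochastic_update(model, 2, 2, c(9, 9, 9), big)
  expect_identical(model2, model)

  # phi = 16: empirical self-replacement frequency within 3 binomial SD of 1/16
  set.seed(4)
  p16 <- devb_params(subsample_factor = 16)
  n <- 16000L
  hits <- 0L
  for (rep in seq_len(n)) {
    up <- stochastic_update(model, 2, 2, c(9, 9, 9), p16)
    if (any(up[2, 2, 1, ] == 9)) hits <- hits + 1L
  }
  expect_lt(abs(hits / n - 1 / 16), 3 * sqrt((1 / 16) * (15 / 16) / n))

  expect_error(stochastic_update(model, 0, 1, c(1, 1, 1)), "bounds")
  expect_error(stochastic_update(model, 4, 1, c(1, 1, 1)), "bounds")
})

test_that("stochastic update conserves sample counts and only writes observed values", {
  model <- init_model(array(5, c(4, 4, 1)), devb_params(n_samples = 10), seed = 1)
  set.seed(9)
  seen <- c(5)
  for (rep in 1:300) {
    v <- sample(100:110, 1)
    seen <- union(seen, v)
    model <- stochastic_update(model, sample(4, 1), sample(4, 1), v,
                               devb_params(n_samples = 10, subsample_factor = 2))
  }
  expect_identical(dim(model), c(4L, 4L, 1L, 10L))
  expect_true(all(model %in% seen))
})

test_that("survival probability matches both closed forms and the trivial points", {
  expect_identical(survival_probability(20, 0), 1)
  expect_equal(survival_probability(20, 1), 0.95)
  expect_equal(survival_probability(20, 50), exp(-log(20 / 19) * 50))
  for (n in c(2, 5, 20, 100)) for (dt in c(0, 1, 7, 50, 320)) {
    expect_lt(abs(survival_probability(n, dt, "power") -
                  survival_probability(n, dt, "exponential")), 1e-12)
  }
  expect_error(survival_probability(1, 5), "at least 2")
  expect_error(survival_probability(20, -1), "non-negative")
})

test_that("tagged-sample decay follows the folded per-frame lifespan law", {
  p <- devb_params(n_samples = 20, subsample_factor = 16)
  # decay curve is monotone decreasing in T and tracks (1 - 1/(N*phi))^T
  prev <- 1
  for (Tn in c(40, 120, 320)) {
    le <- lifespan_experiment(60, 60, p, n_frames = Tn, seed = 5)
    expect_lt(le$surviving_fraction, prev)
    expect_lt(abs(le$surviving_fraction - le$expected_fraction), 3 * le$mc_sd)
    prev <- le$surviving_fraction
  }
})

test_that("identical seeds give bit-identical model trajectories", {
  f <- array(round(runif(8 * 8 * 3, 0, 255)), c(8, 8, 3))
  m1 <- init_model(f, devb_params(), seed = 42)
  m2 <- init_model(f, devb_params(), seed = 42)
  expect_identical(m1, m2)
  set.seed(13); u1 <- stochastic_update(m1, 3, 3, c(1, 2, 3))
  set.seed(13); u2 <- stochastic_update(m2, 3, 3, c(1, 2, 3))
  expect_identical(u1, u2)
})
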