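test_that("gratings have the prescribed luminance statistics", {
  # zero contrast: uniform movie at the mean
  g0 <- make_grating(1, contrast = 0, dims = c(20L, 20L, 10L))
  expect_true(all(g0$luminance == 0.5))
  # full contrast modulates from 0 to 1, never outside
  g <- small_grating(1, nt = 200L)
  expect_gte(min(g$luminance), 0)
  expect_lte(max(g$luminance), 1)
  # spatial mean over whole wavelengths equals the mean luminance:
  # 40 px at 0.9 deg/px = 36 deg = one wavelength
  g1 <- make_grating(1, dims = c(40L, 40L, 20L))
  frame_means <- apply(g1$luminance, 3, mean)
  expect_equal(frame_means, rep(0.5, 20), tolerance = 1e-12)
  # temporal periodicity: at 1 Hz a fixed pixel repeats every 100 frames
  g2 <- small_grating(1, nt = 250L)
  expect_equal(g2$luminance[7, 3, 1:100], g2$luminance[7, 3, 101:200],
               tolerance = 1e-9)
})

test_that("the motion schedule freezes and reverses the drift", {
  sch <- data.frame(start = c(0, 0.5, 1.0), end = c(0.5, 1.0, 1.5),
                    sign = c(0, 1, -1))
  g <- make_grating(1, dims = c(40L, 40L, 150L), schedule = sch)
  l <- g$luminance
  # stationary epoch: identical frames
  expect_equal(l[, , 3], l[, , 48])
  # motion epoch: frames differ
  expect_gt(max(abs(l[, , 60] - l[, , 70])), 0.1)
  # reversal retraces the path: m frames into the reversed epoch the
  # phase equals m frames before its start (both 0.01 m s short of the
  # turning point at frame 101)
  expect_equal(l[, , 101 + 10], l[, , 101 - 10], tolerance = 1e-9)
})

test_that("photon noise preserves mean and contrast and is reproducible", {
  g <- small_grating(1, nt = 100L)
  n1 <- apply_photon_noise(g, 4, seed = 123)
  n2 <- apply_photon_noise(g, 4, seed = 123)
  expect_identical(n1$luminance, n2$luminance)
  n3 <- apply_photon_noise(g, 4, seed = 124)
  expect_false(identical(n1$luminance, n3$luminance))
  # affine renormalisation restores the clean movie's mean and sd
  expect_equal(mean(n1$luminance), mean(g$luminance), tolerance = 1e-6)
  expect_equal(stats::sd(n1$luminance), stats::sd(g$luminance),
               tolerance = 1e-6)
  expect_gte(min(n1$luminance), 0)
  # relative shot noise vanishes at high mean luminance
  nh <- apply_photon_noise(g, 1e6, seed = 5)
  expect_lt(max(abs(nh$luminance - g$luminance)), 0.01)
  bad <- g; bad$luminance[1] <- -0.1
  expect_error(apply_photon_noise(bad, 4), "non-negative")
})

test_that("gaussian blur behaves as a normalised or unit-peak kernel", {
  u <- stimulus_movie(array(0.37, c(30L, 30L, 2L)))
  expect_equal(gaussian_blur(u)$luminance, u$luminance, tolerance = 1e-12)
  # single bright pixel reproduces the kernel: peak at the pixel,
  # total mass 1 under sum normalisation
  d <- array(0, c(30L, 30L, 1L)); d[11, 21, 1] <- 1
  b <- gaussian_blur(stimulus_movie(d))
  expect_equal(sum(b$luminance), 1, tolerance = 1e-9)
  expect_equal(which(b$luminance == max(b$luminance), arr.ind = TRUE)[1, 1:2],
               c(dim1 = 11, dim2 = 21))
  # unit-peak mode keeps the dot's amplitude
  bp <- gaussian_blur(stimulus_movie(d), normalize = "peak")
  expect_equal(max(bp$luminance), 1, tolerance = 1e-9)
  # smoothing reduces the variance of a noise frame
  set.seed(9)
  w <- stimulus_movie(array(stats::runif(30 * 30), c(30L, 30L, 1L)))
  expect_lt(stats::var(as.vector(gaussian_blur(w)$luminance)),
            stats::var(as.vector(w$luminance)))
})

test_that("dot kinematograms conserve dots and honour coherence", {
  # unblurred field: every dot is one bright pixel (minus collisions)
  d <- make_dots(0.37, n_dots = 100L, dims = c(60L, 60L, 20L),
                 schedule = NULL, seed = 21, blur = FALSE)
  counts <- apply(d$luminance, 3, sum)
  expect_true(all(counts <= 100))
  expect_true(all(counts >= 90))   # few collisions on a 60x60 grid
  expect_true(all(d$luminance %in% c(0, 1)))
  # fixed coherent membership: round(c * N)
  expect_equal(round(0.37 * 100), 37)
  # full coherence with speed = 1 px/frame: the pattern translates rigidly
  dc <- make_dots(1, n_dots = 50L, speed = 0.9 / 0.01,
                  dims = c(40L, 40L, 10L), schedule = NULL, seed = 4,
                  blur = FALSE)
  l <- dc$luminance
  for (k in 1:9) {
    rolled <- l[c(40, 1:39), , k]   # shift one pixel rightward, wrapped
    expect_identical(rolled, l[, , k + 1])
  }
  # determinism and blurred range
  b1 <- make_dots(0.5, n_dots = 60L, dims = c(50L, 50L, 10L), seed = 8,
                  schedule = NULL)
  b2 <- make_dots(0.5, n_dots = 60L, dims = c(50L, 50L, 10L), seed = 8,
                  schedule = NULL)
  expect_identical(b1$luminance, b2$luminance)
  expect_gte(min(b1$luminance), 0)
  expect_lte(max(b1$luminance), 1)
  expect_error(make_dots(1.2), "coherence")
})
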