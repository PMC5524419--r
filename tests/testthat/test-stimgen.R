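test_that("geometry validation rejects degenerate configurations", {
  expect_s3_class(display_geometry(), "sb_geometry")
  expect_error(display_geometry(n_frames = 1), "n_frames")
  expect_error(display_geometry(noise_lo = 50, noise_hi = 14), "noise_lo")
  expect_error(display_geometry(signal_increment = 0), "signal_increment")
  expect_error(display_geometry(frame_rate = -1), "frame_rate")
})

test_that("noiseless signal has crossing trajectories with the stated increment", {
  geom <- test_geom()
  for (pol in c("light", "dark")) {
    sig <- make_signal(geom, pol)
    mask <- attr(sig, "trajectory_mask")
    expect_identical(dim(unclass(sig)), c(20L, 20L))
    # bars start at the two opposite edges on frame 1
    expect_identical(which(mask[1, ] > 0), c(1L, 20L))
    # leftward trajectory mirrors the rightward one
    expect_identical(mask, mask[, 20:1])
    # one column per frame each, never co-occupying
    expect_true(all(rowSums(mask) == 2))
    expect_true(all(mask %in% 0:1))
    # on-trajectory deviation is exactly +/- 50 cd/m^2
    dev <- unclass(sig) - geom$background_luminance
    sgn <- if (pol == "light") 1 else -1
    expect_equal(dev[mask == 1], rep(sgn * 50, sum(mask)))
    expect_equal(dev[mask == 0], rep(0, sum(mask == 0)))
  }
  # trajectories cross at the display centre: adjacent columns at frames 10/11
  mask <- attr(make_signal(geom), "trajectory_mask")
  expect_identical(which(mask[10, ] > 0), c(10L, 11L))
  expect_identical(which(mask[11, ] > 0), c(10L, 11L))
})

test_that("noise fields are bounded, uniform and seed-reproducible", {
  geom <- test_geom()
  for (s in c(1L, 99L)) {
    nz <- make_noise(geom, s)
    expect_gte(min(nz), 14.6)
    expect_lte(max(nz), 48.3)
  }
  expect_identical(make_noise(geom, 7L), make_noise(geom, 7L))
  expect_false(identical(unclass(make_noise(geom, 7L)),
                         unclass(make_noise(geom, 8L))))
  # moments of the uniform draw at n = 10^6 samples
  big <- make_display_batch(2500L, geom, seed = 3L)  # 10^6 cells
  mask3 <- array(attr(big, "trajectory_mask"), dim = dim(big))
  nz <- big[mask3 == 0]  # off-trajectory cells are pure noise
  n <- length(nz)
  mid <- (14.6 + 48.3) / 2
  v <- (48.3 - 14.6)^2 / 12
  expect_lt(abs(mean(nz) - mid), 3 * sqrt(v / n))
  # var of the sample variance of a uniform: (m4 - v^2 (n-3)/(n-1)) / n
  m4 <- (48.3 - 14.6)^4 / 80
  expect_lt(abs(var(nz) - v), 3 * sqrt((m4 - v^2) / n))
})

test_that("composition adds the increment on-trajectory and nothing elsewhere", {
  geom <- test_geom()
  sig <- make_signal(geom, "light")
  nz <- make_noise(geom, 11L)
  d <- compose_display(sig, nz)
  mask <- attr(sig, "trajectory_mask")
  expect_equal(unclass(d)[mask == 0], unclass(nz)[mask == 0])
  expect_equal(unclass(d)[mask == 1], unclass(nz)[mask == 1] + 50)
  expect_true(all(d >= 14.6 & d <= 48.3 + 50))
  # dark polarity flips the sign of the on/off luminance difference
  dd <- compose_display(make_signal(geom, "dark"), nz)
  on_off <- function(x) mean(unclass(x)[mask == 1]) - mean(unclass(x)[mask == 0])
  expect_equal(on_off(d) - on_off(nz), 50)
  expect_equal(on_off(dd) - on_off(nz), -50)
  expect_error(compose_display(sig, matrix(0, 10, 10)), "shape")
})

test_that("left-right mirroring of a composed display swaps the trajectories", {
  geom <- test_geom()
  nz <- make_noise(geom, 23L)
  d <- compose_display(make_signal(geom), nz)
  mirrored_noise <- structure(unclass(nz)[, 20:1], geometry = geom, seed = 23L)
  dm <- compose_display(make_signal(geom), mirrored_noise)
  expect_equal(unclass(dm), unclass(d)[, 20:1], ignore_attr = TRUE)
})

test_that("display batches are bit-reproducible under the seed", {
  geom <- test_geom()
  b1 <- make_display_batch(5L, geom, "light", seed = 42L)
  b2 <- make_display_batch(5L, geom, "light", seed = 42L)
  expect_identical(b1, b2)
  expect_false(identical(unclass(b1),
                         unclass(make_display_batch(5L, geom, seed = 43L))))
})

test_that("kernel disambiguation is linear and validated", {
  geom <- test_geom()
  d <- compose_display(make_signal(geom), make_noise(geom, 2L))
  K <- scale_kernel(matrix(rnorm(400), 20, 20))
  expect_equal(unclass(disambiguate_display(d, K, gain = 0)), unclass(d))
  expect_equal(unclass(disambiguate_display(d, K, sign = -1)),
               unclass(disambiguate_display(d, -K, sign = 1)))
  expect_error(disambiguate_display(d, matrix(0, 5, 5)), "shape")
  expect_error(disambiguate_display(d, K * NA), "finite")
  expect_error(disambiguate_display(d, K, sign = 2), "sign")
})

test_that("high/low energy stimulus sets are paired and validated", {
  geom <- test_geom()
  K <- scale_kernel(smooth_kernel(attr(make_signal(geom), "trajectory_mask")))
  st <- make_exp2_stimuli(4L, list(light = K), geometry = geom, seed = 6L)
  expect_named(st, "light")
  expect_identical(dim(st$light$HI), c(20L, 20L, 4L))
  # HI and LO share base displays: midpoint recovers the base
  expect_equal(st$light$HI - st$light$LO,
               array(2 * 50 * as.numeric(K), dim = c(20, 20, 4)),
               ignore_attr = TRUE)
  g0 <- make_exp2_stimuli(3L, list(light = K), geometry = geom, gain = 0,
                          seed = 6L)
  expect_equal(g0$light$HI, g0$light$LO, ignore_attr = TRUE)
  expect_error(make_exp2_stimuli(3L, list(light = K), polarities = "dark"),
               "polarity 'dark'")
})
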