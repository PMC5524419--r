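test_that("classification images implement the difference-of-templates rule", {
  # two classes with identical per-cell means give a null luminance kernel
  X <- array(0, c(2, 2, 4))
  X[, , 1] <- 1; X[, , 2] <- 3    # bounce mean 2
  X[, , 3] <- 0; X[, , 4] <- 4    # stream mean 2
  kp <- classification_images(X, c(1, 1, 0, 0))
  expect_equal(kp$K_L, matrix(0, 2, 2))
  # but the contrast kernel sees the different spreads (1 vs 4)
  expect_equal(kp$K_C, matrix(1 - 4, 2, 2))
  # one trial per class reduces to an elementwise difference
  Y <- array(rnorm(8), c(2, 2, 2))
  kp1 <- classification_images(Y, c(1, 0))
  expect_equal(kp1$K_L, Y[, , 1] - Y[, , 2])
  expect_equal(kp1$K_C, matrix(0, 2, 2))
  expect_identical(kp1$n_bounce, 1L)
  # empty classes raise errors naming the class
  expect_error(classification_images(Y, c(1, 1)), "stream")
  expect_error(classification_images(Y, c(0, 0)), "bounce")
  expect_error(classification_images(Y, c(1, 2)), "binary")
})

test_that("label swap negates both kernels and constants cancel", {
  st <- make_display_batch(60L, test_geom(), seed = 31L)
  resp <- with_test_seed(32L, rbinom(60, 1, 0.5))
  kp <- classification_images(st, resp)
  ks <- classification_images(st, 1 - resp)
  expect_equal(ks$K_L, -kp$K_L)
  expect_equal(ks$K_C, -kp$K_C)
  kc <- classification_images(st + 17.3, resp)
  expect_equal(kc$K_L, kp$K_L, tolerance = 1e-10)
  expect_equal(kc$K_C, kp$K_C, tolerance = 1e-10)
})

test_that("kernels match the per-cell brute-force oracle", {
  st <- make_display_batch(50L, test_geom(), seed = 33L)
  resp <- with_test_seed(34L, rbinom(50, 1, 0.4))
  kp <- classification_images(st, resp)
  oracle <- direct_classification_images(st, resp)
  expect_lt(rel_err(kp$K_L, oracle$K_L), 1e-12)
  expect_lt(rel_err(kp$K_C, oracle$K_C), 1e-12)
})

test_that("kernel smoothing applies the printed 3x3 low-pass filter", {
  # interior unit impulse reproduces the filter taps
  K <- matrix(0, 5, 5); K[3, 3] <- 1
  sm <- smooth_kernel(K)
  expect_equal(sm[2:4, 2:4], streambounce:::kernel_smoothing_filter())
  expect_equal(sum(sm), 5.76)  # 4*0.49 + 4*0.7 + 1
  # constant interior region scales by the filter sum
  C <- matrix(2, 7, 7)
  expect_equal(smooth_kernel(C)[4, 4], 2 * 5.76)
  # smoothing then range-scaling is invariant to positive global rescaling
  K2 <- matrix(rnorm(100), 10, 10)
  expect_equal(scale_kernel(smooth_kernel(3.7 * K2)),
               scale_kernel(smooth_kernel(K2)))
  # replicate boundary keeps a constant field constant
  expect_equal(smooth_kernel(C, boundary = "replicate"),
               matrix(2 * 5.76, 7, 7))
})

test_that("range scaling normalizes the peak and preserves signs", {
  K <- matrix(c(-4, 2, 1, -0.5), 2, 2)
  s <- scale_kernel(K)
  expect_equal(max(abs(s)), 1)
  expect_equal(sign(s), sign(K))
  expect_equal(scale_kernel(s), s)             # idempotent
  expect_error(scale_kernel(matrix(0, 2, 2)), "all-zero")
})

test_that("conditional kernels split correctly and re-pool to the overall kernel", {
  # an observer with a strong visual weight, so the per-level kernels are
  # well resolved at a few thousand trials
  oc <- observer_config(omega_me = 1.5, omega_a = 0.7, omega_r = 0.3,
                        n_trials = 4160L, seed = 35L)
  ses <- simulate_session(oc, bank = test_bank())
  tr <- ses$trials
  used <- which(!tr$excluded)
  X <- array(ses$stimuli[, , used], c(20, 20, length(used)))
  tru <- tr[used, ]
  ck <- conditional_kernels(X, tru, split = "sound", smooth = FALSE,
                            scale = FALSE)
  expect_named(ck, c("0", "1"))
  # re-pooling the split classes reproduces the overall kernel
  overall <- classification_images(X, tru$response)
  n0 <- ck$`0`$n_bounce + ck$`0`$n_stream
  n1 <- ck$`1`$n_bounce + ck$`1`$n_stream
  expect_identical(n0 + n1, nrow(tru))
  # sound and no-sound kernels share the visual template (same generating
  # weights): positive correlation between the split luminance kernels
  expect_gt(kernel_correlation(ck$`0`$K_L, ck$`1`$K_L), 0.3)
  # a constant split column is an empty-level error
  tr2 <- tru
  tr2$sound <- 1
  expect_error(conditional_kernels(X, tr2, split = "sound"), "empty")
})

test_that("kernel correlation and its permutation test behave canonically", {
  K <- matrix(rnorm(400), 20, 20)
  expect_equal(kernel_correlation(K, K), 1)
  expect_equal(kernel_correlation(K, -K), -1)
  expect_error(kernel_correlation(K, matrix(0, 20, 20)), "zero-variance")
  expect_error(kernel_correlation(K, matrix(1, 5, 5)), "shape")
  pt <- permutation_test(K, K, n_iter = 1000L, seed = 2L)
  expect_lte(pt$p_value, 2 / 1001)
  expect_true(pt$significant)
  expect_gt(pt$threshold, 0)
  expect_error(permutation_test(K, K, n_iter = 10L), "1000")
  # permuting both kernels identically leaves the observed rho unchanged
  idx <- with_test_seed(3L, sample.int(400))
  expect_equal(kernel_correlation(matrix(K[idx], 20), matrix(K[idx], 20)),
               kernel_correlation(K, K))
})
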