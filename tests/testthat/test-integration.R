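test_that("attach_energy aligns trials with stimuli", {
  geom <- test_geom()
  bank <- test_bank()
  st <- make_display_batch(6L, geom, seed = 41L)
  tr <- data.frame(response = rep(0:1, 3), sound = 0, previous_response = 0)
  tr2 <- attach_energy(tr, st, bank)
  expect_length(tr2$E_v, 6L)
  # duplicated stimulus layers receive identical energies
  dup <- array(st[, , c(1, 1, 2)], c(20, 20, 3))
  e3 <- attach_energy(tr[1:3, ], dup, bank)$E_v
  expect_equal(e3[1], e3[2])
  expect_error(attach_energy(tr[1:3, ], st, bank), "misaligned")
  # signal bars add coherent motion energy over a pure-noise field
  blank <- vapply(1:30, function(s) {
    nz <- make_noise(geom, s)
    energy_maps(unclass(nz), bank)$total_energy
  }, numeric(1))
  with_sig <- vapply(1:30, function(s) {
    d <- compose_display(make_signal(geom), make_noise(geom, s))
    energy_maps(unclass(d), bank)$total_energy
  }, numeric(1))
  expect_gt(mean(with_sig), mean(blank))
})

test_that("probit predictions follow the cumulative normal link", {
  tr <- quick_trials(n = 2000L, seed = 8L)
  fit <- fit_probit(tr)
  grid <- data.frame(E_v = c(-2, -1, 0, 1, 2), sound = 0,
                     previous_response = 0)
  pr <- predict_bounce(fit, grid)
  expect_equal(pr$p, pnorm(pr$z))
  expect_true(all(diff(pr$p) > 0) == (fit$omega_me > 0))
  z0 <- -fit$omega0 / fit$omega_me
  pr0 <- predict_bounce(fit, data.frame(E_v = z0, sound = 0,
                                        previous_response = 0))
  expect_equal(pr0$p, 0.5)
})

test_that("probit fitting recovers null and non-null coefficients", {
  # all-zero generating weights: estimates within 3 SE of zero
  tr0 <- quick_trials(n = 10000L, omega0 = 0, omega_me = 0, omega_a = 0,
                      omega_r = 0, seed = 44L)
  f0 <- fit_probit(tr0)
  se <- sqrt(diag(f0$coef_cov))
  expect_true(all(abs(f0$coefficients) < 3 * se))
  # AIC identity and covariance shape
  expect_equal(f0$aic, 2 * length(f0$coefficients) - 2 * f0$loglik)
  expect_true(isSymmetric(f0$coef_cov))
  expect_true(all(eigen(f0$coef_cov, only.values = TRUE)$values > 0))
  expect_error(fit_probit(tr0[tr0$response == 1, ]), "both response")
})

test_that("fitted log-likelihood matches an independent optimizer", {
  tr <- quick_trials(n = 200L, seed = 46L)
  fit <- fit_probit(tr)
  dat <- tr[!tr$excluded, ]
  nll <- function(b) {
    z <- b[1] + b[2] * dat$E_v + b[3] * dat$sound +
      b[4] * dat$previous_response
    -sum(dbinom(dat$response, 1, pnorm(z), log = TRUE))
  }
  op <- optim(rep(0, 4), nll, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(fit$loglik + op$value), 1e-6)
})

test_that("perfect separation is reported as an explicit error", {
  tr <- quick_trials(n = 2000L, seed = 47L)
  tr$response <- tr$sound  # sound predicts the response perfectly
  expect_error(fit_probit(tr), "separation")
  expect_warning(res <- fit_probit(tr, on_separation = "warn"), "separation")
  expect_s3_class(res, "sb_fit")
})

test_that("cross-validation partitions trials exactly once each", {
  tr <- quick_trials(n = 2000L, seed = 48L)
  cv <- cross_validate(tr, n_folds = 10L, seed = 1L)
  expect_identical(nrow(cv), sum(!tr$excluded))
  expect_identical(sort(unique(cv$fold)), 1:10)
  # block-based folds keep whole blocks together
  dat <- tr[!tr$excluded, ]
  expect_true(all(tapply(cv$fold, dat$block, function(f)
    length(unique(f))) == 1))
  expect_error(cross_validate(tr[1:20, ], n_folds = 39L), "fewer")
  # blockless tables fall back to seeded random folds
  tr2 <- tr[, setdiff(names(tr), c("block", "block_order", "excluded"))]
  cv2 <- cross_validate(tr2, n_folds = 5L, seed = 9L)
  cv2b <- cross_validate(tr2, n_folds = 5L, seed = 9L)
  expect_identical(cv2, cv2b)
})

test_that("calibration bins have equal counts and valid intervals", {
  tr <- quick_trials(n = 2600L, seed = 49L)
  cv <- cross_validate(tr, n_folds = 13L)
  cal <- calibration(cv$z, cv$response, n_bins = 25L)
  expect_identical(sum(cal$n), nrow(cv))
  expect_true(all(cal$p_obs >= 0 & cal$p_obs <= 1))
  expect_true(all(cal$ci_lo <= cal$ci_hi))
  expect_true(max(cal$n) - min(cal$n) <= 1)
  expect_error(calibration(cv$z[1:10], cv$response[1:10], n_bins = 50L),
               "fewer")
})

test_that("AIC comparison penalizes dropping a used predictor", {
  tr <- quick_trials(n = 6000L, omega_a = 1.2, seed = 50L)
  tab <- model_comparison(tr)
  expect_identical(nrow(tab), 8L)
  full <- tab$aic[tab$model == "me+sound+prev"]
  no_sound <- tab$aic[tab$model == "me+prev"]
  expect_gt(no_sound, full)
  # a useless extra predictor costs at most 2 AIC units beyond the deviance
  expect_lte(tab$aic[tab$model == "me+sound+prev (+pairwise interactions)"],
             full + 2 * 3)
})

test_that("chi-squared effect tests match the closed-form Pearson statistic", {
  tr <- data.frame(sound = rep(c(0, 1), each = 100),
                   previous_response = 0,
                   response = c(rep(c(0, 1), each = 50),
                                rep(c(0, 1), each = 50)))
  expect_equal(chi2_effect(tr, "sound")$chi2, 0)
  # hand-computed Pearson value for the table [[10,20],[30,40]]
  tr2 <- data.frame(
    sound = rep(c(0, 0, 1, 1), c(10, 20, 30, 40)),
    previous_response = 0,
    response = rep(c(0, 1, 0, 1), c(10, 20, 30, 40)))
  o <- c(10, 20, 30, 40)
  n <- 100
  e <- outer(c(30, 70), c(40, 60)) / n
  expect_equal(chi2_effect(tr2, "sound")$chi2,
               sum((matrix(o, 2, byrow = TRUE) - e)^2 / e))
  tr3 <- tr2
  tr3$response <- 1
  expect_error(chi2_effect(tr3, "sound"), "degenerate")
})

test_that("repeated-measures ANOVA matches aov and handles degenerate input", {
  df <- expand.grid(subject = 1:8, motion_energy = c("HI", "LO"),
                    luminance = c("light", "dark"))
  df$z <- with_test_seed(51L,
    rnorm(nrow(df)) + ifelse(df$motion_energy == "HI", 0.7, 0))
  res <- rm_anova_2x2(df)
  ref <- summary(aov(z ~ motion_energy * luminance +
                       Error(factor(subject) / (motion_energy * luminance)),
                     data = df))
  ref_F <- c(ref[[2]][[1]]["motion_energy", "F value"],
             ref[[3]][[1]]["luminance", "F value"],
             ref[[4]][[1]]["motion_energy:luminance", "F value"])
  expect_equal(res$F, ref_F, tolerance = 1e-10)
  expect_true(all(res$df1 == 1) && all(res$df2 == 7))
  # identical condition means per subject: all F = 0
  df0 <- df
  df0$z <- rep(rnorm(8), times = 4)  # constant within each subject
  res0 <- rm_anova_2x2(df0)
  expect_true(all(abs(res0$F) < 1e-20 | is.nan(res0$F)))
  expect_error(rm_anova_2x2(df[df$subject != 1 | df$luminance != "dark", ]),
               "missing")
})

test_that("z-scoring by subject centers and scales each subject", {
  df <- data.frame(subject = rep(1:3, each = 4),
                   p_bounce = c(runif(8), rep(0.5, 4)))
  z <- zscore_by_subject(df)
  expect_equal(as.numeric(tapply(z$z, z$subject, mean)), rep(0, 3))
  expect_equal(as.numeric(tapply(z$z, z$subject, sd))[1:2], rep(1, 2))
  expect_equal(z$z[df$subject == 3], rep(0, 4))  # constant subject maps to 0
})
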