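#' Configuration of a synthetic stream-bounce observer
#'
#' Generating coefficients and session design for a simulated observer who
#' responds according to the probit-linked linear integration model:
#' `Z = omega0 + omega_me * e + omega_a * sound + omega_r * prev`,
#' `response ~ Bernoulli(Phi(Z))`, where `e` is the session-standardized
#' total motion energy of the display (so `omega_me` is expressed per
#' standard deviation of the energy distribution and is portable across
#' normalization settings).
#'
#' The default coefficients were calibrated analytically (mean-field probit
#' inversion) to the experiment's marginal statistics: roughly 27% bounce
#' reports without sound, 61% with sound, 43% overall, with a strong
#' tendency to repeat the previous report. Sessions are organized in blocks
#' of `block_length` trials with sound present on alternating blocks
#' (starting without sound).
#'
#' @param omega0 Decision criterion (default -0.81).
#' @param omega_me Weight of standardized motion energy (default 0.35).
#' @param omega_a Weight of sound presence (default 0.74).
#' @param omega_r Weight of the previous report (default 0.6).
#' @param n_trials Trials per session; must be divisible by `block_length`
#'   when `sound_blocked` (default 10400, i.e. 260 blocks).
#' @param block_length Trials per block (default 40).
#' @param sound_blocked Alternate sound over blocks (default TRUE); if FALSE
#'   sound is absent throughout.
#' @param polarity Bar polarity of the displays.
#' @param seed Session seed.
#' @return An object of class `sb_observer_config`.
#' @export
observer_config <- function(omega0 = -0.81, omega_me = 0.35,
                            omega_a = 0.74, omega_r = 0.6,
                            n_trials = 10400L, block_length = 40L,
                            sound_blocked = TRUE,
                            polarity = c("light", "dark"), seed = 1L) {
  polarity <- match.arg(polarity)
  cf <- c(omega0, omega_me, omega_a, omega_r)
  if (!all(is.finite(cf))) stop("coefficients must be finite", call. = FALSE)
  if (sound_blocked && n_trials %% block_length != 0L) {
    stop("n_trials must be divisible by block_length for a blocked schedule",
         call. = FALSE)
  }
  out <- list(omega0 = omega0, omega_me = omega_me, omega_a = omega_a,
              omega_r = omega_r, n_trials = as.integer(n_trials),
              block_length = as.integer(block_length),
              sound_blocked = sound_blocked, polarity = polarity,
              seed = as.integer(seed))
  class(out) <- "sb_observer_config"
  out
}

#' Simulate a complete experimental session
#'
#' Draws one noisy display per trial, computes its total motion energy,
#' forms the integration model's decision variable (using the previous
#' simulated response within the block; the first trial of a block uses a
#' fair-coin previous response and is flagged excluded from modeling), and
#' samples the report from `Bernoulli(Phi(Z))`. Identical seeds give
#' identical sessions.
#'
#' @param config An [observer_config()].
#' @param bank An [me_filter_bank()]; built from `geometry` when NULL.
#' @param geometry Display geometry (default [display_geometry()]).
#' @param observer Observer label stored in the trial table (default 1).
#' @param energies Optional precomputed per-trial total motion energies; when
#'   supplied, no stimuli are generated (useful for large simulation studies
#'   where one stimulus pool is shared) and `stimuli` is NULL on output.
#' @param normalize Passed to the motion-energy computation.
#' @param return_stimuli Keep the stimulus array in the result (default
#'   TRUE).
#' @return A list with `stimuli` (3-D array or NULL) and `trials`, a
#'   data.frame with columns `observer`, `sound`, `previous_response`,
#'   `block`, `block_order`, `response`, `reaction_time`, `E_v`, `E_std`,
#'   `excluded`.
#' @export
simulate_session <- function(config, bank = NULL,
                             geometry = display_geometry(), observer = 1L,
                             energies = NULL, normalize = FALSE,
                             return_stimuli = TRUE) {
  stopifnot(inherits(config, "sb_observer_config"))
  n <- config$n_trials
  stimuli <- NULL
  if (is.null(energies)) {
    if (is.null(bank)) bank <- me_filter_bank(geometry)
    stimuli <- make_display_batch(n, bank$geometry, config$polarity,
                                  seed = config$seed)
    energies <- motion_energy_batch(stimuli, bank,
                                    normalize = normalize)$total_energy
  } else {
    stopifnot(length(energies) == n)
  }
  e_std <- (energies - mean(energies)) / stats::sd(energies)

  bl <- config$block_length
  n_blocks <- ceiling(n / bl)
  block <- rep(seq_len(n_blocks), each = bl)[seq_len(n)]
  block_order <- (seq_len(n) - 1L) %% bl + 1L
  sound <- if (config$sound_blocked) (block + 1L) %% 2L else rep(0L, n)

  resp <- integer(n)
  prev <- integer(n)
  rt <- numeric(n)
  with_seed(config$seed + 1L, {
    for (i in seq_len(n)) {
      prev[i] <- if (block_order[i] == 1L) stats::rbinom(1L, 1L, 0.5)
                 else resp[i - 1L]
      z <- config$omega0 + config$omega_me * e_std[i] +
        config$omega_a * sound[i] + config$omega_r * prev[i]
      resp[i] <- stats::rbinom(1L, 1L, stats::pnorm(z))
      rt[i] <- stats::rlnorm(1L, meanlog = log(0.6), sdlog = 0.3)
    }
  })
  trials <- data.frame(
    observer = observer, sound = sound, previous_response = prev,
    block = block, block_order = block_order, response = resp,
    reaction_time = rt, E_v = energies, E_std = e_std,
    excluded = block_order == 1L)
  list(stimuli = if (return_stimuli) stimuli else NULL, trials = trials)
}

#' Model-derived classification images via a motion-energy median split
#'
#' Emulates the kernel-derivation step of the polarity experiment: generate
#' `n_stimuli` noisy displays of the given polarity, compute each display's
#' total motion energy, label the upper half of the energy distribution as
#' "bounce" and the lower half as "stream", and run the classification-image
#' pipeline on these pseudo-responses. The deposited procedure used 400,000
#' displays; 20,000 gives stable kernels at desk scale and is the default.
#'
#' @param n_stimuli Even number of displays (>= 2000 recommended).
#' @param polarity `"light"` or `"dark"`.
#' @param bank An [me_filter_bank()].
#' @param seed Seed for the display batch.
#' @param normalize Passed to [motion_energy_batch()].
#' @param ... Passed to [estimate_kernels()] (smoothing/scaling switches).
#' @return An `sb_kernels` object (smoothed and range-scaled by default).
#' @export
simulate_exp2_kernels <- function(n_stimuli = 20000L,
                                  polarity = c("light", "dark"),
                                  bank = me_filter_bank(), seed = 1L,
                                  normalize = FALSE, ...) {
  polarity <- match.arg(polarity)
  if (n_stimuli %% 2L != 0L || n_stimuli < 2L) {
    stop("n_stimuli must be even and >= 2", call. = FALSE)
  }
  stims <- make_display_batch(n_stimuli, bank$geometry, polarity, seed = seed)
  te <- motion_energy_batch(stims, bank, normalize = normalize)$total_energy
  med <- stats::median(te)
  if (stats::sd(te) == 0) stop("degenerate energy distribution", call. = FALSE)
  # upper half = bounce; rank-based so the split is exactly 50/50 under ties
  pseudo <- as.integer(rank(te, ties.method = "first") > n_stimuli / 2)
  kp <- estimate_kernels(stims, pseudo, ...)
  attr(kp, "median_energy") <- med
  attr(kp, "polarity") <- polarity
  kp
}

#' Simulate the 2 x 2 motion-energy x luminance experiment
#'
#' Runs synthetic subjects through the four conditions of the polarity
#' experiment: HI and LO motion-energy displays built by adding/subtracting
#' the model-derived luminance kernels ([make_exp2_stimuli()]), with light
#' and dark bars. Each subject responds via the integration model with an
#' individual criterion jitter (`Z = omega0 + subject intercept +
#' omega_me * e`; no sound is played and no sequential memory is simulated
#' in this short task). Per-subject bounce probabilities are z-scored across
#' the four conditions, ready for [rm_anova_2x2()].
#'
#' @param n_subjects Number of subjects (default 10).
#' @param trials_per_condition Trials per condition and subject (default 32).
#' @param config An [observer_config()] providing `omega0` and `omega_me`.
#' @param kernels Named list of luminance kernels per polarity; derived via
#'   [simulate_exp2_kernels()] (at `kernel_stimuli` displays each) when NULL.
#' @param kernel_stimuli Displays used to derive each kernel (default 20000).
#' @param bank An [me_filter_bank()].
#' @param gain Kernel gain in cd/m^2 (default: the geometry's signal
#'   increment).
#' @param subject_sd SD of the per-subject criterion jitter (default 0.2).
#' @param seed Experiment seed.
#' @param normalize Passed to the energy computations.
#' @return A data.frame with one row per subject x condition: `subject`,
#'   `motion_energy` ("HI"/"LO"), `luminance` ("light"/"dark"), `p_bounce`,
#'   `z`.
#' @export
simulate_exp2_experiment <- function(n_subjects = 10L,
                                     trials_per_condition = 32L,
                                     config = observer_config(),
                                     kernels = NULL,
                                     kernel_stimuli = 20000L,
                                     bank = me_filter_bank(),
                                     gain = NULL, subject_sd = 0.2,
                                     seed = 1L, normalize = FALSE) {
  stopifnot(n_subjects >= 2L, trials_per_condition >= 1L)
  if (is.null(gain)) gain <- bank$geometry$signal_increment
  if (is.null(kernels)) {
    kernels <- list(
      light = simulate_exp2_kernels(kernel_stimuli, "light", bank,
                                    seed = seed, normalize = normalize)$K_L,
      dark = simulate_exp2_kernels(kernel_stimuli, "dark", bank,
                                   seed = seed + 1L,
                                   normalize = normalize)$K_L)
  }
  # one display set per subject x condition, energies standardized jointly
  sets <- list()
  labels <- list()
  for (s in seq_len(n_subjects)) {
    st <- make_exp2_stimuli(trials_per_condition, kernels,
                            geometry = bank$geometry, gain = gain,
                            seed = seed + 100L * s)
    for (pol in names(st)) {
      for (lev in c("HI", "LO")) {
        sets[[length(sets) + 1L]] <- as_stimulus_matrix(st[[pol]][[lev]])
        labels[[length(labels) + 1L]] <-
          data.frame(subject = s, motion_energy = lev, luminance = pol,
                     n = trials_per_condition)
      }
    }
  }
  X <- do.call(cbind, sets)
  lab <- do.call(rbind, labels)
  te <- motion_energy_batch(X, bank, normalize = normalize)$total_energy
  e_std <- (te - mean(te)) / stats::sd(te)
  idx_end <- cumsum(lab$n)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  res <- with_seed(seed + 7L, {
    icpt <- stats::rnorm(n_subjects, 0, subject_sd)
    p <- numeric(nrow(lab))
    for (r in seq_len(nrow(lab))) {
      e <- e_std[idx_start[r]:idx_end[r]]
      z <- config$omega0 + icpt[lab$subject[r]] + config$omega_me * e
      p[r] <- mean(stats::rbinom(length(e), 1L, stats::pnorm(z)))
    }
    p
  })
  out <- cbind(lab[, c("subject", "motion_energy", "luminance")],
               p_bounce = res)
  zscore_by_subject(out, value = "p_bounce", out = "z")
}
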