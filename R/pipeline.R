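#' Classification images predicted by a fitted integration model
#'
#' Feeds the trial predictors through the fitted model, samples one
#' classification response per trial from `Bernoulli(Phi(Z))` (reproducing
#' the response variability of a probabilistic observer; set
#' `threshold = TRUE` for deterministic 0.5-thresholding instead), and runs
#' the classification-image pipeline on these model responses.
#'
#' @param fit An `sb_fit` from [fit_probit()].
#' @param trials Trial table aligned with `stimuli`.
#' @param stimuli Stimulus container aligned with `trials`.
#' @param seed Seed for the response sampling.
#' @param threshold Use `Z > 0` instead of sampling (default FALSE).
#' @param shape Movie shape for flattened stimulus matrices.
#' @param ... Passed to [estimate_kernels()].
#' @return An `sb_kernels` object.
#' @export
model_kernels <- function(fit, trials, stimuli, seed = 1L,
                          threshold = FALSE, shape = NULL, ...) {
  z <- linear_predictor(fit, trials)
  resp <- if (threshold) {
    as.integer(z > 0)
  } else {
    with_seed(seed, stats::rbinom(length(z), 1L, stats::pnorm(z)))
  }
  if (length(unique(resp)) < 2L) {
    stop("model responses are all identical; cannot form kernels",
         call. = FALSE)
  }
  estimate_kernels(stimuli, resp, shape = shape, ...)
}

#' Full analysis of one stimulus + trial dataset
#'
#' The aggregate-observer analysis chain: bounce-rate summaries, chi-squared
#' effects of sound and previous response, the probit integration fit with
#' cross-validated calibration, AIC model comparison, empirical and
#' model-predicted classification images, and their pixel-by-pixel
#' correlation with permutation significance.
#'
#' @param stimuli 3-D stimulus array aligned with `trials`.
#' @param trials Trial table (columns as in [read_trial_table()] /
#'   [simulate_session()]).
#' @param bank An [me_filter_bank()].
#' @param n_folds Cross-validation folds (default 39).
#' @param n_bins Calibration bins (default 50).
#' @param n_perm Permutation iterations for kernel similarity (default
#'   20000).
#' @param seed Seed for model-response sampling, fold assignment and
#'   permutations.
#' @param normalize Passed to the motion-energy computation.
#' @return A list with `summary` (named numeric statistics), `fit`,
#'   `aic_table`, `calibration`, `kernels_empirical`, `kernels_model`, and
#'   the two permutation tests.
#' @export
analyze_dataset <- function(stimuli, trials, bank = me_filter_bank(),
                            n_folds = 39L, n_bins = 50L, n_perm = 20000L,
                            seed = 1L, normalize = FALSE) {
  if (is.null(trials$E_v)) {
    trials <- attach_energy(trials, stimuli, bank, normalize = normalize)
  }
  used <- modeling_rows(trials)
  chi_sound <- chi2_effect(trials, "sound")
  chi_prev <- chi2_effect(trials, "previous_response")
  fit <- fit_probit(trials)
  cv <- cross_validate(trials, n_folds = n_folds, seed = seed)
  cal <- calibration(cv$z, cv$response, n_bins = n_bins)
  aic_table <- model_comparison(trials)

  g <- bank$geometry
  shape <- c(g$n_frames, g$n_positions)
  X <- as_stimulus_matrix(stimuli, g)
  kern_emp <- estimate_kernels(X[, used, drop = FALSE],
                               trials$response[used], shape = shape)
  kern_mod <- model_kernels(fit, trials[used, , drop = FALSE],
                            X[, used, drop = FALSE], seed = seed,
                            shape = shape)
  perm_L <- permutation_test(kern_emp$K_L, kern_mod$K_L, n_iter = n_perm,
                             seed = seed)
  perm_C <- permutation_test(kern_emp$K_C, kern_mod$K_C, n_iter = n_perm,
                             seed = seed + 1L)

  summary <- c(
    n_trials = nrow(trials),
    bounce_rate_overall = 100 * mean(trials$response),
    bounce_rate_no_sound = 100 * mean(trials$response[trials$sound == 0]),
    bounce_rate_sound = 100 * mean(trials$response[trials$sound == 1]),
    chi2_sound = chi_sound$chi2,
    chi2_previous_response = chi_prev$chi2,
    omega0 = fit$omega0, omega_me = fit$omega_me,
    omega_a = fit$omega_a, omega_r = fit$omega_r,
    calibration_coverage = attr(cal, "coverage"),
    kernel_correlation_luminance = perm_L$rho,
    kernel_correlation_contrast = perm_C$rho,
    permutation_p_luminance = perm_L$p_value,
    permutation_p_contrast = perm_C$p_value,
    aic_best_is_main_effects =
      as.numeric(aic_table$model[1] == "me+sound+prev")
  )
  list(summary = summary, fit = fit, aic_table = aic_table,
       calibration = cal, kernels_empirical = kern_emp,
       kernels_model = kern_mod, perm_luminance = perm_L,
       perm_contrast = perm_C, trials = trials)
}

#' Reproduce the aggregate first-experiment analysis from deposited files
#'
#' Loads the deposited stimulus array and trial matrix, attaches motion
#' energy, and runs [analyze_dataset()] on the aggregate observer.
#'
#' @param stimulus_path Path to the stimulus MAT file.
#' @param trial_path Path to the trial-matrix MAT file.
#' @param ... Passed to [analyze_dataset()].
#' @return As [analyze_dataset()], plus the bundle `provenance`.
#' @export
reproduce_exp1 <- function(stimulus_path, trial_path, ...) {
  bundle <- read_dataset_bundle(stimulus_path, trial_path)
  out <- analyze_dataset(bundle$stimuli, bundle$trials, ...)
  out$provenance <- bundle$provenance
  out
}

#' Run a configured simulation-and-analysis pipeline
#'
#' Simulates one or more synthetic observers, pools them into an aggregate
#' dataset, and runs the full analysis chain. With an output directory, the
#' summary (JSON), kernels (TSV) and calibration table (TSV) are written,
#' together with the full seed configuration, so a run can be re-created
#' from its report alone.
#'
#' @param config List with elements `seed` (integer), `n_observers`,
#'   `n_trials` (per observer), optional generating coefficients `omega0`,
#'   `omega_me`, `omega_a`, `omega_r`, and optional `n_folds`, `n_bins`,
#'   `n_perm`, `out_dir`.
#' @return The [analyze_dataset()] result (invisibly if written to disk).
#' @export
run_pipeline <- function(config) {
  defaults <- list(seed = 1L, n_observers = 1L, n_trials = 2080L,
                   n_folds = 39L, n_bins = 50L, n_perm = 20000L,
                   out_dir = NULL)
  unknown <- setdiff(names(config),
                     c(names(defaults),
                       c("omega0", "omega_me", "omega_a", "omega_r")))
  if (length(unknown) > 0) {
    stop("unknown pipeline config entries: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  bank <- me_filter_bank()
  oc_args <- config[intersect(names(config),
                              c("omega0", "omega_me", "omega_a", "omega_r"))]
  stim_list <- list()
  trial_list <- list()
  for (o in seq_len(cfg$n_observers)) {
    oc <- do.call(observer_config,
                  c(oc_args, list(n_trials = cfg$n_trials,
                                  seed = cfg$seed + 1000L * o)))
    ses <- simulate_session(oc, bank = bank, observer = o)
    stim_list[[o]] <- as_stimulus_matrix(ses$stimuli)
    trial_list[[o]] <- ses$trials
  }
  stimuli <- do.call(cbind, stim_list)
  trials <- do.call(rbind, trial_list)
  # block ids must stay unique across observers for fold construction
  trials$block <- cumsum(c(TRUE, diff(trials$block) != 0 |
                             diff(trials$observer) != 0))
  res <- analyze_dataset(stimuli, trials, bank, n_folds = cfg$n_folds,
                         n_bins = cfg$n_bins, n_perm = cfg$n_perm,
                         seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = cfg[setdiff(names(cfg), "out_dir")],
           summary = as.list(res$summary)),
      file.path(cfg$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_kernel_tsv(file.path(cfg$out_dir, "kernel_luminance.tsv"),
                     res$kernels_empirical$K_L)
    write_kernel_tsv(file.path(cfg$out_dir, "kernel_contrast.tsv"),
                     res$kernels_empirical$K_C)
    utils::write.table(res$calibration,
                       file.path(cfg$out_dir, "calibration.tsv"),
                       sep = "\t", row.names = FALSE)
    return(invisible(res))
  }
  res
}
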