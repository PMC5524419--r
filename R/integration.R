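#' Attach total motion energy to a trial table
#'
#' Populates the `E_v` column (the visual covariate of the integration model)
#' by running the motion-energy model over the trial-aligned stimuli.
#'
#' @param trials Trial table whose rows align 1:1 with the stimulus layers.
#' @param stimuli 3-D stimulus array (frames x positions x trials).
#' @param bank An [me_filter_bank()].
#' @param normalize Passed to [motion_energy_batch()].
#' @return The trial table with an `E_v` column.
#' @export
attach_energy <- function(trials, stimuli, bank, normalize = FALSE) {
  X <- as_stimulus_matrix(stimuli, bank$geometry)
  if (ncol(X) != nrow(trials)) {
    stop("trials and stimuli are misaligned: ", nrow(trials), " rows vs ",
         ncol(X), " stimulus layers", call. = FALSE)
  }
  trials$E_v <- motion_energy_batch(X, bank, normalize = normalize)$total_energy
  trials
}

# rows used for modeling: drop the first trial of each block, whose previous
# response comes from outside the block
modeling_rows <- function(trials) {
  if (!is.null(trials$excluded)) return(!as.logical(trials$excluded))
  if (!is.null(trials$block_order)) return(trials$block_order >= 2)
  rep(TRUE, nrow(trials))
}

#' Fit the probit-linked linear integration model
#'
#' Maximum-likelihood Bernoulli fit with a probit link of the bounce report
#' on total visual motion energy, sound presence and the previous report:
#' `Z = omega0 + omega_me * E_v + omega_a * sound + omega_r * prev` and
#' `p(bounce) = Phi(Z)`. Coefficients are unconstrained (they mix weights and
#' scaling factors, so they need not sum to one). First-of-block trials are
#' excluded automatically when the table flags them.
#'
#' @param trials Trial table with columns `response`, `E_v`, `sound`,
#'   `previous_response` (and optionally `block_order` / `excluded`).
#' @param predictors Character subset of
#'   `c("E_v", "sound", "previous_response")` to include (default all).
#' @param interactions Add all pairwise interactions among the included
#'   predictors (default FALSE).
#' @param standardize_energy Center/scale `E_v` before fitting (default
#'   FALSE: the covariate enters raw).
#' @param on_separation `"stop"` (default) aborts on (quasi-)complete
#'   separation; `"warn"` keeps the fit.
#' @return An object of class `sb_fit`: coefficients (`omega0`, `omega_me`,
#'   `omega_a`, `omega_r` as applicable), their covariance `coef_cov`,
#'   `loglik`, `aic`, `n_trials`, the model `formula` and energy scaling info.
#' @export
fit_probit <- function(trials,
                       predictors = c("E_v", "sound", "previous_response"),
                       interactions = FALSE,
                       standardize_energy = FALSE,
                       on_separation = c("stop", "warn")) {
  on_separation <- match.arg(on_separation)
  predictors <- match.arg(predictors, several.ok = TRUE)
  dat <- trials[modeling_rows(trials), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no usable trials", call. = FALSE)
  if (length(unique(dat$response)) < 2L) {
    stop("both response values must be present", call. = FALSE)
  }
  for (p in predictors) {
    if (is.null(dat[[p]])) stop("trials have no column '", p, "'",
                                call. = FALSE)
    if (stats::sd(dat[[p]]) == 0) {
      stop("predictor '", p, "' is constant", call. = FALSE)
    }
  }
  e_center <- 0
  e_scale <- 1
  if (standardize_energy && "E_v" %in% predictors) {
    e_center <- mean(dat$E_v)
    e_scale <- stats::sd(dat$E_v)
    dat$E_v <- (dat$E_v - e_center) / e_scale
  }
  rhs <- paste(predictors, collapse = if (interactions) " * " else " + ")
  if (interactions && length(predictors) > 2L) {
    rhs <- paste0("(", paste(predictors, collapse = " + "), ")^2")
  }
  form <- stats::as.formula(paste("response ~", rhs))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(link = "probit"), data = dat),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("did not converge", msg)) {
        # surfaced below through the separation/convergence check
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged) {
    msg <- paste("probit fit shows (quasi-)complete separation or",
                 "non-convergence; coefficient estimates are unreliable")
    if (on_separation == "stop") stop(msg, call. = FALSE) else warning(msg,
      call. = FALSE)
  }
  cf <- stats::coef(fit)
  names(cf) <- rename_omega(names(cf))
  cv <- stats::vcov(fit)
  dimnames(cv) <- list(names(cf), names(cf))
  out <- list(coefficients = cf,
              omega0 = unname(cf["omega0"]),
              omega_me = if ("omega_me" %in% names(cf)) unname(cf["omega_me"]) else NA_real_,
              omega_a = if ("omega_a" %in% names(cf)) unname(cf["omega_a"]) else NA_real_,
              omega_r = if ("omega_r" %in% names(cf)) unname(cf["omega_r"]) else NA_real_,
              coef_cov = cv,
              loglik = as.numeric(stats::logLik(fit)),
              aic = stats::AIC(fit),
              n_trials = nrow(dat),
              formula = form, predictors = predictors,
              interactions = interactions,
              e_center = e_center, e_scale = e_scale)
  class(out) <- "sb_fit"
  out
}

rename_omega <- function(nm) {
  nm[nm == "(Intercept)"] <- "omega0"
  nm[nm == "E_v"] <- "omega_me"
  nm[nm == "sound"] <- "omega_a"
  nm[nm == "previous_response"] <- "omega_r"
  nm <- gsub("E_v", "me", nm, fixed = TRUE)
  nm <- gsub("previous_response", "prev", nm, fixed = TRUE)
  nm
}

#' @export
print.sb_fit <- function(x, ...) {
  cat(sprintf("probit integration model (n = %d trials)\n", x$n_trials))
  se <- sqrt(diag(x$coef_cov))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-12s % .4f  (SE %.4f)\n", nm, x$coefficients[nm], se[nm]))
  }
  cat(sprintf("  logLik %.2f, AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

# linear predictor Z for a trial table given an sb_fit
linear_predictor <- function(fit, trials) {
  z <- rep(fit$coefficients["omega0"], nrow(trials))
  terms <- setdiff(names(fit$coefficients), "omega0")
  col_of <- c(omega_me = "E_v", omega_a = "sound", omega_r = "previous_response")
  vals <- list(
    omega_me = if (!is.null(trials$E_v)) (trials$E_v - fit$e_center) / fit$e_scale,
    omega_a = trials$sound,
    omega_r = trials$previous_response)
  for (tm in terms) {
    if (tm %in% names(col_of)) {
      z <- z + fit$coefficients[tm] * vals[[tm]]
    } else {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      v <- rep(1, nrow(trials))
      for (p in parts) v <- v * vals[[p]]
      z <- z + fit$coefficients[tm] * v
    }
  }
  unname(z)
}

#' Predicted bounce probabilities
#'
#' Applies the probit link `p(bounce) = Phi(Z)` to the model's linear
#' predictor for each trial.
#'
#' @param fit An `sb_fit` from [fit_probit()].
#' @param trials Trial table with the predictor columns.
#' @return A data.frame with per-trial `z` and `p`.
#' @export
predict_bounce <- function(fit, trials) {
  stopifnot(inherits(fit, "sb_fit"))
  z <- linear_predictor(fit, trials)
  data.frame(z = z, p = stats::pnorm(z))
}

#' Cross-validated predictions of the integration model
#'
#' Partitions the usable trials into `n_folds` folds, fits the model on each
#' complement and predicts the held-out fold, so every trial is predicted
#' exactly once by a model that never saw it. When the table carries block
#' structure (`observer` x `block` ids), whole blocks are assigned to folds
#' round-robin; otherwise trials are assigned to random equal-size folds
#' under `seed`.
#'
#' @inheritParams fit_probit
#' @param n_folds Number of folds (default 39).
#' @param seed Seed for random fold assignment (blockless tables).
#' @return A data.frame with one row per usable trial: `fold`, `z`, `p`
#'   (held-out predictions) and `response`.
#' @export
cross_validate <- function(trials, n_folds = 39L, seed = 1L,
                           predictors = c("E_v", "sound", "previous_response"),
                           interactions = FALSE,
                           standardize_energy = FALSE) {
  dat <- trials[modeling_rows(trials), , drop = FALSE]
  n <- nrow(dat)
  if (n < n_folds) stop("fewer usable trials than folds", call. = FALSE)
  if (!is.null(dat$block)) {
    ids <- paste(if (is.null(dat$observer)) "" else dat$observer, dat$block)
    ublk <- unique(ids)
    fold_of_block <- ((seq_along(ublk) - 1L) %% n_folds) + 1L
    fold <- fold_of_block[match(ids, ublk)]
  } else {
    fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  }
  z <- numeric(n)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    ft <- fit_probit(dat[!test, , drop = FALSE], predictors = predictors,
                     interactions = interactions,
                     standardize_energy = standardize_energy)
    z[test] <- linear_predictor(ft, dat[test, , drop = FALSE])
  }
  data.frame(fold = fold, z = z, p = stats::pnorm(z),
             response = dat$response)
}

#' Calibration of predicted vs observed bounce probabilities
#'
#' Partitions trials into `n_bins` equal-count bins of the model response
#' `Z`, and compares the mean predicted `p(bounce)` per bin with the
#' observed bounce fraction. The 99% confidence interval about the predicted
#' value is binomial, using each bin's trial count.
#'
#' @param z Per-trial model response (e.g. from [cross_validate()]).
#' @param responses Per-trial binary reports aligned with `z`.
#' @param n_bins Number of bins (default 50).
#' @param level Confidence level of the interval (default 0.99).
#' @return A data.frame (class `sb_calibration`) with per-bin `n`, `z_mean`,
#'   `p_pred`, `p_obs`, `ci_lo`, `ci_hi` and an attribute `coverage`, the
#'   fraction of bins whose observed value falls inside the interval.
#' @export
calibration <- function(z, responses, n_bins = 50L, level = 0.99) {
  stopifnot(length(z) == length(responses))
  n <- length(z)
  if (n < n_bins) stop("fewer trials than bins", call. = FALSE)
  # equal-count bins on Z (rank-based; ties broken by order)
  bin <- ceiling(rank(z, ties.method = "first") * n_bins / n)
  alpha <- (1 - level) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- bin == b
    nb <- sum(idx)
    pp <- mean(stats::pnorm(z[idx]))
    data.frame(bin = b, n = nb, z_mean = mean(z[idx]), p_pred = pp,
               p_obs = mean(responses[idx]),
               ci_lo = stats::qbinom(alpha, nb, pp) / nb,
               ci_hi = stats::qbinom(1 - alpha, nb, pp) / nb)
  })
  out <- do.call(rbind, rows)
  attr(out, "coverage") <- mean(out$p_obs >= out$ci_lo & out$p_obs <= out$ci_hi)
  class(out) <- c("sb_calibration", "data.frame")
  out
}

#' AIC comparison of integration-model variants
#'
#' Fits every nonempty subset of the three predictors (motion energy, sound,
#' previous response) as main-effects models, plus the three-predictor model
#' with all pairwise interactions, and tabulates their AICs.
#'
#' @inheritParams fit_probit
#' @return A data.frame sorted by AIC: `model`, `k` (number of
#'   coefficients), `loglik`, `aic`, `delta_aic`.
#' @export
model_comparison <- function(trials, standardize_energy = FALSE) {
  preds <- c("E_v", "sound", "previous_response")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(preds, k, simplify = FALSE)), recursive = FALSE)
  specs <- c(lapply(subsets, function(s) list(predictors = s,
                                              interactions = FALSE)),
             list(list(predictors = preds, interactions = TRUE)))
  rows <- lapply(specs, function(sp) {
    label <- paste(sub("previous_response", "prev",
                       sub("E_v", "me", sp$predictors)), collapse = "+")
    if (sp$interactions) label <- paste0(label, " (+pairwise interactions)")
    ft <- tryCatch(
      fit_probit(trials, predictors = sp$predictors,
                 interactions = sp$interactions,
                 standardize_energy = standardize_energy,
                 on_separation = "warn"),
      error = function(e) e)
    if (inherits(ft, "error")) {
      return(data.frame(model = label, k = NA, loglik = NA, aic = NA,
                        note = conditionMessage(ft)))
    }
    data.frame(model = label, k = length(ft$coefficients),
               loglik = ft$loglik, aic = ft$aic, note = "")
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  rownames(out) <- NULL
  out
}

#' Chi-squared test of a binary factor's effect on the report
#'
#' Pearson chi-squared test (1 df, no continuity correction) of the 2 x 2
#' contingency table of bounce reports against sound presence or the
#' previous report. First-of-block trials are excluded when flagged.
#'
#' @param trials Trial table.
#' @param factor `"sound"` or `"previous_response"`.
#' @return List with `chi2`, `p`, and the contingency `table`.
#' @export
chi2_effect <- function(trials, factor = c("sound", "previous_response")) {
  factor <- match.arg(factor)
  dat <- trials[modeling_rows(trials), , drop = FALSE]
  tab <- table(factor = dat[[factor]], response = dat$response)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("degenerate 2x2 table: a level of '", factor,
         "' or of the response is empty", call. = FALSE)
  }
  ts <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ts$statistic), p = ts$p.value, table = tab)
}

#' Two-factor repeated-measures ANOVA (2 x 2, within subjects)
#'
#' Standard within-subject decomposition for a complete two-by-two design:
#' each effect's F is its mean square over the mean square of its
#' subject-by-effect interaction (df1 = 1, df2 = n_subjects - 1 each).
#' Responses are typically per-subject z-scored bounce probabilities (see
#' [zscore_by_subject()]).
#'
#' @param data Data.frame with columns `subject`, two binary within-subject
#'   factors named in `factors`, and the response `value`.
#' @param factors Character vector of the two factor column names.
#' @param value Name of the response column.
#' @return A data.frame with rows for the two main effects and the
#'   interaction: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(data, factors = c("motion_energy", "luminance"),
                         value = "z") {
  stopifnot(all(c("subject", factors, value) %in% names(data)))
  A <- factor(data[[factors[1]]])
  B <- factor(data[[factors[2]]])
  S <- factor(data$subject)
  if (nlevels(A) != 2L || nlevels(B) != 2L) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  if (nlevels(S) < 2L) stop("need at least two subjects", call. = FALSE)
  y <- data[[value]]
  if (anyNA(tapply(y, list(S, A, B), mean))) {
    stop("design has missing subject x condition cells", call. = FALSE)
  }
  # cell means per subject (collapses replicates within a cell), then the
  # full effect decomposition of the subjects x A x B table
  cell <- tapply(y, list(S, A, B), mean)
  ns <- nlevels(S)
  grand <- mean(cell)
  s_eff <- apply(cell, 1, mean) - grand
  a_eff <- apply(cell, 2, mean) - grand
  b_eff <- apply(cell, 3, mean) - grand
  ab_eff <- apply(cell, c(2, 3), mean) - grand -
    outer(a_eff, rep(1, 2)) - outer(rep(1, 2), b_eff)
  as_eff <- apply(cell, c(1, 2), mean) - grand -
    outer(s_eff, rep(1, 2)) - outer(rep(1, ns), a_eff)
  bs_eff <- apply(cell, c(1, 3), mean) - grand -
    outer(s_eff, rep(1, 2)) - outer(rep(1, ns), b_eff)
  resid <- cell - grand
  for (i in seq_len(ns)) for (j in 1:2) for (k in 1:2) {
    resid[i, j, k] <- resid[i, j, k] - s_eff[i] - a_eff[j] - b_eff[k] -
      ab_eff[j, k] - as_eff[i, j] - bs_eff[i, k]
  }
  ss_a <- 2 * ns * sum(a_eff^2)
  ss_b <- 2 * ns * sum(b_eff^2)
  ss_ab <- ns * sum(ab_eff^2)
  ss_as <- 2 * sum(as_eff^2)
  ss_bs <- 2 * sum(bs_eff^2)
  ss_abs <- sum(resid^2)
  df2 <- ns - 1L
  res <- data.frame(
    effect = c(factors[1], factors[2],
               paste(factors, collapse = ":")),
    F = c(ss_a / (ss_as / df2), ss_b / (ss_bs / df2),
          ss_ab / (ss_abs / df2)),
    df1 = 1L, df2 = df2)
  res$p <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  res
}

#' Z-score a response within each subject
#'
#' Normalizes per-subject condition scores (e.g. bounce probabilities) to
#' zero mean and unit variance across that subject's conditions, the usual
#' transformation before a within-subject ANOVA on probabilities.
#'
#' @param data Data.frame with a `subject` column.
#' @param value Column to transform.
#' @param out Name of the new column (default `"z"`).
#' @return `data` with the added column.
#' @export
zscore_by_subject <- function(data, value = "p_bounce", out = "z") {
  z <- stats::ave(data[[value]], data$subject,
                  FUN = function(v) {
                    s <- stats::sd(v)
                    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
                  })
  data[[out]] <- z
  data
}
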