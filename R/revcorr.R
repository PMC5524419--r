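#' Luminance and contrast classification images
#'
#' Estimates the space-time decision templates of an observer from noisy
#' displays and binary reports. For every space-time cell, the luminance
#' kernel is the difference of per-class mean luminance,
#' `K_L = mean(bounce) - mean(stream)`, and the contrast kernel is the
#' difference of per-class mean squared deviation from that class's own
#' per-cell mean, `K_C = MSE(bounce) - MSE(stream)`. Raw (unsmoothed,
#' unscaled) kernels are returned; see [smooth_kernel()] and
#' [scale_kernel()], or [estimate_kernels()] for the full pipeline.
#'
#' @param stimuli A 3-D array (frames x positions x trials) of noisy
#'   displays, or a flattened cells x trials matrix (then `shape` is
#'   required).
#' @param responses Binary vector (1 = bounce, 0 = stream), one per trial.
#' @param mse_reference `"class"` (default): contrast deviations are taken
#'   from each response class's own per-cell mean; `"grand"`: from the
#'   per-cell mean over all trials.
#' @param shape Movie shape `c(n_frames, n_positions)`; inferred from a 3-D
#'   array.
#' @return An object of class `sb_kernels`: list with matrices `K_L`, `K_C`,
#'   counts `n_bounce`, `n_stream`, and flags `smoothed`, `scaled`.
#' @export
classification_images <- function(stimuli, responses,
                                  mse_reference = c("class", "grand"),
                                  shape = NULL) {
  mse_reference <- match.arg(mse_reference)
  sx <- stimulus_trials(stimuli, length(responses), shape)
  X <- sx$X
  shape <- sx$shape
  responses <- as.numeric(responses)
  if (length(responses) != ncol(X)) {
    stop("stimuli and responses are misaligned: ", ncol(X), " trials vs ",
         length(responses), " responses", call. = FALSE)
  }
  if (!all(responses %in% c(0, 1))) {
    stop("responses must be binary (0 = stream, 1 = bounce)", call. = FALSE)
  }
  nb <- sum(responses == 1)
  ns <- sum(responses == 0)
  if (nb == 0L) stop("no trials in the 'bounce' response class", call. = FALSE)
  if (ns == 0L) stop("no trials in the 'stream' response class", call. = FALSE)

  Xb <- X[, responses == 1, drop = FALSE]
  Xs <- X[, responses == 0, drop = FALSE]
  mb <- rowMeans(Xb)
  ms <- rowMeans(Xs)
  if (mse_reference == "class") {
    mseb <- rowMeans((Xb - mb)^2)
    mses <- rowMeans((Xs - ms)^2)
  } else {
    mg <- rowMeans(X)
    mseb <- rowMeans((Xb - mg)^2)
    mses <- rowMeans((Xs - mg)^2)
  }
  out <- list(K_L = matrix(mb - ms, shape[1], shape[2]),
              K_C = matrix(mseb - mses, shape[1], shape[2]),
              n_bounce = nb, n_stream = ns,
              smoothed = FALSE, scaled = FALSE)
  class(out) <- "sb_kernels"
  out
}

# resolve a stimulus container + trial count into a cells x trials matrix
# plus the movie shape
stimulus_trials <- function(stimuli, n_trials, shape = NULL) {
  d <- dim(stimuli)
  if (length(d) == 3L) {
    return(list(X = matrix(stimuli, d[1] * d[2], d[3]), shape = d[1:2]))
  }
  if (length(d) == 2L) {
    if (!is.null(shape)) {
      if (prod(shape) != nrow(stimuli) || ncol(stimuli) != n_trials) {
        stop("flattened stimuli do not match `shape` / trial count",
             call. = FALSE)
      }
      return(list(X = unclass(stimuli), shape = shape))
    }
    if (n_trials == 1L) {
      return(list(X = matrix(stimuli, length(stimuli), 1L), shape = d))
    }
    stop("flattened stimulus matrices need an explicit `shape`",
         call. = FALSE)
  }
  stop("stimuli must be a matrix or 3-D array", call. = FALSE)
}

# the printed low-pass smoothing taps
kernel_smoothing_filter <- function() {
  matrix(c(0.49, 0.70, 0.49,
           0.70, 1.00, 0.70,
           0.49, 0.70, 0.49), 3, 3, byrow = TRUE)
}

#' Smooth a classification image
#'
#' 2-D convolution with the fixed 3 x 3 low-pass spatiotemporal filter
#' `[0.49, 0.7, 0.49; 0.70, 1.0, 0.70; 0.49, 0.7, 0.49]`, with "same"-size
#' output. Boundary cells use zero padding by default (irrelevant up to scale
#' once the kernel is range-scaled) or edge replication.
#'
#' @param K Kernel matrix.
#' @param boundary `"zero"` (default) or `"replicate"`.
#' @return The smoothed matrix.
#' @export
smooth_kernel <- function(K, boundary = c("zero", "replicate")) {
  boundary <- match.arg(boundary)
  if (!all(is.finite(K))) stop("kernel must be finite", call. = FALSE)
  nr <- nrow(K)
  nc <- ncol(K)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- K
  if (boundary == "replicate") {
    pad[1, 2:(nc + 1)] <- K[1, ]
    pad[nr + 2, 2:(nc + 1)] <- K[nr, ]
    pad[2:(nr + 1), 1] <- K[, 1]
    pad[2:(nr + 1), nc + 2] <- K[, nc]
    pad[1, 1] <- K[1, 1]; pad[1, nc + 2] <- K[1, nc]
    pad[nr + 2, 1] <- K[nr, 1]; pad[nr + 2, nc + 2] <- K[nr, nc]
  }
  f <- kernel_smoothing_filter()
  out <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      out <- out + f[di + 2, dj + 2] *
        pad[(2:(nr + 1)) - di, (2:(nc + 1)) - dj]
    }
  }
  out
}

#' Range-scale a classification image
#'
#' Divides by the maximum absolute value so that `max(abs(K)) == 1`,
#' preserving the sign pattern. Idempotent.
#'
#' @param K Kernel matrix, not all zero.
#' @return The scaled matrix.
#' @export
scale_kernel <- function(K) {
  m <- max(abs(K))
  if (!is.finite(m)) stop("kernel must be finite", call. = FALSE)
  if (m == 0) stop("cannot range-scale an all-zero kernel", call. = FALSE)
  K / m
}

#' Full classification-image pipeline
#'
#' Raw kernels ([classification_images()]), then smoothing
#' ([smooth_kernel()]), then range-scaling ([scale_kernel()]), in that order.
#'
#' @inheritParams classification_images
#' @param smooth,scale Logical switches for the two post-processing steps.
#' @param boundary Passed to [smooth_kernel()].
#' @return An `sb_kernels` object with flags set accordingly.
#' @export
estimate_kernels <- function(stimuli, responses, smooth = TRUE, scale = TRUE,
                             mse_reference = "class", boundary = "zero",
                             shape = NULL) {
  kp <- classification_images(stimuli, responses,
                              mse_reference = mse_reference, shape = shape)
  if (smooth) {
    kp$K_L <- smooth_kernel(kp$K_L, boundary)
    kp$K_C <- smooth_kernel(kp$K_C, boundary)
    kp$smoothed <- TRUE
  }
  if (scale) {
    kp$K_L <- scale_kernel(kp$K_L)
    kp$K_C <- scale_kernel(kp$K_C)
    kp$scaled <- TRUE
  }
  kp
}

#' @export
print.sb_kernels <- function(x, ...) {
  cat(sprintf(
    "classification images (%d x %d): %d bounce vs %d stream trials%s%s\n",
    nrow(x$K_L), ncol(x$K_L), x$n_bounce, x$n_stream,
    if (x$smoothed) ", smoothed" else "",
    if (x$scaled) ", range-scaled" else ""))
  invisible(x)
}

#' Classification images split by an experimental factor
#'
#' Runs the kernel pipeline separately on the two levels of a binary trial
#' factor (`sound` or `previous_response`), as used to ask whether the sound
#' or the previous report alters the visual decision template.
#'
#' @param stimuli Stimulus container aligned with `trials`.
#' @param trials A trial table (see [simulate_session()] /
#'   [read_trial_table()]) with columns `response` and the split factor.
#' @param split `"sound"` or `"previous_response"`.
#' @param shape Movie shape for flattened stimulus matrices.
#' @param ... Passed to [estimate_kernels()].
#' @return Named list of `sb_kernels`, one per factor level (`"0"`, `"1"`).
#' @export
conditional_kernels <- function(stimuli, trials,
                                split = c("sound", "previous_response"),
                                shape = NULL, ...) {
  split <- match.arg(split)
  fac <- trials[[split]]
  if (is.null(fac)) stop("trials have no column '", split, "'", call. = FALSE)
  sx <- stimulus_trials(stimuli, nrow(trials), shape)
  out <- list()
  for (lev in c(0, 1)) {
    idx <- which(fac == lev)
    if (length(idx) == 0L) {
      stop("split level '", split, " = ", lev, "' is empty", call. = FALSE)
    }
    out[[as.character(lev)]] <-
      estimate_kernels(sx$X[, idx, drop = FALSE], trials$response[idx],
                       shape = sx$shape, ...)
  }
  out
}

#' Pixel-by-pixel kernel correlation
#'
#' Pearson correlation between two kernels over their flattened cells.
#'
#' @param K1,K2 Kernel matrices of equal shape.
#' @return Correlation coefficient `rho`.
#' @export
kernel_correlation <- function(K1, K2) {
  if (!identical(dim(K1), dim(K2))) {
    stop("kernels must have equal shapes", call. = FALSE)
  }
  v1 <- as.numeric(K1)
  v2 <- as.numeric(K2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("kernel correlation undefined for a zero-variance kernel",
         call. = FALSE)
  }
  stats::cor(v1, v2)
}

#' Permutation test for kernel similarity
#'
#' Builds the null distribution of the pixel-by-pixel correlation by
#' randomly permuting the cells of `K2` (`n_iter` times) and correlating each
#' permuted kernel with `K1`. The two-sided p-value is the add-one-corrected
#' fraction of null correlations at least as large in magnitude as the
#' observed one; the significance threshold is the 95th percentile of the
#' absolute null correlations (the p = 0.05 bound for a two-sided test).
#'
#' @inheritParams kernel_correlation
#' @param n_iter Number of permutations (>= 1000; default 20000).
#' @param seed Seed for the permutations.
#' @return List with `rho`, `p_value`, `threshold` (p = 0.05 two-sided bound
#'   on `abs(rho)`), `n_iter` and `significant` (`abs(rho) > threshold`).
#' @export
permutation_test <- function(K1, K2, n_iter = 20000L, seed = 1L) {
  if (n_iter < 1000L) stop("n_iter must be at least 1000", call. = FALSE)
  rho <- kernel_correlation(K1, K2)
  v1 <- as.numeric(K1)
  v2 <- as.numeric(K2)
  nc <- length(v2)
  null_rho <- with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) stats::cor(v1, v2[sample.int(nc)]),
           numeric(1))
  })
  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_iter + 1)
  thr <- stats::quantile(abs(null_rho), 0.95, names = FALSE)
  list(rho = rho, p_value = p, threshold = thr, n_iter = n_iter,
       significant = abs(rho) > thr)
}
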