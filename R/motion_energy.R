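#' Spatiotemporal quadrature filter bank for motion energy
#'
#' Builds the filter bank of the opponent motion-energy model: even and odd
#' Gabor spatial filters paired with slow and fast biphasic temporal filters.
#' Spatial filters are `E(x) = cos(2*pi*f*x) * exp(-(x/sigma)^2)` and
#' `O(x) = sin(2*pi*f*x) * exp(-(x/sigma)^2)`; temporal filters are
#' `R(t) = (k*t)^n * exp(-k*t) * (1/n! - beta*(k*t)^2/(n+2)!)` with `n`
#' equal to `n_slow` for the slow filter and `n_fast` for the fast one.
#'
#' Filters share the stimulus' sampling resolution and extent: the temporal
#' grid is the movie's frame times (causal, first frame at t = 0) and the
#' spatial grid spans the display width at one sample per bar, centred on 0
#' (odd length, so the zero lag is on the grid). Convolution is zero-padded
#' with "same"-size output: causal in time, centred in space.
#'
#' @param geometry An [display_geometry()].
#' @param sigma Spatial constant of the Gabor envelope in degrees (0.5).
#' @param spatial_freq Gabor spatial frequency in cycles/degree (1.1).
#' @param k_rate Temporal frequency parameter `k` (100).
#' @param n_slow,n_fast Temporal order `n` of the slow (9) and fast (6)
#'   filters; `n_slow > n_fast` makes the fast filter peak earlier.
#' @param beta Weight of the negative temporal lobe (0.9).
#' @return An object of class `sb_me_bank` holding the parameters, the
#'   sampled filters, and precomputed convolution operators.
#' @export
me_filter_bank <- function(geometry = display_geometry(), sigma = 0.5,
                           spatial_freq = 1.1, k_rate = 100,
                           n_slow = 9L, n_fast = 6L, beta = 0.9) {
  validate_geometry(geometry)
  stopifnot(sigma > 0, spatial_freq > 0, k_rate > 0,
            n_slow > n_fast, n_fast >= 1, beta >= 0, beta <= 1)
  m <- floor(geometry$n_positions / 2)
  x <- (-m:m) * geom_bw(geometry)               # deg, odd length, includes 0
  t <- temporal_axis(geometry)                  # s, causal
  sf <- gabor_pair(x, spatial_freq, sigma)
  tf <- biphasic_pair(t, k_rate, n_slow, n_fast, beta)

  nf <- geometry$n_frames
  np <- geometry$n_positions
  A_slow <- temporal_conv_matrix(tf$slow, nf)
  A_fast <- temporal_conv_matrix(tf$fast, nf)
  B_even <- spatial_conv_matrix(sf$even, np, m)
  B_odd <- spatial_conv_matrix(sf$odd, np, m)

  bank <- list(
    geometry = geometry, sigma = sigma, spatial_freq = spatial_freq,
    k_rate = k_rate, n_slow = as.integer(n_slow),
    n_fast = as.integer(n_fast), beta = beta,
    spatial_grid = x, temporal_grid = t,
    even = sf$even, odd = sf$odd, slow = tf$slow, fast = tf$fast,
    A_slow = A_slow, A_fast = A_fast, B_even = B_even, B_odd = B_odd,
    # vectorised operators for batches: vec(A %*% S %*% B) = (t(B) %x% A) vec(S)
    M_es = kronecker(t(B_even), A_slow),
    M_ef = kronecker(t(B_even), A_fast),
    M_os = kronecker(t(B_odd), A_slow),
    M_of = kronecker(t(B_odd), A_fast)
  )
  class(bank) <- "sb_me_bank"
  bank
}

geom_bw <- function(geometry) geometry$bar_width

gabor_pair <- function(x, f, sigma) {
  if (length(x) == 0) stop("empty spatial grid", call. = FALSE)
  env <- exp(-(x / sigma)^2)
  list(even = cos(2 * pi * f * x) * env,
       odd = sin(2 * pi * f * x) * env)
}

biphasic_pair <- function(t, k, n_slow, n_fast, beta) {
  if (any(t < 0)) stop("temporal grid must be non-negative", call. = FALSE)
  R <- function(n) {
    kt <- k * t
    kt^n * exp(-kt) * (1 / factorial(n) - beta * kt^2 / factorial(n + 2))
  }
  list(slow = R(n_slow), fast = R(n_fast))
}

#' Sampled spatial filters of a bank
#'
#' @param bank An [me_filter_bank()].
#' @return A list with the `even` and `odd` Gabor filters and their grid `x`
#'   (degrees, centred on 0).
#' @export
spatial_filters <- function(bank) {
  stopifnot(inherits(bank, "sb_me_bank"))
  list(even = bank$even, odd = bank$odd, x = bank$spatial_grid)
}

#' Sampled temporal filters of a bank
#'
#' @param bank An [me_filter_bank()].
#' @return A list with the `slow` and `fast` biphasic filters and their grid
#'   `t` (seconds, starting at 0).
#' @export
temporal_filters <- function(bank) {
  stopifnot(inherits(bank, "sb_me_bank"))
  list(slow = bank$slow, fast = bank$fast, t = bank$temporal_grid)
}

# causal "same" convolution along time as an nf x nf matrix:
# (A s)[i] = sum_j r[j] s[i - j + 1]
temporal_conv_matrix <- function(r, nf) {
  A <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (l in seq_len(i)) A[i, l] <- r[i - l + 1]
  }
  A
}

# centred zero-padded "same" convolution along space as an np x np matrix:
# (s B)[p] = sum_q s[q] f[(p - q) + m + 1], filter taps at lags -m..m
spatial_conv_matrix <- function(f, np, m) {
  B <- matrix(0, np, np)
  for (q in seq_len(np)) {
    for (p in seq_len(np)) {
      lag <- p - q
      if (abs(lag) <= m) B[q, p] <- f[lag + m + 1]
    }
  }
  B
}

# The four separable filter responses of a mean-subtracted movie.
quadrature_responses <- function(S0, bank) {
  list(es = bank$A_slow %*% S0 %*% bank$B_even,
       ef = bank$A_fast %*% S0 %*% bank$B_even,
       os = bank$A_slow %*% S0 %*% bank$B_odd,
       of = bank$A_fast %*% S0 %*% bank$B_odd)
}

# Oriented quadrature pairs and directional energies; the sign arrangement is
# the canonical opponent-energy one, with labels fixed so that a bar moving
# towards larger column indices yields more `rightward` than `leftward`
# energy (verified by the direction-selectivity tests).
opponent_energies <- function(q) {
  r1 <- q$es - q$of
  r2 <- q$os + q$ef
  l1 <- q$es + q$of
  l2 <- q$ef - q$os
  rightward <- r1^2 + r2^2
  leftward <- l1^2 + l2^2
  list(rightward = rightward, leftward = leftward,
       opponent = rightward - leftward, flicker = rightward + leftward)
}

#' Motion-energy maps of one display
#'
#' Convolves the mean-subtracted movie with the four separable space-time
#' filters of the bank, combines them into direction-selective quadrature
#' pairs, and squares and sums the pair members to obtain rightward and
#' leftward energy maps. The opponent map is their difference. By default the
#' maps are reported raw, so that total motion energy tracks the display's
#' contrast energy; with `normalize = TRUE` all maps are divided by the
#' display's mean flicker energy (rightward + leftward, averaged over
#' space-time) plus a small epsilon, a divisive scheme that makes the result
#' invariant to global contrast scaling.
#'
#' Profiles of the absolute opponent map are returned per frame
#' (`space_profile`, averaged over positions) and per position
#' (`time_profile`, averaged over frames). The energy peak, dip and drop
#' (peak minus dip) are the extrema of the space-averaged profile over the
#' whole movie. Because the temporal filters are causal, the first frames of
#' any display carry near-zero energy (the filters have not yet ramped up);
#' the crossing of the trajectories shows as a pronounced local minimum a few
#' frames after the geometric crossing, lagged by the filters' time to peak.
#'
#' @param stimulus A stimulus movie (n_frames x n_positions matrix, cd/m^2).
#' @param bank An [me_filter_bank()] matching the stimulus geometry.
#' @param normalize Divide by mean flicker energy (default FALSE).
#' @return An object of class `sb_energy`: list with `rightward`, `leftward`,
#'   `opponent`, `flicker` maps, `total_energy` (mean of `abs(opponent)`),
#'   `space_profile`, `time_profile`, `energy_peak`, `energy_dip`,
#'   `energy_drop` and `normalized`.
#' @export
energy_maps <- function(stimulus, bank, normalize = FALSE) {
  stopifnot(inherits(bank, "sb_me_bank"))
  S <- unclass(stimulus)
  if (!all(is.finite(S))) stop("stimulus must be finite", call. = FALSE)
  g <- bank$geometry
  if (!identical(dim(S), c(g$n_frames, g$n_positions))) {
    stop("stimulus shape does not match the bank's geometry", call. = FALSE)
  }
  e <- opponent_energies(quadrature_responses(S - mean(S), bank))
  if (normalize) {
    denom <- mean(e$flicker)
    denom <- denom + 1e-6 * denom + .Machine$double.eps
    e <- lapply(e, function(m) m / denom)
  }
  aopp <- abs(e$opponent)
  sp <- rowMeans(aopp)  # per frame
  tp <- colMeans(aopp)  # per position
  res <- list(rightward = e$rightward, leftward = e$leftward,
              opponent = e$opponent, flicker = e$flicker,
              total_energy = mean(aopp),
              space_profile = sp, time_profile = tp,
              energy_peak = max(sp), energy_dip = min(sp),
              energy_drop = max(sp) - min(sp),
              normalized = normalize)
  class(res) <- "sb_energy"
  res
}

#' Total motion energy of an energy result
#'
#' The scalar visual covariate of the integration model: the mean over all
#' space-time samples of the absolute opponent energy.
#'
#' @param result An `sb_energy` from [energy_maps()].
#' @return A non-negative scalar.
#' @export
total_energy <- function(result) {
  stopifnot(inherits(result, "sb_energy"))
  mean(abs(result$opponent))
}

#' Batch motion-energy statistics
#'
#' Computes, for every display in a batch, the total motion energy and the
#' peak, dip and drop of the space-averaged absolute opponent-energy profile,
#' using the same definitions as [energy_maps()] but vectorised over trials.
#'
#' @param stimuli A 3-D array (frames x positions x trials) or a flattened
#'   cells x trials matrix.
#' @param bank An [me_filter_bank()].
#' @param normalize As in [energy_maps()].
#' @param chunk Number of trials processed per block (memory control).
#' @return A data.frame with one row per trial: `total_energy`,
#'   `energy_peak`, `energy_dip`, `energy_drop`.
#' @export
motion_energy_batch <- function(stimuli, bank, normalize = FALSE,
                                chunk = 4096L) {
  stopifnot(inherits(bank, "sb_me_bank"))
  g <- bank$geometry
  X <- as_stimulus_matrix(stimuli, g)
  nf <- g$n_frames
  np <- g$n_positions
  if (nrow(X) != nf * np) {
    stop("stimulus cells do not match the bank's geometry", call. = FALSE)
  }
  n <- ncol(X)
  # per-frame averaging operator over the vectorised (frame-fastest) layout
  G <- matrix(0, nf, nf * np)
  for (i in seq_len(nf)) G[i, i + nf * (0:(np - 1))] <- 1 / np
  out <- data.frame(total_energy = numeric(n), energy_peak = numeric(n),
                    energy_dip = numeric(n), energy_drop = numeric(n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    Xc <- X[, idx, drop = FALSE]
    Xc <- sweep(Xc, 2L, colMeans(Xc))  # mean-subtract each display
    es <- bank$M_es %*% Xc
    ef <- bank$M_ef %*% Xc
    os <- bank$M_os %*% Xc
    of <- bank$M_of %*% Xc
    rightward <- (es - of)^2 + (os + ef)^2
    leftward <- (es + of)^2 + (ef - os)^2
    opponent <- rightward - leftward
    if (normalize) {
      denom <- colMeans(rightward + leftward)
      denom <- denom + 1e-6 * denom + .Machine$double.eps
      opponent <- sweep(opponent, 2L, denom, "/")
    }
    aopp <- abs(opponent)
    prof <- G %*% aopp                       # nf x ntrials profiles
    out$total_energy[idx] <- colMeans(aopp)
    out$energy_peak[idx] <- apply(prof, 2L, max)
    out$energy_dip[idx] <- apply(prof, 2L, min)
  }
  out$energy_drop <- out$energy_peak - out$energy_dip
  out
}

#' Contrast-only (direction-blind) energy model
#'
#' The alternative model: the same even/odd Gabor spatial filters as the
#' motion-energy bank, but paired with a single Gaussian temporal profile
#' (standard deviation `temporal_sd`, default 40 ms, centred "same"
#' convolution). The two spatial outputs form one quadrature pair whose
#' squared sum measures local contrast energy; having no direction-selective
#' combination, the model responds identically to a display and its
#' left-right mirror image.
#'
#' @inheritParams energy_maps
#' @param temporal_sd Standard deviation of the Gaussian temporal filter in
#'   seconds (default 0.040).
#' @return A list with the contrast energy `map` (n_frames x n_positions) and
#'   its spatiotemporal mean `total`.
#' @export
contrast_model_energy <- function(stimulus, bank, temporal_sd = 0.040) {
  stopifnot(inherits(bank, "sb_me_bank"))
  S <- unclass(stimulus)
  if (!all(is.finite(S))) stop("stimulus must be finite", call. = FALSE)
  g <- bank$geometry
  if (!identical(dim(S), c(g$n_frames, g$n_positions))) {
    stop("stimulus shape does not match the bank's geometry", call. = FALSE)
  }
  A_g <- gaussian_time_matrix(g, temporal_sd)
  S0 <- S - mean(S)
  ce <- A_g %*% S0 %*% bank$B_even
  co <- A_g %*% S0 %*% bank$B_odd
  map <- ce^2 + co^2
  list(map = map, total = mean(map))
}

# centred Gaussian temporal smoothing as an nf x nf "same" convolution matrix
gaussian_time_matrix <- function(geometry, temporal_sd) {
  stopifnot(temporal_sd > 0)
  nf <- geometry$n_frames
  mt <- floor(nf / 2)
  td <- (-mt:mt) / geometry$frame_rate
  gft <- exp(-td^2 / (2 * temporal_sd^2))
  A <- matrix(0, nf, nf)
  for (l in seq_len(nf)) {
    for (i in seq_len(nf)) {
      lag <- i - l
      if (abs(lag) <= mt) A[i, l] <- gft[lag + mt + 1]
    }
  }
  A
}

#' Batch total contrast energy of the alternative model
#'
#' @inheritParams motion_energy_batch
#' @param temporal_sd As in [contrast_model_energy()].
#' @return Numeric vector of per-trial mean contrast energy.
#' @export
contrast_energy_batch <- function(stimuli, bank, temporal_sd = 0.040,
                                  chunk = 4096L) {
  stopifnot(inherits(bank, "sb_me_bank"))
  g <- bank$geometry
  X <- as_stimulus_matrix(stimuli, g)
  A_g <- gaussian_time_matrix(g, temporal_sd)
  M_ce <- kronecker(t(bank$B_even), A_g)
  M_co <- kronecker(t(bank$B_odd), A_g)
  n <- ncol(X)
  total <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    Xc <- X[, idx, drop = FALSE]
    Xc <- sweep(Xc, 2L, colMeans(Xc))
    total[idx] <- colMeans((M_ce %*% Xc)^2 + (M_co %*% Xc)^2)
  }
  total
}
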