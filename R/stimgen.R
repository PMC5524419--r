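#' Noiseless stream-bounce signal
#'
#' Renders the two moving bars on a uniform background. On frame t (1-based)
#' the rightward bar occupies column t and the leftward bar occupies column
#' `n_positions + 1 - t`, so the trajectories cross at the display centre
#' (the bars swap sides between frames `n/2` and `n/2 + 1` and never share a
#' column at the default 20 x 20 geometry). Bar samples deviate from the
#' background by `signal_increment`: upward for `polarity = "light"`,
#' downward for `"dark"`.
#'
#' @param geometry An [display_geometry()] object.
#' @param polarity `"light"` (bars brighter than background) or `"dark"`.
#' @return A `stimulus movie`: an `n_frames x n_positions` luminance matrix
#'   (cd/m^2, row 1 = first frame, column 1 = leftmost position) with
#'   attributes `polarity`, `trajectory_mask` (integer matrix counting signal
#'   bars per sample; 0/1 at defaults) and `geometry`.
#' @examples
#' sig <- make_signal(display_geometry())
#' which(attr(sig, "trajectory_mask")[1, ] > 0)  # bars start at the edges
#' @export
make_signal <- function(geometry = display_geometry(),
                        polarity = c("light", "dark")) {
  validate_geometry(geometry)
  polarity <- match.arg(polarity)
  nf <- geometry$n_frames
  np <- geometry$n_positions
  mask <- matrix(0L, nf, np)
  for (t in seq_len(nf)) {
    right <- t
    left <- np + 1L - t
    if (right <= np) mask[t, right] <- mask[t, right] + 1L
    if (left >= 1L) mask[t, left] <- mask[t, left] + 1L
  }
  sgn <- if (polarity == "light") 1 else -1
  lum <- geometry$background_luminance +
    sgn * geometry$signal_increment * mask
  structure(lum, polarity = polarity, trajectory_mask = mask,
            geometry = geometry)
}

#' Dynamic luminance noise field
#'
#' Draws one independent uniform luminance sample per space-time cell,
#' bounded by the geometry's `noise_lo` and `noise_hi`. The same seed always
#' reproduces the same field.
#'
#' @inheritParams make_signal
#' @param seed Integer seed for the field.
#' @return An `n_frames x n_positions` luminance matrix with attributes
#'   `seed` and `geometry`.
#' @export
make_noise <- function(geometry = display_geometry(), seed = 1L) {
  validate_geometry(geometry)
  lum <- with_seed(seed, matrix(
    stats::runif(geometry$n_frames * geometry$n_positions,
                 geometry$noise_lo, geometry$noise_hi),
    geometry$n_frames, geometry$n_positions))
  structure(lum, seed = as.integer(seed), geometry = geometry)
}

#' Compose a noisy stream-bounce display
#'
#' Adds the signal increment to the noise field along the bar trajectories:
#' off-trajectory samples equal the noise samples, on-trajectory samples equal
#' noise plus/minus `signal_increment` depending on the signal polarity. No
#' clipping is applied (all values stay physical at default parameters).
#'
#' @param signal A movie from [make_signal()].
#' @param noise A field from [make_noise()] of the same shape.
#' @return A stimulus movie (matrix + attributes as in [make_signal()]).
#' @export
compose_display <- function(signal, noise) {
  if (!identical(dim(signal), dim(noise))) {
    stop("signal and noise shapes differ: ",
         paste(dim(signal), collapse = "x"), " vs ",
         paste(dim(noise), collapse = "x"), call. = FALSE)
  }
  geom <- attr(signal, "geometry")
  lum <- unclass(noise) + (unclass(signal) - geom$background_luminance)
  structure(lum, polarity = attr(signal, "polarity"),
            trajectory_mask = attr(signal, "trajectory_mask"),
            geometry = geom, seed = attr(noise, "seed"))
}

#' Batch of noisy displays
#'
#' Generates `n` composed displays sharing one signal, with independent noise
#' fields, as a 3-D array (frames x positions x trials). This is the package's
#' canonical stimulus container; layer i is trial i.
#'
#' @inheritParams make_signal
#' @param n Number of displays.
#' @param seed Integer seed for the whole batch.
#' @param polarity Bar polarity, as in [make_signal()].
#' @return A 3-D array with attributes `polarity`, `trajectory_mask`,
#'   `geometry` and `seed`.
#' @export
make_display_batch <- function(n, geometry = display_geometry(),
                               polarity = c("light", "dark"), seed = 1L) {
  polarity <- match.arg(polarity)
  validate_geometry(geometry)
  stopifnot(n >= 1)
  sig <- make_signal(geometry, polarity)
  nf <- geometry$n_frames
  np <- geometry$n_positions
  noise <- with_seed(seed, array(
    stats::runif(nf * np * n, geometry$noise_lo, geometry$noise_hi),
    dim = c(nf, np, n)))
  arr <- noise + array(unclass(sig) - geometry$background_luminance,
                       dim = c(nf, np, n))
  structure(arr, polarity = polarity,
            trajectory_mask = attr(sig, "trajectory_mask"),
            geometry = geometry, seed = as.integer(seed))
}

#' Disambiguate a display with a luminance kernel
#'
#' Adds (`sign = +1`, towards "bounce") or subtracts (`sign = -1`, towards
#' "stream") a range-scaled luminance classification image from a display:
#' `output = stimulus + sign * gain * K`, elementwise.
#'
#' @param stimulus A stimulus movie (matrix).
#' @param kernel Luminance kernel `K_L`, same shape, range-scaled so that
#'   `max(abs(K)) == 1`.
#' @param sign `+1` or `-1`.
#' @param gain Kernel amplitude in cd/m^2 per kernel unit; the default equals
#'   the geometry's `signal_increment` (50 cd/m^2 at the kernel peak).
#' @return The modified stimulus movie.
#' @export
disambiguate_display <- function(stimulus, kernel, sign = 1,
                                 gain = NULL) {
  if (!identical(dim(stimulus)[1:2], dim(kernel)[1:2])) {
    stop("kernel shape must equal stimulus shape", call. = FALSE)
  }
  if (!all(is.finite(kernel))) stop("kernel must be finite", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  if (is.null(gain)) {
    geom <- attr(stimulus, "geometry")
    gain <- if (is.null(geom)) 50 else geom$signal_increment
  }
  out <- unclass(stimulus) + sign * gain * as.numeric(kernel)
  attributes(out) <- attributes(stimulus)
  out
}

#' High / low motion-energy displays for the polarity experiment
#'
#' Builds the four stimulus sets of the second experiment: for each bar
#' polarity, `n_base` fresh noisy displays are generated and the
#' model-derived luminance kernel for that polarity is added (HI, high motion
#' energy) or subtracted (LO, low motion energy) from each. HI and LO sets
#' are paired: they share base displays and differ only in the kernel sign.
#'
#' @param n_base Displays per polarity.
#' @param kernels_by_polarity Named list with elements `light` and/or `dark`,
#'   each a range-scaled luminance kernel matrix (e.g. the `K_L` of
#'   [simulate_exp2_kernels()]).
#' @param gain Kernel amplitude in cd/m^2 (default: the geometry's
#'   `signal_increment`).
#' @param polarities Which polarities to build (default both present in
#'   `kernels_by_polarity`).
#' @inheritParams make_display_batch
#' @return A list with one element per `polarity`, each a list with 3-D
#'   arrays `HI` and `LO`.
#' @export
make_exp2_stimuli <- function(n_base, kernels_by_polarity,
                              geometry = display_geometry(),
                              gain = geometry$signal_increment,
                              polarities = names(kernels_by_polarity),
                              seed = 1L) {
  validate_geometry(geometry)
  stopifnot(length(polarities) >= 1)
  out <- list()
  for (i in seq_along(polarities)) {
    pol <- polarities[[i]]
    K <- kernels_by_polarity[[pol]]
    if (is.null(K)) {
      stop("no kernel supplied for polarity '", pol, "'", call. = FALSE)
    }
    if (!all(is.finite(K))) stop("kernel must be finite", call. = FALSE)
    base <- make_display_batch(n_base, geometry, pol,
                               seed = as.integer(seed) + (i - 1L))
    shift <- array(gain * as.numeric(K),
                   dim = c(geometry$n_frames, geometry$n_positions, n_base))
    out[[pol]] <- list(HI = base + shift, LO = base - shift)
  }
  out
}
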