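#' Display geometry for stream-bounce movies
#'
#' Describes the sampling lattice and luminance regime of a stream-bounce
#' display: a short movie of `n_frames` frames, each made of `n_positions`
#' adjacent vertical bars, shown on a mid-grey background. Two signal bars
#' travel along crossing diagonal trajectories; every bar of every frame also
#' carries independent luminance noise drawn uniformly from
#' `[noise_lo, noise_hi]`.
#'
#' @param n_frames Number of movie frames (default 20).
#' @param n_positions Number of horizontal bar positions per frame (default 20).
#' @param frame_rate Frame rate in Hz (default 60; 20 frames = 333 ms).
#' @param bar_width Width of one bar in degrees of visual angle (default 0.085).
#' @param bar_height Height of one bar in degrees (default 0.426; carried as
#'   metadata, the movies are one-dimensional in space).
#' @param background_luminance Background luminance in cd/m^2. The default is
#'   the midpoint of the noise range, `(14.6 + 48.3) / 2 = 31.45`.
#' @param signal_increment Luminance increment (cd/m^2) that defines the moving
#'   bars relative to the local luminance (default 50).
#' @param noise_lo,noise_hi Bounds of the uniform luminance noise in cd/m^2
#'   (defaults 14.6 and 48.3).
#'
#' @return An object of class `sb_geometry` (a validated list of the fields
#'   above).
#' @examples
#' geom <- display_geometry()
#' geom$n_frames / geom$frame_rate  # total duration in seconds
#' @export
display_geometry <- function(n_frames = 20L, n_positions = 20L,
                             frame_rate = 60,
                             bar_width = 0.085, bar_height = 0.426,
                             background_luminance = (14.6 + 48.3) / 2,
                             signal_increment = 50,
                             noise_lo = 14.6, noise_hi = 48.3) {
  geom <- list(
    n_frames = as.integer(n_frames),
    n_positions = as.integer(n_positions),
    frame_rate = frame_rate,
    bar_width = bar_width,
    bar_height = bar_height,
    background_luminance = background_luminance,
    signal_increment = signal_increment,
    noise_lo = noise_lo,
    noise_hi = noise_hi
  )
  class(geom) <- "sb_geometry"
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  if (!inherits(geom, "sb_geometry")) {
    stop("`geometry` must be created with display_geometry()", call. = FALSE)
  }
  num <- vapply(geom, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("geometry fields must be finite scalars: ",
         paste(names(geom)[!num], collapse = ", "), call. = FALSE)
  }
  if (geom$n_frames < 2L || geom$n_positions < 2L) {
    stop("geometry needs n_frames >= 2 and n_positions >= 2", call. = FALSE)
  }
  if (geom$noise_lo >= geom$noise_hi) {
    stop("geometry needs noise_lo < noise_hi", call. = FALSE)
  }
  if (geom$signal_increment <= 0) {
    stop("geometry needs signal_increment > 0", call. = FALSE)
  }
  if (geom$frame_rate <= 0 || geom$bar_width <= 0) {
    stop("geometry needs frame_rate > 0 and bar_width > 0", call. = FALSE)
  }
  invisible(geom)
}

#' @export
print.sb_geometry <- function(x, ...) {
  cat(sprintf(
    "stream-bounce display geometry: %d frames x %d positions @ %g Hz (%.0f ms)\n",
    x$n_frames, x$n_positions, x$frame_rate,
    1000 * x$n_frames / x$frame_rate))
  cat(sprintf("  noise U[%g, %g] cd/m^2, background %g, signal increment %g\n",
              x$noise_lo, x$noise_hi, x$background_luminance,
              x$signal_increment))
  invisible(x)
}

# spatial sample positions (deg), centred on the display midline
spatial_axis <- function(geom) {
  (seq_len(geom$n_positions) - (geom$n_positions + 1) / 2) * geom$bar_width
}

# temporal sample times (s), first frame at t = 0
temporal_axis <- function(geom) {
  (seq_len(geom$n_frames) - 1) / geom$frame_rate
}
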