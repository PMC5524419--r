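# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
# All randomness in the package flows through this helper, so every result is
# a pure function of its seed and arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Flatten a stimulus container to a (n_frames * n_positions) x n_trials
# matrix in column-major (frame fastest) order. Accepts a single movie
# (matrix), a 3-D array, or an already flattened matrix with `ncells` rows.
as_stimulus_matrix <- function(stimuli, geometry = NULL) {
  d <- dim(stimuli)
  if (is.null(d)) stop("stimuli must be a matrix or 3-D array", call. = FALSE)
  if (length(d) == 3L) {
    return(matrix(stimuli, d[1] * d[2], d[3]))
  }
  if (length(d) == 2L) {
    if (!is.null(geometry) &&
        d[1] == geometry$n_frames * geometry$n_positions) {
      return(unclass(stimuli))  # already cells x trials
    }
    return(matrix(stimuli, d[1] * d[2], 1L))
  }
  stop("stimuli must be a matrix or 3-D array", call. = FALSE)
}

# mean and population MSE (mean squared deviation from the per-cell mean)
# of a cells x trials matrix, computed per cell
cellwise_stats <- function(X) {
  mu <- rowMeans(X)
  mse <- rowMeans((X - mu)^2)
  list(mu = mu, mse = mse)
}
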