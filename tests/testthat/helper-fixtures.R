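# shared fixtures, built once per test run
.sb_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sb_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sb_cache)
  }
  get(key, envir = .sb_cache, inherits = FALSE)
}

test_geom <- function() cached("geom", display_geometry())

test_bank <- function() cached("bank", me_filter_bank(test_geom()))

# a small complete session (52 blocks of 40 trials) with stimuli kept
test_session <- function() {
  cached("session", {
    oc <- observer_config(n_trials = 2080L, seed = 5L)
    simulate_session(oc, bank = test_bank())
  })
}

# model-derived luminance kernels for both polarities at desk scale
exp2_kernels <- function() {
  cached("exp2_kernels", {
    bank <- test_bank()
    list(light = simulate_exp2_kernels(20000L, "light", bank, seed = 101L),
         dark = simulate_exp2_kernels(20000L, "dark", bank, seed = 102L))
  })
}

# quick trial table with externally supplied gaussian "energies"; useful where
# the motion-energy stage is not under test
quick_trials <- function(n = 4000L, omega0 = -0.3, omega_me = 0.4,
                         omega_a = 0.6, omega_r = 0.5, seed = 1L) {
  oc <- observer_config(omega0 = omega0, omega_me = omega_me,
                        omega_a = omega_a, omega_r = omega_r,
                        n_trials = n, seed = seed)
  en <- with_test_seed(seed + 500L, stats::rnorm(n))
  simulate_session(oc, energies = en)$trials
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
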