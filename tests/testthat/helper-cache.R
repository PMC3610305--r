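# Heavy simulations shared across test files, computed once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache, inherits = FALSE))
    assign(name, expr, envir = .test_cache)
  get(name, envir = .test_cache, inherits = FALSE)
}

baseline_steady <- function() {
  cached("steady", run_to_steady_state(cvs_params()))
}

baseline_hemorrhage <- function() {
  cached("hemorrhage",
         run_hemorrhage(cvs_params(), steady = baseline_steady()))
}

doubled_steady <- function() {
  cached("steady2",
         run_to_steady_state(with_contractility(cvs_params(), 2)))
}

# rectangular PV loops whose upper-left corners lie exactly on
# P = Ees (V - V0); the analytic fixture for the linear-fit oracle
synthetic_corner_loops <- function(Ees = 2, V0 = -40,
                                   corners = c(10, 12, 14, 16),
                                   width = 5) {
  do.call(rbind, lapply(seq_along(corners), function(k) {
    v <- corners[k]
    pk <- Ees * (v - V0)
    data.frame(
      t = seq(0, 0.5, length.out = 5) + (k - 1) * 0.6,
      P = c(0, pk, pk, pk / 2, 0),
      V = c(v, v, v + width, v + width, v + width),
      loop = k)
  }))
}
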