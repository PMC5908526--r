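# Shared fixtures: reference parameters, a small film grid for mobility
# tests, and cached expensive runs (built once per test session).

ref_params <- function(...) physical_params(...)

small_grid <- function(nx = 64, ny = 64, nz = 64) {
  grid_spec(nx, ny, nz, dx = 19.40 / 64)
}

# planar swimmer state as a swimmer_state object from a planar q vector
state_from_q <- function(q, params, phi = 0, Phi = 0) {
  swimmer_state(q, params, z = 0, phi = phi, Phi = Phi)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the reduced solitary reference run shared by the acceptance tests
# (512 x 256 film: ~3% faster swimming than the square calibration box,
# within the tolerances asserted on it)
solitary_test_run <- function() {
  cached("solitary", {
    p <- physical_params(steps_per_period = 150L)
    g <- grid_spec(512, 256, 64)
    cfg <- suspension_config(N = 1, init_mode = "solitary",
                             grid = g, params = p)
    sys <- initialize_suspension(cfg, g, p, backend = "fcm")
    sys$solver$jac_refresh <- 200L
    run_film(sys, n_periods = 4)
  })
}
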