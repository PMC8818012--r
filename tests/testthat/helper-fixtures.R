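# Shared fixtures.  Heavy simulations are computed once per test run and
# memoised; all geometry is built in code at deliberately coarse resolution
# so the whole suite stays fast while preserving the physics being tested.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_params <- function(...) epileptor_params(...)

# plain rectangular test sheet (exercises the same grid generator as the
# surrogates, via a degenerate two-contact electrode spec)
fx_sheet <- function(L = 20, W = 10, edge = 1) {
  epifield:::.grid_sheet(L, W, edge)
}

# one equilateral triangle of side 1
fx_triangle <- function() {
  tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
              matrix(c(1, 2, 3), 1))
}

# unit sphere from a repeatedly quadrisected octahedron, vertices
# projected to radius 1 (analytic ground truth for vertex normals)
fx_sphere <- function() {
  memo("sphere", {
    v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    tr <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
    s <- tri_surface(v, tr)
    for (k in 1:4) {
      s <- triangle_quadrisect(s)
      vv <- s$vertices / sqrt(rowSums(s$vertices^2))
      s <- tri_surface(vv, s$triangles)
    }
    s
  })
}

# coarse flat-surrogate seizure with SEEG, shared across analysis tests
fx_flat_run <- function() {
  memo("flat_run", {
    p <- fx_params(gamma_11 = 1.2)
    spec <- surrogate_spec("flat", edge_length = 1.2)
    run <- epifield:::.run_surrogate_pipeline(spec, p, duration_s = 25,
                                              stop_extra_s = 3,
                                              record_q1 = TRUE)
    run$onsets <- detect_onsets(run$bipolar)
    run
  })
}

# identifiability experiment (reference on the sine surrogate), the
# heaviest shared fixture
fx_identifiability <- function() {
  memo("identifiability", {
    surface_comparison_experiment(list(
      reference = list(kind = "sine", gamma_11 = 0.9, noise_sd = 0.02,
                       seed = 42L),
      candidates = c("flat", "sine", "gyral"),
      params = fx_params(),
      edge_length = 1.2,
      sweep_gammas = c(0.6, 0.9, 1.3),
      duration_s = 30))
  })
}
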