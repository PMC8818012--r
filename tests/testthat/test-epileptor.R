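# independently coded scalar Epileptor right-hand side, written directly
# from the model equations as an oracle for the vectorized/compiled code
oracle_rhs <- function(u1, u2, v, q1, q2, g, p, u0) {
  f1 <- if (u1 < 0) u1 * u1 * u1 - 3 * u1 * u1 else (q1 - 0.6 * (v - 4)^2) * u1
  f2 <- if (q1 >= -0.25) 6 * (q1 + 0.25) else 0
  du1 <- (u2 - f1 - v + 3.1) / 5.88
  du2 <- (1 - 5 * u1 * u1 - u2) / 5.88
  dv <- ((4 * (u1 - u0) - v) / 20000) / 5.88
  dq1 <- (-q2 + q1 - q1^3 + 0.45 + 0.002 * g - 0.3 * (v - 3.5)) / 5.88
  dq2 <- ((-q2 + f2) / 100) / 5.88
  dg <- 3 * u1 - g / (5.88 * p$tau_12)
  c(du1, du2, dv, dq1, dq2, dg)
}

test_that("field derivatives at zero coupling match the scalar oracle to 1e-12", {
  p <- fx_params()
  set.seed(3)
  for (rep in 1:20) {
    st <- c(runif(1, -2, 2), runif(1, -12, 2), runif(1, 2, 5),
            runif(1, -2, 2), runif(1, 0, 10), runif(1, -800, 100))
    u0 <- runif(1, -3, -1.5)
    got <- field_derivatives(matrix(st, 1), p, kernel = NULL, u0 = u0)
    want <- oracle_rhs(st[1], st[2], st[3], st[4], st[5], st[6], p, u0)
    expect_equal(as.vector(got), want, tolerance = 1e-12)
  }
})

test_that("compiled Heun steps reproduce the R derivative definition", {
  p <- fx_params()
  sheet <- fx_sheet(6, 6, 1)
  kern <- build_local_kernel(sheet, b = 1, cutoff = 4)
  n <- nrow(sheet$vertices)
  set.seed(5)
  state <- cbind(runif(n, -2, 1), runif(n, -11, 1), runif(n, 2.5, 3.5),
                 runif(n, -2, 1), runif(n, 0, 5), runif(n, -700, 0))
  u0 <- rep(-2.3, n)
  dt <- p$dt
  # one Heun step in R from the exported derivative
  k1 <- field_derivatives(state, p, kern, u0)
  k2 <- field_derivatives(state + dt * k1, p, kern, u0)
  want <- state + dt / 2 * (k1 + k2)
  r <- epifield:::.heun_field_cpp(state, u0, unclass(p), dt, 1, 1L,
                                  list(p = kern$W@p, i = kern$W@i, x = kern$W@x),
                                  TRUE, TRUE, integer(0), -0.8, 0)
  expect_equal(r$u1[2, ], want[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$q1[2, ], want[, 4], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$s[2, ], want[, 4] - want[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("uncoupled fixed point is exact, stable, with the closed-form memory value", {
  p <- fx_params()
  st <- single_node_fixed_point(p, -2.3)
  expect_lt(max(abs(epifield:::.rhs_single(st, p, -2.3))), 1e-10)
  expect_equal(unname(st["g"]), p$tau_s * p$tau_12 * p$a_12 * unname(st["u1"]),
               tolerance = 1e-9)
  expect_error(single_node_fixed_point(p, -1.8), "supercritical")
})

test_that("derivatives vanish at the coupled equilibrium and Heaviside gates close", {
  p <- fx_params()
  sheet <- fx_sheet(8, 8, 1)
  kern <- build_local_kernel(sheet)
  n <- nrow(sheet$vertices)
  st <- epifield:::.fp_roots(p, p$u0_surround)
  state <- matrix(rep(st, each = n), n, 6)
  d <- field_derivatives(state, p, kern, rep(-2.3, n))
  expect_lt(max(abs(d)), 1e-8)
  # below all thresholds the coupled and uncoupled derivatives coincide
  d0 <- field_derivatives(state, p, NULL, rep(-2.3, n))
  expect_identical(d, d0)
  expect_error(field_derivatives(state * NA, p, kern, rep(-2.3, n)),
               "non-finite")
})

test_that("uniform subcritical field stays at equilibrium for seconds", {
  p <- fx_params()
  sheet <- fx_sheet(12, 8, 1)
  r <- simulate_field(sheet, p, make_excitability_map(sheet), duration_s = 5,
                      output_hz = 64)
  expect_lt(max(abs(sweep(r$s, 2, r$s[1, ]))), 1e-6)
  expect_true(all(is.na(recruitment_times(r))))
})

test_that("regime classifier separates the published excitability regimes", {
  p <- fx_params()
  expect_equal(classify_excitability_regime(p, -2.3), "fixed_point")
  expect_equal(classify_excitability_regime(p, -1.8), "oscillatory")
  expect_equal(fast_subsystem_bistability(p, -2.3), "bistable")
  expect_equal(fast_subsystem_bistability(p, -3.5), "monostable")
})

test_that("kernel is normalized, positive, with the analytic prefactor", {
  p <- fx_params()
  expect_equal(1 / (2 * pi), 0.15915, tolerance = 1e-4)
  sheet <- fx_sheet(20, 20, 0.8)
  kern <- build_local_kernel(sheet, b = 1, cutoff = 6)
  expect_equal(kern$alpha, 1 / (2 * pi))
  expect_true(all(kern$W@x >= 0))
  ctr <- nearest_vertex(sheet, c(10, 10, 0))
  mass <- sum(kern$W[ctr, ])
  expect_gt(mass, 0.95); expect_lt(mass, 1.05)
  # self-weight alpha * A_i on the diagonal
  expect_equal(kern$W[ctr, ctr], kern$alpha * vertex_areas(sheet)[ctr],
               tolerance = 1e-12)
  expect_error(build_local_kernel(sheet, b = 1, cutoff = 0.3), "diagonal")
})

test_that("halving the time step changes the solution by well under 1 percent", {
  p <- fx_params(gamma_11 = 1.2)
  spec <- surrogate_spec("flat", l = 5, m = 4, edge_length = 1,
                         n_contacts = 2, pitch = 5)
  fl <- make_flat_surrogate(spec)      # 13 x 8 mm sheet
  ez <- nearest_vertex(fl$surface, c(4, 4, 0))
  u0 <- make_excitability_map(fl$surface, ez, ez_diameter = 5)
  kern <- build_local_kernel(fl$surface)
  probe <- nearest_vertex(fl$surface, c(9, 4, 0))
  runs <- lapply(c(0.1, 0.05), function(dt) {
    pp <- p; pp$dt <- dt
    simulate_field(fl$surface, pp, u0, duration_s = 11, output_hz = 125,
                   kernel = kern)
  })
  a <- runs[[1]]$s[, probe]; b <- runs[[2]]$s[, probe]
  m <- min(length(a), length(b))
  expect_gt(sd(a), 0.1)                 # the probe actually seized
  rel <- sqrt(mean((a[1:m] - b[1:m])^2)) / sd(a[1:m])
  expect_lt(rel, 0.01)
})

test_that("recruitment propagates outward from the EZ monotonically in distance", {
  run <- fx_flat_run()
  rec <- recruitment_times(run$result)
  ez <- which(run$u0map$ez_mask)
  expect_true(which.min(rec) %in% ez)
  expect_equal(min(rec, na.rm = TRUE), min(rec[ez], na.rm = TRUE))
  gd <- geodesic_distances(run$surface, ez)$distances
  ok <- !is.na(rec)
  expect_gt(cor(rec[ok], gd[ok], method = "spearman"), 0.95)
})
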