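# a triangle whose first vertex has area exactly 1 and normal (0, 0, 1)
unit_area_vertex <- function() {
  tri_surface(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)),
              matrix(c(1, 2, 3), 1))
}

test_that("gain entries follow the signed dipole kernel", {
  s <- unit_area_vertex()
  el <- electrode(rbind(c(0, 0, 10)))
  G <- compute_gain_matrix(s, el)
  expect_equal(G$G[1, 1], 10 / 1000, tolerance = 1e-12)

  flipped <- tri_surface(s$vertices, s$triangles[, c(1, 3, 2), drop = FALSE])
  expect_equal(compute_gain_matrix(flipped, el)$G, -G$G, tolerance = 1e-12)

  # doubling the on-axis distance quarters the entry
  el2 <- electrode(rbind(c(0, 0, 20)))
  expect_equal(compute_gain_matrix(s, el2)$G[1, 1], G$G[1, 1] / 4,
               tolerance = 0.01)

  # contact on a vertex is a singularity
  expect_error(compute_gain_matrix(s, electrode(rbind(c(0, 0, 0)))),
               "singularity")
})

test_that("projection is linear and referencing commutes with projection", {
  sheet <- fx_sheet(10, 8, 1)
  el <- make_electrode(n_contacts = 4, origin = c(1, 4, 2))
  G <- compute_gain_matrix(sheet, el)
  n <- nrow(sheet$vertices)
  fake <- function(s_mat) list(s = s_mat, t = seq_len(nrow(s_mat)) / 100,
                               fs = 100)
  z <- project_to_sensors(G, fake(matrix(0, 5, n)))
  expect_true(all(z$signals == 0))

  set.seed(1)
  s1 <- matrix(rnorm(5 * n), 5); s2 <- matrix(rnorm(5 * n), 5)
  p1 <- project_to_sensors(G, fake(s1))
  p2 <- project_to_sensors(G, fake(s2))
  p12 <- project_to_sensors(G, fake(s1 + s2))
  expect_equal(p12$signals, p1$signals + p2$signals, tolerance = 1e-12)

  cst <- project_to_sensors(G, fake(matrix(2.5, 3, n)))
  expect_equal(cst$signals[1, ], 2.5 * rowSums(G$G), ignore_attr = TRUE)

  bip_then <- bipolar_reference(p1)
  then_bip <- project_to_sensors(bipolar_reference(G), fake(s1))
  expect_equal(bip_then$signals, then_bip$signals, tolerance = 1e-12)
  expect_equal(colnames(bip_then$signals), c("c2-c1", "c3-c2", "c4-c3"))
  expect_error(project_to_sensors(G, fake(matrix(0, 2, n + 1))), "vertices")
})

test_that("bipolar referencing yields n-1 difference channels", {
  sheet <- fx_sheet(10, 8, 1)
  el <- make_electrode(n_contacts = 9, pitch = 1, origin = c(1, 4, 2))
  G <- compute_gain_matrix(sheet, el)
  bip <- bipolar_reference(G)
  expect_equal(nrow(bip$G), 8)
  # identical monopolar channels difference to zero
  sig <- structure(list(signals = matrix(1.7, 10, 2),
                        t = 1:10, fs = 1, names = c("a", "b"),
                        referencing = "monopolar"), class = "sensor_signals")
  expect_true(all(bipolar_reference(sig)$signals == 0))
  one <- structure(list(signals = matrix(0, 5, 1), t = 1:5, fs = 1,
                        names = "a", referencing = "monopolar"),
                   class = "sensor_signals")
  expect_error(bipolar_reference(one), "two")
})

test_that("selectivity area-at-fraction matches hand-computed cases", {
  toy <- structure(list(G = matrix(c(3, 1), 1), names = "c1",
                        referencing = "monopolar"), class = "gain_matrix")
  expect_equal(gain_selectivity(toy, c(1, 1))$area_mm2, 1)

  unif <- structure(list(G = matrix(1, 1, 10), names = "c1",
                         referencing = "monopolar"), class = "gain_matrix")
  expect_equal(gain_selectivity(unif, rep(2, 10))$area_mm2, 10)

  zero <- structure(list(G = matrix(0, 1, 4), names = "c1",
                         referencing = "monopolar"), class = "gain_matrix")
  expect_true(is.na(gain_selectivity(zero, rep(1, 4))$area_mm2))
})

test_that("bipolar referencing is spatially more selective than monopolar", {
  fl <- make_flat_surrogate(surrogate_spec("flat", edge_length = 1))
  G <- compute_gain_matrix(fl$surface, fl$electrode)
  A <- vertex_areas(fl$surface)
  mono <- gain_selectivity(G, A)$area_mm2
  bip <- gain_selectivity(bipolar_reference(G), A)$area_mm2
  expect_true(all(max(bip) < mono))
})

test_that("gain is translation invariant and decays like a far-field source", {
  sheet <- fx_sheet(10, 8, 1)
  el <- make_electrode(n_contacts = 3, origin = c(2, 4, 1.5))
  G1 <- compute_gain_matrix(sheet, el)$G
  shift <- c(11, -7, 3)
  sheet2 <- tri_surface(sweep(sheet$vertices, 2, -shift), sheet$triangles)
  el2 <- electrode(sweep(el$positions, 2, -shift))
  G2 <- compute_gain_matrix(sheet2, el2)$G
  expect_equal(G1, G2, tolerance = 1e-10)

  # far sensor: total |gain| decays with an exponent between 2 and 3
  R <- 200
  sA <- sum(abs(compute_gain_matrix(sheet, electrode(rbind(c(R, R, R))))$G))
  sB <- sum(abs(compute_gain_matrix(sheet, electrode(rbind(2 * c(R, R, R))))$G))
  slope <- log2(sA / sB)
  expect_gt(slope, 1.8); expect_lt(slope, 3.2)
})

test_that("homogeneous amplitude proxy is symmetric for a centered electrode", {
  fl <- make_flat_surrogate(surrogate_spec("flat", edge_length = 1))
  gbar <- homogeneous_amplitude_proxy(compute_gain_matrix(fl$surface,
                                                          fl$electrode))
  expect_equal(unname(gbar), unname(rev(gbar)), tolerance = 1e-6)
  expect_error(homogeneous_amplitude_proxy(
    bipolar_reference(compute_gain_matrix(fl$surface, fl$electrode))),
    "monopolar")
})

test_that("for spatially homogeneous sources the proxy predicts bipolar envelopes", {
  run <- fx_flat_run()
  gbar <- homogeneous_amplitude_proxy(run$gain)
  # broadcast one vertex's seizure trace to the whole sheet: exactly the
  # homogeneous-dynamics premise of the proxy
  ez <- which(run$u0map$ez_mask)[1]
  n <- ncol(run$result$s)
  hom <- run$result
  hom$s <- matrix(run$result$s[, ez], nrow(run$result$s), n)
  bip <- bipolar_reference(project_to_sensors(run$gain, hom))
  env_means <- vapply(seq_len(ncol(bip$signals)), function(k)
    mean(signal_envelope(bip$signals[, k], bip$fs)), numeric(1))
  expect_gt(cor(gbar, env_means), 0.999)
  # and the amplitude ratio is gbar itself
  expect_equal(env_means / env_means[1], unname(gbar / gbar[1]),
               tolerance = 1e-6)
})
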