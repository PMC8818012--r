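test_that("electrode generator spans l = (n-1) * pitch and is collinear", {
  el <- make_electrode()
  expect_equal(nrow(el$positions), 9)
  expect_equal(sqrt(sum((el$positions[9, ] - el$positions[1, ])^2)), 28,
               tolerance = 1e-9)
  expect_equal(diff(el$positions[, 1]), rep(3.5, 8), tolerance = 1e-9)

  el2 <- make_electrode(n_contacts = 2, pitch = 3.5)
  expect_equal(sqrt(sum((el2$positions[2, ] - el2$positions[1, ])^2)), 3.5)

  # collinearity: cross products of consecutive steps vanish
  d <- diff(el$positions)
  cr <- cbind(d[-1, 2] * d[-nrow(d), 3] - d[-1, 3] * d[-nrow(d), 2],
              d[-1, 3] * d[-nrow(d), 1] - d[-1, 1] * d[-nrow(d), 3],
              d[-1, 1] * d[-nrow(d), 2] - d[-1, 2] * d[-nrow(d), 1])
  expect_true(max(abs(cr)) < 1e-9)
  expect_error(make_electrode(direction = c(0, 0, 0)), "nonzero")
})

test_that("flat surrogate has the exact (l+2m) x 2m footprint and standoff", {
  fl <- make_flat_surrogate(surrogate_spec("flat", edge_length = 1))
  expect_equal(surface_area(fl$surface), 1740, tolerance = 1e-9)
  expect_equal(diff(range(fl$surface$vertices[, 1])), 58)
  expect_equal(diff(range(fl$surface$vertices[, 2])), 30)
  expect_equal(unique(fl$electrode$positions[, 3]), 1.47)
  expect_true(all(fl$surface$vertices[, 3] == 0))
  # contacts span the central l of the footprint
  expect_equal(range(fl$electrode$positions[, 1]), c(15, 43))

  # p x q cells -> 2 p q triangles, (p+1)(q+1) vertices
  expect_equal(nrow(fl$surface$triangles), 2 * 58 * 30)
  expect_equal(nrow(fl$surface$vertices), 59 * 31)
  expect_error(surrogate_spec("flat", edge_length = 16), "margin")
})

test_that("sine surrogate folds with amplitude A over the flat footprint", {
  sp <- surrogate_spec("sine", edge_length = 0.5)
  sn <- make_sine_surrogate(sp)
  expect_equal(range(sn$surface$vertices[, 3]), c(-7.89, 7.89),
               tolerance = 0.02)
  expect_gt(surface_area(sn$surface), 1740)
  expect_equal(diff(range(sn$surface$vertices[, 1])), 58)
  expect_equal(unique(sn$electrode$positions[, 3]), 0)

  flat0 <- make_sine_surrogate(surrogate_spec("sine", amplitude = 0,
                                              edge_length = 1))
  expect_equal(surface_area(flat0$surface), 1740, tolerance = 1e-9)
})

test_that("gyral surrogate is seed-deterministic and area-increasing", {
  spA <- surrogate_spec("gyral", amplitude = 8, wavelength = 25,
                        edge_length = 1, seed = 11)
  g1 <- make_gyral_surrogate(spA)
  g2 <- make_gyral_surrogate(spA)
  expect_identical(g1$surface$vertices, g2$surface$vertices)
  expect_gt(surface_area(g1$surface), 1740)

  g3 <- make_gyral_surrogate(surrogate_spec("gyral", amplitude = 8,
                                            wavelength = 25, edge_length = 1,
                                            seed = 12))
  expect_false(identical(g1$surface$vertices, g3$surface$vertices))

  g0 <- make_gyral_surrogate(surrogate_spec("gyral", amplitude = 0,
                                            edge_length = 1))
  expect_equal(surface_area(g0$surface), 1740, tolerance = 1e-9)
})

test_that("excitability map carves a 5 mm geodesic disc at the EZ values", {
  sheet <- fx_sheet(20, 20, 0.4)
  ctr <- nearest_vertex(sheet, c(10, 10, 0))
  m <- make_excitability_map(sheet, ctr)
  expect_setequal(unique(m$u0), c(-1.8, -2.3))
  expect_true(all(m$u0[m$ez_mask] == -1.8))
  ez_area <- sum(vertex_areas(sheet)[m$ez_mask])
  expect_equal(ez_area, pi * 2.5^2, tolerance = 0.15)

  m0 <- make_excitability_map(sheet)
  expect_true(all(m0$u0 == -2.3))
  expect_false(any(m0$ez_mask))

  coarse <- fx_sheet(20, 20, 4)
  expect_error(make_excitability_map(coarse, nearest_vertex(coarse, c(10, 10, 0)),
                                     ez_diameter = 1),
               "refine")
})

test_that("electrode TSV round-trips", {
  el <- make_electrode(origin = c(15, 15, 1.47))
  f <- tempfile(fileext = ".tsv")
  write_electrode_tsv(el, f)
  back <- read_electrode_tsv(f)
  expect_equal(back$positions, el$positions, ignore_attr = TRUE)
  expect_equal(back$names, el$names)
  unlink(f)
})
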