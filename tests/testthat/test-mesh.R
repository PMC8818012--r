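test_that("vertex areas follow the one-third rule and conserve total area", {
  tri <- fx_triangle()
  expect_equal(vertex_areas(tri), rep(sqrt(3) / 12, 3), tolerance = 1e-12)

  right <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(vertex_areas(right), rep(1 / 6, 3), tolerance = 1e-12)

  sheet <- fx_sheet(8, 6, 1)
  expect_equal(sum(vertex_areas(sheet)), 48, tolerance = 1e-9)
  expect_true(all(vertex_areas(sheet) >= 0))
})

test_that("vertex normals are unit, orientation-sensitive, and radial on a sphere", {
  sheet <- fx_sheet(6, 4, 1)
  nrm <- vertex_normals(sheet)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, nrow(nrm)), tolerance = 1e-9)
  expect_equal(nrm[, 3], rep(1, nrow(nrm)), tolerance = 1e-12)

  flipped <- tri_surface(sheet$vertices, sheet$triangles[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -nrm, tolerance = 1e-12)

  sph <- fx_sphere()
  cosang <- rowSums(vertex_normals(sph) * sph$vertices)
  expect_true(all(cosang > cos(2 * pi / 180)))
})

test_that("quadrisection splits 1 -> 4 with midpoint dedup and exact planar area", {
  tri <- fx_triangle()
  q <- triangle_quadrisect(tri)
  expect_equal(nrow(q$vertices), 6)
  expect_equal(nrow(q$triangles), 4)
  expect_equal(surface_area(q), surface_area(tri), tolerance = 1e-14)

  # unit square as two triangles: V = 4, unique edges E = 5 -> V' = 9, T' = 8
  sq <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  qs <- triangle_quadrisect(sq)
  expect_equal(nrow(qs$vertices), 9)
  expect_equal(nrow(qs$triangles), 8)

  sheet <- fx_sheet(6, 4, 1)
  q1 <- triangle_quadrisect(sheet)
  q2 <- triangle_quadrisect(q1)
  expect_equal(nrow(q1$triangles), 4 * nrow(sheet$triangles))
  expect_equal(nrow(q2$triangles), 16 * nrow(sheet$triangles))
  expect_equal(surface_area(q2), surface_area(sheet), tolerance = 1e-12)
  # the orientation must be preserved by refinement
  expect_equal(vertex_normals(q1)[, 3], rep(1, nrow(q1$vertices)),
               tolerance = 1e-12)

  nonman <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(0, -1, 0), c(0, 0, 1)),
                        rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(triangle_quadrisect(nonman), "non-manifold")
})

test_that("degenerate triangles are rejected and isolated vertices warned about", {
  expect_error(tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           matrix(c(1, 2, 3), 1)),
               "degenerate")
  expect_warning(tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(5, 5, 5)),
                             matrix(c(1, 2, 3), 1)),
                 "isolated")
})

test_that("edge-graph geodesics are exact on grid lines and tightly bound Euclidean", {
  sheet <- fx_sheet(10, 4, 0.4)
  v0 <- nearest_vertex(sheet, c(0, 2, 0))
  v1 <- nearest_vertex(sheet, c(10, 2, 0))
  gf <- geodesic_distances(sheet, v0)
  expect_equal(gf$distances[v1], 10, tolerance = 1e-9)
  expect_equal(gf$distances[v0], 0)

  # random pairs: geodesic >= Euclidean and <= 1.1x on the 0.4 mm grid
  set.seed(7)
  pick <- sample(nrow(sheet$vertices), 20)
  for (a in pick[1:5]) {
    ga <- geodesic_distances(sheet, a)$distances
    eu <- sqrt(colSums((t(sheet$vertices) - sheet$vertices[a, ])^2))
    expect_true(all(ga >= eu - 1e-9))
    expect_true(all(ga[eu > 1] <= 1.1 * eu[eu > 1]))
  }

  # triangle inequality on sampled triples
  d1 <- geodesic_distances(sheet, pick[1])$distances
  d2 <- geodesic_distances(sheet, pick[2])$distances
  expect_true(all(d1 <= d1[pick[2]] + d2 + 1e-9))
})

test_that("geodesic cutoff marks far vertices unreachable instead of erroring", {
  sheet <- fx_sheet(10, 4, 1)
  v0 <- nearest_vertex(sheet, c(0, 2, 0))
  gf <- geodesic_distances(sheet, v0, cutoff = 3)
  expect_true(any(!gf$reachable))
  expect_true(all(is.infinite(gf$distances[!gf$reachable])))
  expect_true(all(gf$distances[gf$reachable] <= 3))
})

test_that("patch extraction keeps the 15 mm ball and only the main component", {
  el <- make_electrode(n_contacts = 2, pitch = 5, origin = c(5, 5, 1),
                       direction = c(1, 0, 0))
  near <- fx_sheet(14, 10, 1)          # fully within 15 mm
  kept <- extract_patch(near, el, radius = 15)
  expect_equal(nrow(kept$vertices), nrow(near$vertices))

  # a sheet with a far corner: brute-force distance filter agrees
  wide <- fx_sheet(40, 10, 1)
  kept2 <- extract_patch(wide, el, radius = 15)
  cp <- el$positions
  dmin <- pmin(sqrt(colSums((t(wide$vertices) - cp[1, ])^2)),
               sqrt(colSums((t(wide$vertices) - cp[2, ])^2)))
  keep_v <- dmin <= 15
  tr <- wide$triangles
  keep_t <- keep_v[tr[, 1]] & keep_v[tr[, 2]] & keep_v[tr[, 3]]
  expect_equal(nrow(kept2$vertices),
               length(unique(as.vector(tr[keep_t, ]))))

  # two disjoint sheets both in range: only the larger survives
  s1 <- fx_sheet(10, 6, 1)
  s2 <- fx_sheet(4, 4, 1)
  s2$vertices[, 3] <- 6                # detached, but within radius
  both <- tri_surface(rbind(s1$vertices, s2$vertices),
                      rbind(s1$triangles, s2$triangles + nrow(s1$vertices)))
  kept3 <- extract_patch(both, el, radius = 15)
  expect_equal(nrow(kept3$vertices), nrow(s1$vertices))

  # idempotence
  again <- extract_patch(kept3, el, radius = 15)
  expect_equal(nrow(again$vertices), nrow(kept3$vertices))
  expect_equal(surface_area(again), surface_area(kept3))
})

test_that("shortest paths subsample uniformly and agree with geodesic distances", {
  sheet <- fx_sheet(29, 4, 1)
  a <- nearest_vertex(sheet, c(0, 2, 0))
  b <- nearest_vertex(sheet, c(29, 2, 0))
  sp <- shortest_path_vertices(sheet, a, b, n_points = 30)
  expect_equal(sp$vertices[1], a)
  expect_equal(sp$vertices[30], b)
  expect_true(all(diff(sp$distances) >= 0))
  expect_equal(diff(sp$distances), rep(1, 29), tolerance = 0.51)
  expect_equal(sp$length, geodesic_distances(sheet, a)$distances[b],
               tolerance = 1e-9)
  expect_warning(sp0 <- shortest_path_vertices(sheet, a, a), "degenerate")
  expect_equal(unique(sp0$vertices), a)
  expect_equal(sp0$distances, numeric(30))
})

test_that("PLY and OFF round-trips preserve geometry", {
  sheet <- fx_sheet(4, 3, 1)
  for (ext in c("ply", "off")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_surface(sheet, f)
    back <- read_surface(f)
    expect_equal(back$vertices, sheet$vertices, ignore_attr = TRUE)
    expect_equal(back$triangles, sheet$triangles, ignore_attr = TRUE)
    unlink(f)
  }
})
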