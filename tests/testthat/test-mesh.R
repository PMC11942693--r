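test_that("unit cube meshes reproduce the 6-tet Kuhn split exactly", {
  m1 <- make_fixture("unit_cube", h = 1)$mesh
  expect_equal(m1$n_elements, 6L)
  v1 <- toothfea:::cpp_tet_volumes(m1$nodes, m1$tets)
  expect_true(all(v1 > 0))
  expect_equal(sum(v1), 1, tolerance = 1e-12)
  m2 <- make_fixture("unit_cube", h = 0.5)$mesh
  expect_equal(m2$n_elements, 48L)
  expect_equal(sum(toothfea:::cpp_tet_volumes(m2$nodes, m2$tets)), 1,
               tolerance = 1e-12)
})

test_that("mesh volume converges to the Monte-Carlo domain volume", {
  g <- build_scenario("healthy")
  mc <- mc_region_volumes(g, n = 2e5, seed = 99)
  v_dom <- sum(mc$volume[mc$region != "OUTSIDE"])
  for (h in c(1, 0.5)) {
    m <- generate_mesh(g, h)
    v_mesh <- sum(toothfea:::cpp_tet_volumes(m$nodes, m$tets))
    expect_lt(abs(v_mesh - v_dom) / v_dom, 0.05)
  }
})

test_that("meshing is deterministic and tags cohere with the classifier", {
  g <- build_scenario("small_ic")
  ma <- generate_mesh(g, 1)
  mb <- generate_mesh(g, 1)
  expect_identical(ma$nodes, mb$nodes)
  expect_identical(ma$tets, mb$tets)
  expect_identical(ma$region, mb$region)
  ctr <- (ma$nodes[ma$tets[, 1], ] + ma$nodes[ma$tets[, 2], ] +
            ma$nodes[ma$tets[, 3], ] + ma$nodes[ma$tets[, 4], ]) / 4
  lab <- classify_points(g, ctr)
  in_dom <- lab != "OUTSIDE"
  expect_true(all(ma$region[in_dom] == lab[in_dom]))
  # every region of the scenario is represented at this resolution
  expect_true(all(c("ENAMEL", "DENTIN", "PULP", "PDL", "BONE", "COMPOSITE",
                    "CEMENT", "INSERT") %in% ma$region))
  expect_error(generate_mesh(g, 100), "mesh-generation")
})

test_that("shape quality is 0 for the regular tet and matches the formula", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  mesh <- single_tet_mesh()
  mesh$nodes <- reg
  q <- jacobian_quality(mesh)
  expect_equal(q$elements$q, 0, tolerance = 1e-9)
  # Kuhn corner tet: squared edges {1,2,3,1,2,1}, l_rms = sqrt(5/3),
  # Q = 1 - sqrt(2) / (5/3)^(3/2)
  mesh$nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  qk <- jacobian_quality(mesh)
  expect_equal(qk$elements$q, 1 - sqrt(2) / (5 / 3)^1.5, tolerance = 1e-12)
  expect_equal(qk$elements$q, 0.3427329, tolerance = 1e-6)
  # degenerate (coplanar) element is rejected before any quality value
  mesh$nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(jacobian_quality(mesh), "invalid-element")
})

test_that("quality report summarises a generated mesh", {
  m <- generate_mesh(build_scenario("healthy"), h = 1.5)
  q <- jacobian_quality(m)
  expect_true(all(q$elements$q >= 0 & q$elements$q <= 1))
  expect_equal(nrow(q$elements), m$n_elements)
  expect_equal(sum(q$region_counts$n_elements), m$n_elements)
  expect_true(q$n_above_threshold >= 0)
})

test_that("facet extraction reports areas and outward normals", {
  m <- make_fixture("unit_cube", h = 1)$mesh
  top <- extract_facets(m, "occlusal")
  expect_equal(nrow(top), 2L)
  expect_equal(sum(top$area), 1, tolerance = 1e-12)
  expect_equal(top$nz, c(1, 1), tolerance = 1e-12)
  ext <- extract_facets(m, "exterior")
  expect_equal(sum(ext$area), 6, tolerance = 1e-12)
  expect_error(extract_facets(m, "nope"), "unknown facet set")
  # empty set comes back as an empty table, not an error
  m$facet_sets$custom <- matrix(integer(), 0, 3)
  expect_equal(nrow(extract_facets(m, "custom")), 0L)
})

test_that("occlusal facet area approximates the tooth ellipse", {
  m <- generate_mesh(build_scenario("healthy"), h = 0.5)
  occ <- extract_facets(m, "occlusal")
  a_ellipse <- pi * 5 * 5.5
  expect_lt(abs(sum(occ$area) - a_ellipse) / a_ellipse, 0.05)
  expect_true(all(occ$nz > cos(10 * pi / 180)))
})

test_that("VTK export round-trips nodes, connectivity and region tags", {
  fx <- make_fixture("tiny_tooth")
  tmp <- tempfile(fileext = ".vtk")
  write_vtk(fx$mesh, tmp,
            point_data = list(temperature = rep(36, fx$mesh$n_nodes)),
            cell_data = list(vm = seq_len(fx$mesh$n_elements) * 1.0))
  m2 <- read_vtk_mesh(tmp, cej_z = fx$geom$cej_z)
  expect_equal(m2$n_nodes, fx$mesh$n_nodes)
  expect_equal(unname(m2$tets), unname(fx$mesh$tets))
  expect_equal(m2$region, fx$mesh$region)
  expect_equal(unname(m2$nodes), unname(fx$mesh$nodes), tolerance = 1e-9)
  expect_equal(sort(m2$node_sets$composite_cement_nodes),
               sort(fx$mesh$node_sets$composite_cement_nodes))
  unlink(tmp)
})
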