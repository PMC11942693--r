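test_that("element stiffness matches the hand-built B-matrix oracle", {
  # reference tet: shape-function gradients are known in closed form
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  grads <- cbind(c(-1, -1, -1), diag(3))     # column a = grad N_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cx <- 3 * (a - 1) + 1
    B[1, cx] <- grads[1, a]
    B[2, cx + 1] <- grads[2, a]
    B[3, cx + 2] <- grads[3, a]
    B[4, cx + 1] <- grads[3, a]; B[4, cx + 2] <- grads[2, a]
    B[5, cx] <- grads[3, a]; B[5, cx + 2] <- grads[1, a]
    B[6, cx] <- grads[2, a]; B[6, cx + 1] <- grads[1, a]
  }
  C <- diag(c(1, 1, 1, 0.5, 0.5, 0.5))       # E = 1, nu = 0
  K_hand <- (1 / 6) * t(B) %*% C %*% B
  expect_equal(element_stiffness(coords, elasticity_tensor(1, 0)), K_hand,
               tolerance = 1e-12)
})

test_that("element stiffness is symmetric with a rigid-body kernel", {
  set.seed(3)
  for (rep in 1:5) {
    coords <- matrix(runif(12), 4, 3)
    if (det(coords[2:4, ] - matrix(coords[1, ], 3, 3, byrow = TRUE)) < 0.01)
      next
    K <- element_stiffness(coords, elasticity_tensor(18600, 0.31))
    expect_equal(K, t(K), tolerance = 1e-12)
    for (axis in 1:3) {
      tr <- rep(0, 12)
      tr[seq(axis, 12, by = 3)] <- 1
      expect_lt(max(abs(K %*% tr)), 1e-9 * max(abs(K)))
    }
  }
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(element_stiffness(flat, elasticity_tensor(1, 0.3)),
               "degenerate")
})

test_that("sparse assembly equals the dense brute-force oracle", {
  fx <- make_fixture("series_bar", h = 1)   # 20 nodes = 60 dofs
  expect_lte(3 * fx$mesh$n_nodes, 60)
  K_sparse <- assemble(fx$mesh, fx$materials)
  K_dense <- dense_assembly_oracle(fx$mesh, fx$materials)
  expect_equal(as.matrix(K_sparse), K_dense, tolerance = 1e-9,
               ignore_attr = TRUE)
  # global rigid translation is in the kernel before boundary conditions
  for (axis in 1:3) {
    tr <- rep(0, 3 * fx$mesh$n_nodes)
    tr[seq(axis, length(tr), by = 3)] <- 1
    expect_lt(max(abs(K_sparse %*% tr)), 1e-9 * max(abs(K_sparse)))
  }
})

test_that("disconnected meshes assemble block-diagonally", {
  m1 <- make_fixture("unit_cube", h = 1)$mesh
  n <- m1$n_nodes
  mesh <- m1
  mesh$nodes <- rbind(m1$nodes, m1$nodes + 5)
  mesh$tets <- rbind(m1$tets, m1$tets + n)
  mesh$region <- rep(m1$region, 2)
  mesh$n_nodes <- 2L * n
  mesh$n_elements <- 2L * m1$n_elements
  K <- assemble(mesh, default_material_table())
  cross <- K[seq_len(3 * n), 3 * n + seq_len(3 * n)]
  expect_equal(Matrix::norm(cross, "M"), 0)
})

test_that("thermal loads vanish without shrinkage strain", {
  m <- generate_mesh(build_scenario("healthy"), h = 2)
  mat <- default_material_table()
  dT <- numeric(m$n_elements)
  expect_equal(max(abs(thermal_load_vector(m, mat, dT))), 0)
  # alpha = 0 everywhere: cooling produces no load
  mat0 <- mat
  mat0$alpha <- 0
  fx <- make_fixture("tiny_tooth")
  dTc <- rep(-26, fx$mesh$n_elements)
  expect_equal(max(abs(thermal_load_vector(fx$mesh, mat0, dTc))), 0)
})

test_that("a free tet under uniform cooling contracts isotropically", {
  mesh <- single_tet_mesh()
  mat <- default_material_table()
  alpha <- mat$alpha[mat$region == "COMPOSITE"]
  dT <- -26
  K <- assemble(mesh, mat)
  f <- thermal_load_vector(mesh, mat, dT)
  fixed <- c(node_dofs(1), node_dofs(2, 2:3), node_dofs(4, 1:2))
  sol <- solve_static(K, f, fixed)
  u <- matrix(sol$u, ncol = 3, byrow = TRUE)
  expect_equal(u, alpha * dT * mesh$nodes, tolerance = 1e-9,
               ignore_attr = TRUE)
  s <- compute_stress(mesh, mat, sol$u, dT)
  expect_lt(max(s$von_mises), 1e-9 * mat$E[mat$region == "COMPOSITE"])
})

test_that("occlusal loading is a uniform pressure with exact resultant", {
  m <- make_fixture("unit_cube", h = 0.5)$mesh
  f <- occlusal_load_vector(m, 2000)
  expect_equal(sum(f[seq(3, length(f), 3)]), -2000, tolerance = 1e-9)
  expect_equal(sum(f[seq(1, length(f), 3)]), 0)
  expect_equal(sum(f[seq(2, length(f), 3)]), 0)
  expect_equal(max(abs(occlusal_load_vector(m, 0))), 0)
  # healthy tooth at the default mesh size: pressure near F / ellipse area
  mh <- generate_mesh(build_scenario("healthy"), h = 0.5)
  A <- sum(extract_facets(mh, "occlusal")$area)
  p <- 2000 / A
  expect_lt(abs(p - 2000 / (pi * 5 * 5.5)) / (2000 / (pi * 5 * 5.5)), 0.05)
})

test_that("patch test: uniform traction produces constant stress", {
  fx <- make_fixture("unit_cube", h = 0.5)
  m <- fx$mesh
  mat <- default_material_table()
  tol <- 1e-9
  fixed <- c(node_dofs(which(m$nodes[, 3] < tol), 3),
             node_dofs(which(m$nodes[, 1] < tol), 1),
             node_dofs(which(m$nodes[, 2] < tol), 2))
  F_tot <- 100
  K <- assemble(m, mat)
  f <- occlusal_load_vector(m, F_tot)
  sol <- solve_static(K, f, fixed)
  s <- compute_stress(m, mat, sol$u)
  expected <- c(0, 0, -F_tot, 0, 0, 0)   # area = 1, so sigma_zz = -p
  for (j in 1:6)
    expect_equal(s$voigt[, j], rep(expected[j], m$n_elements),
                 tolerance = 1e-8 * F_tot, ignore_attr = TRUE)
  expect_equal(s$von_mises, rep(F_tot, m$n_elements),
               tolerance = 1e-8, ignore_attr = TRUE)
  # equilibrium: reactions balance the applied load per axis
  expect_lt(max(abs(sol$reaction_totals + c(0, 0, -F_tot))), 1e-6)
})

test_that("series bar matches the two-spring compliance within 1 percent", {
  fx <- make_fixture("series_bar", h = 0.5)
  F_tot <- 100
  K <- assemble(fx$mesh, fx$materials)
  f <- occlusal_load_vector(fx$mesh, F_tot)
  fixed <- node_dofs(fx$mesh$node_sets$fixed_support)
  sol <- solve_static(K, f, fixed)
  u <- matrix(sol$u, ncol = 3, byrow = TRUE)
  top <- which(fx$mesh$nodes[, 3] > fx$L1 + fx$L2 - 1e-9)
  tip <- mean(u[top, 3])
  expect_equal(tip, -F_tot / fx$area * fx$tip_compliance,
               tolerance = 0.01)
  expect_lt(max(abs(sol$reaction_totals - c(0, 0, F_tot))), 1e-6)
})

test_that("von Mises invariants hold for canonical stress states", {
  expect_equal(von_mises(c(5, 5, 5, 0, 0, 0)), 0)
  expect_equal(von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(von_mises(c(-7, 0, 0, 0, 0, 0)), 7)
  expect_equal(von_mises(c(0, 0, 0, 0, 0, 10)), sqrt(3) * 10,
               tolerance = 1e-12)
  expect_equal(von_mises(c(0, 0, 0, 0, 0, 10)), 17.3205, tolerance = 1e-5)
})

test_that("free shrinkage of a homogeneous cylinder is stress-free", {
  fc <- cached_free_cylinder_phase1()
  sol <- fc$solution
  mat <- fc$fixture$materials
  E <- mat$E[mat$region == "COMPOSITE"]
  alpha <- mat$alpha[mat$region == "COMPOSITE"]
  expect_lt(max(sol$stress$von_mises), 1e-6 * E * alpha * 26)
  # the whole cylinder is a shrinking material: every node is pinned cold
  expect_equal(max(abs(as.numeric(sol$temperature) - 10)), 0)
})

test_that("phase-2 equals phase-1 plus mechanical (superposition)", {
  fx <- make_fixture("tiny_tooth")
  m <- fx$mesh
  mat <- fx$materials
  K <- assemble(m, mat)
  fixed <- node_dofs(m$node_sets$fixed_support)
  fac <- fea_factor(K, fixed)
  s1 <- run_phase(m, mat, "phase1_thermal", fixed_dofs = fixed,
                  factor = fac, K = K)
  sm <- run_phase(m, mat, "mechanical_only", fixed_dofs = fixed,
                  factor = fac, K = K)
  s2 <- run_phase(m, mat, "phase2_thermal_plus_occlusal",
                  fixed_dofs = fixed, factor = fac, K = K)
  scale <- max(abs(s2$u))
  expect_lt(max(abs(s2$u - s1$u - sm$u)), 1e-8 * scale)
  # healthy protocol: pure mechanical load, no thermal strain anywhere
  mh <- generate_mesh(build_scenario("healthy"), h = 2,
                      support_mode = "simple")
  sh <- run_phase(mh, mat, "mechanical_only")
  expect_equal(max(abs(sh$delta_T)), 0)
  expect_gt(max(abs(sh$u)), 0)
})

test_that("small-cavity displacements are stable under mesh refinement", {
  study <- cached_full_study()
  overall_max_disp <- function(sol) max(sqrt(rowSums(sol$u^2)))
  m1 <- generate_mesh(build_scenario("small_c"), h = 1)
  mat <- default_material_table()
  s2_h1 <- run_phase(m1, mat, "phase2_thermal_plus_occlusal")
  d_h1 <- overall_max_disp(s2_h1)
  d_h05 <- overall_max_disp(study$small_c$phase2_thermal_plus_occlusal)
  expect_lt(abs(d_h1 - d_h05) / d_h05, 0.10)
})

test_that("solver guards reject unconstrained systems", {
  fx <- make_fixture("unit_cube", h = 1)
  K <- assemble(fx$mesh, default_material_table())
  expect_error(solve_static(K, numeric(nrow(K)), integer(0)), "non-empty")
})
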