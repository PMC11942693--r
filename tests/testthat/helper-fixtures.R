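# Shared fixtures and oracles for the verification suite.

# Session cache so expensive meshes/solves are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full five-scenario study at the default mesh size (built once; used by the
# acceptance checks and the refinement-stability property).
cached_full_study <- function() {
  cache_get("full_study", function() {
    sols <- list()
    cfg <- study_config()
    mat <- default_material_table(S_target = cfg$S_target,
                                  delta_T = cfg$T_ref - cfg$T_shrink)
    for (sc in SCENARIO_IDS) {
      geom <- build_scenario(sc, cfg$dims)
      mesh <- generate_mesh(geom, cfg$h, cfg$support_mode)
      if (sc == "healthy") {
        sols[[sc]] <- list(mechanical_only = run_phase(
          mesh, mat, "mechanical_only", F_total = cfg$F_total))
      } else {
        K <- assemble(mesh, mat)
        fixed <- node_dofs(mesh$node_sets$fixed_support)
        fac <- fea_factor(K, fixed)
        sols[[sc]] <- list(
          phase1_thermal = run_phase(mesh, mat, "phase1_thermal",
                                     F_total = cfg$F_total,
                                     fixed_dofs = fixed, factor = fac, K = K),
          phase2_thermal_plus_occlusal = run_phase(
            mesh, mat, "phase2_thermal_plus_occlusal", F_total = cfg$F_total,
            fixed_dofs = fixed, factor = fac, K = K))
      }
    }
    sols
  })
}

cached_free_cylinder_phase1 <- function() {
  cache_get("free_cylinder_phase1", function() {
    fx <- make_fixture("free_cylinder")
    list(fixture = fx,
         solution = run_phase(fx$mesh, fx$materials, "phase1_thermal",
                              fixed_dofs = fx$fixed_dofs))
  })
}

# Dense global stiffness by brute-force accumulation of the pure-R element
# stiffness (independent of the compiled assembly path).
dense_assembly_oracle <- function(mesh, materials) {
  n <- 3 * mesh$n_nodes
  K <- matrix(0, n, n)
  for (e in seq_len(mesh$n_elements)) {
    rec <- materials[materials$region == mesh$region[e], ]
    C <- elasticity_tensor(rec$E, rec$nu)
    Ke <- element_stiffness(mesh$nodes[mesh$tets[e, ], ], C)
    # element dofs in node-major order (x1, y1, z1, x2, ...)
    dofs <- rep(3L * (mesh$tets[e, ] - 1L), each = 3) + 1:3
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# Hand-constructed single-tetrahedron mesh (reference tet at the origin).
single_tet_mesh <- function(region = "COMPOSITE") {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(nodes) <- c("x", "y", "z")
  structure(list(nodes = nodes,
                 tets = matrix(1:4, 1),
                 region = region,
                 node_sets = list(external_surface = 1:4,
                                  fixed_support = integer(0),
                                  composite_cement_nodes =
                                    if (region %in% c("COMPOSITE", "CEMENT"))
                                      1:4 else integer(0),
                                  insert_nodes = integer(0)),
                 facet_sets = list(exterior = rbind(c(2, 3, 4), c(1, 3, 4),
                                                    c(1, 2, 4), c(1, 2, 3)),
                                   occlusal = matrix(integer(), 0, 3)),
                 h = 1, spacing = c(1, 1, 1),
                 n_nodes = 4L, n_elements = 1L,
                 support_mode = "none", geom = NULL),
            class = "fea_mesh")
}

# Minimal hand-built solution object for postprocessing unit tests.
fake_solution <- function(vm, region, n_nodes = NULL, u = NULL) {
  m <- length(vm)
  tets <- matrix(rep(1:4, m), ncol = 4, byrow = TRUE)
  if (is.null(n_nodes)) n_nodes <- 4L
  if (is.null(u)) u <- matrix(0, n_nodes, 3)
  mesh <- structure(list(nodes = matrix(0, n_nodes, 3),
                         tets = tets, region = region,
                         n_nodes = n_nodes, n_elements = m,
                         spacing = c(1, 1, 1)),
                    class = "fea_mesh")
  structure(list(mesh = mesh,
                 stress = list(von_mises = vm),
                 u = u, phase = "phase1_thermal"),
            class = "fea_solution")
}
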