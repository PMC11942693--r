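#' Stiffness matrix of one constant-strain tetrahedron
#'
#' Reference pure-R implementation `K_e = V B' C B` with the explicit 6 x 12
#' strain-displacement matrix; the production assembly path runs in compiled
#' code and is tested against this dense route.
#'
#' @param tet_coords 4 x 3 matrix of node coordinates (mm).
#' @param C 6 x 6 elasticity tensor from [elasticity_tensor()].
#' @return Symmetric 12 x 12 stiffness matrix (dofs ordered node-major:
#'   x1, y1, z1, x2, ...).
#' @examples
#' K <- element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
#'                              c(0, 0, 1)), elasticity_tensor(1, 0))
#' @export
element_stiffness <- function(tet_coords, C) {
  stopifnot(nrow(tet_coords) == 4, ncol(tet_coords) == 3,
            all(dim(C) == c(6, 6)))
  D <- tet_coords[2:4, ] - matrix(tet_coords[1, ], 3, 3, byrow = TRUE)
  vol <- det(D) / 6
  if (vol <= 0)
    stop("degenerate element: non-positive volume", call. = FALSE)
  g <- solve(D)                         # column a = grad N_{a+1}
  grads <- cbind(-rowSums(g), g)        # 3 x 4, column a = grad N_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cx <- 3 * (a - 1) + 1
    B[1, cx] <- grads[1, a]
    B[2, cx + 1] <- grads[2, a]
    B[3, cx + 2] <- grads[3, a]
    B[4, cx + 1] <- grads[3, a]; B[4, cx + 2] <- grads[2, a]  # yz
    B[5, cx] <- grads[3, a]; B[5, cx + 2] <- grads[1, a]      # xz
    B[6, cx] <- grads[2, a]; B[6, cx + 1] <- grads[1, a]      # xy
  }
  vol * t(B) %*% C %*% B
}

#' Assemble the global sparse stiffness matrix
#'
#' @param mesh An `fea_mesh`.
#' @param materials A `material_table`.
#' @return Sparse symmetric stiffness matrix of order `3 * n_nodes`
#'   (dof `3 (node - 1) + component`).
#' @export
assemble <- function(mesh, materials) {
  stopifnot(inherits(mesh, "fea_mesh"))
  validate_materials(materials)
  em <- element_materials(mesh, materials)
  trip <- cpp_assemble_elasticity(mesh$nodes, mesh$tets, em$E, em$nu)
  n <- 3 * mesh$n_nodes
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(n, n))
}

#' Thermal (shrinkage) load vector
#'
#' Equivalent nodal forces of the thermal strain
#' `eps_th = alpha * delta_T * (1, 1, 1, 0, 0, 0)`:
#' `f_e = V B' C eps_th`, nonzero only for elements with `alpha * delta_T
#' != 0`.
#'
#' @param mesh An `fea_mesh`.
#' @param materials A `material_table`.
#' @param delta_T Per-element temperature change from [element_delta_T()].
#' @return Numeric load vector of length `3 * n_nodes` (N).
#' @export
thermal_load_vector <- function(mesh, materials, delta_T) {
  stopifnot(length(delta_T) == mesh$n_elements)
  em <- element_materials(mesh, materials)
  cpp_thermal_load(mesh$nodes, mesh$tets, em$E, em$nu, em$alpha * delta_T)
}

#' Occlusal pressure load vector
#'
#' Distributes a total force `F_total` as a uniform pressure
#' `p = F_total / A` acting along -z over the occlusal facet set; each flat
#' facet contributes `p * area / 3` to each of its three nodes, so the
#' resultant is exactly `(0, 0, -F_total)`.
#'
#' @param mesh An `fea_mesh`.
#' @param F_total Total occlusal force in N (default 2000).
#' @return Numeric load vector of length `3 * n_nodes` (N).
#' @export
occlusal_load_vector <- function(mesh, F_total = 2000) {
  stopifnot(F_total >= 0)
  f <- numeric(3 * mesh$n_nodes)
  if (F_total == 0) return(f)
  fac <- extract_facets(mesh, "occlusal")
  A <- sum(fac$area)
  if (nrow(fac) == 0 || A <= 0)
    stop("empty occlusal facet set", call. = FALSE)
  p <- F_total / A
  contrib <- rep(p * fac$area / 3, 3)
  zdof <- 3 * (c(fac$n1, fac$n2, fac$n3) - 1L) + 3L
  agg <- rowsum(contrib, zdof)
  f[as.integer(rownames(agg))] <- -agg[, 1]
  f
}

#' Solve the constrained static system
#'
#' Eliminates the fixed dofs by reduction and solves the free block with a
#' sparse Cholesky factorization (CHOLMOD). Reactions are recovered as
#' `K u - f` at the constrained dofs.
#'
#' @param K Global sparse stiffness from [assemble()].
#' @param f Load vector.
#' @param fixed_dofs Integer dof indices held at zero (use [node_dofs()] to
#'   expand a node set).
#' @param factor Optional prefactorization from [fea_factor()] for repeated
#'   solves with one stiffness matrix.
#' @return List with the displacement vector `u` (length `3 n`), a
#'   `reactions` tibble (`dof`, `node`, `component`, `force`) and
#'   `reaction_totals` (named x/y/z sums in N).
#' @export
solve_static <- function(K, f, fixed_dofs, factor = NULL) {
  if (length(fixed_dofs) == 0)
    stop("fixed_dofs must be non-empty (rigid-body modes)", call. = FALSE)
  fixed_dofs <- sort(unique(as.integer(fixed_dofs)))
  if (is.null(factor)) factor <- fea_factor(K, fixed_dofs)
  u <- numeric(nrow(K))
  u[factor$free] <- as.numeric(Matrix::solve(factor$chol, f[factor$free]))
  r <- as.numeric(K %*% u - f)[fixed_dofs]
  comp <- (fixed_dofs - 1L) %% 3L + 1L
  totals <- vapply(1:3, function(cmp) sum(r[comp == cmp]), numeric(1))
  names(totals) <- c("x", "y", "z")
  list(u = u,
       reactions = tibble::tibble(dof = fixed_dofs,
                                  node = (fixed_dofs - 1L) %/% 3L + 1L,
                                  component = c("x", "y", "z")[comp],
                                  force = r),
       reaction_totals = totals)
}

#' Prefactorize the reduced stiffness for repeated solves
#'
#' @inheritParams solve_static
#' @return A list with the CHOLMOD factor and the free dof indices.
#' @export
fea_factor <- function(K, fixed_dofs) {
  fixed_dofs <- sort(unique(as.integer(fixed_dofs)))
  free <- setdiff(seq_len(nrow(K)), fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  list(chol = Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE), free = free)
}

#' Expand a node set to dof indices
#'
#' @param nodes Integer node indices.
#' @param components Components to include (subset of 1:3).
#' @return Integer dof indices (`3 (node - 1) + component`).
#' @export
node_dofs <- function(nodes, components = 1:3) {
  as.integer(outer(3L * (as.integer(nodes) - 1L), components, `+`))
}

#' Per-element stress recovery
#'
#' Constant-strain stress `sigma = C (B u_e - eps_th)` in Voigt order
#' (xx, yy, zz, yz, xz, xy) plus the von Mises scalar.
#'
#' @param mesh An `fea_mesh`.
#' @param materials A `material_table`.
#' @param u Displacement vector (length `3 n`) or n x 3 matrix.
#' @param delta_T Per-element temperature change (default 0: no thermal
#'   strain).
#' @return A list of class `stress_field` with the m x 6 matrix `voigt`
#'   (MPa) and vector `von_mises` (MPa).
#' @export
compute_stress <- function(mesh, materials, u, delta_T = NULL) {
  if (is.matrix(u)) u <- as.numeric(t(u))
  stopifnot(length(u) == 3 * mesh$n_nodes)
  if (is.null(delta_T)) delta_T <- numeric(mesh$n_elements)
  em <- element_materials(mesh, materials)
  s <- cpp_element_stress(mesh$nodes, mesh$tets, em$E, em$nu,
                          em$alpha * delta_T, u)
  colnames(s) <- c("xx", "yy", "zz", "yz", "xz", "xy", "vm")
  structure(list(voigt = s[, 1:6, drop = FALSE],
                 von_mises = s[, 7]), class = "stress_field")
}

#' Von Mises equivalent stress of Voigt stress states
#'
#' @param voigt Numeric length-6 vector or m x 6 matrix in Voigt order
#'   (xx, yy, zz, yz, xz, xy).
#' @return Non-negative von Mises stress (same units as input).
#' @examples
#' von_mises(c(10, 0, 0, 0, 0, 0))   # uniaxial: |s|
#' von_mises(c(0, 0, 0, 0, 0, 10))   # pure shear: sqrt(3) * tau
#' @export
von_mises <- function(voigt) {
  if (is.null(dim(voigt))) voigt <- matrix(voigt, ncol = 6)
  sqrt(0.5 * ((voigt[, 1] - voigt[, 2])^2 + (voigt[, 2] - voigt[, 3])^2 +
                (voigt[, 3] - voigt[, 1])^2 +
                6 * (voigt[, 4]^2 + voigt[, 5]^2 + voigt[, 6]^2)))
}

#' Run one loading phase on a meshed scenario
#'
#' `phase1_thermal` applies the shrinkage thermal analog only (steady-state
#' temperature solve, then thermo-elastic loads); `mechanical_only` applies
#' the distributed occlusal force only (the healthy-tooth protocol);
#' `phase2_thermal_plus_occlusal` applies both in one linear solve, which by
#' superposition equals the sequential application of the two load
#' functions.
#'
#' @param mesh An `fea_mesh`.
#' @param materials A `material_table`.
#' @param phase One of `"phase1_thermal"`, `"phase2_thermal_plus_occlusal"`,
#'   `"mechanical_only"`.
#' @param F_total Total occlusal force (N), used by the phases that load the
#'   occlusal surface.
#' @param T_shrink,T_ref Dirichlet temperatures of the thermal analog (degC).
#' @param fixed_dofs Constrained dofs; default is the mesh's `fixed_support`
#'   node set (all components).
#' @param factor Optional prefactorization from [fea_factor()].
#' @param K Optional preassembled stiffness (must match `mesh`/`materials`).
#' @return An object of class `fea_solution`: displacement matrix `u`
#'   (n x 3, mm), nodal `temperature`, per-element `delta_T`, `stress`
#'   (`stress_field`), `reactions`, `reaction_totals` and bookkeeping
#'   fields.
#' @examples
#' m <- generate_mesh(build_scenario("healthy"), h = 2)
#' sol <- run_phase(m, default_material_table(), "mechanical_only")
#' max(sol$stress$von_mises)
#' @export
run_phase <- function(mesh, materials,
                      phase = c("phase1_thermal",
                                "phase2_thermal_plus_occlusal",
                                "mechanical_only"),
                      F_total = 2000, T_shrink = 10, T_ref = 36,
                      fixed_dofs = NULL, factor = NULL, K = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(mesh, "fea_mesh"))
  if (is.null(fixed_dofs))
    fixed_dofs <- node_dofs(mesh$node_sets$fixed_support)
  thermal <- phase %in% c("phase1_thermal", "phase2_thermal_plus_occlusal")
  if (thermal) {
    temp <- solve_temperature(mesh, materials,
                              thermal_bcs(mesh, T_shrink, T_ref))
    dT <- element_delta_T(mesh, temp, T_ref)
  } else {
    temp <- structure(rep(T_ref, mesh$n_nodes), class = "temperature_field")
    dT <- numeric(mesh$n_elements)
  }
  f <- numeric(3 * mesh$n_nodes)
  if (thermal) f <- f + thermal_load_vector(mesh, materials, dT)
  if (phase != "phase1_thermal")
    f <- f + occlusal_load_vector(mesh, F_total)
  if (is.null(K)) K <- assemble(mesh, materials)
  sol <- solve_static(K, f, fixed_dofs, factor = factor)
  stress <- compute_stress(mesh, materials, sol$u, dT)
  structure(list(
    mesh = mesh, phase = phase, F_total = F_total,
    T_shrink = T_shrink, T_ref = T_ref,
    temperature = temp, delta_T = dT,
    u = matrix(sol$u, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("ux", "uy", "uz"))),
    stress = stress,
    reactions = sol$reactions, reaction_totals = sol$reaction_totals,
    applied_totals = c(x = sum(f[seq(1, length(f), 3)]),
                       y = sum(f[seq(2, length(f), 3)]),
                       z = sum(f[seq(3, length(f), 3)]))
  ), class = "fea_solution")
}

#' @export
print.fea_solution <- function(x, ...) {
  cat("<fea_solution>", x$phase, "-", x$mesh$n_elements, "elements\n")
  cat("  max |u| =", round(max(sqrt(rowSums(x$u^2))), 6), "mm;",
      "max von Mises =", round(max(x$stress$von_mises), 3), "MPa\n")
  invisible(x)
}
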