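#' Dirichlet boundary conditions of the shrinkage thermal analog
#'
#' All nodes of the polymerizing materials (composite and cement) are pinned
#' at the shrinkage temperature; nodes on the external model surface and all
#' insert nodes are pinned at the reference temperature. Nodes shared
#' between the cement and the insert (the cement-insert interface) receive
#' the shrinkage temperature: the shrinking-material set wins conflicts.
#'
#' @param mesh An `fea_mesh`.
#' @param T_shrink Temperature of composite/cement nodes (degC, default 10).
#' @param T_ref Temperature of external-surface and insert nodes (degC,
#'   default 36).
#' @return A list with integer `nodes` and numeric `values` of equal length.
#' @export
thermal_bcs <- function(mesh, T_shrink = 10, T_ref = 36) {
  warm <- union(mesh$node_sets$external_surface, mesh$node_sets$insert_nodes)
  cold <- mesh$node_sets$composite_cement_nodes
  warm <- setdiff(warm, cold)
  list(nodes = c(cold, warm),
       values = c(rep(T_shrink, length(cold)), rep(T_ref, length(warm))))
}

#' Steady-state heat conduction solve
#'
#' Galerkin solution of `div(k grad T) = 0` with linear tetrahedral elements
#' and the Dirichlet sets of [thermal_bcs()]; the free nodes are obtained
#' from a sparse symmetric positive-definite solve. Under pure Dirichlet
#' data the discrete solution satisfies the maximum principle, so the field
#' is bounded by the prescribed temperatures, and is invariant under uniform
#' scaling of all conductivities.
#'
#' @param mesh An `fea_mesh`.
#' @param materials A `material_table`.
#' @param bcs Dirichlet data as returned by [thermal_bcs()].
#' @return Numeric vector of nodal temperatures (degC), class
#'   `temperature_field`.
#' @examples
#' m <- generate_mesh(build_scenario("healthy"), h = 2)
#' range(solve_temperature(m, default_material_table()))
#' @export
solve_temperature <- function(mesh, materials, bcs = thermal_bcs(mesh)) {
  stopifnot(inherits(mesh, "fea_mesh"))
  validate_materials(materials)
  if (length(bcs$nodes) == 0)
    stop("singular-system: no Dirichlet nodes for the thermal solve",
         call. = FALSE)
  dup <- duplicated(bcs$nodes)
  bcn <- bcs$nodes[!dup]
  bcv <- bcs$values[!dup]
  em <- element_materials(mesh, materials)
  trip <- cpp_assemble_conductance(mesh$nodes, mesh$tets, em$k)
  n <- mesh$n_nodes
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(n, n))
  temp <- numeric(n)
  temp[bcn] <- bcv
  free <- setdiff(seq_len(n), bcn)
  if (length(free)) {
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    rhs <- -K[free, bcn, drop = FALSE] %*% bcv
    ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    temp[free] <- as.numeric(Matrix::solve(ch, rhs))
  }
  structure(temp, class = "temperature_field")
}

#' Per-element temperature change relative to the reference temperature
#'
#' Element delta T is the mean of the four nodal temperatures (the centroid
#' value of the linear interpolant) minus `T_ref`; it drives the thermal
#' strain `alpha * delta_T`.
#'
#' @param mesh An `fea_mesh`.
#' @param field Nodal `temperature_field` (or numeric vector).
#' @param T_ref Reference temperature in degC (default 36).
#' @return Numeric vector of per-element delta T (degC).
#' @export
element_delta_T <- function(mesh, field, T_ref = 36) {
  stopifnot(length(field) == mesh$n_nodes)
  field <- as.numeric(field)
  (field[mesh$tets[, 1]] + field[mesh$tets[, 2]] +
     field[mesh$tets[, 3]] + field[mesh$tets[, 4]]) / 4 - T_ref
}
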