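#' Axis-aligned box geometry (test fixture)
#'
#' A rectangular domain filled with one region, optionally split into two
#' stacked regions at `split_z` (used for the two-material series bar).
#'
#' @param lower,upper Numeric xyz corners (mm).
#' @param label Region label of the box (or of the lower segment).
#' @param split_z Optional z plane splitting the box into two regions.
#' @param upper_label Region label above `split_z`.
#' @return An `fea_geometry` of class `box_geometry`.
#' @export
box_geometry <- function(lower = c(0, 0, 0), upper = c(1, 1, 1),
                         label = "COMPOSITE", split_z = NULL,
                         upper_label = "DENTIN") {
  stopifnot(all(upper > lower), label %in% REGION_LEVELS)
  bbox <- rbind(lower = lower, upper = upper)
  colnames(bbox) <- c("x", "y", "z")
  structure(list(bbox = bbox, label = label, split_z = split_z,
                 upper_label = upper_label),
            class = c("box_geometry", "fea_geometry"))
}

#' @export
classify_points.box_geometry <- function(geom, points) {
  points <- as_points(points)
  bb <- geom$bbox
  inside <- points[, 1] >= bb[1, 1] & points[, 1] <= bb[2, 1] &
    points[, 2] >= bb[1, 2] & points[, 2] <= bb[2, 2] &
    points[, 3] >= bb[1, 3] & points[, 3] <= bb[2, 3]
  lab <- rep("OUTSIDE", nrow(points))
  lab[inside] <- geom$label
  if (!is.null(geom$split_z))
    lab[inside & points[, 3] > geom$split_z] <- geom$upper_label
  lab
}

#' Vertical cylinder geometry (test fixture)
#'
#' @param radius Cylinder radius (mm).
#' @param height Cylinder height (mm), base at z = 0.
#' @param label Region label.
#' @return An `fea_geometry` of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(radius = 2.75, height = 4.2,
                              label = "COMPOSITE") {
  stopifnot(radius > 0, height > 0, label %in% REGION_LEVELS)
  bbox <- rbind(lower = c(-radius, -radius, 0),
                upper = c(radius, radius, height))
  colnames(bbox) <- c("x", "y", "z")
  structure(list(bbox = bbox, radius = radius, height = height,
                 label = label),
            class = c("cylinder_geometry", "fea_geometry"))
}

#' @export
classify_points.cylinder_geometry <- function(geom, points) {
  points <- as_points(points)
  inside <- points[, 1]^2 + points[, 2]^2 <= geom$radius^2 &
    points[, 3] >= 0 & points[, 3] <= geom$height
  lab <- rep("OUTSIDE", nrow(points))
  lab[inside] <- geom$label
  lab
}

#' Statically determinate constraints removing rigid-body modes
#'
#' Classic 3-2-1 scheme on a structured mesh: node A is fixed in x, y, z; a
#' node B sharing A's y and z (displaced along x) is fixed in y and z; a
#' node C sharing A's z is fixed in z. The scheme is compatible with any
#' uniform scaling about A, so a free thermal contraction remains
#' stress-free under these constraints.
#'
#' @param mesh An `fea_mesh`.
#' @return Integer vector of six dof indices.
#' @export
minimal_constraints <- function(mesh) {
  xyz <- mesh$nodes
  tol <- 1e-9
  ord <- order(xyz[, 3], xyz[, 2], xyz[, 1])
  a <- ord[1]
  same_yz <- abs(xyz[, 2] - xyz[a, 2]) < tol & abs(xyz[, 3] - xyz[a, 3]) < tol
  cand_b <- which(same_yz & abs(xyz[, 1] - xyz[a, 1]) > tol)
  if (!length(cand_b)) stop("no suitable node B for 3-2-1 constraints")
  b <- cand_b[which.max(abs(xyz[cand_b, 1] - xyz[a, 1]))]
  same_z <- abs(xyz[, 3] - xyz[a, 3]) < tol
  cand_c <- which(same_z & abs(xyz[, 2] - xyz[a, 2]) > tol)
  if (!length(cand_c)) stop("no suitable node C for 3-2-1 constraints")
  c_ <- cand_c[which.max(abs(xyz[cand_c, 2] - xyz[a, 2]))]
  c(node_dofs(a), node_dofs(b, 2:3), node_dofs(c_, 3))
}

#' Deterministic test fixtures
#'
#' Small meshes with analytic expectations used by the verification suite:
#' * `unit_cube` - homogeneous unit box (patch test, assembly oracle).
#' * `series_bar` - 1 x 1 mm two-material column, composite below dentin,
#'   Poisson ratios set to zero so the series-spring tip displacement
#'   `(F/A)(L1/E1 + L2/E2)` is exact.
#' * `free_cylinder` - homogeneous composite cylinder with only
#'   rigid-body-removing constraints; free shrinkage reproduces the
#'   calibrated volumetric contraction.
#' * `tiny_tooth` - coarse small-cavity scenario for end-to-end smoke runs.
#'
#' @param name Fixture name.
#' @param h Mesh size (mm); default chosen per fixture.
#' @return A list with `name`, `geom`, `mesh`, `materials` and, where
#'   relevant, `fixed_dofs` and analytic reference values.
#' @examples
#' fx <- make_fixture("unit_cube", h = 0.5)
#' fx$mesh$n_elements
#' @export
make_fixture <- function(name = c("unit_cube", "series_bar", "free_cylinder",
                                  "tiny_tooth"), h = NULL) {
  name <- match.arg(name)
  mat <- default_material_table()
  switch(name,
    unit_cube = {
      if (is.null(h)) h <- 0.5
      geom <- box_geometry()
      mesh <- generate_mesh(geom, h, support_mode = "simple")
      list(name = name, geom = geom, mesh = mesh, materials = mat)
    },
    series_bar = {
      if (is.null(h)) h <- 0.5
      L1 <- 2; L2 <- 2
      geom <- box_geometry(lower = c(0, 0, 0), upper = c(1, 1, L1 + L2),
                           label = "COMPOSITE", split_z = L1,
                           upper_label = "DENTIN")
      mesh <- generate_mesh(geom, h, support_mode = "simple")
      mat0 <- mat
      mat0$nu[mat0$region %in% c("COMPOSITE", "DENTIN")] <- 0
      E1 <- mat0$E[mat0$region == "COMPOSITE"]
      E2 <- mat0$E[mat0$region == "DENTIN"]
      list(name = name, geom = geom, mesh = mesh, materials = mat0,
           L1 = L1, L2 = L2, area = 1,
           tip_compliance = L1 / E1 + L2 / E2)
    },
    free_cylinder = {
      if (is.null(h)) h <- 0.4
      geom <- cylinder_geometry()
      mesh <- generate_mesh(geom, h, support_mode = "none")
      list(name = name, geom = geom, mesh = mesh, materials = mat,
           fixed_dofs = minimal_constraints(mesh))
    },
    tiny_tooth = {
      if (is.null(h)) h <- 2
      geom <- build_scenario("small_c")
      mesh <- generate_mesh(geom, h, support_mode = "simple")
      list(name = name, geom = geom, mesh = mesh, materials = mat)
    })
}
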