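#' Generate a region-tagged tetrahedral mesh from a geometry
#'
#' Lays a background grid of characteristic spacing `h` over the geometry's
#' bounding box, keeps the cells whose centers classify into the domain, and
#' splits each kept cell into six positively oriented tetrahedra (Kuhn
#' split). The boundary is stair-step by construction, which guarantees
#' positive element volumes and fully deterministic meshes; the geometric
#' error is controlled by `h`. Each element is tagged with the region of its
#' centroid (falling back to the cell-center label for centroids pushed just
#' outside the stair-step boundary).
#'
#' Named node sets: `external_surface` (nodes on boundary facets),
#' `fixed_support` (see `support_mode`), `composite_cement_nodes` and
#' `insert_nodes` (nodes of elements with those tags). Named facet sets:
#' `exterior` (all boundary facets) and `occlusal` (boundary facets whose
#' outward normal is within 10 degrees of +z at heights within one cell of
#' the mesh top).
#'
#' @param geom An `fea_geometry` object.
#' @param h Characteristic cell size in mm (each axis uses the nearest
#'   spacing that divides the bounding box exactly).
#' @param support_mode `"full"` fixes all nodes on the lateral (x/y extreme)
#'   faces of the mesh below the crown, mirroring lateral fixation of the
#'   bone block; `"simple"` fixes the z = min base; `"none"` leaves the set
#'   empty (fixtures supply their own constraints).
#' @return An object of class `fea_mesh`.
#' @examples
#' m <- generate_mesh(build_scenario("healthy"), h = 2)
#' m$n_elements
#' @export
generate_mesh <- function(geom, h, support_mode = c("full", "simple", "none")) {
  support_mode <- match.arg(support_mode)
  stopifnot(h > 0)
  bb <- geom$bbox
  len <- bb[2, ] - bb[1, ]
  ncell <- as.integer(round(len / h))
  if (any(ncell < 1L))
    stop("mesh-generation: h = ", h, " is larger than the domain extent",
         call. = FALSE)
  sp <- len / ncell
  nx <- ncell[1]; ny <- ncell[2]; nz <- ncell[3]

  cx <- rep.int(seq_len(nx) - 1L, ny * nz)
  cy <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  cz <- rep(seq_len(nz) - 1L, each = nx * ny)
  centers <- cbind(bb[1, 1] + (cx + 0.5) * sp[1],
                   bb[1, 2] + (cy + 0.5) * sp[2],
                   bb[1, 3] + (cz + 0.5) * sp[3])
  lab <- classify_points(geom, centers)
  keep <- lab != "OUTSIDE"
  if (!any(keep))
    stop("mesh-generation: no cell center classifies into the domain ",
         "(h too large?)", call. = FALSE)
  cx <- cx[keep]; cy <- cy[keep]; cz <- cz[keep]
  cell_lab <- lab[keep]

  node_id <- function(ix, iy, iz)
    1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  # 8 cube corners, local index dx + 2 dy + 4 dz
  corners <- matrix(0L, length(cx), 8)
  kk <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corners[, dx + 2 * dy + 4 * dz + 1] <- node_id(cx + dx, cy + dy, cz + dz)
    kk <- kk + 1L
  }
  # 6 Kuhn tets along the (0,0,0)-(1,1,1) diagonal, all positively oriented
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 6, 2, 8), c(1, 4, 3, 8),
                c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 7, 5, 8))
  tets <- do.call(rbind, lapply(seq_len(6), function(t)
    corners[, kuhn[t, ], drop = FALSE]))
  elem_cell <- rep(seq_along(cx), times = 6)
  used <- sort(unique(as.vector(tets)))
  remap <- integer((nx + 1L) * (ny + 1L) * (nz + 1L))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  gid <- used - 1L
  ix <- gid %% (nx + 1L)
  iy <- (gid %/% (nx + 1L)) %% (ny + 1L)
  iz <- gid %/% ((nx + 1L) * (ny + 1L))
  nodes <- cbind(x = bb[1, 1] + ix * sp[1],
                 y = bb[1, 2] + iy * sp[2],
                 z = bb[1, 3] + iz * sp[3])

  centroids <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
                  nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  region <- classify_points(geom, centroids)
  region[region == "OUTSIDE"] <- cell_lab[elem_cell[region == "OUTSIDE"]]

  bnd <- boundary_facets(tets)
  fac <- bnd$facets
  opp <- bnd$opposite
  nrm <- facet_normals(nodes, fac, opp)
  fc_z <- (nodes[fac[, 1], 3] + nodes[fac[, 2], 3] + nodes[fac[, 3], 3]) / 3
  zmax <- max(nodes[, 3])
  occl <- nrm$normal[, 3] >= cos(10 * pi / 180) & fc_z >= zmax - max(sp)

  tol <- min(sp) / 4
  lateral <- nodes[, 1] <= min(nodes[, 1]) + tol |
    nodes[, 1] >= max(nodes[, 1]) - tol |
    nodes[, 2] <= min(nodes[, 2]) + tol |
    nodes[, 2] >= max(nodes[, 2]) - tol
  if (!is.null(geom$cej_z)) lateral <- lateral & nodes[, 3] <= geom$cej_z + tol
  fixed <- switch(support_mode,
    full = which(lateral),
    simple = which(nodes[, 3] <= min(nodes[, 3]) + tol),
    none = integer(0))

  cc_nodes <- sort(unique(as.vector(
    tets[region %in% c("COMPOSITE", "CEMENT"), , drop = FALSE])))
  ins_nodes <- sort(unique(as.vector(
    tets[region == "INSERT", , drop = FALSE])))

  structure(list(
    nodes = nodes,
    tets = tets,
    region = region,
    node_sets = list(external_surface = sort(unique(as.vector(fac))),
                     fixed_support = fixed,
                     composite_cement_nodes = cc_nodes,
                     insert_nodes = ins_nodes),
    facet_sets = list(exterior = fac,
                      occlusal = fac[occl, , drop = FALSE]),
    facet_data = {
      ext <- tibble::tibble(n1 = fac[, 1], n2 = fac[, 2], n3 = fac[, 3],
                            area = nrm$area, nx = nrm$normal[, 1],
                            ny = nrm$normal[, 2], nz = nrm$normal[, 3])
      list(exterior = ext, occlusal = ext[occl, ])
    },
    h = h, spacing = sp,
    n_nodes = nrow(nodes), n_elements = nrow(tets),
    support_mode = support_mode,
    geom = geom
  ), class = "fea_mesh")
}

# Facets occurring in exactly one tetrahedron, with the opposite node of the
# owning element (used to orient outward normals).
boundary_facets <- function(tets) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  key <- facet_key(faces)
  ord <- order(key)
  ks <- key[ord]
  nk <- length(ks)
  same_next <- c(ks[-nk] == ks[-1], FALSE)
  same_prev <- c(FALSE, same_next[-nk])
  single <- ord[!(same_next | same_prev)]
  list(facets = faces[single, , drop = FALSE], opposite = opp[single])
}

# Order-independent numeric facet key (exact in doubles for < ~2e5 nodes).
facet_key <- function(faces) {
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  n1 <- max(hi) + 1
  (as.numeric(lo) * n1 + mid) * n1 + hi
}

# Unit outward normals and areas for boundary facets.
facet_normals <- function(nodes, fac, opp) {
  v1 <- nodes[fac[, 2], , drop = FALSE] - nodes[fac[, 1], , drop = FALSE]
  v2 <- nodes[fac[, 3], , drop = FALSE] - nodes[fac[, 1], , drop = FALSE]
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  area <- sqrt(rowSums(nrm^2)) / 2
  ctr <- (nodes[fac[, 1], , drop = FALSE] + nodes[fac[, 2], , drop = FALSE] +
            nodes[fac[, 3], , drop = FALSE]) / 3
  outward <- rowSums(nrm * (ctr - nodes[opp, , drop = FALSE]))
  flip <- outward < 0
  nrm[flip, ] <- -nrm[flip, ]
  list(normal = nrm / (2 * area), area = area)
}

#' Element quality report (Jacobian-style shape metric)
#'
#' Per-element shape quality `Q = 1 - V / V_reg(l_rms)` clamped to `[0, 1]`,
#' where `V_reg(l) = l^3 / (6 sqrt(2))` is the volume of the regular
#' tetrahedron with the element's root-mean-square edge length. `Q = 0` is
#' the ideal (regular) shape and values approach 1 for slivers, matching the
#' usual range convention of commercial Jacobian quality metrics (whose
#' exact formulas are proprietary).
#'
#' @param mesh An `fea_mesh`.
#' @param threshold Reporting threshold; the count of elements with
#'   `Q > threshold` is included in the summary (default 0.7).
#' @return An object of class `mesh_quality`: a list with the per-element
#'   tibble `elements` (`element`, `region`, `volume`, `q`), the per-region
#'   `region_counts` tibble and `n_above_threshold`.
#' @examples
#' q <- jacobian_quality(generate_mesh(build_scenario("healthy"), h = 2))
#' q$n_above_threshold
#' @export
jacobian_quality <- function(mesh, threshold = 0.7) {
  stopifnot(inherits(mesh, "fea_mesh"))
  vol <- cpp_tet_volumes(mesh$nodes, mesh$tets)
  bad <- which(vol <= 0)
  if (length(bad))
    stop("invalid-element: non-positive volume in element(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  l2 <- 0
  for (p in seq_len(6)) {
    d <- mesh$nodes[mesh$tets[, pairs[p, 1]], , drop = FALSE] -
      mesh$nodes[mesh$tets[, pairs[p, 2]], , drop = FALSE]
    l2 <- l2 + rowSums(d^2)
  }
  lrms <- sqrt(l2 / 6)
  vreg <- lrms^3 / (6 * sqrt(2))
  q <- pmin(1, pmax(0, 1 - vol / vreg))
  elements <- tibble::tibble(element = seq_along(q), region = mesh$region,
                             volume = vol, q = q)
  structure(list(
    elements = elements,
    region_counts = dplyr::count(elements, .data$region, name = "n_elements"),
    threshold = threshold,
    n_above_threshold = sum(q > threshold)
  ), class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat("<mesh_quality>", nrow(x$elements), "elements; Q in [",
      round(min(x$elements$q), 4), ",", round(max(x$elements$q), 4), "];",
      x$n_above_threshold, "elements with Q >", x$threshold, "\n")
  print(x$region_counts)
  invisible(x)
}

#' Extract a named facet set with areas and outward normals
#'
#' @param mesh An `fea_mesh`.
#' @param set_name Name of a facet set (`"occlusal"` or `"exterior"`).
#' @return A tibble with node indices `n1`, `n2`, `n3`, facet `area` (mm^2)
#'   and unit outward normal components `nx`, `ny`, `nz`.
#' @examples
#' extract_facets(generate_mesh(build_scenario("healthy"), h = 2), "occlusal")
#' @export
extract_facets <- function(mesh, set_name) {
  stopifnot(inherits(mesh, "fea_mesh"))
  if (!set_name %in% names(mesh$facet_sets))
    stop("unknown facet set: ", set_name, call. = FALSE)
  if (!is.null(mesh$facet_data[[set_name]]))
    return(mesh$facet_data[[set_name]])
  fac <- mesh$facet_sets[[set_name]]
  if (nrow(fac) == 0)
    return(tibble::tibble(n1 = integer(), n2 = integer(), n3 = integer(),
                          area = numeric(), nx = numeric(), ny = numeric(),
                          nz = numeric()))
  opp <- facet_opposite(mesh, fac)
  fn <- facet_normals(mesh$nodes, fac, opp)
  tibble::tibble(n1 = fac[, 1], n2 = fac[, 2], n3 = fac[, 3],
                 area = fn$area, nx = fn$normal[, 1], ny = fn$normal[, 2],
                 nz = fn$normal[, 3])
}

# Find, for each facet, a node of the owning tet not on the facet.
facet_opposite <- function(mesh, fac) {
  bnd <- boundary_facets(mesh$tets)
  n1 <- max(mesh$tets) + 1
  key_of <- function(f) {
    lo <- pmin(f[, 1], f[, 2], f[, 3])
    hi <- pmax(f[, 1], f[, 2], f[, 3])
    mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
    (as.numeric(lo) * n1 + mid) * n1 + hi
  }
  idx <- match(key_of(fac), key_of(bnd$facets))
  if (anyNA(idx)) stop("facet set contains non-boundary facets", call. = FALSE)
  bnd$opposite[idx]
}

#' @export
print.fea_mesh <- function(x, ...) {
  cat("<fea_mesh>", x$n_nodes, "nodes,", x$n_elements,
      "tetrahedra (h =", x$h, "mm)\n")
  print(table(x$region))
  invisible(x)
}

#' Write a mesh (and optional fields) as a legacy ASCII VTK unstructured grid
#'
#' Region tags are written as integer cell data (`region_id`, indexing
#' [REGION_LEVELS]). Extra per-node vectors/scalars and per-element scalars
#' can be attached.
#'
#' @param mesh An `fea_mesh`.
#' @param file Output path (`.vtk`).
#' @param point_data Named list of length-n numeric vectors or n x 3
#'   matrices.
#' @param cell_data Named list of length-m numeric vectors.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- mesh$n_nodes; m <- mesh$n_elements
  writeLines(c("# vtk DataFile Version 3.0", "toothfea mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(paste(format(mesh$nodes[, 1], trim = TRUE),
                   format(mesh$nodes[, 2], trim = TRUE),
                   format(mesh$nodes[, 3], trim = TRUE)), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(format(v[, 1], trim = TRUE),
                         format(v[, 2], trim = TRUE),
                         format(v[, 3], trim = TRUE)), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, trim = TRUE), con)
      }
    }
  }
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, REGION_LEVELS) - 1L), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], trim = TRUE), con)
  }
  invisible(file)
}

#' Read a tetrahedral mesh from a legacy ASCII VTK unstructured grid
#'
#' Accepts externally produced meshes: linear tetrahedra (cell type 10) with
#' an integer `region_id` cell-data array indexing [REGION_LEVELS]. Node and
#' facet sets are rebuilt from the connectivity and region tags with the
#' same rules as [generate_mesh()].
#'
#' @param file Path to a `.vtk` file.
#' @param cej_z Optional crown-base height used to clip the lateral
#'   `fixed_support` set (default: no clipping).
#' @return An `fea_mesh`.
#' @export
read_vtk_mesh <- function(file, cej_z = NULL) {
  ln <- readLines(file)
  grab <- function(pat) grep(pat, ln)[1]
  ip <- grab("^POINTS")
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- scan(text = ln[(ip + 1):length(ln)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  ic <- grab("^CELLS")
  m <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cel <- scan(text = ln[(ic + 1):length(ln)], n = 5 * m, quiet = TRUE)
  cel <- matrix(as.integer(cel), ncol = 5, byrow = TRUE)
  if (any(cel[, 1] != 4L))
    stop("read_vtk_mesh supports linear tetrahedra only", call. = FALSE)
  tets <- cel[, 2:5, drop = FALSE] + 1L
  it <- grab("^CELL_TYPES")
  types <- scan(text = ln[(it + 1):length(ln)], n = m, quiet = TRUE)
  if (any(types != 10))
    stop("read_vtk_mesh supports cell type 10 (tetrahedron) only",
         call. = FALSE)
  ir <- grep("^SCALARS region_id", ln)[1]
  if (is.na(ir)) stop("missing region_id cell data", call. = FALSE)
  rid <- scan(text = ln[(ir + 2):length(ln)], n = m, quiet = TRUE)
  region <- REGION_LEVELS[as.integer(rid) + 1L]

  bnd <- boundary_facets(tets)
  fac <- bnd$facets
  nrm <- facet_normals(nodes, fac, bnd$opposite)
  edge <- sqrt(rowSums((nodes[tets[, 1], ] - nodes[tets[, 2], ])^2))
  h <- stats::median(edge)
  fc_z <- (nodes[fac[, 1], 3] + nodes[fac[, 2], 3] + nodes[fac[, 3], 3]) / 3
  occl <- nrm$normal[, 3] >= cos(10 * pi / 180) & fc_z >= max(nodes[, 3]) - h
  tol <- h / 4
  lateral <- nodes[, 1] <= min(nodes[, 1]) + tol |
    nodes[, 1] >= max(nodes[, 1]) - tol |
    nodes[, 2] <= min(nodes[, 2]) + tol |
    nodes[, 2] >= max(nodes[, 2]) - tol
  if (!is.null(cej_z)) lateral <- lateral & nodes[, 3] <= cej_z + tol
  structure(list(
    nodes = nodes, tets = tets, region = region,
    node_sets = list(
      external_surface = sort(unique(as.vector(fac))),
      fixed_support = which(lateral),
      composite_cement_nodes = sort(unique(as.vector(
        tets[region %in% c("COMPOSITE", "CEMENT"), , drop = FALSE]))),
      insert_nodes = sort(unique(as.vector(
        tets[region == "INSERT", , drop = FALSE])))),
    facet_sets = list(exterior = fac, occlusal = fac[occl, , drop = FALSE]),
    facet_data = {
      ext <- tibble::tibble(n1 = fac[, 1], n2 = fac[, 2], n3 = fac[, 3],
                            area = nrm$area, nx = nrm$normal[, 1],
                            ny = nrm$normal[, 2], nz = nrm$normal[, 3])
      list(exterior = ext, occlusal = ext[occl, ])
    },
    h = h, spacing = rep(h, 3),
    n_nodes = nrow(nodes), n_elements = nrow(tets),
    support_mode = "full", geom = NULL
  ), class = "fea_mesh")
}
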