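#' Region labels of the synthetic restored-tooth model
#'
#' Ordered set of region labels used throughout the package. Every point of
#' the model domain maps to exactly one label; points of the bounding box
#' that belong to no region are reported as `"OUTSIDE"`.
#'
#' @format Character vector of the eight region names.
#' @export
REGION_LEVELS <- c("ENAMEL", "DENTIN", "PULP", "PDL", "BONE",
                   "COMPOSITE", "CEMENT", "INSERT")

#' Scenario identifiers of the five-model study
#'
#' `healthy` (intact tooth), `small_c`/`big_c` (cavity restored with
#' composite only) and `small_ic`/`big_ic` (insert + cement + composite cap).
#'
#' @format Character vector of the five scenario ids.
#' @export
SCENARIO_IDS <- c("healthy", "small_c", "small_ic", "big_c", "big_ic")

#' Parametric dimensions of the synthetic tooth model
#'
#' The synthetic stand-in for a scanned mandibular first molar is an elliptic
#' cylinder (vestibulo-oral by mesio-distal cross-section) with a flat
#' occlusal surface, an enamel crown shell, a dentin body, an elliptic pulp
#' chamber, a periodontal-ligament (PDL) shell below the cemento-enamel
#' junction, and a rectangular supporting bone block. Class-I-like cavities
#' are vertical cylinders entered from the occlusal surface.
#'
#' All lengths are in millimetres. The z axis is vertical with the root apex
#' plane at z = 0 and the occlusal plane at z = `height`.
#'
#' @param height Tooth height (root apex to occlusal plane).
#' @param vo_width Vestibulo-oral width of the tooth ellipse.
#' @param md_width Mesio-distal width of the tooth ellipse.
#' @param crown_height Height of the enamel-covered crown above the
#'   cemento-enamel junction (CEJ).
#' @param enamel_occlusal_thickness Occlusal enamel cap thickness.
#' @param enamel_lateral_thickness Lateral enamel band thickness (inner
#'   offset of the tooth ellipse).
#' @param pulp_semi_axes Semi-axes of the elliptic pulp chamber (x, y).
#' @param pulp_z_range Vertical extent of the pulp chamber, `c(lo, hi)`.
#' @param cavity_diameter Diameter of the cylindrical cavity preparation.
#' @param insert_diameter Diameter of the hydroxyapatite insert.
#' @param insert_thickness_small,insert_thickness_big Insert heights defining
#'   the small and big cavity depths.
#' @param cement_floor_thickness Luting cement layer thickness beneath the
#'   insert.
#' @param composite_cap_thickness Composite top layer covering the insert in
#'   the enamel part of the tooth.
#' @param bone_block Bone block extents `c(x, y, z)`; the block is centred
#'   laterally on the tooth axis and its top face sits at the CEJ.
#' @param pdl_thickness PDL shell thickness around the root.
#'
#' @return An object of class `tooth_dims` (a validated named list).
#' @examples
#' d <- tooth_dims()
#' d$height
#' @export
tooth_dims <- function(height = 21, vo_width = 10, md_width = 11,
                       crown_height = 8,
                       enamel_occlusal_thickness = 2.5,
                       enamel_lateral_thickness = 1.5,
                       pulp_semi_axes = c(1.5, 1.8),
                       pulp_z_range = c(2, 12),
                       cavity_diameter = 5.5,
                       insert_diameter = 4.7,
                       insert_thickness_small = 1.7,
                       insert_thickness_big = 4.7,
                       cement_floor_thickness = 0.5,
                       composite_cap_thickness = 2.0,
                       bone_block = c(16, 17, 14),
                       pdl_thickness = 0.25) {
  d <- list(height = height, vo_width = vo_width, md_width = md_width,
            crown_height = crown_height,
            enamel_occlusal_thickness = enamel_occlusal_thickness,
            enamel_lateral_thickness = enamel_lateral_thickness,
            pulp_semi_axes = pulp_semi_axes, pulp_z_range = pulp_z_range,
            cavity_diameter = cavity_diameter,
            insert_diameter = insert_diameter,
            insert_thickness_small = insert_thickness_small,
            insert_thickness_big = insert_thickness_big,
            cement_floor_thickness = cement_floor_thickness,
            composite_cap_thickness = composite_cap_thickness,
            bone_block = bone_block, pdl_thickness = pdl_thickness)
  scalars <- unlist(d[setdiff(names(d), "composite_cap_thickness")])
  if (any(!is.finite(unlist(d))))
    stop("invalid-geometry: all dimensions must be finite", call. = FALSE)
  if (any(scalars <= 0))
    stop("invalid-geometry: all dimensions must be strictly positive",
         call. = FALSE)
  if (composite_cap_thickness < 0)
    stop("invalid-geometry: composite_cap_thickness must be >= 0",
         call. = FALSE)
  if (cavity_diameter >= min(vo_width, md_width))
    stop("invalid-geometry: cavity_diameter must be smaller than the tooth",
         call. = FALSE)
  if (insert_diameter >= cavity_diameter)
    stop("invalid-geometry: insert_diameter must be < cavity_diameter",
         call. = FALSE)
  if (length(pulp_semi_axes) != 2L || length(pulp_z_range) != 2L ||
      length(bone_block) != 3L)
    stop("invalid-geometry: pulp_semi_axes/pulp_z_range are pairs and ",
         "bone_block a triple", call. = FALSE)
  if (pulp_z_range[1] >= pulp_z_range[2] || pulp_z_range[2] >= height)
    stop("invalid-geometry: pulp_z_range must be increasing and below the ",
         "occlusal plane", call. = FALSE)
  if (crown_height >= height)
    stop("invalid-geometry: crown_height must be below tooth height",
         call. = FALSE)
  if (bone_block[1] <= vo_width + 2 * pdl_thickness ||
      bone_block[2] <= md_width + 2 * pdl_thickness)
    stop("invalid-geometry: bone block must enclose tooth plus PDL laterally",
         call. = FALSE)
  structure(d, class = "tooth_dims")
}

#' Build the parametric geometry of one restoration scenario
#'
#' Constructs the deterministic point-classifier for one of the five study
#' scenarios. Restoration stacks are nested coaxial cylinders entered from
#' the occlusal surface: the composite cap (thickness
#' `composite_cap_thickness`), then - in insert scenarios - the insert
#' cylinder with a cement layer around it and a cement floor of
#' `cement_floor_thickness` beneath it. The cavity depth is derived as
#' `composite_cap_thickness + cement_floor_thickness + insert_thickness`,
#' identical for the composite-only control of the same size so that control
#' and insert scenario share one preparation.
#'
#' @param scenario_id One of [SCENARIO_IDS].
#' @param dims A [tooth_dims()] object.
#'
#' @return An object of class `c("tooth_geometry", "fea_geometry")` with the
#'   scenario, derived cavity measures and bounding box.
#' @examples
#' g <- build_scenario("small_ic")
#' g$cavity_depth
#' @export
build_scenario <- function(scenario_id = SCENARIO_IDS,
                           dims = tooth_dims()) {
  scenario_id <- match.arg(scenario_id)
  stopifnot(inherits(dims, "tooth_dims"))
  size <- if (grepl("^small", scenario_id)) "small"
          else if (grepl("^big", scenario_id)) "big" else "none"
  has_cavity <- scenario_id != "healthy"
  has_insert <- grepl("_ic$", scenario_id)
  t_ins <- switch(size, small = dims$insert_thickness_small,
                  big = dims$insert_thickness_big, none = NA_real_)
  cavity_depth <- if (has_cavity)
    dims$composite_cap_thickness + dims$cement_floor_thickness + t_ins
  else 0
  if (has_cavity) {
    if (cavity_depth >= dims$height - 1)
      stop("invalid-geometry: cavity depth ", cavity_depth,
           " mm reaches within 1 mm of the tooth height", call. = FALSE)
    floor_z <- dims$height - cavity_depth
    if (floor_z <= dims$pulp_z_range[2])
      stop("invalid-geometry: cavity (floor at z = ", floor_z,
           ") intersects the pulp chamber", call. = FALSE)
  }
  cej <- dims$height - dims$crown_height
  bb <- dims$bone_block
  bbox <- rbind(lower = c(-bb[1] / 2, -bb[2] / 2, cej - bb[3]),
                upper = c(bb[1] / 2, bb[2] / 2, dims$height))
  colnames(bbox) <- c("x", "y", "z")
  structure(list(
    scenario_id = scenario_id,
    dims = dims,
    size = size,
    has_cavity = has_cavity,
    has_insert = has_insert,
    insert_thickness = t_ins,
    cavity_depth = cavity_depth,
    cavity_floor_z = if (has_cavity) dims$height - cavity_depth else NA_real_,
    insert_top_z = if (has_insert)
      dims$height - dims$composite_cap_thickness else NA_real_,
    insert_bottom_z = if (has_insert)
      dims$height - dims$composite_cap_thickness - t_ins else NA_real_,
    cej_z = cej,
    bbox = bbox
  ), class = c("tooth_geometry", "fea_geometry"))
}

#' Classify points into model regions
#'
#' Deterministic, total classification of points of the bounding box into
#' the region labels of [REGION_LEVELS], in the fixed priority order
#' INSERT, CEMENT, COMPOSITE, PULP, ENAMEL, DENTIN, PDL, BONE. Points of the
#' bounding box belonging to no region return `"OUTSIDE"`.
#'
#' @param geom An `fea_geometry` object.
#' @param points Numeric matrix (n x 3) of xyz coordinates in mm.
#' @return Character vector of length n with region labels.
#' @examples
#' g <- build_scenario("small_ic")
#' classify_points(g, rbind(c(0, 0, 20), c(0, 0, 18)))
#' @export
classify_points <- function(geom, points) {
  UseMethod("classify_points")
}

#' @export
classify_points.tooth_geometry <- function(geom, points) {
  points <- as_points(points)
  d <- geom$dims
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  a <- d$vo_width / 2; b <- d$md_width / 2
  in_ellipse <- (x / a)^2 + (y / b)^2 <= 1
  in_tooth <- in_ellipse & z >= 0 & z <= d$height
  lab <- rep("OUTSIDE", nrow(points))

  r2 <- x^2 + y^2
  if (geom$has_cavity) {
    rc <- d$cavity_diameter / 2
    in_cavity <- r2 <= rc^2 & z >= geom$cavity_floor_z & z <= d$height
  } else {
    in_cavity <- rep(FALSE, nrow(points))
  }

  # tissues first (lowest priority), then restoration overrides inside cavity
  pa <- d$pulp_semi_axes[1]; pb <- d$pulp_semi_axes[2]
  in_pulp <- in_tooth &
    (x / pa)^2 + (y / pb)^2 <= 1 &
    z >= d$pulp_z_range[1] & z <= d$pulp_z_range[2]
  ai <- a - d$enamel_lateral_thickness
  bi <- b - d$enamel_lateral_thickness
  in_enamel <- in_tooth & z >= geom$cej_z &
    (z >= d$height - d$enamel_occlusal_thickness |
       (x / ai)^2 + (y / bi)^2 > 1)
  ap <- a + d$pdl_thickness; bp <- b + d$pdl_thickness
  in_pdl <- !in_tooth & z < geom$cej_z & z >= -d$pdl_thickness &
    (x / ap)^2 + (y / bp)^2 <= 1
  bb <- geom$bbox
  in_bone <- z >= bb["lower", "z"] & z <= geom$cej_z &
    x >= bb["lower", "x"] & x <= bb["upper", "x"] &
    y >= bb["lower", "y"] & y <= bb["upper", "y"]

  lab[in_bone] <- "BONE"
  lab[in_pdl] <- "PDL"
  lab[in_tooth] <- "DENTIN"
  lab[in_enamel] <- "ENAMEL"
  lab[in_pulp] <- "PULP"
  lab[in_cavity] <- "COMPOSITE"
  if (geom$has_insert) {
    ri <- d$insert_diameter / 2
    in_cem <- in_cavity & z <= geom$insert_top_z     # annulus + floor layer
    in_ins <- r2 <= ri^2 & z >= geom$insert_bottom_z & z <= geom$insert_top_z
    lab[in_cem] <- "CEMENT"
    lab[in_ins] <- "INSERT"
  }
  lab
}

#' Classify a single point
#'
#' Scalar wrapper around [classify_points()] that rejects points outside the
#' bounding box.
#'
#' @inheritParams classify_points
#' @param point Numeric xyz triple in mm.
#' @return A single region label.
#' @export
classify_point <- function(geom, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3)
  bb <- geom$bbox
  if (any(point < bb["lower", ] - 1e-12) || any(point > bb["upper", ] + 1e-12))
    stop("out-of-domain: point lies outside the geometry bounding box",
         call. = FALSE)
  classify_points(geom, matrix(point, 1))
}

#' Expected region volumes of a scenario geometry
#'
#' Closed-form volumes for the cylindrical restoration components (insert,
#' cement, composite) and, optionally, Monte-Carlo estimates with standard
#' errors for every region of the model.
#'
#' @param geom A `tooth_geometry`.
#' @param n_mc Number of Monte-Carlo sample points over the bounding box
#'   (0 = closed forms only).
#' @param seed RNG seed for the Monte-Carlo quadrature.
#' @return A tibble with columns `region`, `volume` (mm^3), `se` (mm^3,
#'   `NA` for closed forms) and `method`.
#' @examples
#' expected_region_volumes(build_scenario("small_ic"))
#' @export
expected_region_volumes <- function(geom, n_mc = 0, seed = 1) {
  stopifnot(inherits(geom, "tooth_geometry"))
  d <- geom$dims
  rc <- d$cavity_diameter / 2
  closed <- c(COMPOSITE = 0, CEMENT = 0, INSERT = 0)
  if (geom$has_cavity && !geom$has_insert) {
    closed["COMPOSITE"] <- pi * rc^2 * geom$cavity_depth
  } else if (geom$has_insert) {
    ri <- d$insert_diameter / 2
    closed["INSERT"] <- pi * ri^2 * geom$insert_thickness
    closed["CEMENT"] <- pi * (rc^2 - ri^2) * geom$insert_thickness +
      pi * rc^2 * d$cement_floor_thickness
    closed["COMPOSITE"] <- pi * rc^2 * d$composite_cap_thickness
  }
  out <- tibble::tibble(region = names(closed), volume = unname(closed),
                        se = NA_real_, method = "closed_form")
  if (n_mc > 0) {
    mc <- mc_region_volumes(geom, n_mc, seed)
    out <- dplyr::bind_rows(out, mc)
  }
  out
}

#' Monte-Carlo region volumes
#'
#' Uniform rejection sampling over the bounding box; the per-region volume
#' estimate is `p * V_box` with binomial standard error. Used to validate
#' both the closed-form volumes and mesh volume conservation.
#'
#' @inheritParams expected_region_volumes
#' @param n Number of uniform sample points.
#' @return A tibble with columns `region`, `volume`, `se`, `method`.
#' @export
mc_region_volumes <- function(geom, n = 1e5, seed = 1) {
  bb <- geom$bbox
  vbox <- prod(bb["upper", ] - bb["lower", ])
  pts <- withr_seed(seed, {
    matrix(stats::runif(3 * n), ncol = 3) %*%
      diag(bb["upper", ] - bb["lower", ]) +
      matrix(bb["lower", ], n, 3, byrow = TRUE)
  })
  lab <- classify_points(geom, pts)
  counts <- table(factor(lab, levels = c(REGION_LEVELS, "OUTSIDE")))
  p <- as.numeric(counts) / n
  tibble::tibble(region = names(counts),
                 volume = p * vbox,
                 se = sqrt(p * (1 - p) / n) * vbox,
                 method = "monte_carlo")
}

# Coerce to an n x 3 numeric matrix.
as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

# Evaluate expr under a local RNG seed without touching the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.tooth_geometry <- function(x, ...) {
  cat("<tooth_geometry> scenario:", x$scenario_id, "\n")
  if (x$has_cavity)
    cat("  cavity depth:", x$cavity_depth, "mm (floor at z =",
        x$cavity_floor_z, "mm)\n")
  cat("  bounding box: [", paste(x$bbox["lower", ], collapse = ", "), "] to [",
      paste(x$bbox["upper", ], collapse = ", "), "] mm\n")
  invisible(x)
}
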