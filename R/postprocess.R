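#' Region groups used for reporting
#'
#' The study reports three component groups: `enamel`, `dentin` and
#' `restoration` (the union of composite, cement and insert, because maxima
#' are reported for the restoration as a whole).
#'
#' @format Named list mapping group name to region labels.
#' @export
REGION_GROUPS <- list(enamel = "ENAMEL",
                      dentin = "DENTIN",
                      restoration = c("COMPOSITE", "CEMENT", "INSERT"))

#' Descriptive statistics of one region group
#'
#' Unweighted statistics over the per-element von Mises stresses of the
#' group's elements (average, standard deviation, quartiles by linear
#' interpolation between order statistics, maximum) plus the maximum
#' displacement magnitude over the nodes belonging to the group's elements.
#'
#' @param solution An `fea_solution` from [run_phase()].
#' @param group One of `names(REGION_GROUPS)`.
#' @return A one-row tibble, or a zero-row tibble if the group has no
#'   elements (e.g. `restoration` in the healthy scenario): absent, not zero.
#' @examples
#' m <- generate_mesh(build_scenario("healthy"), h = 2)
#' sol <- run_phase(m, default_material_table(), "mechanical_only")
#' region_stats(sol, "enamel")
#' @export
region_stats <- function(solution, group = names(REGION_GROUPS)) {
  group <- match.arg(group)
  stopifnot(inherits(solution, "fea_solution"))
  mesh <- solution$mesh
  in_group <- mesh$region %in% REGION_GROUPS[[group]]
  empty <- tibble::tibble(group = character(), n_elements = integer(),
                          average = numeric(), stdev = numeric(),
                          q1 = numeric(), median = numeric(), q3 = numeric(),
                          max_vm = numeric(), max_displacement = numeric())
  if (!any(in_group)) return(empty)
  vm <- solution$stress$von_mises[in_group]
  nodes <- unique(as.vector(mesh$tets[in_group, , drop = FALSE]))
  disp <- sqrt(rowSums(solution$u[nodes, , drop = FALSE]^2))
  qs <- stats::quantile(vm, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(group = group, n_elements = sum(in_group),
                 average = mean(vm),
                 stdev = if (sum(in_group) > 1) stats::sd(vm) else 0,
                 q1 = qs[1], median = qs[2], q3 = qs[3],
                 max_vm = max(vm), max_displacement = max(disp))
}

#' Descriptive statistics of all region groups
#'
#' @inheritParams region_stats
#' @return A tibble with one row per non-empty group.
#' @export
solution_region_stats <- function(solution) {
  dplyr::bind_rows(lapply(names(REGION_GROUPS), region_stats,
                          solution = solution))
}

#' Volumetric contraction of the restoration
#'
#' Compares the restoration volume before and after the shrinkage phase.
#' The default `element` method sums deformed tetrahedron volumes (node
#' positions `x + u`); the `cylinder_fit` method mirrors the published
#' description of approximating the restoration as a cylinder: new radius
#' from the mean radial displacement of the lateral boundary nodes, new
#' height from the mean axial displacements of the top and bottom node
#' layers, and `V1 = pi r1^2 h1`. Both are reported.
#'
#' @param solution A phase-1 `fea_solution`.
#' @param regions Region labels forming the restoration (default composite,
#'   cement and insert).
#' @return A tibble of class `contraction_result` with columns `method`,
#'   `V0`, `V1` (mm^3) and `rate` (percent, `100 (V0 - V1) / V0`).
#' @export
contraction_rate <- function(solution,
                             regions = c("COMPOSITE", "CEMENT", "INSERT")) {
  stopifnot(inherits(solution, "fea_solution"))
  mesh <- solution$mesh
  sel <- mesh$region %in% regions
  if (!any(sel))
    stop("empty restoration region: no elements tagged ",
         paste(regions, collapse = "/"), call. = FALSE)
  tets <- mesh$tets[sel, , drop = FALSE]
  v0 <- sum(cpp_tet_volumes(mesh$nodes, tets))
  deformed <- mesh$nodes + solution$u
  v1 <- sum(cpp_tet_volumes(deformed, tets))

  nodes <- unique(as.vector(tets))
  xyz <- mesh$nodes[nodes, , drop = FALSE]
  u <- solution$u[nodes, , drop = FALSE]
  tol <- 1e-8 + 0.25 * min(mesh$spacing)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  lat <- r >= max(r) - tol
  ur <- (xyz[lat, 1] * u[lat, 1] + xyz[lat, 2] * u[lat, 2]) / r[lat]
  top <- xyz[, 3] >= max(xyz[, 3]) - tol
  bot <- xyz[, 3] <= min(xyz[, 3]) + tol
  r0 <- mean(r[lat]); r1 <- r0 + mean(ur)
  h0 <- mean(xyz[top, 3]) - mean(xyz[bot, 3])
  h1 <- h0 + mean(u[top, 3]) - mean(u[bot, 3])
  out <- tibble::tibble(
    method = c("element", "cylinder_fit"),
    V0 = c(v0, pi * r0^2 * h0),
    V1 = c(v1, pi * r1^2 * h1))
  out$rate <- 100 * (out$V0 - out$V1) / out$V0
  class(out) <- c("contraction_result", class(out))
  out
}

#' Percent decrease of an insert scenario relative to its control
#'
#' `100 (control - insert) / control`. Negative values mean the insert
#' scenario increased the quantity; they are flagged through the
#' `"increase"` attribute (cf. the published dentin pair where the insert
#' slightly raised the maximum stress).
#'
#' @param control_value Control (composite-only) value, must be > 0.
#' @param insert_value Insert-scenario value.
#' @return Numeric percent decrease(s) with logical attribute `increase`.
#' @examples
#' percent_decrease(518.47, 322.63)  # 37.77
#' @export
percent_decrease <- function(control_value, insert_value) {
  if (any(!is.finite(control_value)) || any(control_value <= 0))
    stop("control_value must be positive", call. = FALSE)
  pd <- 100 * (control_value - insert_value) / control_value
  structure(pd, increase = pd < 0)
}

#' Mean dentin stress near the cavity floor
#'
#' Operationalizes "stress at the preparation bottom": the mean per-element
#' von Mises stress over dentin elements whose centroid lies within
#' `distance` below the cavity floor and inside the cavity cylinder's
#' radius.
#'
#' @param solution An `fea_solution` whose mesh was built from a cavity
#'   scenario.
#' @param distance Depth of the sampling layer below the cavity floor (mm).
#' @return Mean von Mises stress (MPa).
#' @export
near_floor_stress <- function(solution, distance = 0.5) {
  stopifnot(inherits(solution, "fea_solution"))
  if (distance <= 0) stop("distance must be > 0", call. = FALSE)
  geom <- solution$mesh$geom
  if (is.null(geom) || !isTRUE(geom$has_cavity))
    stop("near_floor_stress requires a cavity scenario", call. = FALSE)
  mesh <- solution$mesh
  ctr <- (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
  rc <- geom$dims$cavity_diameter / 2
  zf <- geom$cavity_floor_z
  sel <- mesh$region == "DENTIN" &
    ctr[, 3] < zf & ctr[, 3] >= zf - distance &
    ctr[, 1]^2 + ctr[, 2]^2 <= rc^2
  if (!any(sel))
    stop("empty-selection: no dentin elements within ", distance,
         " mm below the cavity floor", call. = FALSE)
  mean(solution$stress$von_mises[sel])
}

#' Write a study report to disk
#'
#' Writes CSV tables mirroring the study's reporting layout (stress maxima
#' with percent decreases, descriptive statistics, displacement maxima,
#' contraction rates) plus a JSON file with the full numeric payload that
#' round-trips through [read_report()].
#'
#' @param study A `study_report` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(study$stats, "descriptive_stats.csv")
  wcsv(study$percent_decrease, "percent_decrease.csv")
  wcsv(study$contraction, "contraction.csv")
  wcsv(study$near_floor, "near_floor_stress.csv")
  if (nrow(study$failures)) wcsv(study$failures, "failures.csv")
  pj <- file.path(dir, "report.json")
  payload <- list(stats = study$stats,
                  percent_decrease = study$percent_decrease,
                  contraction = study$contraction,
                  near_floor = study$near_floor,
                  failures = study$failures,
                  meta = study$meta)
  jsonlite::write_json(payload, pj, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  paths <- c(paths, pj)
  invisible(paths)
}

#' Read a study report back from its JSON payload
#'
#' @param path Path to a `report.json` written by [write_report()] (or the
#'   directory containing it).
#' @return A `study_report` object.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(df, template) {
    if (length(df) == 0 || (is.data.frame(df) && nrow(df) == 0))
      return(template)
    tibble::as_tibble(df)
  }
  structure(list(
    stats = as_tb(x$stats, empty_stats()),
    percent_decrease = as_tb(x$percent_decrease, empty_decrease()),
    contraction = as_tb(x$contraction, empty_contraction()),
    near_floor = as_tb(x$near_floor, empty_near_floor()),
    failures = as_tb(x$failures, empty_failures()),
    meta = x$meta
  ), class = "study_report")
}

empty_stats <- function() {
  tibble::tibble(scenario = character(), phase = character(),
                 group = character(), n_elements = integer(),
                 average = numeric(), stdev = numeric(), q1 = numeric(),
                 median = numeric(), q3 = numeric(), max_vm = numeric(),
                 max_displacement = numeric())
}
empty_decrease <- function() {
  tibble::tibble(phase = character(), group = character(),
                 metric = character(), control_scenario = character(),
                 insert_scenario = character(), control = numeric(),
                 insert = numeric(), decrease_pct = numeric(),
                 increase = logical())
}
empty_contraction <- function() {
  tibble::tibble(scenario = character(), method = character(),
                 V0 = numeric(), V1 = numeric(), rate = numeric())
}
empty_near_floor <- function() {
  tibble::tibble(scenario = character(), phase = character(),
                 distance = numeric(), mean_vm = numeric())
}
empty_failures <- function() {
  tibble::tibble(scenario = character(), error = character())
}
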