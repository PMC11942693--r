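#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved loading phase into a per-element tibble
#'
#' @param x An `fea_solution`.
#' @param ... Unused.
#' @return A tibble with one row per element: `element`, `region`, Voigt
#'   stress components, `von_mises` (MPa) and `delta_T` (degC).
#' @export
tidy.fea_solution <- function(x, ...) {
  v <- x$stress$voigt
  tibble::tibble(element = seq_len(nrow(v)), region = x$mesh$region,
                 s_xx = v[, 1], s_yy = v[, 2], s_zz = v[, 3],
                 s_yz = v[, 4], s_xz = v[, 5], s_xy = v[, 6],
                 von_mises = x$stress$von_mises, delta_T = x$delta_T)
}

#' One-row summary of a solved loading phase
#'
#' @param x An `fea_solution`.
#' @param ... Unused.
#' @return A one-row tibble: phase, mesh size, displacement and stress
#'   maxima, and reaction totals.
#' @export
glance.fea_solution <- function(x, ...) {
  tibble::tibble(phase = x$phase, n_nodes = x$mesh$n_nodes,
                 n_elements = x$mesh$n_elements,
                 max_displacement = max(sqrt(rowSums(x$u^2))),
                 max_von_mises = max(x$stress$von_mises),
                 reaction_z = x$reaction_totals["z"],
                 applied_z = x$applied_totals["z"])
}

#' Tidy a study report into one long tibble
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return The per-scenario/phase/group statistics tibble.
#' @export
tidy.study_report <- function(x, ...) x$stats

#' One-row summary of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A one-row tibble with scenario counts, mesh size and the
#'   element-method contraction range.
#' @export
glance.study_report <- function(x, ...) {
  el <- x$contraction[x$contraction$method == "element", ]
  tibble::tibble(n_scenarios = length(unique(x$stats$scenario)),
                 n_failures = nrow(x$failures),
                 h = x$meta$h,
                 contraction_min = if (nrow(el)) min(el$rate) else NA_real_,
                 contraction_max = if (nrow(el)) max(el$rate) else NA_real_)
}

#' Tidy a mesh quality report
#'
#' @param x A `mesh_quality`.
#' @param ... Unused.
#' @return The per-element tibble (`element`, `region`, `volume`, `q`).
#' @export
tidy.mesh_quality <- function(x, ...) x$elements
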