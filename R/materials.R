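#' Calibrate the shrinkage-equivalent thermal expansion coefficient
#'
#' The thermal analog emulates polymerization contraction by cooling the
#' curing materials by `delta_T` with a linear expansion coefficient `alpha`
#' chosen so that the free volumetric shrinkage matches `S_target`:
#' `(1 + alpha * (-delta_T))^3 = 1 - S_target`, hence
#' `alpha = (1 - (1 - S_target)^(1/3)) / delta_T`.
#'
#' @param S_target Volumetric shrinkage fraction in (0, 1) (default 0.037,
#'   i.e. 3.7 % free contraction).
#' @param delta_T Temperature drop in degrees C (default 26, i.e. 36 to 10).
#' @return Linear expansion coefficient in 1/degC.
#' @examples
#' calibrate_alpha(0.037, 26)
#' @export
calibrate_alpha <- function(S_target = 0.037, delta_T = 26) {
  if (!is.finite(S_target) || S_target <= 0 || S_target >= 1)
    stop("S_target must lie in (0, 1)", call. = FALSE)
  if (!is.finite(delta_T) || delta_T <= 0)
    stop("delta_T must be positive", call. = FALSE)
  (1 - (1 - S_target)^(1 / 3)) / delta_T
}

#' Default material table
#'
#' Per-region isotropic linear elastic constants (Young's modulus in MPa,
#' Poisson ratio), linear thermal expansion `alpha` (1/degC) and thermal
#' conductivity `k`. Default `alpha` is the shrinkage-calibrated value for
#' the polymerizing materials (composite and cement) and 0 elsewhere, so the
#' thermal analog strains only the curing restoration. `alpha_mode =
#' "literature"` instead assigns typical literature expansion coefficients
#' to enamel (11.4e-6), dentin (8e-6) and the hydroxyapatite insert
#' (13.3e-6) in addition to the calibrated composite/cement value.
#'
#' The periodontal ligament has no published row in the study's property
#' set; a literature-typical soft record (E = 50 MPa, nu = 0.45) is used and
#' can be overridden. Conductivities only matter through ratios under the
#' fully Dirichlet-pinned boundary conditions, so `k = 1` everywhere.
#'
#' @param alpha_mode `"shrinkage"` (default) or `"literature"`.
#' @param S_target,delta_T Passed to [calibrate_alpha()].
#' @param T_ref Reference (stress-free) temperature in degC, default 36.
#' @param overrides Optional named list `list(REGION = list(field = value))`
#'   applied after defaults, e.g. `list(PDL = list(E = 68.9))`.
#' @return A tibble of class `material_table` with columns `region`, `E`,
#'   `nu`, `alpha`, `k`, and attribute `T_ref`.
#' @examples
#' default_material_table()
#' @export
default_material_table <- function(alpha_mode = c("shrinkage", "literature"),
                                   S_target = 0.037, delta_T = 26,
                                   T_ref = 36, overrides = NULL) {
  alpha_mode <- match.arg(alpha_mode)
  a_cal <- calibrate_alpha(S_target, delta_T)
  tab <- tibble::tibble(
    region = REGION_LEVELS,
    E = c(84100, 18600, 6.8, 50, 1370, 16600, 4000, 100000),
    nu = c(0.3, 0.31, 0.45, 0.45, 0.3, 0.24, 0.35, 0.28),
    alpha = c(0, 0, 0, 0, 0, a_cal, a_cal, 0),
    k = 1)
  if (alpha_mode == "literature") {
    tab$alpha[tab$region == "ENAMEL"] <- 11.4e-6
    tab$alpha[tab$region == "DENTIN"] <- 8e-6
    tab$alpha[tab$region == "INSERT"] <- 13.3e-6
  }
  if (!is.null(overrides)) {
    for (reg in names(overrides)) {
      if (!reg %in% tab$region)
        stop("unknown region in material overrides: ", reg, call. = FALSE)
      for (f in names(overrides[[reg]]))
        tab[tab$region == reg, f] <- overrides[[reg]][[f]]
    }
  }
  validate_materials(tab)
  structure(tab, T_ref = T_ref, class = c("material_table", class(tab)))
}

validate_materials <- function(tab) {
  stopifnot(all(REGION_LEVELS %in% tab$region))
  if (any(tab$E <= 0) || any(tab$nu < 0) || any(tab$nu >= 0.5) ||
      any(tab$alpha < 0) || any(tab$k <= 0))
    stop("material record out of range (need E > 0, 0 <= nu < 0.5, ",
         "alpha >= 0, k > 0)", call. = FALSE)
  invisible(tab)
}

#' Isotropic elasticity tensor in Voigt notation
#'
#' 6 x 6 stiffness in Voigt order (xx, yy, zz, yz, xz, xy) with the
#' engineering-shear convention: normal block `lambda + 2 mu` diagonal /
#' `lambda` off-diagonal, shear diagonal `mu`, with Lame parameters
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))` and `mu = E / (2 (1 + nu))`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio (must be < 0.5).
#' @return A 6 x 6 numeric matrix (MPa).
#' @examples
#' elasticity_tensor(18600, 0.31)
#' @export
elasticity_tensor <- function(E, nu) {
  stopifnot(E > 0)
  if (nu >= 0.5)
    stop("singular-material: Poisson ratio must be < 0.5", call. = FALSE)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# Per-element material vectors in element order.
element_materials <- function(mesh, materials) {
  idx <- match(mesh$region, materials$region)
  if (anyNA(idx))
    stop("material table missing region(s): ",
         paste(unique(mesh$region[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  list(E = materials$E[idx], nu = materials$nu[idx],
       alpha = materials$alpha[idx], k = materials$k[idx])
}
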