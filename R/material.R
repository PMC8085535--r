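# Compressible neo-Hookean constitutive model for the deformable implant
# parts, parameterized by engineering constants (E, v). Strain-energy
# density:
#   Psi = G/2 (I1 - 3) - G ln J + lambda/2 (ln J)^2
# with I1 = tr(F'F), J = det F. The Cauchy stress that follows is
#   sigma = (1/J) [ G (B - I) + lambda ln J I ],   B = F F'.

#' Lame constants from engineering constants
#'
#' `G = E / (2 (1 + v))`, `lambda = 2 G v / (1 - 2 v)`.
#'
#' @param E Young's modulus (MPa), > 0.
#' @param v Poisson's ratio, in `[0, 0.5)`; the incompressible limit is
#'   unsupported.
#' @return list with `G` and `lam` (MPa).
#' @export
#' @examples
#' lame_from_engineering(1200, 0.46)    # UHMWPE
#' lame_from_engineering(210000, 0.3)   # CoCrMo
lame_from_engineering <- function(E, v) {
  assert_scalar_num(E, "E", 0, strict_lower = TRUE)
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 0.5)
    stop_tkr("Poisson's ratio must be in [0, 0.5) (got %s)", format(v))
  G <- E / (2 * (1 + v))
  list(G = G, lam = 2 * G * v / (1 - 2 * v))
}

#' Compressible neo-Hookean material
#'
#' @param name material label.
#' @param E Young's modulus (MPa).
#' @param v Poisson's ratio.
#' @return object of class `neo_hookean` with derived Lame constants `G`
#'   and `lam`.
#' @export
neo_hookean <- function(name, E, v) {
  lam <- lame_from_engineering(E, v)
  structure(list(name = name, E = E, v = v, G = lam$G, lam = lam$lam),
            class = "neo_hookean")
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf(
    "neo_hookean '%s': E = %g MPa, v = %g (G = %.4f, lambda = %.4f MPa)\n",
    x$name, x$E, x$v, x$G, x$lam))
  invisible(x)
}

#' Rigid material placeholder
#'
#' Rigid bodies carry no constitutive response; a nominal density is kept
#' for solver-file bookkeeping (quasi-static analyses never use inertia).
#'
#' @param name material label.
#' @param density tonne/mm^3; default is steel-like 7.8e-9.
#' @return object of class `rigid_material`.
#' @export
rigid_material <- function(name, density = 7.8e-9) {
  assert_scalar_num(density, "density", 0, strict_lower = TRUE)
  structure(list(name = name, density = density), class = "rigid_material")
}

#' @export
print.rigid_material <- function(x, ...) {
  cat(sprintf("rigid_material '%s': density = %g tonne/mm^3\n", x$name,
              x$density))
  invisible(x)
}

check_deformation_gradient <- function(F_) {
  F_ <- as.matrix(F_)
  if (!all(dim(F_) == c(3L, 3L)))
    stop_tkr("deformation gradient must be 3 x 3")
  J <- det(F_)
  if (J <= 0)
    stop_tkr("inverted element: det(F) = %g <= 0", J)
  list(F_ = F_, J = J)
}

#' Neo-Hookean strain-energy density
#'
#' @param F_ 3 x 3 deformation gradient with positive determinant.
#' @param m a [neo_hookean()] material.
#' @return energy density (MPa); zero iff `F_` is a rotation.
#' @export
strain_energy <- function(F_, m) {
  chk <- check_deformation_gradient(F_)
  I1 <- sum(chk$F_^2)                    # tr(F'F)
  lJ <- log(chk$J)
  m$G / 2 * (I1 - 3) - m$G * lJ + m$lam / 2 * lJ^2
}

#' Neo-Hookean Cauchy stress
#'
#' `sigma = (1/J) (G (B - I) + lambda ln(J) I)` with `B = F F'`; the unique
#' stress consistent with [strain_energy()] (verifiable by finite
#' differences of the energy under virtual deformations).
#'
#' @param F_ 3 x 3 deformation gradient with positive determinant.
#' @param m a [neo_hookean()] material.
#' @return symmetric 3 x 3 Cauchy stress (MPa).
#' @export
cauchy_stress <- function(F_, m) {
  chk <- check_deformation_gradient(F_)
  B <- chk$F_ %*% t(chk$F_)
  (m$G * (B - diag(3)) + m$lam * log(chk$J) * diag(3)) / chk$J
}

#' Default implant material library
#'
#' CoCrMo for the femoral component (E = 210000 MPa, v = 0.3), UHMWPE for
#' the tibial insert (E = 1200 MPa, v = 0.46), rigid entries for the bones
#' and the tibial tray.
#'
#' @return named list of materials keyed by part name.
#' @export
default_materials <- function() {
  list(
    femoral_component = neo_hookean("CoCrMo", 210000, 0.3),
    tibial_insert = neo_hookean("UHMWPE", 1200, 0.46),
    tibial_tray = rigid_material("rigid_tray"),
    femur = rigid_material("rigid_femur"),
    tibia = rigid_material("rigid_tibia"),
    fibula = rigid_material("rigid_fibula")
  )
}

#' Serialize a material library to YAML
#' @param mats named material list as from [default_materials()].
#' @param path optional output file.
#' @return YAML string.
#' @export
materials_to_yaml <- function(mats, path = NULL) {
  lst <- lapply(mats, function(m) {
    if (inherits(m, "neo_hookean"))
      list(type = "neo-Hookean", name = m$name, E = m$E, v = m$v)
    else
      list(type = "rigid", name = m$name, density = m$density)
  })
  txt <- yaml::as.yaml(list(materials = lst))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
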