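# Rigid alignment perturbations of implant components.
#
# Axis conventions (model frame): varus/valgus tilt rotates about the
# anteroposterior y axis, internal/external rotation about the vertical z
# axis, flexion about the mediolateral x axis. Sign convention: varus and
# internal rotation are positive right-handed rotations about +y and +z;
# valgus and external rotation are their negatives.

.alignment_axes <- list(
  varus = c(0, 1, 0), valgus = c(0, 1, 0),
  internal_rotation = c(0, 0, 1), external_rotation = c(0, 0, 1),
  flexion = c(1, 0, 0),
  translation = NULL)

.alignment_signs <- c(varus = 1, valgus = -1, internal_rotation = 1,
                      external_rotation = -1, flexion = 1, translation = 1)

#' Rigid alignment perturbation
#'
#' @param mode one of `"varus"`, `"valgus"`, `"internal_rotation"`,
#'   `"external_rotation"`, `"flexion"`, `"translation"`.
#' @param magnitude rotation angle in degrees, or translation distance in
#'   mm; must be >= 0 (the mode encodes the sense).
#' @param pivot rotation pivot (mm); defaults, when the perturbation is
#'   applied through [apply_alignment()], to the centroid of the surface's
#'   bounding box.
#' @param axis unit 3-vector; fixed by `mode` for rotations, required
#'   direction for `translation`.
#' @return object of class `alignment_perturbation`.
#' @export
alignment_perturbation <- function(mode, magnitude, pivot = NULL,
                                   axis = NULL) {
  mode <- match.arg(mode, names(.alignment_signs))
  assert_scalar_num(magnitude, "magnitude", 0)
  if (mode == "translation") {
    if (is.null(axis)) stop_tkr("translation requires an `axis` direction")
  } else {
    axis <- axis %||% .alignment_axes[[mode]]
  }
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop_tkr("`axis` must have nonzero length")
  structure(list(mode = mode, magnitude = magnitude, pivot = pivot,
                 axis = axis / n),
            class = "alignment_perturbation")
}

#' @export
print.alignment_perturbation <- function(x, ...) {
  unit <- if (x$mode == "translation") "mm" else "deg"
  cat(sprintf("alignment_perturbation: %s %g %s\n", x$mode, x$magnitude,
              unit))
  invisible(x)
}

#' Apply a rigid alignment perturbation to a surface
#'
#' Pure rigid motion: topology, vertex count and all pairwise distances are
#' preserved.
#'
#' @param s a [tri_surface()].
#' @param p an [alignment_perturbation()].
#' @return transformed [tri_surface()].
#' @export
apply_alignment <- function(s, p) {
  stopifnot(inherits(p, "alignment_perturbation"))
  if (p$mode == "translation") {
    s$vertices <- sweep(s$vertices, 2, p$axis * p$magnitude, `+`)
    return(s)
  }
  pivot <- p$pivot %||%
    ((apply(s$vertices, 2, min) + apply(s$vertices, 2, max)) / 2)
  angle <- .alignment_signs[[p$mode]] * p$magnitude
  R <- rotation_matrix(p$axis, angle)
  s$vertices <- transform_points(s$vertices, R = R, pivot = pivot)
  s
}

#' Invert an alignment perturbation
#' @param p an [alignment_perturbation()].
#' @return the inverse perturbation (same pivot and axis, opposite sense).
#' @export
invert_alignment <- function(p) {
  flip <- c(varus = "valgus", valgus = "varus",
            internal_rotation = "external_rotation",
            external_rotation = "internal_rotation")
  if (p$mode == "translation") {
    p$axis <- -p$axis
  } else if (p$mode %in% names(flip)) {
    p$mode <- unname(flip[p$mode])
  } else {                     # flexion: negate via axis reversal
    p$axis <- -p$axis
  }
  p
}
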