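# Perturbation-grid driver and variation metrics for the sensitivity
# analyses: one-at-a-time ligament perturbations (attachment shifts,
# reference-strain and stiffness scalings) and femoral-component
# malalignment (varus/valgus tilt, internal/external rotation), each
# summarized by the relative percentile variation (VAR) of the peak
# contact pressures against the reference configuration.

#' Relative percentile variation
#'
#' `VAR = (estimated - reference) / reference * 100`. Sign is preserved;
#' rounding is presentation-only (see [round_half_up()]).
#'
#' @param estimated estimated scalar value.
#' @param reference reference scalar value, nonzero.
#' @return signed percentage.
#' @export
#' @examples
#' var_pct(8.98, 2.93)   # 206.48... : 5 deg internal rotation, 1st peak
#' var_pct(2.74, 2.93)   # -6.48... : MCL anterior 5 mm, 1st peak
var_pct <- function(estimated, reference) {
  if (any(reference == 0)) stop_tkr("reference value must be nonzero")
  (estimated - reference) / reference * 100
}

#' Perturbation specification
#'
#' @param target `"MCL"`, `"LCL"`, `"both"` (ligament kinds) or
#'   `"femoral_component"` (alignment kinds).
#' @param kind `"attachment_shift"`, `"eps_r_scale"`, `"k_scale"`,
#'   `"varus"`, `"valgus"`, `"internal_rotation"`, `"external_rotation"`.
#' @param magnitude mm for shifts, signed percent for scalings, degrees
#'   for rotations.
#' @param direction shift direction tag (attachment_shift only).
#' @param label table row label.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target, kind, magnitude, direction = NULL,
                              label = NULL) {
  kinds <- c("attachment_shift", "eps_r_scale", "k_scale", "varus",
             "valgus", "internal_rotation", "external_rotation",
             "reference")
  if (!kind %in% kinds) stop_tkr("unknown perturbation kind '%s'", kind)
  structure(list(target = target, kind = kind, magnitude = magnitude,
                 direction = direction,
                 label = label %||% sprintf("%s %s %g", target, kind,
                                            magnitude)),
            class = "perturbation_spec")
}

# Table row sets of the one-at-a-time designs. The ligament design holds
# 33 perturbed rows: 5 mm attachment shifts (joint AP/ML/PD rows plus the
# four single-ligament directions in each plane), eps_r scaled by +/-5%
# and +/-10%, k scaled by +/-10%, each applied to MCL, LCL or both.
ligament_grid <- function() {
  out <- list()
  add <- function(target, kind, magnitude, direction, label)
    out[[length(out) + 1L]] <<- perturbation_spec(target, kind, magnitude,
                                                  direction, label)
  # attachment shifts: the joint rows move both ligaments in the first
  # direction of the named plane
  planes <- list(AP = c("anterior", "posterior"),
                 ML = c("medial", "lateral"),
                 PD = c("proximal", "distal"))
  for (pl in names(planes)) {
    dirs <- planes[[pl]]
    add("both", "attachment_shift", 5, dirs[1],
        sprintf("MCL+LCL %s 5 mm", pl))
    for (lig in c("MCL", "LCL")) for (d in dirs)
      add(lig, "attachment_shift", 5, d, sprintf("%s %s 5 mm", lig, d))
  }
  for (pct in c(-5, 5, -10, 10)) for (tg in c("both", "MCL", "LCL")) {
    lbl_t <- if (tg == "both") "MCL+LCL" else tg
    add(tg, "eps_r_scale", pct, NULL,
        sprintf("%s eps_r %+d%%", lbl_t, pct))
  }
  for (pct in c(-10, 10)) for (tg in c("both", "MCL", "LCL")) {
    lbl_t <- if (tg == "both") "MCL+LCL" else tg
    add(tg, "k_scale", pct, NULL, sprintf("%s k %+d%%", lbl_t, pct))
  }
  out
}

# 10 perturbed rows: varus/valgus tilt 1, 3, 5 deg; internal/external
# rotation 1, 5 deg
alignment_grid <- function() {
  out <- list()
  for (kind in c("varus", "valgus")) for (deg in c(1, 3, 5))
    out[[length(out) + 1L]] <- perturbation_spec(
      "femoral_component", kind, deg,
      label = sprintf("%s tilt %d deg",
                      if (kind == "varus") "Varus" else "Valgus", deg))
  for (kind in c("internal_rotation", "external_rotation"))
    for (deg in c(1, 5))
      out[[length(out) + 1L]] <- perturbation_spec(
        "femoral_component", kind, deg,
        label = sprintf("%s rotation %d deg",
                        if (kind == "internal_rotation") "Internal"
                        else "External", deg))
  out
}

#' Build a perturbation grid
#'
#' `"ligament_table"` reproduces the 33-row one-at-a-time ligament design
#' (attachment shifts of 5 mm, reference-strain scalings of +/-5% and
#' +/-10%, stiffness scalings of +/-10%, each for MCL, LCL and both);
#' `"alignment_table"` the 10-row malalignment design (varus/valgus 1, 3,
#' 5 deg; internal/external rotation 1, 5 deg); `"custom"` passes
#' `specs` through.
#'
#' @param design `"ligament_table"`, `"alignment_table"` or `"custom"`.
#' @param specs list of [perturbation_spec()]s for `design = "custom"`.
#' @return list of [perturbation_spec()]s.
#' @export
build_perturbation_grid <- function(design = c("ligament_table",
                                               "alignment_table",
                                               "custom"),
                                    specs = list()) {
  design <- match.arg(design)
  switch(design,
         ligament_table = ligament_grid(),
         alignment_table = alignment_grid(),
         custom = specs)
}

# apply a perturbation spec to (ligaments, femoral surface)
apply_perturbation <- function(spec, ligaments, femoral, pivot = NULL) {
  if (spec$kind == "reference")
    return(list(ligaments = ligaments, femoral = femoral))
  if (spec$kind %in% c("varus", "valgus", "internal_rotation",
                       "external_rotation")) {
    p <- alignment_perturbation(spec$kind, spec$magnitude, pivot = pivot)
    return(list(ligaments = ligaments, femoral = apply_alignment(femoral,
                                                                 p)))
  }
  targets <- if (spec$target == "both") c("MCL", "LCL") else spec$target
  for (tg in targets) {
    if (is.null(ligaments[[tg]]))
      stop_tkr("no ligament '%s' in model", tg)
    ligaments[[tg]] <- switch(
      spec$kind,
      attachment_shift = perturb_attachments(ligaments[[tg]],
                                             spec$direction,
                                             spec$magnitude),
      eps_r_scale = scale_parameter(ligaments[[tg]], "eps_r",
                                    spec$magnitude),
      k_scale = scale_parameter(ligaments[[tg]], "k", spec$magnitude))
  }
  list(ligaments = ligaments, femoral = femoral)
}

#' Run a sensitivity analysis over a perturbation grid
#'
#' For each spec: perturb the reference configuration, rebuild the contact
#' model, re-settle, run the gait cycle, extract peak pressures, and
#' report VAR against the unperturbed reference row. Per-row failures are
#' recorded (`status` column) without aborting the batch.
#'
#' @param femoral reference femoral component [tri_surface()].
#' @param foundation a [foundation_model()] of the insert.
#' @param ligaments named list of reference [ligament_bundle()]s.
#' @param grid list of [perturbation_spec()]s.
#' @param bc a [gait_bc()].
#' @param joint_center rotation center for pose and alignment pivots.
#' @param tol_rel per-step equilibrium tolerance.
#' @return data frame of class `sensitivity_table`: label, P1, VAR1, P2,
#'   VAR2 (MPa / percent, full precision), status; the reference row
#'   first. Attribute `rounded` holds the presentation table (2 decimals,
#'   half-up).
#' @export
run_sensitivity <- function(femoral, foundation, ligaments, grid, bc,
                            joint_center = NULL, tol_rel = 1e-6) {
  solve_case <- function(fem, ligs) {
    model <- contact_model(fem, foundation, ligs,
                           joint_center = joint_center)
    traj <- run_gait(model, bc, tol_rel = tol_rel)
    peak_metrics(traj, bc)
  }
  ref <- solve_case(femoral, ligaments)
  rows <- list(data.frame(label = "Reference configuration",
                          P1 = ref$P1, VAR1 = 0, P2 = ref$P2, VAR2 = 0,
                          status = "ok"))
  for (spec in grid) {
    row <- tryCatch({
      per <- apply_perturbation(spec, ligaments, femoral,
                                pivot = joint_center)
      pk <- solve_case(per$femoral, per$ligaments)
      data.frame(label = spec$label, P1 = pk$P1,
                 VAR1 = var_pct(pk$P1, ref$P1), P2 = pk$P2,
                 VAR2 = var_pct(pk$P2, ref$P2), status = "ok")
    }, error = function(e)
      data.frame(label = spec$label, P1 = NA_real_, VAR1 = NA_real_,
                 P2 = NA_real_, VAR2 = NA_real_,
                 status = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rounded <- out
  for (cn in c("P1", "VAR1", "P2", "VAR2"))
    rounded[[cn]] <- round_half_up(out[[cn]], 2L)
  attr(out, "rounded") <- rounded
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Force-curve similarity metrics
#'
#' RMS, mean and standard deviation of the predicted and reference series,
#' each compared by [var_pct()]. STD uses the population definition by
#' default.
#'
#' @param predicted,reference force series on a common time grid.
#' @param population use population (divide by n) standard deviation.
#' @return list of class `curve_comparison` with `RMS_var`, `Mean_var`,
#'   `STD_var` (percent).
#' @export
compare_force_curves <- function(predicted, reference, population = TRUE) {
  if (length(predicted) != length(reference))
    stop_tkr("series length mismatch after resampling (%d vs %d)",
             length(predicted), length(reference))
  rms <- function(x) sqrt(mean(x^2))
  std <- function(x) if (population)
    sqrt(mean((x - mean(x))^2)) else sd(x)
  structure(list(
    RMS_var = var_pct(rms(predicted), rms(reference)),
    Mean_var = var_pct(mean(predicted), mean(reference)),
    STD_var = var_pct(std(predicted), std(reference))
  ), class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("RMS Var: %.1f%%, Mean Var: %.1f%%, STD Var: %.1f%%\n",
              x$RMS_var, x$Mean_var, x$STD_var))
  invisible(x)
}

#' Recompute VAR columns from a printed pressure table
#'
#' Given a table of peak pressures (columns `label`, `P1`, `P2`) whose
#' first row is the reference configuration, recompute the relative
#' percentile variation of every row, rounded half-up to 2 decimals as in
#' the published presentation.
#'
#' @param tab data frame with columns `label`, `P1`, `P2`.
#' @return `tab` with `VAR1` and `VAR2` columns appended.
#' @export
var_table <- function(tab) {
  need <- c("label", "P1", "P2")
  if (!all(need %in% names(tab)))
    stop_tkr("pressure table needs columns %s", paste(need, collapse = ", "))
  tab$VAR1 <- round_half_up(var_pct(tab$P1, tab$P1[1]), 2L)
  tab$VAR2 <- round_half_up(var_pct(tab$P2, tab$P2[1]), 2L)
  tab
}
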