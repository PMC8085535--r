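# Assembly of the complete TKR model object and FEBio-format (.feb, XML)
# export. Part roles are fixed: femur/tibia/fibula/tray are rigid bodies,
# femoral component and tibial insert are deformable and carry tetrahedral
# meshes. Three contacts (two rigid ties, one sliding-elastic), three
# cylindrical joint connectors (flexion x, distraction z, varus-valgus y),
# a two-step protocol (contact settling, then gait).

.part_roles <- c(femur = "rigid", tibia = "rigid", fibula = "rigid",
                 tibial_tray = "rigid",
                 femoral_component = "deformable",
                 tibial_insert = "deformable")

#' Body part
#'
#' @param name one of `femur`, `tibia`, `fibula`, `femoral_component`,
#'   `tibial_insert`, `tibial_tray` (role is fixed by name).
#' @param mesh a [tet_mesh()] for deformable parts, a [tri_surface()] for
#'   rigid parts.
#' @param material a [neo_hookean()] or [rigid_material()].
#' @return object of class `body_part`.
#' @export
body_part <- function(name, mesh, material) {
  if (!name %in% names(.part_roles))
    stop_tkr("unknown part name '%s'", name)
  role <- .part_roles[[name]]
  if (role == "deformable") {
    if (!inherits(mesh, "tet_mesh"))
      stop_tkr("deformable part '%s' requires a tet_mesh (volumetric mesh)",
               name)
    if (!inherits(material, "neo_hookean"))
      stop_tkr("deformable part '%s' requires a neo_hookean material", name)
  } else {
    if (!inherits(mesh, "tri_surface"))
      stop_tkr("rigid part '%s' requires a tri_surface", name)
    if (!inherits(material, "rigid_material"))
      stop_tkr("rigid part '%s' requires a rigid_material", name)
  }
  structure(list(name = name, mesh = mesh, role = role,
                 material = material), class = "body_part")
}

#' Contact interface
#' @param kind `"rigid_tie"` (deformable face set tied to a rigid body) or
#'   `"sliding_elastic"` (two deformable face sets, sliding permitted,
#'   penetration prevented).
#' @param primary,secondary part names of the interface sides.
#' @param penalty contact penalty.
#' @param auto_penalty use automatic penalty scaling.
#' @param augmented augmented-Lagrangian flag.
#' @return object of class `contact_interface`.
#' @export
contact_interface <- function(kind = c("rigid_tie", "sliding_elastic"),
                              primary, secondary, penalty = 1,
                              auto_penalty = TRUE, augmented = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, primary = primary, secondary = secondary,
                 penalty = penalty, auto_penalty = auto_penalty,
                 augmented = augmented), class = "contact_interface")
}

#' Cylindrical joint connector
#' @param name `"flexion_extension"`, `"joint_distraction"` or
#'   `"varus_valgus"`.
#' @param body_a,body_b connected rigid part names.
#' @param origin joint center (mm).
#' @param axis unit axis (fixed by name: x, z, y respectively).
#' @param driven_dof `"rotation"` or `"translation"`.
#' @param drive `"prescribed_motion"` or `"applied_load"`.
#' @param curve name of the load curve driving this connector.
#' @return object of class `cylindrical_connector`.
#' @export
cylindrical_connector <- function(name = c("flexion_extension",
                                           "joint_distraction",
                                           "varus_valgus"),
                                  body_a, body_b, origin,
                                  axis = NULL, driven_dof, drive, curve) {
  name <- match.arg(name)
  fixed_axis <- switch(name, flexion_extension = c(1, 0, 0),
                       joint_distraction = c(0, 0, 1),
                       varus_valgus = c(0, 1, 0))
  axis <- axis %||% fixed_axis
  if (sqrt(sum(axis^2)) < 1e-12) stop_tkr("connector axis must be nonzero")
  structure(list(name = name, body_a = body_a, body_b = body_b,
                 origin = as.numeric(origin), axis = axis / sqrt(sum(axis^2)),
                 driven_dof = driven_dof, drive = drive, curve = curve),
            class = "cylindrical_connector")
}

#' Assemble the complete TKR finite-element model
#'
#' Wires parts, materials, ligaments, contacts, connectors and the
#' two-step load protocol into one validated model object:
#' femur/femoral-component and tray/insert joined by rigid ties, the
#' articulation by sliding-elastic contact; flexion driven by prescribed
#' rotation, distraction by the axial force, varus-valgus by the drive
#' moment; step 1 is the contact-settling ramp. Enabled DOFs on the femur
#' chain are exactly z translation and x/y rotation; tibia, fibula and
#' tray are fully constrained.
#'
#' @param parts named list of [body_part()]s covering all six roles.
#' @param ligaments list of [ligament_bundle()]s (MCL femur-tibia, LCL
#'   femur-fibula).
#' @param curves load-curve list from [build_load_curves()] (`flexion`,
#'   `Fz`, `My`, `step_times`).
#' @param config optional list: `settle_increments` (default 10),
#'   `joint_center` (default mean ligament origin, overridden by geometry
#'   attribute when present).
#' @return object of class `fe_model`.
#' @export
assemble_model <- function(parts, ligaments, curves, config = list()) {
  need <- names(.part_roles)
  missing_parts <- setdiff(need, names(parts))
  if (length(missing_parts))
    stop_tkr("missing part(s): %s", paste(missing_parts, collapse = ", "))
  for (p in parts) stopifnot(inherits(p, "body_part"))
  for (nm in c("flexion", "Fz", "My"))
    if (is.null(curves[[nm]]))
      stop_tkr("missing load curve '%s'", nm)
  if (length(ligaments) < 1L) stop_tkr("at least one ligament required")

  jc <- config$joint_center %||%
    colMeans(do.call(rbind, lapply(ligaments, `[[`, "origin")))

  contacts <- list(
    contact_interface("rigid_tie", "femur", "femoral_component"),
    contact_interface("rigid_tie", "tibial_tray", "tibial_insert"),
    contact_interface("sliding_elastic", "femoral_component",
                      "tibial_insert"))

  connectors <- list(
    cylindrical_connector("flexion_extension", "femur", "tibia",
                          origin = jc, driven_dof = "rotation",
                          drive = "prescribed_motion", curve = "flexion"),
    cylindrical_connector("joint_distraction", "femur", "tibia",
                          origin = jc, driven_dof = "translation",
                          drive = "applied_load", curve = "Fz"),
    cylindrical_connector("varus_valgus", "femur", "tibia",
                          origin = jc, driven_dof = "rotation",
                          drive = "applied_load", curve = "My"))

  step_times <- curves$step_times %||%
    c(0.1, max(curves$flexion$times))
  steps <- list(
    list(id = 1L, name = "settle", t_end = step_times[1],
         increments = config$settle_increments %||% 10L),
    list(id = 2L, name = "gait", t_end = step_times[2],
         increments = config$gait_increments %||%
           max(length(curves$Fz$times) - 2L, 1L)))

  structure(list(
    parts = parts[need], ligaments = ligaments,
    curves = curves[c("flexion", "Fz", "My")],
    contacts = contacts, connectors = connectors, steps = steps,
    joint_center = jc,
    enabled_dofs = c("z_translation", "x_rotation", "y_rotation"),
    constrained_parts = c("tibia", "fibula", "tibial_tray")
  ), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  nd <- sum(vapply(x$parts, function(p)
    nrow(p$mesh$nodes %||% p$mesh$vertices), 0))
  cat(sprintf(paste0(
    "fe_model: 6 parts (%d nodes), %d ligaments, %d contacts, ",
    "%d connectors, %d steps\n"),
    nd, length(x$ligaments), length(x$contacts), length(x$connectors),
    length(x$steps)))
  invisible(x)
}

# ligament force-displacement table for solver export: displacement
# d = L - L_0 against bundle force, sampled on a strain grid
ligament_force_table <- function(b, eps_max = 0.3, n = 25L) {
  eps <- seq(-0.05, eps_max, length.out = n)
  data.frame(displacement = eps * b$L_0,
             force = ligament_force_strain(eps, b$k, b$eps_l) / b$n_strands)
}

#' Write a model to FEBio XML format
#'
#' Emits a `febio_spec` XML document (version 3.0 by default; 2.5 supported
#' as a secondary dialect) with full decimal precision and no timestamps,
#' so writing the same model twice is byte-identical.
#'
#' @param m an [assemble_model()] result.
#' @param path output file path.
#' @param spec_version `"3.0"` or `"2.5"`.
#' @return `path`, invisibly.
#' @export
write_feb <- function(m, path, spec_version = "3.0") {
  if (!spec_version %in% c("3.0", "2.5"))
    stop_tkr("unsupported FEBio spec version '%s'", spec_version)
  # the file is emitted as text directly (not via a DOM builder): fixed
  # float formatting and element order make repeated writes byte-identical
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  row_txt <- function(mat) apply(mat, 1L, function(r)
    paste(fmt_num(r), collapse = ","))

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<febio_spec version="%s">', spec_version))
  add('  <Module type="solid"/>')

  add("  <Material>")
  mat_id <- 0L
  for (p in m$parts) {
    mat_id <- mat_id + 1L
    mm <- p$material
    if (inherits(mm, "neo_hookean")) {
      add(sprintf('    <material id="%d" name="%s" type="neo-Hookean">',
                  mat_id, mm$name))
      add(sprintf("      <E>%s</E>", fmt_num(mm$E)))
      add(sprintf("      <v>%s</v>", fmt_num(mm$v)))
    } else {
      add(sprintf('    <material id="%d" name="%s" type="rigid body">',
                  mat_id, mm$name))
      add(sprintf("      <density>%s</density>", fmt_num(mm$density)))
    }
    add("    </material>")
  }
  add("  </Material>")

  add("  <Mesh>")
  for (p in m$parts) {
    if (p$role == "deformable") {
      nodes <- p$mesh$nodes; elems <- p$mesh$tets; etype <- "tet4"
    } else {
      nodes <- p$mesh$vertices; elems <- p$mesh$faces; etype <- "tri3"
    }
    add(sprintf('    <Nodes name="%s_nodes">', p$name))
    add(sprintf('      <node id="%d">%s</node>', seq_len(nrow(nodes)),
                row_txt(nodes)))
    add("    </Nodes>")
    add(sprintf('    <Elements type="%s" name="%s">', etype, p$name))
    add(sprintf('      <elem id="%d">%s</elem>', seq_len(nrow(elems)),
                apply(elems, 1L, paste, collapse = ",")))
    add("    </Elements>")
  }
  add("  </Mesh>")

  add("  <MeshDomains>")
  for (p in m$parts) {
    dk <- if (p$role == "deformable") "SolidDomain" else "ShellDomain"
    add(sprintf('    <%s name="%s" mat="%s"/>', dk, p$name,
                p$material$name))
  }
  add("  </MeshDomains>")

  # ligaments as discrete nonlinear springs with tabulated
  # force-displacement curves (displacement = L - L0)
  add("  <Discrete>")
  for (b in m$ligaments) {
    add(sprintf('    <discrete_material name="%s" type="nonlinear spring">',
                b$name))
    tab <- ligament_force_table(b)
    add("      <force>")
    add(sprintf("        <pt>%s,%s</pt>", fmt_num(tab$displacement),
                fmt_num(tab$force)))
    add("      </force>")
    add("    </discrete_material>")
    add(sprintf('    <discrete dmat="%s" discrete_set="%s">', b$name,
                b$name))
    add(sprintf("      <origin>%s</origin>",
                paste(fmt_num(b$origin), collapse = ",")))
    add(sprintf("      <insertion>%s</insertion>",
                paste(fmt_num(b$insertion), collapse = ",")))
    add("    </discrete>")
  }
  add("  </Discrete>")

  add("  <Contact>")
  for (ct in m$contacts) {
    ty <- if (ct$kind == "rigid_tie") "rigid" else "sliding-elastic"
    add(sprintf('    <contact type="%s" surface_pair="%s_%s">', ty,
                ct$primary, ct$secondary))
    if (ct$kind == "sliding_elastic") {
      add(sprintf("      <penalty>%s</penalty>", fmt_num(ct$penalty)))
      add(sprintf("      <auto_penalty>%d</auto_penalty>",
                  as.integer(ct$auto_penalty)))
      add(sprintf("      <laugon>%d</laugon>", as.integer(ct$augmented)))
      add("      <fric_coeff>0</fric_coeff>")
    }
    add("    </contact>")
  }
  add("  </Contact>")

  add("  <Rigid>")
  for (cx in m$connectors) {
    add(sprintf('    <rigid_connector type="rigid cylindrical joint" name="%s">',
                cx$name))
    add(sprintf("      <body_a>%s</body_a>", cx$body_a))
    add(sprintf("      <body_b>%s</body_b>", cx$body_b))
    add(sprintf("      <joint_origin>%s</joint_origin>",
                paste(fmt_num(cx$origin), collapse = ",")))
    add(sprintf("      <joint_axis>%s</joint_axis>",
                paste(fmt_num(cx$axis), collapse = ",")))
    add(sprintf("      <driven_dof>%s</driven_dof>", cx$driven_dof))
    add(sprintf("      <drive>%s</drive>", cx$drive))
    add(sprintf("      <curve>%s</curve>", cx$curve))
    add("    </rigid_connector>")
  }
  for (cp in m$constrained_parts) {
    add(sprintf('    <rigid_constraint name="fix_%s" type="fix">', cp))
    add(sprintf("      <rb>%s</rb>", cp))
    add("      <dofs>Rx,Ry,Rz,Ru,Rv,Rw</dofs>")
    add("    </rigid_constraint>")
  }
  add("  </Rigid>")

  add("  <LoadData>")
  cid <- 0L
  for (nm in names(m$curves)) {
    cid <- cid + 1L
    lc <- m$curves[[nm]]
    add(sprintf('    <load_controller id="%d" name="%s" type="loadcurve">',
                cid, nm))
    add("      <interpolate>LINEAR</interpolate>")
    add("      <extend>CONSTANT</extend>")
    add("      <points>")
    add(sprintf("        <point>%s,%s</point>", fmt_num(lc$times),
                fmt_num(lc$values)))
    add("      </points>")
    add("    </load_controller>")
  }
  add("  </LoadData>")

  add("  <Step>")
  for (stp in m$steps) {
    add(sprintf('    <step id="%d" name="%s">', stp$id, stp$name))
    add("      <Control>")
    add(sprintf("        <time_steps>%d</time_steps>",
                as.integer(stp$increments)))
    add(sprintf("        <step_size>%s</step_size>",
                fmt_num(stp$t_end / stp$increments)))
    add("        <time_stepper>")
    add("          <auto>1</auto>")
    add("        </time_stepper>")
    add("      </Control>")
    add("    </step>")
  }
  add("  </Step>")
  add("</febio_spec>")

  con <- file(path, "wb")   # fixed LF endings for byte-stable output
  on.exit(close(con))
  writeLines(unlist(out), con, sep = "\n")
  invisible(path)
}

#' Digest of a FEBio model file
#'
#' Parses a `.feb` file and counts nodes, elements, materials, contacts,
#' connectors, steps and load curves — the round-trip verification
#' counterpart of [write_feb()].
#'
#' @param path `.feb` file path.
#' @return list of counts (class `feb_digest`).
#' @export
summarize_feb <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop_tkr("cannot parse '%s' as XML: %s", path,
                             conditionMessage(e)))
  cnt <- function(xp) length(xml2::xml_find_all(doc, xp))
  structure(list(
    n_nodes = cnt("//Mesh/Nodes/node"),
    n_elements = cnt("//Mesh/Elements/elem"),
    n_materials = cnt("//Material/material"),
    n_contacts = cnt("//Contact/contact"),
    n_connectors = cnt("//Rigid/rigid_connector"),
    n_steps = cnt("//Step/step"),
    n_curves = cnt("//LoadData/load_controller"),
    n_ligaments = cnt("//Discrete/discrete"),
    spec_version = xml2::xml_attr(xml2::xml_root(doc), "version")
  ), class = "feb_digest")
}

#' @export
print.feb_digest <- function(x, ...) {
  cat(sprintf(paste0(
    "feb_digest (spec %s): %d nodes, %d elements, %d materials, ",
    "%d contacts, %d connectors, %d ligaments, %d steps, %d curves\n"),
    x$spec_version, x$n_nodes, x$n_elements, x$n_materials, x$n_contacts,
    x$n_connectors, x$n_ligaments, x$n_steps, x$n_curves))
  invisible(x)
}

# counts expected in the written file, for round-trip checks
model_counts <- function(m) {
  nn <- sum(vapply(m$parts, function(p)
    nrow(if (p$role == "deformable") p$mesh$nodes else p$mesh$vertices),
    0))
  ne <- sum(vapply(m$parts, function(p)
    nrow(if (p$role == "deformable") p$mesh$tets else p$mesh$faces), 0))
  list(n_nodes = nn, n_elements = ne, n_materials = length(m$parts),
       n_contacts = length(m$contacts),
       n_connectors = length(m$connectors), n_steps = length(m$steps),
       n_curves = length(m$curves), n_ligaments = length(m$ligaments))
}

#' Build the default synthetic TKR model end-to-end
#'
#' Convenience wrapper: synthetic geometry, default materials and
#' ligaments, synthetic gait, tetrahedralized deformable parts, assembled
#' [fe_model()].
#'
#' @param geom_params a [synthetic_geom_params()].
#' @param bc a [gait_bc()]; default normal synthetic gait.
#' @param max_cell_volume tet refinement bound (mm^3) for deformable parts.
#' @return an `fe_model`.
#' @export
build_synthetic_model <- function(geom_params = synthetic_geom_params(),
                                  bc = synth_gait("normal"),
                                  max_cell_volume = Inf) {
  geo <- make_synthetic_tkr(geom_params)
  mats <- default_materials()
  lms <- synthetic_landmarks(geom_params)
  bundles <- make_default_bundles(lms)
  curves <- build_load_curves(bc)
  parts <- list(
    femur = body_part("femur", geo$femur_stub, mats$femur),
    tibia = body_part("tibia", geo$tibia_stub, mats$tibia),
    fibula = body_part("fibula", geo$fibula_stub, mats$fibula),
    tibial_tray = body_part("tibial_tray", geo$tibial_tray,
                            mats$tibial_tray),
    femoral_component = body_part(
      "femoral_component", tetrahedralize(geo$femoral_component,
                                          max_cell_volume),
      mats$femoral_component),
    tibial_insert = body_part(
      "tibial_insert", tetrahedralize(geo$tibial_insert, max_cell_volume),
      mats$tibial_insert))
  assemble_model(parts, bundles, curves,
                 config = list(joint_center = c(0, 0,
                                                condyle_center_z(geom_params))))
}
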