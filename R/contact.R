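# Reduced-order quasi-static contact solver: the rigid femoral component
# articulates on the tibial insert modeled as a Winkler elastic foundation
# (local pressure proportional to local penetration), with the collateral
# ligament wrench added. Three joint DOFs: flexion (prescribed), vertical
# translation and varus-valgus rotation (solved for force/moment
# equilibrium against the applied axial force Fz and drive moment My).

#' Elastic-foundation model of the insert articular surface
#'
#' Selects the articular (upward-facing) faces of the insert and attaches
#' per-face foundation stiffness. By default the foundation modulus uses
#' the confined-layer formula `k_f = E (1-v) / ((1+v)(1-2v) h)` with the
#' insert material constants and the local layer thickness `h` measured
#' from the mesh (face centroid height above the insert bottom).
#'
#' @param insert insert [tri_surface()].
#' @param material a [neo_hookean()]; default UHMWPE.
#' @param k_f explicit foundation modulus (MPa/mm); overrides the
#'   confined-layer formula (scalar or per-face vector).
#' @param normal_min_z faces with unit-normal z-component above this are
#'   articular candidates.
#' @param min_height optional centroid-height cutoff (mm) for candidates.
#' @return object of class `foundation_model` with per-face `centroids`,
#'   `normals`, `areas`, `k_f`, `thickness`.
#' @export
foundation_model <- function(insert, material = neo_hookean("UHMWPE", 1200,
                                                            0.46),
                             k_f = NULL, normal_min_z = 0.3,
                             min_height = -Inf) {
  n <- face_normals(insert)
  keep <- which(n[, 3] > normal_min_z)
  cen <- face_centroids(insert)
  keep <- keep[cen[keep, 3] >= min_height]
  if (!length(keep)) stop_tkr("no articular faces found on '%s'",
                              insert$name)
  z0 <- min(insert$vertices[, 3])
  h <- pmax(cen[keep, 3] - z0, 1e-6)
  if (is.null(k_f)) {
    E <- material$E; v <- material$v
    k_f <- E * (1 - v) / ((1 + v) * (1 - 2 * v) * h)
  } else {
    k_f <- rep_len(k_f, length(keep))
  }
  if (any(k_f <= 0)) stop_tkr("foundation modulus must be positive")
  structure(list(
    face_ids = keep,
    centroids = cen[keep, , drop = FALSE],
    normals = n[keep, , drop = FALSE],
    areas = face_areas(insert)[keep],
    k_f = k_f, thickness = h, insert_name = insert$name
  ), class = "foundation_model")
}

#' @export
print.foundation_model <- function(x, ...) {
  cat(sprintf(
    "foundation_model on '%s': %d contact faces, k_f %.3g..%.3g MPa/mm\n",
    x$insert_name, length(x$areas), min(x$k_f), max(x$k_f)))
  invisible(x)
}

#' Reduced-order contact model
#'
#' @param femoral rigid femoral component [tri_surface()].
#' @param foundation a [foundation_model()].
#' @param ligaments list of [ligament_bundle()]s; origins ride with the
#'   femur, insertions stay fixed.
#' @param joint_center rotation center for flexion and varus-valgus (mm);
#'   defaults to the femoral bounding-box centroid.
#' @param max_penetration ray search bound behind the foundation surface
#'   (mm).
#' @return object of class `contact_model`.
#' @export
contact_model <- function(femoral, foundation, ligaments = list(),
                          joint_center = NULL, max_penetration = 5) {
  stopifnot(inherits(foundation, "foundation_model"))
  jc <- joint_center %||%
    ((apply(femoral$vertices, 2, min) + apply(femoral$vertices, 2, max)) / 2)
  structure(list(femoral = femoral, fnd = foundation,
                 ligaments = ligaments, joint_center = as.numeric(jc),
                 t_cap = max_penetration, t_far = 1e4),
            class = "contact_model")
}

#' Joint pose
#' @param theta flexion angle (deg, prescribed).
#' @param u_z vertical offset (mm, solved).
#' @param phi varus-valgus angle (deg, solved).
#' @return object of class `joint_pose`.
#' @export
joint_pose <- function(theta = 0, u_z = 0, phi = 0) {
  structure(list(theta = theta, u_z = u_z, phi = phi),
            class = "joint_pose")
}

# pose rotation: flexion about x then varus-valgus about y, both through
# the joint center; then vertical translation u_z
pose_rotation <- function(theta, phi) {
  rotation_matrix(c(0, 1, 0), phi) %*% rotation_matrix(c(1, 0, 0), theta)
}

# map a world point set into the femoral body frame at pose (theta,u_z,phi)
world_to_body <- function(pts, R, jc, u_z) {
  sweep(sweep(pts, 2, jc + c(0, 0, u_z)) %*% R, 2, jc, `+`)
}

body_to_world <- function(pts, R, jc, u_z) {
  sweep(sweep(pts, 2, jc) %*% t(R), 2, jc + c(0, 0, u_z), `+`)
}

# core evaluation at a pose: per-face penetration, pressures, wrench
eval_contact_state <- function(model, theta, u_z, phi) {
  jc <- model$joint_center
  R <- pose_rotation(theta, phi)
  o_b <- world_to_body(model$fnd$centroids, R, jc, u_z)
  d_b <- model$fnd$normals %*% R
  t <- ray_mesh_first_hit(o_b, d_b, model$femoral$vertices,
                          model$femoral$faces, -model$t_cap, model$t_far)
  pen <- ifelse(is.na(t), 0, pmax(0, -t))
  p <- model$fnd$k_f * pen

  A <- model$fnd$areas
  nrm <- model$fnd$normals
  pA <- p * A
  Fc <- colSums(pA * nrm)
  rel <- sweep(model$fnd$centroids, 2, jc)
  # y-component of r x F with F = pA * n
  Mc_y <- sum(pA * (rel[, 3] * nrm[, 1] - rel[, 1] * nrm[, 3]))

  Fl <- c(0, 0, 0); Ml_y <- 0
  lig_state <- list()
  for (b in model$ligaments) {
    o_w <- body_to_world(matrix(b$origin, 1L), R, jc, u_z)[1, ]
    dvec <- b$insertion - o_w
    L <- sqrt(sum(dvec^2))
    f <- ligament_force(L, b)
    fv <- f * dvec / L
    Fl <- Fl + fv
    r <- o_w - jc
    Ml_y <- Ml_y + (r[3] * fv[1] - r[1] * fv[3])
    lig_state[[b$name]] <- list(length = L, force = f)
  }

  list(pen = pen, pressure = p, gap_min = suppressWarnings(
         min(t[!is.na(t)], Inf)),
       F_contact = Fc, M_contact_y = Mc_y,
       F_lig = Fl, M_lig_y = Ml_y, ligaments = lig_state)
}

pressure_field_from_state <- function(model, st) {
  p <- st$pressure
  A <- model$fnd$areas
  loaded <- p > 0
  pA <- p * A
  total <- sum(pA * model$fnd$normals[, 3])
  cop <- if (any(loaded)) {
    unname(colSums(pA[loaded] *
                     model$fnd$centroids[loaded, 1:2, drop = FALSE]) /
             sum(pA[loaded]))
  } else c(NA_real_, NA_real_)
  structure(list(pressure = p, face_ids = model$fnd$face_ids,
                 total_force = total, cop = cop,
                 max_pressure = if (length(p)) max(p) else 0,
                 n_loaded = sum(loaded)),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf(
    "pressure_field: %d/%d faces loaded, total Fz = %.2f N, p_max = %.3f MPa, COP = (%.2f, %.2f) mm\n",
    x$n_loaded, length(x$pressure), x$total_force, x$max_pressure,
    x$cop[1], x$cop[2]))
  invisible(x)
}

#' Settle the femoral component to first contact
#'
#' Bisection on the vertical offset: returns the largest downward `u_z`
#' at which the maximum penetration does not exceed `tol`, i.e. the pose
#' where the component first touches the insert.
#'
#' @param model a [contact_model()].
#' @param tol penetration tolerance (mm).
#' @param theta flexion angle held during settling (deg).
#' @param phi varus-valgus angle held during settling (deg).
#' @return vertical offset `u_z` (mm, negative = downward).
#' @export
settle_to_contact <- function(model, tol = 1e-6, theta = 0, phi = 0) {
  # signed apex clearance: positive = gap, negative = penetration
  clearance <- function(u) {
    st <- eval_contact_state(model, theta, u, phi)
    if (max(st$pen) > 0) -max(st$pen) else st$gap_min
  }
  g0 <- clearance(0)
  if (g0 < 0)
    stop_tkr(paste0("initial pose already interpenetrates (max penetration",
                    " %.4g mm); review geometry or alignment"), -g0)
  if (!is.finite(g0))
    stop_tkr("no ray from the foundation hits the femoral surface")
  # bracket: clearance decreases as the component moves down
  lo <- 0; f_lo <- g0
  hi <- -g0 * 1.05; f_hi <- clearance(hi)
  k <- 0L
  while (f_hi > 0) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 1.5 - 0.5; f_hi <- clearance(hi)
    k <- k + 1L
    if (k > 60L) stop_tkr("settling failed to find contact")
  }
  # Illinois regula falsi on the near-linear clearance function
  for (i in 1:60) {
    mid <- (lo * f_hi - hi * f_lo) / (f_hi - f_lo)
    f_mid <- clearance(mid)
    if (abs(f_mid) < tol / 2) return(mid)
    if (f_mid >= 0) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
      f_lo <- f_lo / 2          # Illinois damping
    }
  }
  lo                            # gap side of the bracket
}

# residual vector at pose (theta, u_z, phi) under loads (Fz, My)
equilibrium_residual <- function(model, theta, u_z, phi, Fz, My) {
  st <- eval_contact_state(model, theta, u_z, phi)
  c(st$F_contact[3] + st$F_lig[3] - Fz,
    st$M_contact_y + st$M_lig_y - My)
}

#' Solve one quasi-static timestep
#'
#' Finds the vertical offset and varus-valgus angle at which the vertical
#' contact-plus-ligament force balances the applied axial force and the
#' y-moment balances the applied varus-valgus moment, by damped Newton
#' iteration with a numerical Jacobian and a vertical-bisection fallback.
#'
#' @param model a [contact_model()].
#' @param theta prescribed flexion (deg).
#' @param Fz applied axial force (N), >= 0.
#' @param My applied varus-valgus moment (N*mm).
#' @param prev_pose warm-start [joint_pose()]; defaults to a settled pose.
#' @param max_iter Newton iteration budget.
#' @param tol_rel relative equilibrium tolerance.
#' @return list with `pose` ([joint_pose()]), `field`
#'   ([pressure_field_from_state()]), `residual` (force, moment), and the
#'   per-ligament state.
#' @export
solve_timestep <- function(model, theta, Fz, My = 0, prev_pose = NULL,
                           max_iter = 100L, tol_rel = 1e-6) {
  if (Fz < 0) stop_tkr("Fz must be >= 0")
  tol1 <- tol_rel * max(Fz, 1)
  tol2 <- tol_rel * max(abs(My), 1)

  if (Fz == 0) {
    u0 <- settle_to_contact(model, theta = theta)
    st <- eval_contact_state(model, theta, u0, 0)
    st$pressure[] <- 0; st$pen[] <- 0
    return(list(pose = joint_pose(theta, u0, 0),
                field = pressure_field_from_state(model, st),
                residual = c(0, 0), ligaments = st$ligaments,
                converged = TRUE))
  }

  if (is.null(prev_pose)) {
    u <- settle_to_contact(model, theta = theta) - 0.01
    phi <- 0
  } else {
    u <- prev_pose$u_z; phi <- prev_pose$phi
  }

  sol <- newton_2d(model, theta, u, phi, Fz, My, tol1, tol2, max_iter)
  if (is.null(sol)) {
    # Newton stalls when only one condyle carries load (the moment is then
    # insensitive to phi until the second condyle engages); fall back to
    # nested bracketed solves exploiting the monotone force/moment maps
    sol <- nested_solve(model, theta, u, phi, Fz, My, tol1, tol2)
  }
  if (is.null(sol))
    stop_tkr(paste0("no equilibrium within iteration budget ",
                    "(Fz = %g N, My = %g N*mm, theta = %g deg)"),
             Fz, My, theta)
  u <- sol$u; phi <- sol$phi; res <- sol$res

  st <- eval_contact_state(model, theta, u, phi)
  list(pose = joint_pose(theta, u, phi),
       field = pressure_field_from_state(model, st),
       residual = res, ligaments = st$ligaments, converged = TRUE)
}

# damped 2D Newton with numerical Jacobian; NULL on failure
newton_2d <- function(model, theta, u, phi, Fz, My, tol1, tol2, max_iter) {
  res <- equilibrium_residual(model, theta, u, phi, Fz, My)
  h_u <- 1e-5; h_phi <- 1e-5
  for (it in seq_len(max_iter)) {
    if (abs(res[1]) <= tol1 && abs(res[2]) <= tol2)
      return(list(u = u, phi = phi, res = res))
    r_u <- equilibrium_residual(model, theta, u + h_u, phi, Fz, My)
    r_p <- equilibrium_residual(model, theta, u, phi + h_phi, Fz, My)
    Jm <- cbind((r_u - res) / h_u, (r_p - res) / h_phi)
    step <- tryCatch(solve(Jm, -res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    step[1] <- max(min(step[1], 0.5), -0.5)
    step[2] <- max(min(step[2], 1), -1)
    lam <- 1
    nr0 <- sum((res / c(tol1, tol2))^2)
    progressed <- FALSE
    repeat {
      res_new <- equilibrium_residual(model, theta, u + lam * step[1],
                                      phi + lam * step[2], Fz, My)
      if (sum((res_new / c(tol1, tol2))^2) < nr0) {
        progressed <- TRUE; break
      }
      if (lam < 1 / 64) break
      lam <- lam / 2
    }
    if (!progressed) return(NULL)
    u <- u + lam * step[1]; phi <- phi + lam * step[2]
    res <- res_new
  }
  if (abs(res[1]) <= tol1 && abs(res[2]) <= tol2)
    list(u = u, phi = phi, res = res) else NULL
}

# monotone vertical force balance at fixed phi: the vertical contact force
# grows as the component moves down, so the residual is decreasing in u
vertical_solve <- function(model, theta, phi, Fz, My, u_start, tol) {
  r_of <- function(u) equilibrium_residual(model, theta, u, phi, Fz, My)[1]
  lo <- u_start; f_lo <- r_of(lo)           # lo: deep side (residual > 0)
  k <- 0L
  while (f_lo < 0) {
    lo <- lo - 0.25; f_lo <- r_of(lo)
    k <- k + 1L; if (k > 200L) stop_tkr("vertical solve failed to bracket")
  }
  hi <- lo + 0.25; f_hi <- r_of(hi)
  while (f_hi > 0) {
    lo <- hi; f_lo <- f_hi
    hi <- hi + 0.25; f_hi <- r_of(hi)
    k <- k + 1L; if (k > 200L) stop_tkr("vertical solve failed to bracket")
  }
  for (i in 1:80) {
    mid <- (lo * f_hi - hi * f_lo) / (f_hi - f_lo)
    f_mid <- r_of(mid)
    if (abs(f_mid) <= tol) return(mid)
    if (f_mid > 0) { lo <- mid; f_lo <- f_mid; f_hi <- f_hi / 2 }
    else { hi <- mid; f_hi <- f_mid; f_lo <- f_lo / 2 }
  }
  mid
}

# nested bracketed solve: outer Illinois on phi driving the y-moment
# residual (monotone decreasing in phi for dished geometry), inner
# vertical force balance per phi
nested_solve <- function(model, theta, u0, phi0, Fz, My, tol1, tol2) {
  u_cur <- u0
  m_of <- function(phi) {
    u_cur <<- vertical_solve(model, theta, phi, Fz, My, u_cur, tol1 / 4)
    equilibrium_residual(model, theta, u_cur, phi, Fz, My)[2]
  }
  a <- phi0; f_a <- m_of(a)
  if (abs(f_a) <= tol2)
    return(list(u = u_cur, phi = a,
                res = equilibrium_residual(model, theta, u_cur, a, Fz, My)))
  dirn <- if (f_a > 0) 1 else -1       # moment decreases with phi
  step <- 0.5
  b <- a
  for (k in 1:60) {
    b <- b + dirn * step
    f_b <- m_of(b)
    if (sign(f_b) != sign(f_a)) break
    a <- b; f_a <- f_b
    step <- min(step * 1.5, 4)
    if (k == 60L) return(NULL)
  }
  # narrow the bracket; once near the balanced configuration (both
  # condyles engaged) the coupled Newton iteration takes over for the
  # final polish — the inner-solve noise floor sits above tight absolute
  # moment tolerances, Newton's exact evaluations do not
  scale0 <- max(abs(f_a), abs(f_b))
  for (i in 1:80) {
    mid <- (a * f_b - b * f_a) / (f_b - f_a)
    if (!is.finite(mid)) return(NULL)
    f_mid <- m_of(mid)
    if (abs(f_mid) <= max(tol2, 1e-3 * scale0) || abs(b - a) < 0.05) {
      fin <- newton_2d(model, theta, u_cur, mid, Fz, My, tol1, tol2, 50L)
      if (!is.null(fin)) return(fin)
    }
    if (abs(f_mid) <= tol2) {
      res <- equilibrium_residual(model, theta, u_cur, mid, Fz, My)
      if (abs(res[1]) <= tol1 && abs(res[2]) <= tol2)
        return(list(u = u_cur, phi = mid, res = res))
    }
    if (sign(f_mid) == sign(f_a)) {
      a <- mid; f_a <- f_mid; f_b <- f_b / 2
    } else {
      b <- mid; f_b <- f_mid; f_a <- f_a / 2
    }
  }
  NULL
}

#' Run the contact solver over a gait cycle
#'
#' One quasi-static solve per boundary-condition sample, warm-started from
#' the previous pose. Equilibrium residuals and ligament state are logged
#' per step.
#'
#' @param model a [contact_model()].
#' @param bc a [gait_bc()].
#' @param keep_fields keep the full per-face pressure vector for every
#'   step (memory heavy); summaries are always kept.
#' @param tol_rel relative equilibrium tolerance per step.
#' @return object of class `gait_trajectory`: a data frame `summary`
#'   (time, theta, u_z, phi, total force, max pressure, COP, residuals)
#'   plus `poses`, `fields` (if kept) and `ligaments` per step.
#' @export
run_gait <- function(model, bc, keep_fields = FALSE, tol_rel = 1e-6) {
  stopifnot(inherits(bc, "gait_bc"))
  n <- length(bc$t)
  poses <- vector("list", n)
  fields <- if (keep_fields) vector("list", n) else NULL
  ligs <- vector("list", n)
  sumrows <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    sol <- tryCatch(
      solve_timestep(model, bc$flexion[i], bc$Fz[i], bc$My[i],
                     prev_pose = prev, tol_rel = tol_rel),
      error = function(e)
        stop_tkr("gait solve failed at sample %d (t = %.4f s): %s",
                 i, bc$t[i], conditionMessage(e)))
    prev <- sol$pose
    poses[[i]] <- sol$pose
    if (keep_fields) fields[[i]] <- sol$field
    ligs[[i]] <- sol$ligaments
    sumrows[[i]] <- data.frame(
      time = bc$t[i], theta = sol$pose$theta, u_z = sol$pose$u_z,
      phi = sol$pose$phi, Fz_applied = bc$Fz[i], My_applied = bc$My[i],
      total_force = sol$field$total_force,
      max_pressure = sol$field$max_pressure,
      cop_x = sol$field$cop[1], cop_y = sol$field$cop[2],
      residual_force = sol$residual[1], residual_moment = sol$residual[2])
  }
  structure(list(summary = do.call(rbind, sumrows), poses = poses,
                 fields = fields, ligaments = ligs, label = bc$label),
            class = "gait_trajectory")
}

#' @export
print.gait_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "gait_trajectory '%s': %d steps, peak force %.1f N, peak pressure %.3f MPa\n",
    x$label, nrow(s), max(s$total_force), max(s$max_pressure)))
  invisible(x)
}

#' Peak contact metrics at the two axial-force peaks
#'
#' Identifies the interior local maxima of the applied axial force nearest
#' 20% and 80% of stance (ties resolved to the earlier sample; fewer than
#' two interior maxima falls back to the 20%/80% time indices with a
#' warning) and reports the maximum per-face contact pressure and total
#' vertical contact force at those samples.
#'
#' @param traj a [run_gait()] trajectory.
#' @param bc the [gait_bc()] that drove it.
#' @return list with `P1`, `P2` (MPa), `F1`, `F2` (N), and the sample
#'   indices `i1`, `i2`.
#' @export
peak_metrics <- function(traj, bc) {
  s <- traj$summary
  if (nrow(s) < 2L) stop_tkr("trajectory has fewer than 2 samples")
  Fz <- bc$Fz
  frac <- (bc$t - bc$t[1]) / (bc$t[length(bc$t)] - bc$t[1])
  n <- length(Fz)
  interior <- which(diff(sign(diff(Fz))) < 0) + 1L
  pick <- function(target) {
    if (!length(interior)) return(NA_integer_)
    d <- abs(frac[interior] - target)
    cand <- interior[d == min(d)]
    cand[1]                                   # earlier sample on ties
  }
  if (length(interior) < 2L) {
    warning("fewer than two interior force maxima; using 20%/80% indices")
    i1 <- which.min(abs(frac - 0.2))
    i2 <- which.min(abs(frac - 0.8))
  } else {
    i1 <- pick(0.2); i2 <- pick(0.8)
  }
  list(P1 = s$max_pressure[i1], P2 = s$max_pressure[i2],
       F1 = s$total_force[i1], F2 = s$total_force[i2], i1 = i1, i2 = i2)
}

# medial-compartment share of the total vertical contact force (+x medial)
medial_force_share <- function(model, field) {
  pA <- field$pressure * model$fnd$areas * model$fnd$normals[, 3]
  tot <- sum(pA)
  if (tot <= 0) return(NA_real_)
  sum(pA[model$fnd$centroids[, 1] > 0]) / tot
}
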