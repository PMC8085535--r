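# Parametric synthetic TKR geometry: a bicondylar femoral component (two
# partial-sphere condyles bridged by a block), a dished tibial insert
# (rectangular block with two spherical-cap recesses), a flat tray, and
# cylindrical bone stubs. The assembly is mirror-symmetric about the
# sagittal midplane x = 0 and every part is watertight by construction.

# --- primitives ------------------------------------------------------------

# closed UV sphere, outward-oriented
uv_sphere <- function(center = c(0, 0, 0), radius = 1, n_theta = 24L,
                      n_phi = 12L, name = "sphere") {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ph <- seq(0, pi, length.out = n_phi + 1L)           # 0 = top pole
  rings <- ph[-c(1L, n_phi + 1L)]
  verts <- rbind(
    c(0, 0, radius),                                   # top pole
    do.call(rbind, lapply(rings, function(p)
      cbind(radius * sin(p) * cos(th), radius * sin(p) * sin(th),
            radius * cos(p)))),
    c(0, 0, -radius))                                  # bottom pole
  nr <- length(rings)
  idx <- function(ring, j) 1L + (ring - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  # top cap
  for (j in seq_len(n_theta))
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  # bands
  if (nr > 1L) for (r in seq_len(nr - 1L)) for (j in seq_len(n_theta)) {
    a <- idx(r, j); b <- idx(r, j + 1L)
    c_ <- idx(r + 1L, j); d <- idx(r + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, c_, b)
    faces[[length(faces) + 1L]] <- c(b, c_, d)
  }
  bot <- nrow(verts)
  for (j in seq_len(n_theta))
    faces[[length(faces) + 1L]] <- c(bot, idx(nr, j + 1L), idx(nr, j))
  s <- tri_surface(sweep(verts, 2, center, `+`),
                   do.call(rbind, faces), name = name, tol = 1e-12,
                   orient = FALSE)
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# axis-aligned closed box
box_surface <- function(lo, hi, name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # expand.grid order: x fastest. index (i,j,k) -> 1 + (i-1) + 2(j-1) + 4(k-1)
  quad <- function(a, b, c_, d) rbind(c(a, b, c_), c(a, c_, d))
  f <- rbind(
    quad(1, 3, 4, 2),   # z = lo (normal -z)
    quad(5, 6, 8, 7),   # z = hi (+z)
    quad(1, 2, 6, 5),   # y = lo (-y)
    quad(3, 7, 8, 4),   # y = hi (+y)
    quad(1, 5, 7, 3),   # x = lo (-x)
    quad(2, 4, 8, 6))   # x = hi (+x)
  s <- tri_surface(v, f, name = name, tol = 1e-12, orient = FALSE)
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# closed z-aligned cylinder
cylinder_surface <- function(center_xy = c(0, 0), radius = 10, z0 = 0,
                             z1 = 10, n_seg = 24L, name = "cylinder") {
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring0 <- cbind(center_xy[1] + radius * cos(th),
                 center_xy[2] + radius * sin(th), z0)
  ring1 <- cbind(ring0[, 1], ring0[, 2], z1)
  verts <- rbind(ring0, ring1, c(center_xy, z0), c(center_xy, z1))
  cb <- 2L * n_seg + 1L; ct <- 2L * n_seg + 2L
  faces <- list()
  for (j in seq_len(n_seg)) {
    jn <- j %% n_seg + 1L
    faces[[length(faces) + 1L]] <- c(j, jn, n_seg + jn)
    faces[[length(faces) + 1L]] <- c(j, n_seg + jn, n_seg + j)
    faces[[length(faces) + 1L]] <- c(cb, jn, j)            # bottom cap
    faces[[length(faces) + 1L]] <- c(ct, n_seg + j, n_seg + jn) # top cap
  }
  s <- tri_surface(verts, do.call(rbind, faces), name = name, tol = 1e-12,
                   orient = FALSE)
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# split a grid cell (a,b,c_,d counter-clockwise) into two triangles; the
# diagonal flips on the negative-x side so meshes stay mirror-symmetric
heightfield_cell_split <- function(a, b, c_, d, left) {
  if (left) list(c(b, c_, d), c(b, d, a)) else list(c(a, b, c_), c(a, c_, d))
}

# closed block whose top face is a height field z = top_fn(x, y)
heightfield_block <- function(xlim, ylim, z_bottom, top_fn, nx = 40L,
                              ny = 20L, name = "block") {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1L)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1L)
  g <- expand.grid(x = xs, y = ys)             # x fastest
  ztop <- top_fn(g$x, g$y)
  nvert_layer <- nrow(g)
  verts <- rbind(cbind(g$x, g$y, ztop),
                 cbind(g$x, g$y, z_bottom))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i          # top layer
  idb <- function(i, j) nvert_layer + id(i, j)           # bottom layer
  faces <- vector("list", 4L * nx * ny + 4L * (nx + ny))
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
    # cell-diagonal orientation mirrored across x = 0 so the face set (not
    # just the vertex set) is sagittally symmetric
    tris <- heightfield_cell_split(a, b, c_, d,
                                   xs[i] + xs[i + 1L] < 0)
    k <- k + 1L; faces[[k]] <- tris[[1L]]                # top (+z up)
    k <- k + 1L; faces[[k]] <- tris[[2L]]
    ab <- idb(i, j); bb <- idb(i + 1L, j)
    cb <- idb(i + 1L, j + 1L); db <- idb(i, j + 1L)
    trib <- heightfield_cell_split(ab, bb, cb, db,
                                   xs[i] + xs[i + 1L] < 0)
    k <- k + 1L; faces[[k]] <- trib[[1L]][c(1L, 3L, 2L)] # bottom (-z)
    k <- k + 1L; faces[[k]] <- trib[[2L]][c(1L, 3L, 2L)]
  }
  for (i in seq_len(nx)) {                               # y = ylim[1] wall
    a <- id(i, 1L); b <- id(i + 1L, 1L)
    k <- k + 1L; faces[[k]] <- c(a, idb(i, 1L), idb(i + 1L, 1L))
    k <- k + 1L; faces[[k]] <- c(a, idb(i + 1L, 1L), b)
    a2 <- id(i, ny + 1L); b2 <- id(i + 1L, ny + 1L)      # y = ylim[2] wall
    k <- k + 1L; faces[[k]] <- c(a2, idb(i + 1L, ny + 1L), idb(i, ny + 1L))
    k <- k + 1L; faces[[k]] <- c(a2, b2, idb(i + 1L, ny + 1L))
  }
  for (j in seq_len(ny)) {                               # x walls
    a <- id(1L, j); b <- id(1L, j + 1L)
    k <- k + 1L; faces[[k]] <- c(a, idb(1L, j + 1L), idb(1L, j))
    k <- k + 1L; faces[[k]] <- c(a, b, idb(1L, j + 1L))
    a2 <- id(nx + 1L, j); b2 <- id(nx + 1L, j + 1L)
    k <- k + 1L; faces[[k]] <- c(a2, idb(nx + 1L, j), idb(nx + 1L, j + 1L))
    k <- k + 1L; faces[[k]] <- c(a2, idb(nx + 1L, j + 1L), b2)
  }
  s <- tri_surface(verts, do.call(rbind, faces), name = name, tol = 1e-12,
                   orient = FALSE)
  if (surface_volume(s) < 0) s$faces <- s$faces[, c(1, 3, 2)]
  # grid layout metadata lets tetrahedralize() use an exact prism-column
  # decomposition (the dished block is not star-shaped)
  attr(s, "heightfield") <- list(nx = nx, ny = ny,
                                 n_layer = nvert_layer)
  s
}

# --- parameter set ---------------------------------------------------------

#' Synthetic TKR geometry parameters
#'
#' Defaults give a generic bicondylar geometry: condyle radius 20 mm inside
#' 24 mm dishes (non-conforming, initial point contact at each dish
#' center), condyles 46 mm apart mediolaterally, a 10 mm thick insert and a
#' 2 mm initial apex gap between component and insert.
#'
#' @param condyle_radius condyle sphere radius R_c (mm).
#' @param dish_radius insert dish radius R_d (mm); must exceed
#'   `condyle_radius` so contact initializes at a point, not a conforming
#'   edge.
#' @param condyle_spacing mediolateral center-to-center condyle distance
#'   d_ml (mm).
#' @param insert_width,insert_depth insert block x/y extent (mm).
#' @param insert_height insert block thickness (mm).
#' @param dish_depth recess depth below the flat insert top (mm).
#' @param initial_gap apex gap between condyle and dish at assembly (mm).
#' @param tray_thickness tray plate thickness (mm).
#' @param stub_radius,stub_length bone stub cylinder dimensions (mm).
#' @param resolution global mesh density multiplier (1 = default density).
#' @return list of class `synthetic_geom_params`.
#' @export
synthetic_geom_params <- function(condyle_radius = 20, dish_radius = 24,
                                  condyle_spacing = 46, insert_width = 76,
                                  insert_depth = 30, insert_height = 10,
                                  dish_depth = 3, initial_gap = 2,
                                  tray_thickness = 4, stub_radius = 14,
                                  stub_length = 35, resolution = 1) {
  assert_scalar_num(condyle_radius, "condyle_radius", 0, strict_lower = TRUE)
  assert_scalar_num(dish_radius, "dish_radius", 0, strict_lower = TRUE)
  assert_scalar_num(condyle_spacing, "condyle_spacing", 0)
  assert_scalar_num(insert_height, "insert_height", 0, strict_lower = TRUE)
  assert_scalar_num(dish_depth, "dish_depth", 0, strict_lower = TRUE)
  assert_scalar_num(resolution, "resolution", 0, strict_lower = TRUE)
  if (condyle_radius >= dish_radius)
    stop_tkr(paste0("condyle_radius (%.3g) must be < dish_radius (%.3g): ",
                    "equal radii give conforming-edge contact, breaking ",
                    "point-contact initialization"),
             condyle_radius, dish_radius)
  if (dish_depth >= insert_height)
    stop_tkr("dish_depth must be smaller than insert_height")
  structure(as.list(environment()), class = "synthetic_geom_params")
}

# dish sphere center height above insert: cap of depth `dish_depth`
dish_center_z <- function(p) p$insert_height - p$dish_depth + p$dish_radius

# femoral condyle center height giving `initial_gap` at each dish apex
condyle_center_z <- function(p)
  p$insert_height - p$dish_depth + p$condyle_radius + p$initial_gap

#' Generate the synthetic TKR part set
#'
#' Builds six watertight surfaces in the model frame (x mediolateral,
#' y anteroposterior, z vertical; insert bottom at z = 0): femoral
#' component, tibial insert, tibial tray, and femur/tibia/fibula stubs.
#' The assembly is mirror-symmetric about x = 0.
#'
#' @param params a [synthetic_geom_params()].
#' @return named list of [tri_surface()] objects with elements
#'   `femoral_component`, `tibial_insert`, `tibial_tray`, `femur_stub`,
#'   `tibia_stub`, `fibula_stub`, plus attribute `params`.
#' @export
make_synthetic_tkr <- function(params = synthetic_geom_params()) {
  p <- params
  res <- p$resolution
  zc <- condyle_center_z(p)
  half <- p$condyle_spacing / 2

  # even azimuthal counts keep the vertex sets mirror-symmetric in x
  n_th <- 2L * max(4L, as.integer(round(14 * res)))
  n_ph <- max(4L, as.integer(round(14 * res)))
  cond_m <- uv_sphere(c(half, 0, zc), p$condyle_radius, n_th, n_ph)
  bridge <- box_surface(
    c(-max(half, p$condyle_radius / 2), -p$condyle_radius / 3, zc),
    c(max(half, p$condyle_radius / 2), p$condyle_radius / 3,
      zc + p$condyle_radius))
  fem <- if (p$condyle_spacing > 0) {
    cond_l <- uv_sphere(c(-half, 0, zc), p$condyle_radius, n_th, n_ph)
    merge_surfaces(cond_m, cond_l, bridge, name = "femoral_component")
  } else {
    merge_surfaces(cond_m, bridge, name = "femoral_component")
  }

  czd <- dish_center_z(p)
  rd2 <- p$dish_radius^2
  top_fn <- function(x, y) {
    z <- rep(p$insert_height, length(x))
    for (cx in unique(c(half, -half))) {
      r2 <- (x - cx)^2 + y^2
      inside <- r2 < rd2
      zd <- rep(Inf, length(x))
      zd[inside] <- czd - sqrt(rd2 - r2[inside])
      z <- pmin(z, zd)
    }
    z
  }
  nx <- max(10L, as.integer(round(p$insert_width * res)))
  ny <- max(6L, as.integer(round(p$insert_depth * res)))
  insert <- heightfield_block(c(-p$insert_width / 2, p$insert_width / 2),
                              c(-p$insert_depth / 2, p$insert_depth / 2),
                              0, top_fn, nx = nx, ny = ny,
                              name = "tibial_insert")

  tray <- box_surface(c(-p$insert_width / 2, -p$insert_depth / 2,
                        -p$tray_thickness),
                      c(p$insert_width / 2, p$insert_depth / 2, 0),
                      name = "tibial_tray")

  n_seg <- 2L * max(4L, as.integer(round(10 * res)))
  femur_stub <- cylinder_surface(c(0, 0), p$stub_radius,
                                 zc + p$condyle_radius,
                                 zc + p$condyle_radius + p$stub_length,
                                 n_seg, name = "femur_stub")
  tibia_stub <- cylinder_surface(c(0, 0), p$stub_radius,
                                 -p$tray_thickness - p$stub_length,
                                 -p$tray_thickness, n_seg,
                                 name = "tibia_stub")
  # fibula stub sits posterior on the midline so the assembly stays
  # mirror-symmetric about the sagittal plane
  fibula_stub <- cylinder_surface(c(0, -p$insert_depth), p$stub_radius / 2.5,
                                  -p$tray_thickness - p$stub_length,
                                  -p$tray_thickness, n_seg,
                                  name = "fibula_stub")

  out <- list(femoral_component = fem, tibial_insert = insert,
              tibial_tray = tray, femur_stub = femur_stub,
              tibia_stub = tibia_stub, fibula_stub = fibula_stub)
  attr(out, "params") <- p
  out
}

# residual of mirroring a surface through x = 0: for each reflected vertex,
# distance to the nearest original vertex (max over vertices)
mirror_residual <- function(s) {
  v <- s$vertices
  vr <- v; vr[, 1] <- -vr[, 1]
  # nearest-neighbour by exact match on rounded coordinates, else brute force
  mx <- 0
  for (i in seq_len(nrow(vr))) {
    d2 <- (v[, 1] - vr[i, 1])^2 + (v[, 2] - vr[i, 2])^2 +
      (v[, 3] - vr[i, 3])^2
    mx <- max(mx, sqrt(min(d2)))
  }
  mx
}

#' Default ligament attachment landmarks for the synthetic geometry
#'
#' MCL runs on the medial side (+x) from the femoral condyle region to the
#' tibia; LCL runs on the lateral side (-x) from femur to the fibula stub.
#' Points are in the model frame (mm).
#'
#' @param params a [synthetic_geom_params()].
#' @return list with `femur` (MCL/LCL origins) and `tibia`/`fibula`
#'   insertion points.
#' @export
synthetic_landmarks <- function(params = synthetic_geom_params()) {
  p <- params
  zc <- condyle_center_z(p)
  half <- p$condyle_spacing / 2
  list(
    femur = list(
      mcl_origin = c(half + p$condyle_radius, 0, zc),
      lcl_origin = c(-half - p$condyle_radius, 0, zc)),
    tibia = list(
      mcl_insertion = c(half + p$condyle_radius + 3, 0,
                        zc - p$condyle_radius - 40)),
    fibula = list(
      lcl_insertion = c(-half - p$condyle_radius - 3, -8,
                        zc - p$condyle_radius - 35))
  )
}
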