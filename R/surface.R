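#' Triangulated surface mesh
#'
#' The basic geometry container of the pipeline: a triangle soup promoted to
#' an indexed mesh. Vertices are deduplicated within `tol` (mm) at
#' construction; faces indexing is validated.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param name part label.
#' @param tol vertex-welding tolerance in mm.
#' @param orient if `TRUE` and the mesh is closed, flip all faces when the
#'   signed (divergence-theorem) volume is negative so that face normals
#'   point outward.
#' @return an object of class `tri_surface` with elements `vertices`,
#'   `faces`, `name`.
#' @export
tri_surface <- function(vertices, faces, name = "part", tol = 1e-9,
                        orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop_tkr("`vertices` must be n x 3")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop_tkr("`faces` must be m x 3")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_tkr("face indices out of range [1, %d]", nrow(vertices))

  dd <- weld_vertices(vertices, faces, tol)
  s <- structure(list(vertices = dd$vertices, faces = dd$faces, name = name),
                 class = "tri_surface")
  if (orient && nrow(s$faces) > 0) {
    rep_ <- validate_surface(s)
    if (rep_$watertight && surface_volume(s) < 0)
      s$faces <- s$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  s
}

# weld coincident vertices (within tol) and drop unused ones
weld_vertices <- function(vertices, faces, tol = 1e-9) {
  if (nrow(vertices) == 0L)
    return(list(vertices = vertices, faces = faces))
  key <- apply(round(vertices / max(tol, 1e-300)), 1L,
               function(r) paste(r, collapse = "|"))
  first <- match(key, key)            # representative row per group
  keep <- sort(unique(first))
  remap <- integer(nrow(vertices))
  remap[keep] <- seq_along(keep)
  new_faces <- matrix(remap[first[faces]], ncol = 3L)
  storage.mode(new_faces) <- "integer"
  list(vertices = vertices[keep, , drop = FALSE], faces = new_faces)
}

#' @export
print.tri_surface <- function(x, ...) {
  rep_ <- validate_surface(x)
  cat(sprintf("tri_surface '%s': %d vertices, %d faces, %s\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              if (rep_$watertight) "watertight" else
                sprintf("%d boundary edges", rep_$n_boundary_edges)))
  invisible(x)
}

face_areas <- function(s) {
  v1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  e1 <- s$vertices[s$faces[, 2], , drop = FALSE] - v1
  e2 <- s$vertices[s$faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(s) {
  v1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  e1 <- s$vertices[s$faces[, 2], , drop = FALSE] - v1
  e2 <- s$vertices[s$faces[, 3], , drop = FALSE] - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_centroids <- function(s) {
  (s$vertices[s$faces[, 1], , drop = FALSE] +
   s$vertices[s$faces[, 2], , drop = FALSE] +
   s$vertices[s$faces[, 3], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed surface
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed meshes.
#'
#' @param s a [tri_surface()].
#' @return volume in mm^3.
#' @export
surface_volume <- function(s) {
  a <- s$vertices[s$faces[, 1], , drop = FALSE]
  b <- s$vertices[s$faces[, 2], , drop = FALSE]
  c_ <- s$vertices[s$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# undirected edge table: one row per directed edge (face side)
directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

#' Surface validity report
#'
#' Counts the defects that break finite-element meshing: boundary edges
#' (holes), non-manifold edges, duplicate vertices, degenerate (zero-area)
#' faces. A surface is watertight iff it has no boundary edges.
#'
#' @param s a [tri_surface()].
#' @param area_tol faces with area below this (mm^2) count as degenerate.
#' @param dup_tol vertex coincidence tolerance (mm).
#' @return list of class `surface_validation` with counts, a `watertight`
#'   flag, an `oriented` flag (every interior edge traversed once in each
#'   direction), and the boundary edge list.
#' @export
validate_surface <- function(s, area_tol = 1e-12, dup_tol = 1e-9) {
  de <- directed_edges(s$faces)
  und <- cbind(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  ekey <- und[, 1] * (nrow(s$vertices) + 1) + und[, 2]
  cnt <- table(ekey)
  n_boundary <- sum(cnt == 1)
  n_nonmanifold <- sum(cnt > 2)

  # orientation: each shared undirected edge should appear once per direction
  dkey <- de[, 1] * (nrow(s$vertices) + 1) + de[, 2]
  oriented <- !any(duplicated(dkey))

  key <- apply(round(s$vertices / max(dup_tol, 1e-300)), 1L,
               function(r) paste(r, collapse = "|"))
  n_dup <- nrow(s$vertices) - length(unique(key))

  areas <- if (nrow(s$faces)) face_areas(s) else numeric(0)
  degenerate <- which(areas <= area_tol)

  boundary_edges <- und[cnt[match(ekey, names(cnt))] == 1, , drop = FALSE]
  boundary_edges <- unique(boundary_edges)

  structure(list(
    n_boundary_edges = as.integer(n_boundary),
    n_nonmanifold_edges = as.integer(n_nonmanifold),
    n_duplicate_vertices = as.integer(n_dup),
    n_degenerate_faces = length(degenerate),
    degenerate_faces = degenerate,
    boundary_edges = boundary_edges,
    watertight = n_boundary == 0,
    oriented = oriented
  ), class = "surface_validation")
}

#' @export
print.surface_validation <- function(x, ...) {
  cat(sprintf(paste0(
    "surface validation: %s\n",
    "  boundary edges:     %d\n  non-manifold edges: %d\n",
    "  duplicate vertices: %d\n  degenerate faces:   %d\n"),
    if (x$watertight) "watertight" else "NOT watertight",
    x$n_boundary_edges, x$n_nonmanifold_edges,
    x$n_duplicate_vertices, x$n_degenerate_faces))
  invisible(x)
}

#' Remove zero-area faces
#'
#' @param s a [tri_surface()].
#' @param area_tol degeneracy threshold (mm^2).
#' @return `s` without degenerate faces.
#' @export
drop_degenerate_faces <- function(s, area_tol = 1e-12) {
  bad <- validate_surface(s, area_tol = area_tol)$degenerate_faces
  if (length(bad)) s$faces <- s$faces[-bad, , drop = FALSE]
  s
}

# concatenate surfaces into one (disjoint components), preserving orientation
merge_surfaces <- function(..., name = "merged") {
  parts <- list(...)
  offs <- 0L
  verts <- list(); fcs <- list()
  for (p in parts) {
    verts[[length(verts) + 1L]] <- p$vertices
    fcs[[length(fcs) + 1L]] <- p$faces + offs
    offs <- offs + nrow(p$vertices)
  }
  tri_surface(do.call(rbind, verts), do.call(rbind, fcs), name = name,
              tol = 1e-12, orient = FALSE)
}
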