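#' Tetrahedral volume mesh
#'
#' @param nodes numeric n x 3 matrix (mm).
#' @param tets integer m x 4 connectivity, 1-based. The ordering convention
#'   is positive signed volume: `det([b-a, c-a, d-a]) > 0`.
#' @param name part label.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, name = "part") {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop_tkr("`nodes` must be n x 3")
  if (ncol(tets) != 4L) stop_tkr("`tets` must be m x 4")
  if (nrow(tets) > 0 && (min(tets) < 1L || max(tets) > nrow(nodes)))
    stop_tkr("tet node indices out of range")
  vols <- tet_volumes(nodes, tets)
  if (any(vols <= 0))
    stop_tkr("%d tetrahedra have non-positive volume", sum(vols <= 0))
  structure(list(nodes = nodes, tets = tets, name = name),
            class = "tet_mesh")
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Total volume of a tet mesh
#' @param m a [tet_mesh()].
#' @return volume (mm^3).
#' @export
tet_mesh_volume <- function(m) sum(tet_volumes(m$nodes, m$tets))

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh '%s': %d nodes, %d tets, volume %.6g mm^3\n",
              x$name, nrow(x$nodes), nrow(x$tets), tet_mesh_volume(x)))
  invisible(x)
}

# connected components of a surface via shared vertices
surface_components <- function(s) {
  n <- nrow(s$vertices)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(s$faces))) {
    f <- s$faces[r, ]
    a <- find(f[1]); b <- find(f[2]); c_ <- find(f[3])
    parent[b] <- a; parent[c_] <- a
  }
  roots <- vapply(s$faces[, 1], find, integer(1))
  split(seq_len(nrow(s$faces)), roots)
}

#' Tetrahedralize a watertight surface
#'
#' Builds a volume mesh by fanning every surface triangle to the centroid of
#' its connected component, then refining by longest-edge bisection until no
#' tetrahedron exceeds `max_cell_volume`. Exact for star-shaped components
#' (all synthetic parts qualify); non-star-shaped input is detected through
#' inverted fan tetrahedra and rejected. Refinement preserves total volume
#' exactly and keeps boundary faces on the input surface (new nodes are
#' edge midpoints).
#'
#' @param s a watertight [tri_surface()].
#' @param max_cell_volume target maximum tet volume (mm^3); `Inf` disables
#'   refinement.
#' @return a [tet_mesh()].
#' @export
tetrahedralize <- function(s, max_cell_volume = Inf) {
  rep_ <- validate_surface(s)
  if (!rep_$watertight) {
    be <- rep_$boundary_edges
    shown <- paste(apply(head(be, 5L), 1L, paste, collapse = "-"),
                   collapse = ", ")
    stop_tkr("surface '%s' is not watertight: %d boundary edges (%s%s)",
             s$name, rep_$n_boundary_edges, shown,
             if (nrow(be) > 5L) ", ..." else "")
  }
  hf <- attr(s, "heightfield")
  if (!is.null(hf)) {
    # prism-column decomposition of a heightfield block: each top grid
    # triangle with its bottom counterpart forms a wedge split into 3 tets;
    # exact for any (also non-star-shaped) height field
    nodes <- s$vertices
    nx <- hf$nx; ny <- hf$ny; nl <- hf$n_layer
    id <- function(i, j) (j - 1L) * (nx + 1L) + i
    tets <- list()
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i + 1L, j + 1L)
      d <- id(i, j + 1L)
      left <- nodes[a, 1] + nodes[b, 1] < 0
      for (tri in heightfield_cell_split(a, b, c_, d, left)) {
        t1 <- tri; b1 <- tri + nl
        tets[[length(tets) + 1L]] <- rbind(
          c(b1[1], b1[2], b1[3], t1[3]),
          c(b1[1], b1[2], t1[3], t1[2]),
          c(b1[1], t1[2], t1[3], t1[1]))
      }
    }
    tets <- do.call(rbind, tets)
    vols <- tet_volumes(nodes, tets)
    neg <- vols < 0
    if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    return(refine_tets(nodes, tets, max_cell_volume, s$name))
  }

  comps <- surface_components(s)
  nodes <- s$vertices
  tets <- list()
  for (fidx in comps) {
    faces <- s$faces[fidx, , drop = FALSE]
    vids <- sort(unique(as.vector(faces)))
    centroid <- colMeans(nodes[vids, , drop = FALSE])
    nodes <- rbind(nodes, centroid)
    ci <- nrow(nodes)
    # fan: (centroid, v1, v2, v3); positive volume iff outward-oriented
    # faces seen from an interior centroid
    tt <- cbind(ci, faces)
    vols <- tet_volumes(nodes, tt)
    if (any(vols <= 1e-15))
      stop_tkr(paste0("component of '%s' is not star-shaped with respect ",
                      "to its centroid; cannot fan-tetrahedralize"), s$name)
    tets[[length(tets) + 1L]] <- tt
  }
  tets <- do.call(rbind, tets)
  refine_tets(nodes, tets, max_cell_volume, s$name)
}

# longest-edge bisection until every tet volume <= max_cell_volume;
# volume is conserved exactly and new nodes are edge midpoints
refine_tets <- function(nodes, tets, max_cell_volume, name) {
  if (is.finite(max_cell_volume)) {
    assert_scalar_num(max_cell_volume, "max_cell_volume", 0,
                      strict_lower = TRUE)
    # queue-based longest-edge bisection; each split conserves volume
    out <- list()
    queue <- lapply(seq_len(nrow(tets)), function(i) tets[i, ])
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    node_env <- new.env()
    node_list <- nodes
    midpoint_id <- function(i, j) {
      key <- paste(min(i, j), max(i, j), sep = "_")
      id <- node_env[[key]]
      if (is.null(id)) {
        node_list <<- rbind(node_list, (node_list[i, ] + node_list[j, ]) / 2)
        id <- nrow(node_list)
        node_env[[key]] <- id
      }
      id
    }
    while (length(queue)) {
      t4 <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      v <- tet_volumes(node_list, matrix(t4, 1L))
      if (v <= max_cell_volume) {
        out[[length(out) + 1L]] <- t4
        next
      }
      elen <- apply(pairs, 1L, function(pr)
        sum((node_list[t4[pr[1]], ] - node_list[t4[pr[2]], ])^2))
      pr <- pairs[which.max(elen), ]
      m <- midpoint_id(t4[pr[1]], t4[pr[2]])
      t_a <- t4; t_a[pr[1]] <- m
      t_b <- t4; t_b[pr[2]] <- m
      queue[[length(queue) + 1L]] <- t_a
      queue[[length(queue) + 1L]] <- t_b
    }
    tets <- do.call(rbind, out)
    nodes <- node_list
  }

  # bisection can flip orientation parity; restore positive ordering
  vols <- tet_volumes(nodes, tets)
  neg <- vols < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]

  tet_mesh(nodes, tets, name = name)
}
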