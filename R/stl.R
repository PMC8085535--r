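#' Read an STL surface file
#'
#' Reads binary or ASCII STL (auto-detected), welds coincident vertices
#' within `tol`, and optionally drops zero-area facets. STL stores a bare
#' triangle soup, so welding is what recovers shared mesh topology.
#'
#' @param path file path.
#' @param name part label; defaults to the file stem.
#' @param tol vertex welding tolerance (mm).
#' @param drop_degenerate remove zero-area facets (default `FALSE`: they are
#'   only reported, see [validate_surface()]).
#' @return a [tri_surface()].
#' @export
read_stl <- function(path, name = NULL, tol = 1e-9, drop_degenerate = FALSE) {
  if (!file.exists(path)) stop_tkr("cannot read STL file '%s'", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  tri <- if (is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop_tkr("STL file '%s' contains no facets", path)
  nf <- nrow(tri) / 3L
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  s <- tri_surface(tri, faces, name = name, tol = tol)
  if (drop_degenerate) s <- drop_degenerate_faces(s)
  s
}

is_ascii_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  Encoding(txt) <- "bytes"
  grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop_tkr("malformed ASCII STL: vertex count %d not divisible by 3",
             length(vl))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4]))
  m <- do.call(rbind, nums)
  if (anyNA(m)) stop_tkr("malformed ASCII STL: non-numeric vertex line")
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L) stop_tkr("malformed binary STL header")
  out <- matrix(0, nrow = 3L * nf, ncol = 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stop_tkr("truncated binary STL facet %d", i)
    readBin(con, "raw", n = 2L)
    out[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], ncol = 3L,
                                            byrow = TRUE)
  }
  out
}

#' Write an STL surface file
#'
#' @param s a [tri_surface()].
#' @param path output path.
#' @param ascii write ASCII STL (default binary).
#' @return `path`, invisibly.
#' @export
write_stl <- function(s, path, ascii = FALSE) {
  n <- face_normals(s)
  v <- s$vertices
  f <- s$faces
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", s$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", s$name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("tkrfem", s$name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(t(rbind(n[i, ], v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
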