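#' Indexed triangle mesh
#'
#' Constructs an indexed triangle surface mesh in world millimetres.
#' Faces are index triples into the vertex table; counter-clockwise
#' winding (seen from outside) encodes the outward normal. Stored STL
#' facet normals are never used anywhere in the package: orientation
#' always comes from winding.
#'
#' @param vertices numeric matrix, one vertex per row, columns x/y/z (mm).
#' @param faces integer matrix, one face per row, three 1-based vertex
#'   indices per row.
#' @return An object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices, "vertices")
  if (length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3L)
  }
  faces <- matrix(as.integer(faces), ncol = 3L)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  validate_mesh(m)
  m
}

as_point_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop(sprintf("'%s' must be coercible to an n x 3 matrix", what))
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L)
    stop(sprintf("'%s' must have 3 columns (x, y, z)", what))
  dimnames(x) <- NULL
  x
}

validate_mesh <- function(m) {
  v <- m$vertices; f <- m$faces
  if (any(!is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (nrow(f) > 0) {
    if (any(f < 1L) || any(f > nrow(v)))
      stop("mesh face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("mesh face references the same vertex twice")
  }
  invisible(m)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  nb <- tryCatch(length(boundary_loops(x)), error = function(e) NA_integer_)
  cat(sprintf("  boundary loops: %s\n", ifelse(is.na(nb), "?", nb)))
  invisible(x)
}

# per-face corner coordinate arrays, used all over
face_corners <- function(m) {
  list(a = m$vertices[m$faces[, 1], , drop = FALSE],
       b = m$vertices[m$faces[, 2], , drop = FALSE],
       c = m$vertices[m$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Face normals, areas and mesh volume
#'
#' `face_normals()` returns unit outward normals from winding,
#' `face_areas()` triangle areas in mm^2, and `mesh_volume()` the signed
#' enclosed volume in mm^3 (positive for outward-wound closed surfaces;
#' the divergence-theorem sum of signed tetra volumes against the origin).
#'
#' @param m a [triangle_mesh()].
#' @return numeric matrix / vector / scalar.
#' @export
face_normals <- function(m) {
  fc <- face_corners(m)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_normals
#' @export
face_areas <- function(m) {
  fc <- face_corners(m)
  0.5 * sqrt(rowSums(cross3(fc$b - fc$a, fc$c - fc$a)^2))
}

#' @rdname face_normals
#' @export
mesh_volume <- function(m) {
  fc <- face_corners(m)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

# undirected edge table: one row per face edge, key = "lo_hi"
mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed) when every edge is shared by exactly two
#' faces. Multi-component closed surfaces (e.g. a shell made of an outer
#' and an inner table) count as watertight.
#'
#' @param m a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(m) {
  if (nrow(m$faces) == 0) return(FALSE)
  tab <- table(mesh_edge_keys(m$faces))
  all(tab == 2L)
}

#' Weld duplicated vertices
#'
#' Merges vertices that coincide after rounding coordinates to the weld
#' tolerance, re-indexes faces, and drops faces degenerated by the merge.
#' Exact-match hashing on rounded coordinates makes the result
#' deterministic and independent of vertex order.
#'
#' @param m a [triangle_mesh()].
#' @param tol weld tolerance in mm (non-negative). Default `1e-6`.
#' @return a welded [triangle_mesh()].
#' @export
weld_vertices <- function(m, tol = 1e-6) {
  if (tol < 0) stop("weld tolerance must be >= 0")
  v <- m$vertices
  if (nrow(v) == 0) return(m)
  key_v <- if (tol > 0) round(v / tol) else v
  keys <- paste(key_v[, 1], key_v[, 2], key_v[, 3], sep = "|")
  first <- !duplicated(keys)
  map <- match(keys, keys[first])
  newv <- v[first, , drop = FALSE]
  f <- m$faces
  if (nrow(f) > 0) {
    f <- matrix(map[f], ncol = 3L)
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!degen, , drop = FALSE]
  }
  triangle_mesh(newv, f)
}

#' Outward-facing subset of a centred shell mesh
#'
#' Keeps faces whose outward normal points away from the origin
#' (normal . centroid > 0): for a centred, roughly star-shaped
#' two-layer skull shell this selects the outer table and discards the
#' inner table, whose outward-from-the-bone normals point towards the
#' head centre.
#'
#' @param m a centred [triangle_mesh()].
#' @return a [triangle_mesh()] with the outward-facing faces only.
#' @export
outward_faces <- function(m) {
  fc <- face_corners(m)
  ctr <- (fc$a + fc$b + fc$c) / 3
  keep <- rowSums(face_normals(m) * ctr) > 0
  triangle_mesh(m$vertices, m$faces[keep, , drop = FALSE])
}

# drop vertices not referenced by any face, re-index
compact_mesh <- function(m) {
  used <- sort(unique(as.vector(m$faces)))
  map <- integer(nrow(m$vertices))
  map[used] <- seq_along(used)
  triangle_mesh(m$vertices[used, , drop = FALSE],
                matrix(map[m$faces], ncol = 3L))
}
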