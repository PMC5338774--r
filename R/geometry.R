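#' Plane in 3D
#'
#' A plane given by a point on it and a unit normal. Used as the
#' midsagittal mirroring plane and as a clipping plane. The default
#' `plane3()` with no arguments is the midsagittal plane of a centred
#' skull: x = 0 with normal (1, 0, 0), whose reflection is the diagonal
#' matrix diag(-1, 1, 1).
#'
#' @param point 3-vector, a point on the plane (mm).
#' @param normal 3-vector, plane normal (normalised internally).
#' @return an object of class `plane3`.
#' @export
plane3 <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3 || length(normal) != 3)
    stop("plane point and normal must be 3-vectors")
  len <- sqrt(sum(normal^2))
  if (!is.finite(len) || len < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / len), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Fit a plane through three landmark points
#'
#' Headless replacement for interactive midsagittal-plane placement: the
#' user supplies three anatomical landmarks (e.g. nasion and the two
#' orbital rims projected onto the midline) and gets the plane through
#' them.
#'
#' @param p1,p2,p3 3-vectors (mm), not collinear.
#' @return a [plane3()].
#' @export
plane_from_landmarks <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- crossv(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9) stop("landmarks are collinear; no unique plane")
  plane3(p1, n)
}

crossv <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

signed_dist <- function(points, plane) {
  sweep(points, 2, plane$point) %*% plane$normal
}

#' Centre a mesh at the origin
#'
#' Translates the mesh so the centre of its axis-aligned bounding box is
#' at the origin, and returns the offset needed to undo the move.
#'
#' @param m a non-empty [triangle_mesh()].
#' @return list with `mesh` (centred) and `offset` (3-vector: original
#'   bbox centre, so `vertices + offset` restores the input).
#' @export
center_mesh <- function(m) {
  if (nrow(m$vertices) == 0) stop("cannot centre an empty mesh")
  bb <- apply(m$vertices, 2, range)
  ctr <- colMeans(bb)
  list(mesh = triangle_mesh(sweep(m$vertices, 2, ctr), m$faces),
       offset = ctr)
}

#' Reflect a mesh across a plane
#'
#' Householder reflection v - 2((v - p) . n) n of every vertex; face
#' winding is reversed so normals remain outward. Across the default
#' midsagittal plane (x = 0) this is the diagonal mirror matrix
#' diag(-1, 1, 1), the transform that turns the healthy half of a
#' centred skull into a curvature template for the defect side.
#'
#' @param m a [triangle_mesh()].
#' @param plane a [plane3()]; default the midsagittal x = 0 plane.
#' @return the reflected [triangle_mesh()].
#' @export
reflect_mesh <- function(m, plane = plane3()) {
  v <- reflect_points(m$vertices, plane)
  triangle_mesh(v, m$faces[, c(1, 3, 2), drop = FALSE])
}

#' @rdname reflect_mesh
#' @param points n x 3 matrix of points.
#' @export
reflect_points <- function(points, plane = plane3()) {
  points <- as_point_matrix(points)
  d <- as.vector(signed_dist(points, plane))
  points - 2 * outer(d, plane$normal)
}

#' Clip a mesh with a plane
#'
#' Keeps faces whose three vertices lie on the non-negative side of the
#' plane ((v - p) . n >= 0). Faces crossing the plane are dropped, not
#' split: clipping is a marker-placement / inner-view aid, not part of
#' the implant geometry, so a clean face subset is preferable to new
#' geometry. A face lying entirely in the plane belongs to neither side.
#'
#' @param m a [triangle_mesh()].
#' @param plane a [plane3()].
#' @return the clipped [triangle_mesh()] (vertex table preserved).
#' @export
clip_mesh <- function(m, plane) {
  if (nrow(m$faces) == 0) return(m)
  d <- as.vector(signed_dist(m$vertices, plane))
  dm <- matrix(d[m$faces], ncol = 3L)
  keep <- dm[, 1] >= 0 & dm[, 2] >= 0 & dm[, 3] >= 0 &
    (dm[, 1] > 0 | dm[, 2] > 0 | dm[, 3] > 0)
  triangle_mesh(m$vertices, m$faces[keep, , drop = FALSE])
}

#' Rigid landmark registration (orthogonal Procrustes)
#'
#' Closed-form least-squares rigid transform (rotation + translation, no
#' scaling) mapping `source` landmark points onto `target`, via the SVD
#' solution of the orthogonal Procrustes problem with the
#' determinant-sign correction that excludes reflections. Used to align
#' the mirrored template skull to the original before marker placement.
#'
#' @param source,target n x 3 matrices of corresponding points, n >= 3,
#'   not collinear.
#' @return an object of class `rigid_transform`: list with 3 x 3
#'   `rotation` (det +1) and 3-vector `translation`, applied as
#'   `p %*% t(rotation) + translation`.
#' @export
rigid_register <- function(source, target) {
  source <- as_point_matrix(source, "source")
  target <- as_point_matrix(target, "target")
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of points")
  if (nrow(source) < 3) stop("degenerate input: need >= 3 point pairs")
  cs <- colMeans(source); ct <- colMeans(target)
  A <- sweep(source, 2, cs); B <- sweep(target, 2, ct)
  # collinearity check: second singular value of the centred cloud
  sv <- svd(A)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate input: landmarks are collinear")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = R,
                 translation = as.vector(ct - R %*% cs)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param transform a `rigid_transform` from [rigid_register()].
#' @param x an n x 3 point matrix or a [triangle_mesh()].
#' @return the transformed object, same type as `x`.
#' @export
apply_rigid <- function(transform, x) {
  if (inherits(x, "triangle_mesh")) {
    triangle_mesh(apply_rigid(transform, x$vertices), x$faces)
  } else {
    p <- as_point_matrix(x)
    sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
  }
}

#' Boundary loops of an open mesh
#'
#' Finds the closed rims of a surface: edges used by exactly one face,
#' chained into ordered vertex cycles. The longest rim of a cranial
#' defect is where the outer-edge markers go. Loops are sorted by
#' descending polyline length (mm); each loop starts at its smallest
#' vertex index and proceeds towards the smaller-index neighbour, so the
#' result is deterministic.
#'
#' @param m a [triangle_mesh()], edge-manifold (every edge in at most
#'   two faces).
#' @return list of integer vectors, each an ordered closed cycle of
#'   vertex indices (first vertex not repeated at the end); empty list
#'   for a watertight mesh.
#' @export
boundary_loops <- function(m) {
  if (nrow(m$faces) == 0) return(list())
  keys <- mesh_edge_keys(m$faces)
  tab <- table(keys)
  if (any(tab > 2L)) stop("topology error: non-manifold edge (> 2 faces)")
  bkeys <- names(tab)[tab == 1L]
  if (length(bkeys) == 0) return(list())
  ends <- do.call(rbind, strsplit(bkeys, "_", fixed = TRUE))
  ends <- matrix(as.integer(ends), ncol = 2L)
  # adjacency over boundary vertices; each appears in exactly 2 boundary
  # edges when rims are simple cycles
  adj <- split(c(ends[, 2], ends[, 1]), c(ends[, 1], ends[, 2]))
  verts <- as.integer(names(adj))
  if (any(vapply(adj, length, 1L) != 2L))
    stop("topology error: boundary is not a union of simple cycles")
  visited <- logical(max(verts))
  loops <- list()
  for (v0 in sort(verts)) {
    if (visited[v0]) next
    nbrs <- sort(adj[[as.character(v0)]])
    loop <- integer(0)
    prev <- v0; cur <- nbrs[1]
    loop <- c(v0)
    visited[v0] <- TRUE
    while (cur != v0) {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      nb <- adj[[as.character(cur)]]
      nxt <- nb[nb != prev][1]
      prev <- cur; cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }
  len <- vapply(loops, function(l) {
    p <- m$vertices[l, , drop = FALSE]
    q <- m$vertices[c(l[-1], l[1]), , drop = FALSE]
    sum(sqrt(rowSums((q - p)^2)))
  }, 1.0)
  loops[order(-len)]
}
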