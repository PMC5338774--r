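#' Delaunay tetrahedralization of a marker cloud
#'
#' Incremental Bowyer-Watson 3D Delaunay triangulation. Input points are
#' first deduplicated at `dedupe_tol` (coordinate rounding, as in
#' [weld_vertices()]); the union of the returned tetrahedra is the
#' convex hull of the points and every tetrahedron satisfies the
#' empty-circumsphere property up to degeneracy tie-breaking.
#'
#' Marker clouds sampled from smooth skull surfaces are nearly
#' cospherical (all inner-layer markers lie close to one sphere), the
#' classic degenerate input for Delaunay codes. When the insertion
#' machinery detects a degeneracy (singular circumcentre system,
#' inverted or sliver cavity tetrahedra, or a failed post-validation),
#' the triangulation is recomputed with a deterministic symbolic-style
#' jitter: pseudo-random offsets of magnitude 1e-9 mm drawn from a
#' fixed internal seed, escalated tenfold per retry (at most to 1e-5
#' mm). Circumradii reported in the result are always computed from the
#' original, unjittered coordinates, so downstream alpha filtering is
#' unaffected. The same input therefore always yields the same
#' tetrahedra.
#'
#' @param points n x 3 matrix (mm), n >= 4 after deduplication, not all
#'   coplanar.
#' @param dedupe_tol deduplication tolerance in mm. Default 1e-6.
#' @return an object of class `tet_mesh`: list with `points` (the
#'   deduplicated input), integer `tets` (m x 4, positively oriented)
#'   and `circumradius` (length m, mm).
#' @export
delaunay_tetrahedralize <- function(points, dedupe_tol = 1e-6) {
  points <- as_point_matrix(points)
  if (dedupe_tol > 0) {
    keys <- apply(round(points / dedupe_tol), 1, paste, collapse = "|")
    points <- points[!duplicated(keys), , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 4) stop("parameter error: need >= 4 distinct points")
  # affine-independence check via singular values of the centred cloud
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  scale <- max(sv[1], 1)
  if (sv[3] < 1e-9 * scale)
    stop("degeneracy error: points are coplanar or collinear")
  tets <- NULL
  for (attempt in 0:5) {
    jit <- if (attempt == 0) 0 else 1e-9 * 10^(attempt - 1)
    pj <- points
    if (jit > 0) {
      pj <- points + with_seed(745211L + attempt,
                               matrix(stats::runif(3 * n, -jit, jit), n, 3))
    }
    tets <- tryCatch(bowyer_watson(pj), error = function(e) NULL)
    if (!is.null(tets)) tets <- prune_flat_tets(points, tets)
    if (!is.null(tets) && validate_tetra(points, tets)) break
    tets <- NULL
  }
  if (is.null(tets))
    stop("degeneracy error: Delaunay triangulation failed on this input")
  cr <- circumspheres(points, tets)$radius
  structure(list(points = points, tets = tets, circumradius = cr),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d points, %d tetrahedra\n",
              nrow(x$points), nrow(x$tets)))
  if (nrow(x$tets) > 0)
    cat(sprintf("  circumradius range [%.3f, %.3f] mm\n",
                min(x$circumradius), max(x$circumradius)))
  invisible(x)
}

# circumcentre and radius of each tet; radius Inf for singular tets
circumspheres <- function(points, tets) {
  m <- nrow(tets)
  ctr <- matrix(NA_real_, m, 3)
  rad <- rep(Inf, m)
  for (k in seq_len(m)) {
    p <- points[tets[k, ], , drop = FALSE]
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    cc <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(cc) && all(is.finite(cc))) {
      ctr[k, ] <- cc
      rad[k] <- sqrt(sum((cc - p[1, ])^2))
    }
  }
  list(center = ctr, radius = rad)
}

tet_signed_volume <- function(points, tets) {
  a <- points[tets[, 1], , drop = FALSE]
  b <- points[tets[, 2], , drop = FALSE]
  c_ <- points[tets[, 3], , drop = FALSE]
  d <- points[tets[, 4], , drop = FALSE]
  rowSums(cross3(b - a, c_ - a) * (d - a)) / 6
}

bowyer_watson <- function(p) {
  n <- nrow(p)
  ctr <- colMeans(apply(p, 2, range))
  ext <- max(apply(p, 2, function(x) diff(range(x))), 1)
  L <- 1e3 * ext
  super <- rbind(ctr + c( L,  L,  L), ctr + c( L, -L, -L),
                 ctr + c(-L,  L, -L), ctr + c(-L, -L,  L))
  pts <- rbind(p, super)
  sidx <- n + 1:4
  tets <- matrix(sidx, nrow = 1)
  if (tet_signed_volume(pts, tets)[1] < 0) tets <- tets[, c(1, 2, 4, 3), drop = FALSE]
  cs <- circumspheres(pts, tets)
  cc <- cs$center; r2 <- cs$radius^2
  eps2 <- (1e-9 * ext)^2
  for (ip in seq_len(n)) {
    q <- pts[ip, ]
    d2 <- (cc[, 1] - q[1])^2 + (cc[, 2] - q[2])^2 + (cc[, 3] - q[3])^2
    bad <- which(d2 < r2 - eps2)
    if (length(bad) == 0)
      stop("degeneracy: inserted point inside no circumsphere")
    # cavity boundary = faces of bad tets not shared by two bad tets
    faces <- rbind(tets[bad, c(2, 3, 4), drop = FALSE],
                   tets[bad, c(1, 4, 3), drop = FALSE],
                   tets[bad, c(1, 2, 4), drop = FALSE],
                   tets[bad, c(1, 3, 2), drop = FALSE])
    key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "_")
    once <- key %in% names(which(table(key) == 1L))
    bfaces <- faces[once, , drop = FALSE]
    newtets <- cbind(bfaces, ip)
    vol <- tet_signed_volume(pts, newtets)
    flip <- vol < 0
    if (any(flip))
      newtets[flip, ] <- newtets[flip, c(1, 3, 2, 4), drop = FALSE]
    if (any(abs(vol) < 1e-12 * ext^3))
      stop("degeneracy: flat cavity tetrahedron")
    ncs <- circumspheres(pts, newtets)
    if (any(!is.finite(ncs$radius)))
      stop("degeneracy: singular circumsphere")
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keep, , drop = FALSE], newtets)
    cc <- rbind(cc[keep, , drop = FALSE], ncs$center)
    r2 <- c(r2[keep], ncs$radius^2)
  }
  real <- rowSums(matrix(tets %in% sidx, nrow(tets), 4)) == 0
  tets <- tets[real, , drop = FALSE]
  if (nrow(tets) == 0) stop("degeneracy: no tetrahedra survive")
  storage.mode(tets) <- "integer"
  tets
}

# drop tets that are exactly flat in the unjittered coordinates (zero
# volume to machine precision): these are slivers the jitter created
# out of cospherical/coplanar subsets, and their two coincident sides
# leave the boundary closed when removed; reorient the rest
prune_flat_tets <- function(points, tets) {
  ext <- max(apply(points, 2, function(x) diff(range(x))), 1)
  vol <- tet_signed_volume(points, tets)
  keep <- abs(vol) > 1e-12 * ext^3
  tets <- tets[keep, , drop = FALSE]
  flip <- tet_signed_volume(points, tets) < 0
  if (any(flip)) tets[flip, ] <- tets[flip, c(1, 3, 2, 4), drop = FALSE]
  tets
}

# structural validation: orientation, face incidence, closed boundary,
# volume consistency with the boundary surface, all points used
validate_tetra <- function(points, tets) {
  vol <- tet_signed_volume(points, tets)
  if (any(vol <= 0)) return(FALSE)
  if (!all(seq_len(nrow(points)) %in% tets)) return(FALSE)
  faces <- all_tet_faces(tets)
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "_")
  tab <- table(key)
  if (any(tab > 2L)) return(FALSE)
  surf <- tet_boundary_faces(points, tets)
  ekeys <- mesh_edge_keys(surf)
  if (any(table(ekeys) != 2L)) return(FALSE)
  vsurf <- sum(rowSums(points[surf[, 1], , drop = FALSE] *
    cross3(points[surf[, 2], , drop = FALSE],
           points[surf[, 3], , drop = FALSE]))) / 6
  isTRUE(abs(vsurf - sum(vol)) <= 1e-6 * max(sum(vol), 1))
}

all_tet_faces <- function(tets) {
  rbind(tets[, c(2, 3, 4), drop = FALSE],
        tets[, c(1, 4, 3), drop = FALSE],
        tets[, c(1, 2, 4), drop = FALSE],
        tets[, c(1, 3, 2), drop = FALSE])
}

# boundary faces (incidence 1) of a tet complex, wound outward
tet_boundary_faces <- function(points, tets) {
  faces <- all_tet_faces(tets)
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "_")
  once <- key %in% names(which(table(key) == 1L))
  bf <- faces[once, , drop = FALSE]
  bopp <- opp[once]
  # wind each face so its normal points away from the opposite vertex
  a <- points[bf[, 1], , drop = FALSE]
  b <- points[bf[, 2], , drop = FALSE]
  c_ <- points[bf[, 3], , drop = FALSE]
  d <- points[bopp, , drop = FALSE]
  s <- rowSums(cross3(b - a, c_ - a) * (d - a))
  flip <- s > 0
  bf[flip, ] <- bf[flip, c(1, 3, 2), drop = FALSE]
  bf
}

#' Alpha filtering of a tetrahedralization
#'
#' Keeps tetrahedra whose circumradius is at most `alpha` (mm), the
#' vtkDelaunay3D-style alpha criterion that carves concavities out of
#' the convex hull; `alpha = NULL` keeps everything. For a thin
#' double-layer marker cloud this is what removes the huge
#' hull-spanning tetrahedra bridging the implant's concave inner side,
#' whose circumradii are on the order of the skull's radius of
#' curvature, while local shell tetrahedra survive.
#'
#' @param tm a `tet_mesh` from [delaunay_tetrahedralize()].
#' @param alpha positive circumradius threshold in mm, or `NULL` for no
#'   filtering.
#' @return the filtered `tet_mesh`.
#' @export
alpha_filter <- function(tm, alpha = NULL) {
  if (is.null(alpha) || (is.character(alpha) && alpha == "none")) return(tm)
  alpha <- as.numeric(alpha)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0 or NULL")
  keep <- tm$circumradius <= alpha
  if (!any(keep))
    stop(sprintf(
      "empty-result error: alpha %.4g removes all tetrahedra (minimum circumradius %.4g mm)",
      alpha, min(tm$circumradius)))
  structure(list(points = tm$points,
                 tets = tm$tets[keep, , drop = FALSE],
                 circumradius = tm$circumradius[keep]),
            class = "tet_mesh")
}

#' Boundary surface of a tetrahedral complex
#'
#' Extracts the triangles incident to exactly one kept tetrahedron,
#' wound outward (away from the owning tetrahedron's fourth vertex),
#' and compacts them into an indexed surface mesh — the final implant
#' surface ready for STL export.
#'
#' @param tm a non-empty `tet_mesh`.
#' @return a [triangle_mesh()].
#' @export
extract_boundary_surface <- function(tm) {
  if (nrow(tm$tets) == 0) stop("tet mesh has no tetrahedra")
  bf <- tet_boundary_faces(tm$points, tm$tets)
  compact_mesh(triangle_mesh(tm$points, bf))
}
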