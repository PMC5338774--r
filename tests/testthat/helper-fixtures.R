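# fixtures and independent oracles used across the suite

# --- simple meshes -------------------------------------------------------

# regular tetrahedron surface (closed), edge length sqrt(8)
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  triangle_mesh(v, f)
}

# axis-aligned unit cube [0,1]^3 as 12 outward-wound triangles
cube_mesh <- function(lo = 0, hi = 1) {
  v <- as.matrix(expand.grid(x = c(lo, hi), y = c(lo, hi), z = c(lo, hi)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  triangle_mesh(v, f)
}

# flat unit square in the z = 0 plane, two triangles (open)
plate_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

random_points <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -scale, scale), n, 3)
}

random_marker_set <- function(n, seed, scale = 10) {
  set.seed(seed)
  marker_set(matrix(stats::runif(3 * n, -scale, scale), n, 3),
             sample(0:3, n, replace = TRUE))
}

# --- independent STL binary reader (tests only) --------------------------
# parses the binary layout directly; no welding, no package code paths

independent_read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tri <- vector("list", nfac)
  for (i in seq_len(nfac)) {
    vals <- readBin(con, "double", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tri[[i]] <- matrix(vals[4:12], nrow = 3, byrow = TRUE)
  }
  tri
}

# --- brute-force geometric oracles ---------------------------------------

# convex-hull facets by exhaustive triple enumeration (<= ~12 points):
# a triple is a hull facet iff all other points are weakly on one side
brute_hull_faces <- function(pts) {
  n <- nrow(pts)
  faces <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- crossprod_vec(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    d <- (pts %*% nrm) - sum(nrm * pts[i, ])
    if (all(d <= 1e-9) || all(d >= -1e-9))
      faces[[length(faces) + 1L]] <- sort(c(i, j, k))
  }
  unique(faces)
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# circumsphere of 4 points (centre + radius) by solving the linear system
circumsphere4 <- function(p) {
  A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  cc <- solve(A, b)
  list(center = cc, radius = sqrt(sum((cc - p[1, ])^2)))
}

# empty-circumsphere check of a tetrahedralization by brute force
assert_delaunay_property <- function(tm, tol = 1e-7) {
  for (k in seq_len(nrow(tm$tets))) {
    cs <- circumsphere4(tm$points[tm$tets[k, ], , drop = FALSE])
    others <- setdiff(seq_len(nrow(tm$points)), tm$tets[k, ])
    if (length(others) == 0) next
    d <- sqrt(rowSums(sweep(tm$points[others, , drop = FALSE], 2,
                            cs$center)^2))
    expect_true(all(d >= cs$radius - tol),
                label = sprintf("tet %d circumsphere empty", k))
  }
}

# exact distance from a point to every triangle of a mesh
point_to_mesh_distance <- function(p, mesh) {
  vapply(seq_len(nrow(mesh$faces)), function(k) {
    tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
    point_triangle_distance(p, tri[1, ], tri[2, ], tri[3, ])
  }, 1.0)
}

point_triangle_distance <- function(p, a, b, c) {
  # project, clamp to the triangle via barycentric region tests
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

# all-pairs mean oracle for the smoother at y = 1, radius = Inf
brute_smooth_all_pairs <- function(markers) {
  pos <- markers$positions
  layer <- marker_layer(markers)
  border <- is_border_marker(markers)
  out <- pos
  for (i in seq_len(nrow(pos))) {
    if (border[i]) next
    acc <- c(0, 0, 0); nn <- 0L
    for (j in seq_len(nrow(pos))) {
      if (j == i || layer[j] != layer[i]) next
      acc <- acc + pos[j, ]; nn <- nn + 1L
    }
    if (nn > 0) out[i, ] <- acc / nn
  }
  out
}

# standard small phantom used by the voxel-heavy tests
small_phantom_spec <- function(...) {
  phantom_spec(outer_semiaxes = c(25, 30, 22), thickness = 3,
               defect_angle = 35, subdivision = 3, ...)
}
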