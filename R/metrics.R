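#' Binary voxel occupancy grid
#'
#' Isotropic voxel grid in world mm. Voxel centres sit at
#' `origin + (i - 1) * spacing` per axis (`origin` is the centre of
#' voxel (1,1,1)); `occupancy` is a logical array of dimension `shape`.
#' Two grids are comparable (Dice, Hausdorff) only when origin, spacing
#' and shape all agree, so meshes being compared must be voxelized on
#' one shared grid.
#'
#' @param origin 3-vector (mm), centre of the first voxel.
#' @param spacing isotropic voxel edge length (mm), > 0.
#' @param shape 3 positive integers.
#' @param occupancy logical array of dim `shape`; default all empty.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, shape, occupancy = NULL) {
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  if (length(origin) != 3 || length(shape) != 3)
    stop("origin and shape must have length 3")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (any(shape < 1L)) stop("shape must be positive")
  if (is.null(occupancy)) occupancy <- array(FALSE, dim = shape)
  if (!identical(as.integer(dim(occupancy)), shape))
    stop("occupancy dimensions do not match shape")
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 occupancy = occupancy), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %.3g mm, %d occupied (%.1f mm^3)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              sum(x$occupancy), sum(x$occupancy) * x$spacing^3))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$shape, b$shape)
}

#' An empty grid covering one or more meshes
#'
#' Builds the shared voxel grid for comparing meshes: covers the union
#' bounding box padded by one voxel on every side.
#'
#' @param meshes a [triangle_mesh()] or list of them.
#' @param spacing voxel size in mm.
#' @return an empty [voxel_grid()].
#' @export
grid_for_meshes <- function(meshes, spacing = 0.5) {
  if (inherits(meshes, "triangle_mesh")) meshes <- list(meshes)
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min); hi <- apply(allv, 2, max)
  shape <- as.integer(ceiling((hi - lo) / spacing)) + 2L
  voxel_grid(lo - spacing / 2, spacing, shape)
}

#' Voxelize a watertight mesh
#'
#' Marks a voxel occupied iff its centre lies inside the surface, by
#' parity counting of surface crossings along a +x ray. The ray origin
#' is offset by a fixed 1e-7 mm in y and z so rays never graze triangle
#' edges exactly, keeping the parity test deterministic without any
#' randomness. Multi-component closed surfaces work as expected: a
#' shell's cavity gets even parity and stays empty.
#'
#' @param m a watertight [triangle_mesh()].
#' @param spacing voxel size in mm (used when `grid` is NULL). Default
#'   0.5 mm.
#' @param grid optional shared [voxel_grid()]; when comparing two
#'   meshes, voxelize both on one grid from [grid_for_meshes()].
#' @return the filled [voxel_grid()].
#' @export
voxelize <- function(m, spacing = 0.5, grid = NULL) {
  if (!is_watertight(m))
    stop("topology error: mesh is not watertight, cannot voxelize")
  if (is.null(grid)) grid <- grid_for_meshes(m, spacing)
  sp <- grid$spacing
  off <- 1e-7
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * sp + off
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * sp + off
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * sp
  fc <- face_corners(m)
  ny <- grid$shape[2]; nz <- grid$shape[3]; nx <- grid$shape[1]
  # crossings per (y, z) ray column, accumulated triangle by triangle
  col_ids <- vector("list", nrow(m$faces))
  col_xs <- vector("list", nrow(m$faces))
  for (t in seq_len(nrow(m$faces))) {
    y1 <- fc$a[t, 2]; y2 <- fc$b[t, 2]; y3 <- fc$c[t, 2]
    z1 <- fc$a[t, 3]; z2 <- fc$b[t, 3]; z3 <- fc$c[t, 3]
    den <- (y2 - y1) * (z3 - z1) - (y3 - y1) * (z2 - z1)
    if (abs(den) < 1e-30) next           # triangle parallel to the ray
    iy <- which(ys >= min(y1, y2, y3) & ys <= max(y1, y2, y3))
    iz <- which(zs >= min(z1, z2, z3) & zs <= max(z1, z2, z3))
    if (!length(iy) || !length(iz)) next
    gy <- rep(ys[iy], times = length(iz))
    gz <- rep(zs[iz], each = length(iy))
    l2 <- ((gy - y1) * (z3 - z1) - (gz - z1) * (y3 - y1)) / den
    l3 <- ((gz - z1) * (y2 - y1) - (gy - y1) * (z2 - z1)) / den
    inside <- l2 >= 0 & l3 >= 0 & (l2 + l3) <= 1
    if (!any(inside)) next
    l1 <- 1 - l2 - l3
    xc <- l1[inside] * fc$a[t, 1] + l2[inside] * fc$b[t, 1] +
      l3[inside] * fc$c[t, 1]
    ci <- (rep(iy, times = length(iz)) +
             (rep(iz, each = length(iy)) - 1L) * ny)[inside]
    col_ids[[t]] <- ci
    col_xs[[t]] <- xc
  }
  ids <- unlist(col_ids); xsx <- unlist(col_xs)
  occ <- array(FALSE, dim = grid$shape)
  if (length(ids)) {
    ord <- order(ids, xsx)
    ids <- ids[ord]; xsx <- xsx[ord]
    start <- which(!duplicated(ids))
    end <- c(start[-1] - 1L, length(ids))
    for (k in seq_along(start)) {
      cid <- ids[start[k]]
      cross <- xsx[start[k]:end[k]]
      par <- findInterval(xs, cross) %% 2L == 1L
      if (any(par)) {
        iy <- ((cid - 1L) %% ny) + 1L
        iz <- ((cid - 1L) %/% ny) + 1L
        occ[par, iy, iz] <- TRUE
      }
    }
  }
  voxel_grid(grid$origin, sp, grid$shape, occ)
}

#' Dice similarity coefficient (percent)
#'
#' DSC = 2 |A n B| / (|A| + |B|) over occupied voxels of two grids
#' sharing origin, spacing and shape, in percent.
#'
#' @param A,B [voxel_grid()]s on the same grid, not both empty.
#' @return percentage in `[0, 100]`.
#' @export
dice_coefficient <- function(A, B) {
  if (!same_grid(A, B)) stop("grid error: grids differ, voxelize on a shared grid")
  na <- sum(A$occupancy); nb <- sum(B$occupancy)
  if (na + nb == 0) stop("undefined-metric error: both grids empty")
  100 * 2 * sum(A$occupancy & B$occupancy) / (na + nb)
}

occupied_centers <- function(g) {
  idx <- which(g$occupancy, arr.ind = TRUE)
  sweep((idx - 1) * g$spacing, 2, g$origin, "+")
}

# 6-connected boundary voxels of an occupancy array (occupied voxels
# with at least one empty/outside face neighbour)
boundary_mask <- function(occ) {
  d <- dim(occ)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  sl <- function(i, j, k) pad[i, j, k, drop = FALSE]
  x <- 2:(d[1] + 1); y <- 2:(d[2] + 1); z <- 2:(d[3] + 1)
  full <- sl(x, y, z) &
    sl(x - 1L, y, z) & sl(x + 1L, y, z) &
    sl(x, y - 1L, z) & sl(x, y + 1L, z) &
    sl(x, y, z - 1L) & sl(x, y, z + 1L)
  occ & !full
}

# directed Hausdorff from points of A to set B: max over a in A of the
# distance to the nearest b; exact because the farthest a from B is
# never interior to B (interior points have distance 0) and the nearest
# b to any outside point lies on B's boundary
directed_hausdorff <- function(gA, gB) {
  inter <- gA$occupancy & gB$occupancy
  outside <- gA$occupancy & !inter
  if (!any(outside)) return(0)
  pa <- sweep((which(outside, arr.ind = TRUE) - 1) * gA$spacing,
              2, gA$origin, "+")
  pb <- sweep((which(boundary_mask(gB$occupancy), arr.ind = TRUE) - 1) *
                gB$spacing, 2, gB$origin, "+")
  maxmin <- 0
  chunk <- 2000L
  for (s in seq(1, nrow(pa), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pa))
    blk <- pa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(pb^2), "+") -
      2 * blk %*% t(pb)
    maxmin <- max(maxmin, sqrt(max(pmax(apply(d2, 1, min), 0))))
  }
  maxmin
}

#' Hausdorff distance in voxel units
#'
#' Symmetric Hausdorff distance between the occupied-voxel centre sets
#' of two grids, divided by the voxel spacing, i.e. reported in voxel
#' units.
#'
#' @param A,B non-empty [voxel_grid()]s on the same grid.
#' @return non-negative distance in voxels.
#' @export
hausdorff_voxels <- function(A, B) {
  if (!same_grid(A, B)) stop("grid error: grids differ, voxelize on a shared grid")
  if (sum(A$occupancy) == 0 || sum(B$occupancy) == 0)
    stop("undefined-metric error: empty voxel set")
  max(directed_hausdorff(A, B), directed_hausdorff(B, A)) / A$spacing
}

#' Volume of an occupancy grid
#'
#' @param A a [voxel_grid()].
#' @return list with `voxels` (count) and `mm3` (count x spacing^3).
#' @export
volume_report <- function(A) {
  n <- sum(A$occupancy)
  list(voxels = n, mm3 = n * A$spacing^3)
}
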