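#' Synthetic skull-shell phantom specification
#'
#' Parameters of the synthetic phantom used to exercise the whole
#' planning pipeline without clinical data. The phantom is a thin
#' curved shell (outer + inner table) built on an ellipsoid: realistic
#' adult half-calvaria proportions are roughly 70 x 85 x 60 mm
#' semiaxes with a 4 mm table-to-table thickness, and those are the
#' defaults. An `asymmetry` factor away from 1 scales the x-coordinate
#' of the x > 0 half, emulating the left/right asymmetry of real skulls
#' that makes pure mirroring insufficient. A conical wedge of the shell
#' around `defect_axis` (half-angle `defect_angle` degrees) is removed
#' to form the one-sided defect; the removed wedge, closed with a rim
#' wall, is the ground-truth patch the planned implant is scored
#' against.
#'
#' @param outer_semiaxes 3 positive semiaxes (mm). Default
#'   `c(70, 85, 60)`.
#' @param thickness shell thickness (mm), < min semiaxis. Default 4.
#' @param asymmetry x-scale factor applied to the x > 0 half; 1 =
#'   perfectly symmetric. Default 1.
#' @param defect_axis direction of the defect centre (normalised
#'   internally). Default `c(0.8, 0, 0.6)` — a right parietal defect.
#' @param defect_angle cone half-angle in degrees, 0 < angle < 90.
#'   Default 25.
#' @param subdivision icosphere subdivision level, integer >= 2
#'   (20 * 4^s faces per table). Default 3.
#' @param seed integer seed carried into downstream stochastic steps.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semiaxes = c(70, 85, 60), thickness = 4,
                         asymmetry = 1, defect_axis = c(0.8, 0, 0.6),
                         defect_angle = 25, subdivision = 3L, seed = 1L) {
  outer_semiaxes <- as.numeric(outer_semiaxes)
  if (length(outer_semiaxes) != 3 || any(outer_semiaxes <= 0))
    stop("parameter error: outer_semiaxes must be 3 positive lengths")
  if (!(thickness > 0 && thickness < min(outer_semiaxes)))
    stop("parameter error: thickness must be positive and < min semiaxis")
  if (!(asymmetry > 0)) stop("parameter error: asymmetry must be > 0")
  if (!(defect_angle > 0 && defect_angle < 90))
    stop("parameter error: defect_angle must be in (0, 90) degrees")
  subdivision <- as.integer(subdivision)
  if (is.na(subdivision) || subdivision < 2)
    stop("parameter error: subdivision must be an integer >= 2")
  da <- as.numeric(defect_axis)
  if (length(da) != 3 || sqrt(sum(da^2)) < 1e-12)
    stop("parameter error: defect_axis must be a non-zero 3-vector")
  structure(list(outer_semiaxes = outer_semiaxes, thickness = thickness,
                 asymmetry = asymmetry, defect_axis = da / sqrt(sum(da^2)),
                 defect_angle = defect_angle, subdivision = subdivision,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# subdivided icosahedron on the unit sphere; deterministic
icosphere <- function(subdivision) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    nv <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]), sep = "_")
    uk <- unique(ekey)
    mid_of <- match(ekey, uk)
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- nv + mid_of[seq_len(nf)]
    m23 <- nv + mid_of[nf + seq_len(nf)]
    m31 <- nv + mid_of[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

#' Generate a skull phantom with defect and ground truth
#'
#' Builds the intact shell, the defect skull and the ground-truth
#' patch from a [phantom_spec()]. The outer table is the scaled
#' icosphere; the inner table is built by offsetting every outer
#' vertex `thickness` mm against its analytic outward ellipsoid normal,
#' so the shell thickness is locally uniform rather than a scaled copy.
#' Faces whose outward radial direction lies within `defect_angle` of
#' `defect_axis` form the removed wedge; the defect skull keeps its rim
#' open (two boundary loops: outer-table and inner-table rims) while
#' the truth patch closes the wedge with a rim wall into a watertight
#' solid. Construction is fully deterministic: identical specs give
#' identical meshes, bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `defect`, `intact`, `truth` (each a
#'   [triangle_mesh()]) and `defect_solid`, the complement solid
#'   (defect shell closed with the same rim wall) so that
#'   volume(truth) + volume(defect_solid) = volume(intact).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  ico <- icosphere(spec$subdivision)
  ax <- spec$outer_semiaxes
  vout <- sweep(ico$vertices, 2, ax, "*")
  # outward unit normal of the ellipsoid at vout: grad of the implicit form
  nrm <- sweep(vout, 2, ax^2, "/")
  nrm <- nrm / sqrt(rowSums(nrm^2))
  vin <- vout - spec$thickness * nrm
  if (spec$asymmetry != 1) {
    pos <- vout[, 1] > 0
    vout[pos, 1] <- vout[pos, 1] * spec$asymmetry
    pos <- vin[, 1] > 0
    vin[pos, 1] <- vin[pos, 1] * spec$asymmetry
  }
  f <- ico$faces
  nv <- nrow(vout)
  verts <- rbind(vout, vin)
  f_out <- f
  f_in <- f[, c(1, 3, 2), drop = FALSE] + nv   # flipped: outward from shell
  intact <- triangle_mesh(verts, rbind(f_out, f_in))
  # wedge classification on outer-face centroid directions
  ctr <- (vout[f[, 1], ] + vout[f[, 2], ] + vout[f[, 3], ]) / 3
  dirs <- ctr / sqrt(rowSums(ctr^2))
  cosang <- dirs %*% spec$defect_axis
  wedge <- as.vector(cosang) >= cos(spec$defect_angle * pi / 180)
  if (!any(wedge)) stop("defect_angle too small: no faces in the wedge")
  defect <- compact_mesh(triangle_mesh(
    verts, rbind(f_out[!wedge, , drop = FALSE], f_in[!wedge, , drop = FALSE])))
  # rim wall: directed boundary edges of the wedge region on the outer
  # table, each joined to its inner-table copy with two triangles
  wf <- f[wedge, , drop = FALSE]
  de <- rbind(wf[, c(1, 2)], wf[, c(2, 3)], wf[, c(3, 1)])
  dkey <- paste(de[, 1], de[, 2], sep = "_")
  rkey <- paste(de[, 2], de[, 1], sep = "_")
  bnd <- de[!(dkey %in% rkey), , drop = FALSE]
  a <- bnd[, 1]; b <- bnd[, 2]
  wall <- rbind(cbind(b, a, a + nv), cbind(b, a + nv, b + nv))
  truth <- compact_mesh(triangle_mesh(
    verts, rbind(f_out[wedge, , drop = FALSE], f_in[wedge, , drop = FALSE],
                 wall)))
  wall_rev <- wall[, c(1, 3, 2), drop = FALSE]
  defect_solid <- compact_mesh(triangle_mesh(
    verts, rbind(f_out[!wedge, , drop = FALSE], f_in[!wedge, , drop = FALSE],
                 wall_rev)))
  list(defect = defect, intact = intact, truth = truth,
       defect_solid = defect_solid)
}

#' Analytic shell volume of a symmetric phantom
#'
#' (4/3) pi (a b c - a' b' c') for the outer semiaxes and the
#' inner-table semiaxes reduced by the thickness; exact for the
#' limiting smooth ellipsoid the subdivided phantom approaches. Only
#' meaningful for `asymmetry = 1`.
#'
#' @param spec a [phantom_spec()].
#' @return volume in mm^3.
#' @export
phantom_shell_volume <- function(spec) {
  a <- spec$outer_semiaxes
  4 / 3 * pi * (prod(a) - prod(a - spec$thickness))
}
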