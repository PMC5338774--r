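#' Smoothing parameters
#'
#' Parameters of the constrained Laplacian marker smoother: `radius_x`
#' (mm) limits the neighbourhood to markers within that Euclidean
#' radius (inclusive); `border_weight_y` (dimensionless, >= 1) is the
#' weight given to fixed edge ("border") markers in the weighted mean,
#' letting the rim pull harder on nearby surface markers;
#' `iterations` repeats the pass. With `border_weight_y = 1` one pass
#' is the plain Laplacian update: each surface marker moves to the
#' unweighted mean of its same-layer neighbours,
#' x_i <- (1/N) * sum_j x_j, N excluding the marker itself.
#'
#' @param radius_x neighbourhood radius in mm, > 0. Default 6: below
#'   the typical spacing of an evenly spread marker set, so default
#'   smoothing regularises clustered markers without displacing an
#'   already even cloud; raise towards 1.5-2x the marker spacing for a
#'   strong aesthetic smoothing pass (at the cost of some shrinkage).
#' @param border_weight_y weight of edge markers, >= 1. Default 2.
#' @param iterations number of passes, >= 1. Default 1.
#' @return an object of class `smooth_params`.
#' @export
smooth_params <- function(radius_x = 6, border_weight_y = 2, iterations = 1L) {
  if (!is.finite(radius_x) && !is.infinite(radius_x))
    stop("parameter error: radius_x must be more than zero")
  if (!(radius_x > 0))
    stop("parameter error: radius_x must be more than zero")
  if (!is.finite(border_weight_y) || border_weight_y < 1)
    stop("parameter error: border_weight_y must be more than one or equal")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1)
    stop("parameter error: iterations must be >= 1")
  structure(list(radius_x = radius_x, border_weight_y = border_weight_y,
                 iterations = iterations), class = "smooth_params")
}

#' Same-layer neighbours within the smoothing radius
#'
#' Indices j != i of markers in the same layer (outer {0,2} / inner
#' {1,3}) as marker i with Euclidean distance <= `radius_x`
#' (inclusive). Edge markers of the layer are included: they are
#' legitimate, fixed neighbours that anchor the rim.
#'
#' @param markers a [marker_set()].
#' @param i marker index (1-based).
#' @param radius_x radius in mm (may be `Inf`).
#' @return integer vector of neighbour indices.
#' @export
neighbors_within_radius <- function(markers, i, radius_x) {
  n <- length(markers)
  if (i < 1 || i > n) stop("marker index out of range")
  same <- marker_layer(markers) == marker_layer(markers)[i]
  d2 <- rowSums(sweep(markers$positions, 2, markers$positions[i, ])^2)
  which(same & d2 <= radius_x^2 & seq_len(n) != i)
}

#' Constrained Laplacian smoothing of the marker cloud
#'
#' One pass repositions every surface marker (types 2, 3)
#' simultaneously (Jacobi update) to the weighted mean of its
#' same-layer neighbours within `radius_x`, with weight
#' `border_weight_y` for edge markers and 1 otherwise:
#' x_i <- sum_j w_j x_j / sum_j w_j. Edge markers (types 0, 1) are
#' "true" markers, already fixed on the defect rim by the user, and
#' never move; they anchor the implant to the bone and counteract the
#' shrinkage any Laplacian smoother causes. A surface marker with no
#' neighbour in range is left unchanged. Marker order, types and
#' layers are preserved.
#'
#' The simultaneous update makes the result independent of marker
#' order; with all weights 1 the update is the classic x_i = (1/N)
#' sum_j x_j over the N adjacent (neighbouring) markers, the marker
#' itself excluded.
#'
#' @param markers a [marker_set()] with at least 3 markers (fewer and
#'   the operation is dismissed).
#' @param params a [smooth_params()].
#' @return the smoothed [marker_set()].
#' @export
smooth_markers <- function(markers, params = smooth_params()) {
  if (!inherits(params, "smooth_params"))
    params <- do.call(smooth_params, as.list(params))
  if (length(markers) < 3)
    stop("smoothing dismissed: less than three markers")
  pos <- markers$positions
  types <- markers$types
  layer <- marker_layer(types)
  border <- is_border_marker(types)
  w <- ifelse(border, params$border_weight_y, 1)
  movable <- which(!border)
  r2 <- params$radius_x^2
  for (it in seq_len(params$iterations)) {
    newpos <- pos
    for (i in movable) {
      d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
      nb <- layer == layer[i] & d2 <= r2
      nb[i] <- FALSE
      if (!any(nb)) next
      ww <- w[nb]
      newpos[i, ] <- colSums(pos[nb, , drop = FALSE] * ww) / sum(ww)
    }
    pos <- newpos
  }
  marker_set(pos, types)
}

#' Laplacian roughness of the surface markers
#'
#' Diagnostic used to compare unsmoothed and smoothed plans: the mean
#' squared distance of each surface marker to the (unweighted) mean of
#' its same-layer neighbours within `radius_x` — the discrete Laplacian
#' energy of the marker cloud. Smoothing drives it down; edge markers
#' contribute as neighbours but not as terms.
#'
#' @param markers a [marker_set()].
#' @param radius_x neighbourhood radius in mm.
#' @return non-negative scalar (mm^2); `NA` if no surface marker has
#'   neighbours.
#' @export
marker_roughness <- function(markers, radius_x = 12) {
  layer <- marker_layer(markers)
  border <- is_border_marker(markers)
  pos <- markers$positions
  terms <- c()
  for (i in which(!border)) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    nb <- layer == layer[i] & d2 <= radius_x^2
    nb[i] <- FALSE
    if (!any(nb)) next
    mu <- colMeans(pos[nb, , drop = FALSE])
    terms <- c(terms, sum((pos[i, ] - mu)^2))
  }
  if (length(terms) == 0) return(NA_real_)
  mean(terms)
}
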