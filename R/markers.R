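#' Typed landmark markers
#'
#' A `marker_set` holds the ordered, typed 3D landmarks that drive
#' implant construction. Marker types follow the planning convention
#' 0 = outer edge, 1 = inner edge, 2 = outer surface, 3 = inner surface.
#' Edge markers (types 0, 1) sit on the defect rim and stay fixed during
#' smoothing ("border" markers); surface markers (2, 3) sample the
#' mirrored template. Types 0 and 2 form the OUTER layer, 1 and 3 the
#' INNER layer; smoothing neighbourhoods never cross layers.
#'
#' @param positions n x 3 numeric matrix (mm).
#' @param types integer vector in 0..3, one per marker.
#' @return an object of class `marker_set` with elements `positions`
#'   and `types`.
#' @export
marker_set <- function(positions, types) {
  positions <- as_point_matrix(positions, "positions")
  types <- as.integer(types)
  if (nrow(positions) != length(types))
    stop("positions and types must have the same length")
  if (length(types) && (any(is.na(types)) | any(types < 0L | types > 3L)))
    stop("marker type out of range: types must be integers in 0..3")
  if (any(!is.finite(positions))) stop("marker positions must be finite")
  structure(list(positions = positions, types = types), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  tt <- tabulate(x$types + 1L, nbins = 4L)
  cat(sprintf(paste0("<marker_set> %d markers ",
                     "(outer edge %d, inner edge %d, ",
                     "outer surface %d, inner surface %d)\n"),
              length(x$types), tt[1], tt[2], tt[3], tt[4]))
  invisible(x)
}

#' @export
length.marker_set <- function(x) length(x$types)

#' Marker layer and border classification
#'
#' `marker_layer()` maps types to `"outer"` ({0, 2}) or `"inner"`
#' ({1, 3}); `is_border_marker()` flags edge markers (types 0, 1),
#' which are fixed in position during smoothing.
#'
#' @param x a [marker_set()] or an integer type vector.
#' @return character / logical vector, one entry per marker.
#' @export
marker_layer <- function(x) {
  t <- if (inherits(x, "marker_set")) x$types else as.integer(x)
  ifelse(t %in% c(0L, 2L), "outer", "inner")
}

#' @rdname marker_layer
#' @export
is_border_marker <- function(x) {
  t <- if (inherits(x, "marker_set")) x$types else as.integer(x)
  t %in% c(0L, 1L)
}

#' Read and write marker files
#'
#' The canonical marker file is CSV with header `x,y,z,type` (decimal
#' point, UTF-8, one marker per line); a JSON variant stores a list of
#' `{x, y, z, type}` objects. Positions round-trip losslessly (printed
#' with 17 significant digits) and order is preserved, so
#' save -> load -> save is byte-identical.
#'
#' @param path file path; format chosen by extension (`.json` = JSON,
#'   anything else CSV).
#' @return `read_markers()` a [marker_set()]; `write_markers()` `path`
#'   invisibly.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path)
    if (length(rec) == 0 || NROW(rec) == 0)
      return(marker_set(matrix(numeric(0), ncol = 3), integer(0)))
    if (!all(c("x", "y", "z", "type") %in% names(rec)))
      stop("marker format error: JSON records need fields x, y, z, type")
    return(marker_set(cbind(rec$x, rec$y, rec$z), rec$type))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("marker format error: empty file")
  if (trimws(lines[1]) != "x,y,z,type")
    stop("marker format error: expected header 'x,y,z,type'")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0)
    return(marker_set(matrix(numeric(0), ncol = 3), integer(0)))
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    vals <- suppressWarnings(as.numeric(p))
    if (length(p) != 4L || any(is.na(vals)))
      stop(sprintf("marker format error at line %d: '%s'", i + 1L, body[i]))
    ty <- vals[4]
    if (ty != round(ty) || ty < 0 || ty > 3)
      stop(sprintf("marker format error at line %d: type %s out of range 0..3",
                   i + 1L, p[4]))
  }
  num <- matrix(as.numeric(unlist(parts)), ncol = 4L, byrow = TRUE)
  marker_set(num[, 1:3, drop = FALSE], num[, 4])
}

#' @rdname read_markers
#' @param markers a non-empty [marker_set()].
#' @export
write_markers <- function(markers, path) {
  if (length(markers) == 0) stop("refusing to save an empty marker set")
  p <- markers$positions
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                     type = markers$types)
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    rows <- sprintf("%.17g,%.17g,%.17g,%d",
                    p[, 1], p[, 2], p[, 3], markers$types)
    writeLines(c("x,y,z,type", rows), path)
  }
  invisible(path)
}

#' Place edge markers along a defect rim
#'
#' Headless stand-in for clicking markers "along the edge of the
#' defect": samples `n` arc-length-uniform points on the closed
#' polygonal rim loop, starting at the loop's first vertex. Sample k
#' sits at arc length k * P / n (P = rim perimeter), so for n equal to
#' the loop's vertex count on an equilateral loop the original vertices
#' are returned.
#'
#' @param mesh the defect [triangle_mesh()] the loop lives on.
#' @param loop integer vector of vertex indices forming a closed loop
#'   (as returned by [boundary_loops()]), length >= 3.
#' @param n number of markers, >= 3.
#' @param mtype 0 (outer edge) or 1 (inner edge).
#' @return a [marker_set()] of `n` edge markers.
#' @export
place_edge_markers <- function(mesh, loop, n, mtype = 0L) {
  if (length(loop) < 3) stop("loop must have >= 3 vertices")
  if (n < 3) stop("parameter error: need n >= 3 edge markers")
  mtype <- as.integer(mtype)
  if (!mtype %in% c(0L, 1L)) stop("edge markers must have type 0 or 1")
  pts <- mesh$vertices[loop, , drop = FALSE]
  seg <- rbind(pts, pts[1, , drop = FALSE])
  seglen <- sqrt(rowSums(diff(seg)^2))
  P <- sum(seglen)
  cum <- c(0, cumsum(seglen))          # arc length at each loop vertex
  s <- (seq_len(n) - 1) * P / n
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seglen))
  frac <- (s - cum[idx]) / seglen[idx]
  a <- seg[idx, , drop = FALSE]
  b <- seg[idx + 1L, , drop = FALSE]
  marker_set(a + frac * (b - a), rep(mtype, n))
}

#' Place surface markers on the mirrored template
#'
#' Headless stand-in for clicking markers on the mirrored-skull
#' template: samples `n` points uniformly by area (seeded) from template
#' faces whose centroids lie within `region_radius` of `region_center`,
#' then moves each point `inward_offset` mm against the local outward
#' face normal. Outer-surface markers (type 2) use offset 0; inner-
#' surface markers (type 3) use the shell thickness, reconstructing an
#' inner table that the mirrored STL may not resolve. Calling twice with
#' the same seed gives the same base sample, so paired outer/inner
#' marker columns can be produced by two calls differing only in
#' `mtype`/`inward_offset`.
#'
#' @param template a non-empty [triangle_mesh()] (the mirrored skull).
#' @param region_center 3-vector (mm), centre of the defect region.
#' @param region_radius positive radius (mm) selecting candidate faces.
#' @param n number of markers, >= 1.
#' @param mtype 2 (outer surface) or 3 (inner surface).
#' @param inward_offset offset along the inward normal (mm); default 0
#'   for type 2 and 4 (the default shell thickness) for type 3.
#' @param seed integer seed for the area-weighted sampling.
#' @return a [marker_set()] of `n` surface markers.
#' @export
place_surface_markers <- function(template, region_center, region_radius, n,
                                  mtype = 2L,
                                  inward_offset = if (mtype == 3L) 4 else 0,
                                  seed = 1L) {
  if (nrow(template$faces) == 0) stop("template mesh is empty")
  if (n < 1) stop("parameter error: need n >= 1 surface markers")
  if (region_radius <= 0) stop("parameter error: region_radius must be > 0")
  mtype <- as.integer(mtype)
  if (!mtype %in% c(2L, 3L)) stop("surface markers must have type 2 or 3")
  fc <- face_corners(template)
  centroids <- (fc$a + fc$b + fc$c) / 3
  d2 <- rowSums(sweep(centroids, 2, as.numeric(region_center))^2)
  cand <- which(d2 <= region_radius^2)
  if (length(cand) == 0)
    stop("empty-region error: no template faces within region_radius")
  areas <- face_areas(template)[cand]
  normals <- face_normals(template)
  pts <- with_seed(seed, {
    fi <- cand[sample.int(length(cand), n, replace = TRUE,
                          prob = areas / sum(areas))]
    # uniform point in triangle via the sqrt warp
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    a <- fc$a[fi, , drop = FALSE]
    b <- fc$b[fi, , drop = FALSE]
    cc <- fc$c[fi, , drop = FALSE]
    p <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    p - inward_offset * normals[fi, , drop = FALSE]
  })
  marker_set(pts, rep(mtype, n))
}

# evaluate expr with a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
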