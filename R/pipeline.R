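#' Implant planning configuration
#'
#' Declarative configuration for the end-to-end planner
#' [plan_implant()], mirroring the three workflow blocks: dataset
#' preparation (load, centre, mirror, optional rigid registration),
#' marker setting (from a file or placed automatically), and final
#' adjustments (Laplacian smoothing, Delaunay triangulation with alpha
#' filtering, STL export). All interactive refinement collapses into
#' this config: to refine a plan, edit the config and re-run.
#'
#' @param input path to the defect-skull STL, or a [triangle_mesh()].
#' @param mirror_plane a [plane3()]; default midsagittal x = 0 after
#'   centring. May also be a list of 3 landmark points (each a
#'   3-vector) fitted via [plane_from_landmarks()].
#' @param register_landmarks optional list with `source` and `target`
#'   n x 3 landmark matrices; when given, the mirrored template is
#'   rigidly registered onto the original skull.
#' @param markers path to a marker file, a [marker_set()], or `NULL`
#'   for automatic placement.
#' @param n_edge total number of edge markers (split between the outer
#'   and inner rim loops). Default 24.
#' @param n_surface number of surface markers per layer. Default 40.
#' @param thickness shell thickness in mm used to offset inner-surface
#'   markers. Default 4.
#' @param region_scale automatic placement samples outward-facing
#'   template faces within `region_scale` x (mean rim radius) of the
#'   rim centroid. Default 1.
#' @param smooth logical; `FALSE` skips the smoothing stage entirely
#'   (the "unsmoothed" comparison arm). Default `TRUE`.
#' @param smooth_params a [smooth_params()].
#' @param alpha circumradius threshold in mm for [alpha_filter()],
#'   `"auto"` or `NULL` for none. `"auto"` picks the smallest alpha
#'   whose kept tetrahedra use every marker and bound a closed
#'   (watertight) surface — enough to solidify the implant shell while
#'   still excluding the hull-spanning tetrahedra that would fill the
#'   implant's concave inner side. Default `"auto"`.
#' @param dedupe_tol marker deduplication tolerance (mm). Default 1e-6.
#' @param output_stl optional path for the implant STL.
#' @param output_report optional path for the JSON plan report.
#' @param seed integer; single top-level seed fanned out to all
#'   stochastic substeps (surface sampling). Default 1.
#' @return an object of class `plan_config`.
#' @export
plan_config <- function(input, mirror_plane = plane3(),
                        register_landmarks = NULL, markers = NULL,
                        n_edge = 24L, n_surface = 40L, thickness = 4,
                        region_scale = 1, smooth = TRUE,
                        smooth_params = cranioplan::smooth_params(),
                        alpha = "auto", dedupe_tol = 1e-6,
                        output_stl = NULL, output_report = NULL, seed = 1L) {
  if (is.character(input) && !file.exists(input))
    stop("config error: input STL does not exist: ", input)
  if (is.list(mirror_plane) && !inherits(mirror_plane, "plane3")) {
    if (length(mirror_plane) == 3)
      mirror_plane <- do.call(plane_from_landmarks, mirror_plane)
    else stop("config error: mirror_plane must be a plane3 or 3 landmarks")
  }
  if (is.character(markers) && !file.exists(markers))
    stop("config error: marker file does not exist: ", markers)
  structure(list(input = input, mirror_plane = mirror_plane,
                 register_landmarks = register_landmarks, markers = markers,
                 n_edge = as.integer(n_edge),
                 n_surface = as.integer(n_surface),
                 thickness = thickness,
                 region_scale = region_scale,
                 smooth = isTRUE(smooth), smooth_params = smooth_params,
                 alpha = alpha, dedupe_tol = dedupe_tol,
                 output_stl = output_stl, output_report = output_report,
                 seed = as.integer(seed)),
            class = "plan_config")
}

stage_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

run_stage <- function(report, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fun(), error = function(e) stage_fail(name, e))
  report$stages[[name]] <- c(list(seconds = round(
    proc.time()[["elapsed"]] - t0, 3)), attr(out, "stage_info"))
  attr(out, "stage_info") <- NULL
  list(value = out, report = report)
}

stage_info <- function(x, ...) {
  attr(x, "stage_info") <- list(...)
  x
}

#' Plan a cranial implant end to end
#'
#' Runs the full pipeline: load the defect skull, centre it, duplicate
#' and mirror it across the midsagittal plane to obtain the curvature
#' template, optionally register the template to the original, obtain
#' markers (from file or placed automatically on the defect rim and the
#' template), smooth the marker cloud, tetrahedralize it, alpha-filter,
#' extract the boundary surface and write the implant STL plus a JSON
#' report. Deterministic given the config seed: two runs with the same
#' config produce byte-identical STL output.
#'
#' Automatic marker placement finds the defect rim loops
#' ([boundary_loops()]), places half the edge markers on the longest
#' (outer-table) rim as type 0 and half on the second rim as type 1,
#' and samples `n_surface` template points for the outer-surface layer
#' (type 2) plus the same sample offset inward by `thickness` for the
#' inner-surface layer (type 3), so the two layers are paired.
#'
#' @param config a [plan_config()].
#' @return an object of class `implant_plan`: list with `implant`
#'   (a [triangle_mesh()]), `markers` (smoothed [marker_set()]),
#'   `markers_raw` (before smoothing), `tetra` (filtered `tet_mesh`)
#'   and `report` (stage-by-stage counts, parameters, timings, output
#'   digests).
#' @export
plan_implant <- function(config) {
  stopifnot(inherits(config, "plan_config"))
  report <- list(stages = list(),
                 parameters = list(
                   n_edge = config$n_edge, n_surface = config$n_surface,
                   thickness = config$thickness,
                   smooth = config$smooth,
                   radius_x = config$smooth_params$radius_x,
                   border_weight_y = config$smooth_params$border_weight_y,
                   iterations = config$smooth_params$iterations,
                   alpha = if (is.numeric(config$alpha)) config$alpha
                           else as.character(config$alpha %||% "none"),
                   dedupe_tol = config$dedupe_tol, seed = config$seed))
  on_fail_cleanup <- function() {
    for (p in c(config$output_stl, config$output_report))
      if (!is.null(p) && file.exists(p)) unlink(p)
  }
  res <- tryCatch(
    plan_implant_stages(config, report),
    error = function(e) { on_fail_cleanup(); stop(e) })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plan_implant_stages <- function(config, report) {
  st <- run_stage(report, "load", function() {
    m <- if (inherits(config$input, "triangle_mesh")) config$input
         else read_stl(config$input)
    stage_info(m, vertices = nrow(m$vertices), faces = nrow(m$faces))
  })
  skull <- st$value; report <- st$report

  st <- run_stage(report, "center", function() {
    ctr <- center_mesh(skull)
    stage_info(ctr$mesh, offset = round(ctr$offset, 6))
  })
  skull <- st$value; report <- st$report

  st <- run_stage(report, "mirror", function() {
    stage_info(reflect_mesh(skull, config$mirror_plane),
               plane_point = config$mirror_plane$point,
               plane_normal = config$mirror_plane$normal)
  })
  template <- st$value; report <- st$report

  if (!is.null(config$register_landmarks)) {
    st <- run_stage(report, "register", function() {
      tr <- rigid_register(config$register_landmarks$source,
                           config$register_landmarks$target)
      stage_info(apply_rigid(tr, template),
                 translation = round(tr$translation, 4))
    })
    template <- st$value; report <- st$report
  }

  st <- run_stage(report, "markers", function() {
    mk <- obtain_markers(config, skull, template)
    stage_info(mk, count = length(mk),
               edge = sum(is_border_marker(mk)),
               surface = sum(!is_border_marker(mk)))
  })
  markers_raw <- st$value; report <- st$report

  if (config$smooth) {
    st <- run_stage(report, "smooth", function() {
      sm <- smooth_markers(markers_raw, config$smooth_params)
      stage_info(sm, max_displacement = round(max(sqrt(rowSums(
        (sm$positions - markers_raw$positions)^2))), 4))
    })
    markers <- st$value; report <- st$report
  } else {
    markers <- markers_raw
    report$stages[["smooth"]] <- list(skipped = TRUE)
  }

  st <- run_stage(report, "triangulate", function() {
    tm <- delaunay_tetrahedralize(markers$positions, config$dedupe_tol)
    alpha <- config$alpha
    if (identical(alpha, "auto")) alpha <- auto_alpha(tm)
    tm2 <- alpha_filter(tm, alpha)
    stage_info(tm2, tets_total = nrow(tm$tets), tets_kept = nrow(tm2$tets),
               alpha_mm = if (is.null(alpha)) NA_real_ else round(alpha, 4))
  })
  tetra <- st$value; report <- st$report

  st <- run_stage(report, "surface", function() {
    s <- extract_boundary_surface(tetra)
    stage_info(s, vertices = nrow(s$vertices), faces = nrow(s$faces),
               watertight = is_watertight(s))
  })
  implant <- st$value; report <- st$report

  digests <- list()
  if (!is.null(config$output_stl)) {
    write_stl(implant, config$output_stl, "binary")
    digests$implant_stl <- unname(tools::md5sum(config$output_stl))
  }
  report$digests <- digests
  out <- structure(list(implant = implant, markers = markers,
                        markers_raw = markers_raw, tetra = tetra,
                        report = report),
                   class = "implant_plan")
  if (!is.null(config$output_report))
    jsonlite::write_json(report, config$output_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  out
}

# Automatic alpha: find the smallest alpha whose kept complex spans
# every marker and has a closed boundary surface (the threshold where
# the implant first solidifies), then take the smallest closed alpha at
# least 1.5x that threshold. At the bare threshold the boundary still
# detours through local dents where single tetrahedra are missing; the
# 1.5 safety margin closes those while staying far below the
# circumradii of the hull-spanning tetrahedra that would fill the
# implant's concave inner side (those are on the order of the skull's
# curvature radius, several times the solidification threshold).
auto_alpha <- function(tm, margin = 1.5) {
  cand <- sort(unique(tm$circumradius[is.finite(tm$circumradius)]))
  npts <- nrow(tm$points)
  m <- nrow(tm$tets)
  faces <- all_tet_faces(tm$tets)
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  fkey <- paste(lo, mid, hi, sep = "_")
  owner <- rep(seq_len(m), times = 4L)
  # skip straight to the smallest alpha using all markers (monotone)
  covlo <- 1L; covhi <- length(cand)
  covers <- function(k) {
    length(unique(as.vector(tm$tets[tm$circumradius <= cand[k], ]))) == npts
  }
  while (covlo < covhi) {
    mid_k <- (covlo + covhi) %/% 2L
    if (covers(mid_k)) covhi <- mid_k else covlo <- mid_k + 1L
  }
  closed_at <- function(k) {
    keep <- tm$circumradius <= cand[k]
    fsel <- keep[owner]
    kk <- fkey[fsel]
    bnd <- fsel
    bnd[fsel] <- kk %in% names(which(table(kk) == 1L))
    bf <- faces[bnd, , drop = FALSE]
    e <- rbind(bf[, 1:2], bf[, 2:3], bf[, c(3, 1)])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
    all(table(ek) == 2L)
  }
  kmin <- NA_integer_
  for (k in covlo:length(cand)) {
    if (closed_at(k)) { kmin <- k; break }
  }
  if (is.na(kmin)) return(cand[length(cand)])
  target <- margin * cand[kmin]
  for (k in seq(kmin, length(cand))) {
    if (cand[k] >= target && closed_at(k)) return(cand[k])
  }
  cand[kmin]
}

obtain_markers <- function(config, skull, template) {
  if (inherits(config$markers, "marker_set")) return(config$markers)
  if (is.character(config$markers)) return(read_markers(config$markers))
  loops <- boundary_loops(skull)
  if (length(loops) == 0)
    stop("automatic placement needs a defect rim, but the mesh is closed")
  n_half <- max(3L, config$n_edge %/% 2L)
  edge_out <- place_edge_markers(skull, loops[[1]], n_half, 0L)
  # inner-rim markers are staggered half a step relative to the outer
  # ring (sampled at double density, odd samples kept) so the two rim
  # polygons interleave and their chord cuts do not line up
  edge_in <- if (length(loops) >= 2) {
    dense <- place_edge_markers(skull, loops[[2]], 2L * n_half, 1L)
    keep <- seq(2L, 2L * n_half, by = 2L)
    marker_set(dense$positions[keep, , drop = FALSE], dense$types[keep])
  } else marker_set(matrix(numeric(0), ncol = 3), integer(0))
  rim <- rbind(edge_out$positions, edge_in$positions)
  center <- colMeans(rim)
  radius <- config$region_scale * max(sqrt(rowSums(sweep(rim, 2, center)^2)))
  # the template is a two-layer shell; surface markers belong on the
  # outer table, i.e. on faces whose outward normal points away from
  # the head centre (the mesh is centred by the preparation stage).
  # Restrict further to faces inside the rim polygon (per direction
  # from the rim centroid, nearer than the rim itself), so the sampled
  # region is the defect, not a sphere that under- or over-shoots an
  # elongated rim.
  outer_tab <- faces_inside_rim(outward_faces(template),
                                edge_out$positions, center,
                                config$region_scale)
  # emulate a user spreading clicks evenly over the defect region:
  # draw a larger seeded area-uniform pool, then keep the n_surface
  # points that are farthest from the rim markers and from each other
  # (greedy farthest-point thinning). The outer and inner pools share
  # the seed, so base points pair up and the layers stay parallel.
  pool_n <- 8L * config$n_surface
  pool_out <- place_surface_markers(outer_tab, center, radius, pool_n,
                                    2L, 0, seed = config$seed)
  pool_in <- place_surface_markers(outer_tab, center, radius, pool_n,
                                   3L, config$thickness, seed = config$seed)
  sel <- farthest_point_select(pool_out$positions, config$n_surface)
  surf_out <- marker_set(pool_out$positions[sel, , drop = FALSE],
                         pool_out$types[sel])
  surf_in <- marker_set(pool_in$positions[sel, , drop = FALSE],
                        pool_in$types[sel])
  marker_set(rbind(edge_out$positions, edge_in$positions,
                   surf_out$positions, surf_in$positions),
             c(edge_out$types, edge_in$types, surf_out$types, surf_in$types))
}

# faces whose centroid direction from the rim centroid points at the
# rim polygon from inside: distance along that direction at most
# region_scale times the distance of the angularly-nearest rim marker
faces_inside_rim <- function(mesh, rim, center, region_scale = 1) {
  if (nrow(mesh$faces) == 0) return(mesh)
  fc <- face_corners(mesh)
  ctr <- (fc$a + fc$b + fc$c) / 3
  u <- sweep(ctr, 2, center)
  un <- sqrt(rowSums(u^2)); un[un == 0] <- 1
  v <- sweep(rim, 2, center)
  vn <- sqrt(rowSums(v^2))
  cosang <- (u %*% t(v)) / (un %o% vn)
  nearest <- max.col(cosang)
  keep <- un <= region_scale * vn[nearest]
  triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
}

# greedy farthest-point subset: repeatedly take the pool point with the
# largest distance to everything selected so far (anchors included), a
# deterministic stand-in for how a user spaces manual clicks
farthest_point_select <- function(pool, k, anchors = NULL) {
  n <- nrow(pool)
  if (k >= n) return(seq_len(n))
  if (!is.null(anchors) && nrow(anchors) > 0) {
    d2 <- vapply(seq_len(n), function(i) {
      min(rowSums(sweep(anchors, 2, pool[i, ])^2))
    }, 1.0)
  } else {
    d2 <- rep(Inf, n)
    d2[1] <- 0   # seed the selection with the first pool point
  }
  sel <- integer(0)
  for (j in seq_len(k)) {
    i <- which.max(d2)
    sel <- c(sel, i)
    di <- rowSums(sweep(pool, 2, pool[i, ])^2)
    d2 <- pmin(d2, di)
  }
  sort(sel)
}

#' @export
print.implant_plan <- function(x, ...) {
  cat("<implant_plan>\n")
  cat(sprintf("  markers: %d (%d fixed edge)\n", length(x$markers),
              sum(is_border_marker(x$markers))))
  cat(sprintf("  tetrahedra kept: %d\n", nrow(x$tetra$tets)))
  cat(sprintf("  implant surface: %d faces, watertight: %s\n",
              nrow(x$implant$faces), is_watertight(x$implant)))
  cat(sprintf("  implant volume: %.1f mm^3\n", mesh_volume(x$implant)))
  invisible(x)
}

#' @export
summary.implant_plan <- function(object, ...) {
  cat("Implant plan summary\n")
  cat("====================\n")
  for (nm in names(object$report$stages)) {
    s <- object$report$stages[[nm]]
    kv <- paste(names(s), vapply(s, function(v) paste(format(v), collapse = ","),
                                 ""), sep = "=", collapse = ", ")
    cat(sprintf("  %-12s %s\n", nm, kv))
  }
  invisible(object)
}
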