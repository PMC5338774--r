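test_that("marker CSV round trip is lossless and byte-identical", {
  set.seed(42)
  mk <- marker_set(matrix(runif(30, -50, 50), 10, 3),
                   c(0, 0, 1, 1, 2, 2, 2, 3, 3, 3))
  f <- tempfile(fileext = ".csv")
  write_markers(mk, f)
  mk2 <- read_markers(f)
  expect_identical(mk2$positions, mk$positions)
  expect_identical(mk2$types, mk$types)
  # save -> load -> save: byte identical
  f2 <- tempfile(fileext = ".csv")
  write_markers(mk2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("marker JSON round trip preserves positions and types", {
  mk <- marker_set(rbind(c(1.25, -2.5, 3.75), c(0.1, 0.2, 0.3)), c(0, 2))
  f <- tempfile(fileext = ".json")
  write_markers(mk, f)
  mk2 <- read_markers(f)
  expect_equal(mk2$positions, mk$positions)
  expect_identical(mk2$types, mk$types)
})

test_that("malformed marker files give format errors with line numbers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,type", "0.0,0.0,0.0,7"), f)
  expect_error(read_markers(f), "line 2.*out of range")
  writeLines(c("x,y,z,type", "1,2,3,0", "a,b,c,1"), f)
  expect_error(read_markers(f), "line 3")
  writeLines("x,y,z,type", f)
  expect_length(read_markers(f), 0)   # header-only file is a valid empty set
  writeLines("wrong,header", f)
  expect_error(read_markers(f), "header")
})

test_that("layer and border derivations follow the type convention", {
  mk <- marker_set(matrix(0, 4, 3), 0:3)
  expect_equal(marker_layer(mk), c("outer", "inner", "outer", "inner"))
  expect_equal(is_border_marker(mk), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(marker_set(matrix(0, 1, 3), 7), "out of range")
})

test_that("edge markers resample the rim uniformly by arc length", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  loop <- boundary_loops(sq)[[1]]
  # unit square, n = 4: exactly the 4 corners (perimeter 4, s = 0,1,2,3)
  mk <- place_edge_markers(sq, loop, 4, 0L)
  sort_rows <- function(x) x[order(x[, 1], x[, 2], x[, 3]), ]
  expect_equal(sort_rows(mk$positions), sort_rows(sq$vertices),
               tolerance = 1e-12)
  # k equally spaced loop vertices, n = k: the original vertices
  expect_equal(mk$positions[1, ], sq$vertices[loop[1], ])
  # regular hexagon, n = 3 (minimum): samples at s = 0, P/3, 2P/3
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  hexv <- cbind(cos(ang), sin(ang), 0)
  hexm <- triangle_mesh(rbind(hexv, c(0, 0, 0)),
                        cbind(1:6, c(2:6, 1), 7))
  hl <- boundary_loops(hexm)[[1]]
  mk3 <- place_edge_markers(hexm, hl, 3, 1L)
  expect_equal(nrow(mk3$positions), 3)
  # antipodal property at s = 0 and s = P/2 for n = 6 every other sample
  mk6 <- place_edge_markers(hexm, hl, 6, 0L)
  expect_equal(mk6$positions[1, ] + mk6$positions[4, ], c(0, 0, 0),
               tolerance = 1e-9)
  expect_error(place_edge_markers(hexm, hl, 2, 0L), "n >= 3")
})

test_that("edge markers lie exactly on the rim polyline", {
  set.seed(5)
  # irregular planar loop
  ang <- sort(runif(8, 0, 2 * pi))
  v <- cbind((1 + runif(8)) * cos(ang), (1 + runif(8)) * sin(ang), 0)
  m <- triangle_mesh(rbind(v, c(0, 0, 0)), cbind(1:8, c(2:8, 1), 9))
  loop <- boundary_loops(m)[[1]]
  mk <- place_edge_markers(m, loop, 7, 0L)
  pts <- m$vertices[loop, , drop = FALSE]
  seg_a <- pts
  seg_b <- pts[c(2:nrow(pts), 1), , drop = FALSE]
  for (i in seq_len(7)) {
    p <- mk$positions[i, ]
    d <- vapply(seq_len(nrow(seg_a)), function(s) {
      ab <- seg_b[s, ] - seg_a[s, ]
      t <- max(0, min(1, sum((p - seg_a[s, ]) * ab) / sum(ab^2)))
      sqrt(sum((seg_a[s, ] + t * ab - p)^2))
    }, 1.0)
    expect_lt(min(d), 1e-9)
  }
})

test_that("surface markers sample the template with exact counts", {
  sph <- generate_phantom(small_phantom_spec())$intact
  outer <- outward_faces(center_mesh(sph)$mesh)
  mk <- place_surface_markers(outer, c(0, 0, 22), 15, 5, 2L, 0, seed = 9)
  expect_length(mk, 5)
  expect_true(all(mk$types == 2L))
  # offset 0: points lie on the template surface (barycentric samples)
  for (i in 1:5) {
    d2f <- min(point_to_mesh_distance(mk$positions[i, ], outer))
    expect_lt(d2f, 1e-6)
  }
})

test_that("inner-surface markers sit one offset below a sphere template", {
  # analytic sphere of radius 10: offset 2 puts samples at radius 8
  ico <- generate_phantom(
    phantom_spec(outer_semiaxes = c(10, 10, 10), thickness = 2,
                 defect_angle = 30, subdivision = 3))$intact
  outer <- outward_faces(ico)
  mk <- place_surface_markers(outer, c(0, 0, 10), 6, 8, 3L, 2, seed = 4)
  r <- sqrt(rowSums(mk$positions^2))
  # faceted sphere: vertices at 10, face centres slightly less
  expect_true(all(abs(r - 8) < 0.05))
})

test_that("surface sampling is deterministic given the seed", {
  sph <- generate_phantom(small_phantom_spec())$intact
  outer <- outward_faces(sph)
  a <- place_surface_markers(outer, c(0, 0, 22), 15, 10, 2L, 0, seed = 33)
  b <- place_surface_markers(outer, c(0, 0, 22), 15, 10, 2L, 0, seed = 33)
  expect_identical(a$positions, b$positions)
  c_ <- place_surface_markers(outer, c(0, 0, 22), 15, 10, 2L, 0, seed = 34)
  expect_false(identical(a$positions, c_$positions))
})

test_that("empty sampling region raises an error", {
  sph <- generate_phantom(small_phantom_spec())$intact
  expect_error(place_surface_markers(sph, c(500, 0, 0), 5, 3, 2L, 0, seed = 1),
               "empty-region")
})
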