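test_that("centering puts the bbox centre at the origin and is invertible", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(2, 2, 2), c(2, 0, 0)),
                     rbind(c(1, 2, 3)))
  res <- center_mesh(m)
  expect_equal(res$offset, c(1, 1, 1))
  expect_equal(res$mesh$vertices[1, ], c(-1, -1, -1))
  expect_equal(res$mesh$vertices[2, ], c(1, 1, 1))
  # idempotence on an already-centred mesh
  res2 <- center_mesh(res$mesh)
  expect_equal(res2$offset, c(0, 0, 0))
  expect_equal(res2$mesh$vertices, res$mesh$vertices)
  # general mesh: bbox min = -bbox max per axis afterwards
  set.seed(7)
  m3 <- triangle_mesh(random_points(20, 7), rbind(c(1, 2, 3), c(4, 5, 6)))
  bb <- apply(center_mesh(m3)$mesh$vertices, 2, range)
  expect_equal(bb[1, ], -bb[2, ])
})

test_that("reflection across the midsagittal plane is diag(-1,1,1)", {
  p <- rbind(c(1, 2, 3))
  expect_equal(reflect_points(p), rbind(c(-1, 2, 3)))
  # matches the explicit diagonal matrix on a random cloud
  pts <- random_points(25, 11)
  expect_equal(reflect_points(pts), pts %*% diag(c(-1, 1, 1)))
})

test_that("reflection across an offset plane matches the Householder map", {
  # plane through (1,0,0) with normal (1,0,0); hand-computed oracle:
  # translate by -p, apply I - 2nn^T, translate back -> (3,5,7) -> (-1,5,7)
  pl <- plane3(c(1, 0, 0), c(1, 0, 0))
  expect_equal(as.vector(reflect_points(rbind(c(3, 5, 7)), pl)), c(-1, 5, 7))
})

test_that("reflection is an involution and an isometry", {
  set.seed(3)
  pts <- random_points(30, 3)
  for (pl in list(plane3(), plane3(c(1, 2, 3), c(1, 1, -2)),
                  plane3(c(0, -5, 2), c(0.3, -0.4, 0.87)))) {
    twice <- reflect_points(reflect_points(pts, pl), pl)
    expect_equal(twice, pts, tolerance = 1e-9)
    expect_equal(as.matrix(dist(reflect_points(pts, pl))), as.matrix(dist(pts)),
                 tolerance = 1e-9)
  }
  # area preservation and winding flip keep outward orientation
  m <- tetra_mesh()
  r <- reflect_mesh(m, plane3(c(0, 1, 0), c(0, 1, 0)))
  expect_equal(sum(face_areas(r)), sum(face_areas(m)), tolerance = 1e-12)
  expect_equal(mesh_volume(r), mesh_volume(m), tolerance = 1e-9)
})

test_that("clipping keeps, drops and splits-as-drops the right faces", {
  pl <- plane3(c(0, 0, 0.5), c(0, 0, 1))
  m <- cube_mesh()   # z = 0 and z = 1 faces, sides straddle
  clipped <- clip_mesh(m, pl)
  # only the z = 1 cap survives: sides cross the plane, bottom is below
  expect_equal(nrow(clipped$faces), 2)
  expect_true(all(m$vertices[clipped$faces, 3] == 1))
  # complementary clip: faces appear in at most one side
  other <- clip_mesh(m, plane3(c(0, 0, 0.5), c(0, 0, -1)))
  key <- function(f) apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  expect_length(intersect(key(clipped$faces), key(other$faces)), 0)
  expect_true(all(c(key(clipped$faces), key(other$faces)) %in% key(m$faces)))
})

test_that("Procrustes registration recovers exact rigid transforms", {
  pts <- random_points(10, 21)
  # pure translation
  tr <- rigid_register(pts, sweep(pts, 2, c(5, 0, 0), "+"))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(5, 0, 0), tolerance = 1e-9)
  # 90 degrees about z
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr2 <- rigid_register(pts, pts %*% t(Rz))
  expect_lt(norm(tr2$rotation - Rz, "F"), 1e-6)
  # identity
  tr3 <- rigid_register(pts, pts)
  expect_equal(tr3$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr3$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("Procrustes recovers random rigid transforms on noiseless pairs", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- random_points(8, seed + 100)
    # random rotation via QR of a random matrix, det forced to +1
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    t0 <- rnorm(3, sd = 10)
    target <- sweep(pts %*% t(q), 2, t0, "+")
    tr <- rigid_register(pts, target)
    expect_lt(norm(tr$rotation - q, "F"), 1e-6)
    expect_lt(sqrt(sum((tr$translation - t0)^2)), 1e-6)
    expect_equal(apply_rigid(tr, pts), target, tolerance = 1e-6)
  }
})

test_that("degenerate registration input errors", {
  expect_error(rigid_register(rbind(c(0, 0, 0), c(1, 1, 1)),
                              rbind(c(0, 0, 0), c(1, 1, 1))), "3 point")
  line <- cbind(1:5, 0, 0)
  expect_error(rigid_register(line, line), "collinear")
})

test_that("boundary loop detection matches enumeration oracles", {
  # closed tetrahedron: no loops
  expect_length(boundary_loops(tetra_mesh()), 0)
  # tetrahedron minus one face: one loop of 3 vertices
  m <- tetra_mesh()
  open3 <- triangle_mesh(m$vertices, m$faces[-4, , drop = FALSE])
  loops <- boundary_loops(open3)
  expect_length(loops, 1)
  expect_length(loops[[1]], 3)
  expect_setequal(loops[[1]], as.vector(m$faces[4, ]))
  # flat square of 2 triangles: one loop of 4 vertices
  loops2 <- boundary_loops(plate_mesh())
  expect_length(loops2, 1)
  expect_length(loops2[[1]], 4)
  # watertight meshes have no loops
  expect_length(boundary_loops(cube_mesh()), 0)
})

test_that("non-manifold edges raise a topology error", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))  # edge 1-2 in 3 faces
  expect_error(boundary_loops(triangle_mesh(v, f)), "non-manifold")
})

test_that("plane constructor normalises and validates", {
  pl <- plane3(c(0, 0, 0), c(2, 0, 0))
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
  expect_error(plane3(c(0, 0, 0), c(0, 0, 0)), "non-zero")
  pl2 <- plane_from_landmarks(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(abs(pl2$normal), c(1, 0, 0))
  expect_error(plane_from_landmarks(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})
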