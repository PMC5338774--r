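test_that("four non-coplanar points give exactly one tetrahedron", {
  tm <- delaunay_tetrahedralize(tetra_mesh()$vertices)
  expect_equal(nrow(tm$tets), 1)
  expect_setequal(as.vector(tm$tets), 1:4)
  expect_gt(min(cranioplan:::tet_signed_volume(tm$points, tm$tets)), 0)
})

test_that("regular tetrahedron plus centroid splits into 4 Delaunay tets", {
  v <- tetra_mesh()$vertices
  pts <- rbind(v, colMeans(v))
  tm <- delaunay_tetrahedralize(pts)
  expect_equal(nrow(tm$tets), 4)
  # each tet = one outer face + the centroid
  expect_true(all(apply(tm$tets, 1, function(t) 5 %in% t)))
  # brute-force empty-circumsphere verification over all 5 points
  assert_delaunay_property(tm)
})

test_that("coplanar or too-few points raise degeneracy errors", {
  flat <- cbind(runif(6), runif(6), 0)
  expect_error(delaunay_tetrahedralize(flat), "coplanar|degenera")
  expect_error(delaunay_tetrahedralize(matrix(rnorm(9), 3, 3)), ">= 4")
  # duplicates collapse below 4 points
  p <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(delaunay_tetrahedralize(p), ">= 4")
})

test_that("random clouds satisfy the empty-circumsphere property", {
  for (seed in 1:8) {
    pts <- random_points(sample(6:10, 1), seed + 300)
    tm <- delaunay_tetrahedralize(pts)
    assert_delaunay_property(tm)
    # union of tets = convex hull: total tet volume vs hull volume
    # via the divergence theorem over the brute-force hull facets
    surf <- extract_boundary_surface(tm)
    expect_equal(sum(cranioplan:::tet_signed_volume(tm$points, tm$tets)),
                 mesh_volume(surf), tolerance = 1e-9)
  }
})

test_that("alpha filtering gates on the regular-tetrahedron circumradius", {
  # edge 1 regular tetrahedron: circumradius sqrt(3/8)
  edge <- sqrt(8)
  v <- tetra_mesh()$vertices / edge      # edge length 1 now
  tm <- delaunay_tetrahedralize(v)
  r_reg <- sqrt(3 / 8)
  expect_equal(tm$circumradius[1], r_reg, tolerance = 1e-9)
  expect_equal(nrow(alpha_filter(tm, r_reg + 1e-9)$tets), 1)
  expect_error(alpha_filter(tm, r_reg - 1e-3), "empty-result")
  # alpha = NULL keeps everything
  expect_equal(nrow(alpha_filter(tm, NULL)$tets), 1)
})

test_that("alpha below the minimum circumradius reports it in the error", {
  pts <- random_points(8, 17)
  tm <- delaunay_tetrahedralize(pts)
  expect_error(alpha_filter(tm, 1e-6), "minimum circumradius")
})

test_that("kept-tet set grows monotonically with alpha", {
  pts <- random_points(12, 55)
  tm <- delaunay_tetrahedralize(pts)
  alphas <- sort(unique(tm$circumradius))
  prev <- 0
  for (a in alphas) {
    k <- nrow(alpha_filter(tm, a + 1e-12)$tets)
    expect_gte(k, prev)
    prev <- k
  }
  expect_equal(prev, nrow(tm$tets))
})

test_that("boundary surface of a single tet has 4 outward triangles", {
  tm <- delaunay_tetrahedralize(tetra_mesh()$vertices)
  surf <- extract_boundary_surface(tm)
  expect_equal(nrow(surf$faces), 4)
  expect_true(is_watertight(surf))
  expect_gt(mesh_volume(surf), 0)   # outward winding
})

test_that("shared interior faces vanish from the boundary surface", {
  # triangular bipyramid: two tets sharing one face -> 6 boundary tris
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.4, 1),
               c(0.5, 0.4, -1))
  tm <- delaunay_tetrahedralize(pts)
  expect_equal(nrow(tm$tets), 2)
  surf <- extract_boundary_surface(tm)
  expect_equal(nrow(surf$faces), 6)
  expect_true(is_watertight(surf))
})

test_that("boundary at alpha=none equals the brute-force convex hull", {
  for (seed in c(2, 9, 23)) {
    pts <- random_points(sample(5:10, 1), seed)
    tm <- delaunay_tetrahedralize(pts)
    surf <- extract_boundary_surface(tm)
    hull <- brute_hull_faces(pts)
    # compare triangle sets as sorted index triples, mapped back to
    # original indices through coordinates
    remap <- match(
      apply(round(surf$vertices, 9), 1, paste, collapse = "|"),
      apply(round(pts, 9), 1, paste, collapse = "|"))
    got <- unique(lapply(seq_len(nrow(surf$faces)), function(i)
      sort(remap[surf$faces[i, ]])))
    expect_setequal(
      vapply(got, paste, "", collapse = "_"),
      vapply(hull, paste, "", collapse = "_"))
    # 5-point case: Euler formula check 2h - 4 triangles
    if (nrow(pts) == 5 && length(unique(unlist(hull))) == 5)
      expect_equal(nrow(surf$faces), 2 * 5 - 4)
  }
})

test_that("boundary volume equals the sum of kept tet volumes", {
  pts <- random_points(15, 71)
  tm <- delaunay_tetrahedralize(pts)
  med <- stats::median(tm$circumradius)
  kept <- alpha_filter(tm, med)
  surf <- extract_boundary_surface(kept)
  expect_equal(mesh_volume(surf),
               sum(cranioplan:::tet_signed_volume(kept$points, kept$tets)),
               tolerance = 1e-9)
})

test_that("cospherical degenerate input still triangulates deterministically", {
  # 8 cube corners + centre: perfectly cospherical corners
  pts <- rbind(cube_mesh()$vertices, c(0.5, 0.5, 0.5))
  tm1 <- delaunay_tetrahedralize(pts)
  tm2 <- delaunay_tetrahedralize(pts)
  expect_identical(tm1$tets, tm2$tets)
  expect_equal(sum(cranioplan:::tet_signed_volume(tm1$points, tm1$tets)), 1,
               tolerance = 1e-6)
})
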