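# Voxel-grid and mesh primitives.

test_that("mask_union matches the elementwise-OR oracle and its algebra", {
  set.seed(101)
  masks <- lapply(1:5, function(i) {
    binary_mask(array(runif(20^3) < 0.3, c(20, 20, 20)), spacing = rep(0.1, 3))
  })
  u <- mask_union(masks)
  oracle <- masks[[1]]$grid
  for (m in masks[-1]) oracle <- oracle | m$grid # brute-force elementwise OR
  expect_identical(u$grid, oracle)
  expect_gte(mask_volume(u), max(vapply(masks, mask_volume, numeric(1))))

  # idempotent / commutative / associative on random triples
  a <- masks[[1]]; b <- masks[[2]]; cc <- masks[[3]]
  expect_identical(mask_union(list(a, a))$grid, a$grid)
  expect_identical(mask_union(list(a, b))$grid, mask_union(list(b, a))$grid)
  expect_identical(mask_union(list(mask_union(list(a, b)), cc))$grid,
                   mask_union(list(a, mask_union(list(b, cc))))$grid)
})

test_that("mask_union handles disjoint, nested and mismatched inputs", {
  g1 <- array(FALSE, c(3, 3, 3)); g1[1, 1, 1] <- TRUE
  g2 <- array(FALSE, c(3, 3, 3)); g2[3, 3, 3] <- TRUE
  u <- mask_union(list(binary_mask(g1), binary_mask(g2)))
  expect_equal(sum(u$grid), 2L)

  sub <- g1
  sup <- g1; sup[2, 2, 2] <- TRUE # A subset of B -> union is B
  expect_identical(mask_union(list(binary_mask(sub), binary_mask(sup)))$grid, sup)

  expect_error(mask_union(list(binary_mask(g1),
                               binary_mask(array(TRUE, c(2, 2, 2))))),
               "incompatible")
})

test_that("mask_to_mesh volumes match analytic solids", {
  cube <- binary_mask(array(TRUE, c(10, 10, 10)), spacing = rep(0.1, 3))
  mc <- mask_to_mesh(cube)
  expect_equal(mesh_volume(mc), 1.0, tolerance = 0.05)
  expect_silent(validate_surface_mesh(mc))

  sm <- mask_to_mesh(sphere_mask(1, 0.1))
  expect_equal(mesh_volume(sm), 4 / 3 * pi, tolerance = 0.05)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  ms <- mask_to_mesh(binary_mask(single))
  expect_equal(nrow(ms$vertices), 8L)
  expect_gt(mesh_volume(ms), 0)
  expect_silent(validate_surface_mesh(ms))
})

test_that("mask_to_mesh rejects empty and multi-component masks", {
  expect_error(mask_to_mesh(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
  g <- array(FALSE, c(5, 5, 5)); g[1, 1, 1] <- TRUE; g[5, 5, 5] <- TRUE
  expect_error(mask_to_mesh(binary_mask(g)), "2 connected components")
})

test_that("checkerboard voxel pairs still extract to a closed mesh", {
  g <- array(FALSE, c(4, 4, 4))
  g[2, 2, 2] <- TRUE; g[3, 3, 2] <- TRUE # share only a lattice edge
  m <- mask_to_mesh(binary_mask(g))
  expect_silent(validate_surface_mesh(m))
})

test_that("mesh_to_mask voxelization matches analytic volumes and refines", {
  cube <- mask_to_mesh(binary_mask(array(TRUE, c(10, 10, 10)),
                                   spacing = rep(0.1, 3)))
  mk <- mesh_to_mask(cube, spacing = rep(0.1, 3))
  expect_equal(sum(mk$grid), 1000L, tolerance = 0.05)

  sph <- sphere_mesh(1)
  v_coarse <- mask_volume(mesh_to_mask(sph, spacing = rep(0.2, 3)))
  v_fine <- mask_volume(mesh_to_mask(sph, spacing = rep(0.1, 3)))
  expect_equal(v_coarse / v_fine, 1, tolerance = 0.03)
  # grid derived from the mesh bbox: output can never be empty
  expect_gt(sum(mesh_to_mask(sphere_mesh(0.5), spacing = rep(0.2, 3))$grid), 0)
})

test_that("voxelized volume tracks analytic volume across shapes and sizes", {
  shapes <- list(c(1, 1, 1), c(1.5, 1.5, 1.5), c(2, 1, 1), c(1, 2, 1.5),
                 c(0.8, 1.2, 1.6))
  for (ax in shapes) {
    m <- generate_heart(heart_phantom_params(semi_axes = ax,
                                             lobe_amplitudes = rep(0, 4)))
    analytic <- 4 / 3 * pi * prod(ax)
    vox <- mask_volume(mesh_to_mask(m, spacing = rep(0.08, 3)))
    # mesh discretization + voxelization both within 5% of the ellipsoid
    expect_equal(vox, analytic, tolerance = 0.05)
  }
})

test_that("open meshes are rejected by mesh_to_mask", {
  sph <- sphere_mesh(1)
  open <- surface_mesh(sph$vertices, sph$triangles[-1, , drop = FALSE],
                       validate = FALSE)
  expect_error(mesh_to_mask(open, spacing = rep(0.2, 3)), "not closed")
})

test_that("center_of_mass_align recovers offsets and preserves shape", {
  sph <- sphere_mesh(1)
  shifted <- surface_mesh(sweep(sph$vertices, 2, c(1, 2, 3), `+`),
                          sph$triangles, validate = FALSE)
  res <- center_of_mass_align(shifted, sph)
  expect_equal(res$translation, c(-1, -2, -3), tolerance = 1e-12)
  expect_equal(colMeans(res$moved$vertices), colMeans(sph$vertices),
               tolerance = 1e-9)
  # identity case
  expect_equal(center_of_mass_align(sph, sph)$translation, c(0, 0, 0),
               tolerance = 1e-12)
  # inter-vertex distances unchanged (random pair)
  set.seed(7)
  other <- sphere_mesh(1.3, center = rnorm(3))
  moved <- center_of_mass_align(other, sph)$moved
  idx <- sample(nrow(other$vertices), 50)
  d0 <- dist(other$vertices[idx, ])
  d1 <- dist(moved$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # centroids coincide after aligning a random mesh pair
  expect_lt(max(abs(colMeans(moved$vertices) - colMeans(sph$vertices))), 1e-9)
})

test_that("apply_field adds displacements and inverts exactly", {
  sph <- sphere_mesh(1)
  zero <- deformation_field(matrix(0, nrow(sph$vertices), 3))
  expect_identical(apply_field(sph, zero)$vertices, sph$vertices)

  const <- deformation_field(matrix(rep(c(0, 0, 1), each = nrow(sph$vertices)),
                                    ncol = 3))
  expect_equal(colMeans(apply_field(sph, const)$vertices) -
                 colMeans(sph$vertices), c(0, 0, 1), tolerance = 1e-12)

  set.seed(42)
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.1),
                                ncol = 3))
  moved <- apply_field(sph, f)
  expect_equal(moved$vertices, sph$vertices + f$displacements) # oracle
  back <- apply_field(moved, deformation_field(-f$displacements))
  expect_lt(max(abs(back$vertices - sph$vertices)), 1e-12)

  expect_error(apply_field(sph, deformation_field(matrix(0, 5, 3))),
               "does not match")
})

test_that("mask constructor enforces invariants", {
  expect_error(binary_mask(array(TRUE, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(binary_mask(matrix(TRUE, 2, 2)), "3D")
  m <- binary_mask(array(c(TRUE, FALSE), c(2, 2, 2)), spacing = c(0.1, 0.1, 0.3))
  expect_equal(mask_volume(m), 4 * 0.1 * 0.1 * 0.3)
})
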