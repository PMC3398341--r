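# Linear/bilinear navigator-channel adaptation of a deformation field.

test_that("node weights normalize and clamp within the heart bbox", {
  bbox <- list(x = c(-6, 6), y = c(0, 14))
  expect_equal(unlist(compute_node_weights(c(-6, 0, 0), bbox)),
               c(k_x = 0, k_y = 0)) # superior-right corner
  expect_equal(unlist(compute_node_weights(c(0, 7, 2), bbox)),
               c(k_x = 0.5, k_y = 0.5))
  w <- compute_node_weights(c(-20, 99, 0), bbox)
  expect_equal(c(w$k_x, w$k_y), c(0, 1)) # clamped
  expect_error(compute_node_weights(c(0, 0, 0), list(x = c(1, 1), y = c(0, 2))),
               "degenerate")
})

test_that("adapt_longitudinal reproduces hand-computed values", {
  ch5 <- channel_state("NC5", delta = 2.0, shift = 0.5)
  ch6 <- channel_state("NC6", delta = 1.0, shift = 0.2)
  w_eq <- list(k_x = 0.5, k_y = 0.5)
  # equal weights: 0.5*(2.5/2) + 0.5*(1.2/1) = 1.225
  expect_equal(adapt_longitudinal(1.0, w_eq, ch5, ch6), 1.225,
               tolerance = 1e-12)

  # zero shifts: identity for any weight
  z5 <- channel_state("NC5", 2.0, 0); z6 <- channel_state("NC6", 1.0, 0)
  for (ky in c(0, 0.3, 1)) {
    expect_identical(adapt_longitudinal(0.73, list(k_x = 0, k_y = ky), z5, z6),
                     0.73)
  }

  # both ratios equal r -> r * delta regardless of k_y
  r5 <- channel_state("NC5", 2.0, 1.0) # ratio 1.5
  r6 <- channel_state("NC6", 0.5, 0.25) # ratio 1.5
  for (ky in c(0, 0.4, 1)) {
    expect_equal(adapt_longitudinal(2.0, list(k_x = 0, k_y = ky), r5, r6), 3.0,
                 tolerance = 1e-12)
  }

  # role_map swaps which channel anchors the superior end
  w0 <- list(k_x = 0, k_y = 0) # most superior node
  expect_equal(adapt_longitudinal(1.0, w0, ch5, ch6), 2.5 / 2)
  expect_equal(adapt_longitudinal(1.0, w0, ch5, ch6,
                                  role_map = c(superior = "NC6")), 1.2)
})

test_that("adapt_lateral covers the three regions and their degeneracies", {
  dc <- demo_channels()
  st <- dc$states[1:4]
  w <- list(k_x = 0.25, k_y = 0.6)
  t_of <- function(i) 0.8 * (dc$states[[i]]$delta + dc$states[[i]]$shift) /
    dc$states[[i]]$delta
  expect_equal(adapt_lateral(0.8, w, "upper", st),
               0.75 * t_of(3) + 0.25 * t_of(4), tolerance = 1e-12)
  expect_equal(adapt_lateral(0.8, w, "lower", st),
               0.75 * t_of(1) + 0.25 * t_of(2), tolerance = 1e-12)
  expect_equal(adapt_lateral(0.8, w, "middle", st),
               0.75 * 0.4 * t_of(3) + 0.25 * 0.4 * t_of(4) +
                 0.75 * 0.6 * t_of(1) + 0.25 * 0.6 * t_of(2),
               tolerance = 1e-12)

  # all shifts zero -> identity in every region
  z <- lapply(1:4, function(i) channel_state(paste0("NC", i), 0.5, 0))
  for (rg in c("upper", "middle", "lower")) {
    expect_identical(adapt_lateral(0.31, w, rg, z), 0.31)
  }

  # all four ratios equal r -> r * delta in the middle regardless of weights
  req <- lapply(1:4, function(i) channel_state(paste0("NC", i), 0.4 * i, 0.2 * i))
  expect_equal(adapt_lateral(1.0, list(k_x = 0.8, k_y = 0.1), "middle", req),
               1.5, tolerance = 1e-12)

  # k_y -> 1 limit: middle converges to the lower-region formula
  for (kx in c(0, 0.33, 1)) {
    wl <- list(k_x = kx, k_y = 1)
    expect_equal(adapt_lateral(0.8, wl, "middle", st),
                 adapt_lateral(0.8, wl, "lower", st), tolerance = 1e-12)
    wl$k_y <- 0
    expect_equal(adapt_lateral(0.8, wl, "middle", st),
                 adapt_lateral(0.8, wl, "upper", st), tolerance = 1e-12)
  }
})

test_that("epsilon guard falls back to the additive correction", {
  tiny <- channel_state("NC5", 1e-9, 0.4)
  ch6 <- channel_state("NC6", 1.0, 0)
  # superior node: entire weight on the degenerate channel
  expect_equal(adapt_longitudinal(0.5, list(k_x = 0, k_y = 0), tiny, ch6),
               0.5 + 0.4, tolerance = 1e-12)
  # zero shift through the guard is still the identity
  tiny0 <- channel_state("NC5", 0, 0)
  expect_identical(adapt_longitudinal(0.5, list(k_x = 0, k_y = 0), tiny0, ch6),
                   0.5)
})

test_that("partition_regions matches a per-node threshold oracle", {
  dc <- demo_channels()
  sph <- sphere_mesh(5, center = c(0, 7, 0))
  part <- partition_regions(sph, dc$geom)
  expect_equal(part$upper_boundary_y, 4)
  expect_equal(part$lower_boundary_y, 10)
  y <- sph$vertices[, 2]
  oracle <- ifelse(y < 4, "upper", ifelse(y > 10, "lower", "middle"))
  expect_equal(as.character(part$labels), oracle)

  # a mesh straddling the lower boundary only gets middle/lower labels
  flatmesh <- sphere_mesh(1, center = c(0, 10, 0))
  expect_true(all(partition_regions(flatmesh, dc$geom)$labels %in%
                    c("middle", "lower")))

  bad <- dc$geom
  bad[[1]]$center[2] <- 0 # move the NC1/NC2 row above the NC3/NC4 row
  bad[[2]]$center[2] <- 0
  expect_error(partition_regions(sph, bad), "superior")
})

test_that("adapt_field: zero shifts give a bit-for-bit identity", {
  sph <- sphere_mesh(5, center = c(0, 7, 0))
  set.seed(23)
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.4),
                                ncol = 3))
  dc <- demo_channels(shifts = rep(0, 6))
  out <- adapt_field(f, sph, dc$states, dc$geom)
  expect_identical(out$displacements, f$displacements)
})

test_that("adapt_field matches the straight-line per-node oracle to 1e-12", {
  set.seed(29)
  sph <- sphere_mesh(5, center = c(1, 7, -1), n_theta = 24L, n_phi = 42L)
  expect_gte(nrow(sph$vertices), 900) # ~1000 random nodes
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.5),
                                ncol = 3))
  dc <- demo_channels()
  out <- adapt_field(f, sph, dc$states, dc$geom)
  oracle <- oracle_adapt(f, sph, dc$states, dc$geom)
  expect_lt(max(abs(out$displacements - oracle)), 1e-12)

  # anterior-posterior (z) displacements exactly preserved
  expect_identical(out$displacements[, 3], f$displacements[, 3])

  # including degenerate channels
  dc2 <- demo_channels(deltas = c(0.5, 1e-9, 0.45, -0.5, 0, -0.55))
  out2 <- adapt_field(f, sph, dc2$states, dc2$geom)
  oracle2 <- oracle_adapt(f, sph, dc2$states, dc2$geom)
  expect_lt(max(abs(out2$displacements - oracle2)), 1e-12)
})

test_that("adapt_field respects the NC5/NC6 role configuration", {
  sph <- sphere_mesh(5, center = c(0, 7, 0))
  set.seed(31)
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.3),
                                ncol = 3))
  dc <- demo_channels()
  a5 <- adapt_field(f, sph, dc$states, dc$geom,
                    role_map = c(superior = "NC5"))
  a6 <- adapt_field(f, sph, dc$states, dc$geom,
                    role_map = c(superior = "NC6"))
  expect_false(identical(a5$displacements[, 2], a6$displacements[, 2]))
  expect_equal(a6$displacements,
               oracle_adapt(f, sph, dc$states, dc$geom, superior = "NC6"),
               tolerance = 1e-12)
})

test_that("uniform longitudinal shift scales every y-displacement", {
  sph <- sphere_mesh(5, center = c(0, 7, 0))
  set.seed(37)
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.3),
                                ncol = 3))
  d <- 0.8; s <- 0.3
  states <- list(channel_state("NC1", 0.5, 0), channel_state("NC2", 0.5, 0),
                 channel_state("NC3", 0.5, 0), channel_state("NC4", 0.5, 0),
                 channel_state("NC5", d, s), channel_state("NC6", d, s))
  out <- adapt_field(f, sph, states, demo_channels()$geom)
  expect_equal(out$displacements[, 2], f$displacements[, 2] * (d + s) / d,
               tolerance = 1e-12)
})

test_that("adapt_field validates channel sets", {
  sph <- sphere_mesh(2, center = c(0, 7, 0))
  f <- deformation_field(matrix(0, nrow(sph$vertices), 3))
  dc <- demo_channels()
  expect_error(adapt_field(f, sph, dc$states[1:5], dc$geom), "NC6")
  expect_error(adapt_field(f, sph, c(dc$states[1:5], dc$states[5]), dc$geom),
               "exactly once")
})

test_that("reconstruct applies the adapted field (pipeline identity)", {
  sph <- sphere_mesh(3, center = c(0, 7, 0))
  set.seed(41)
  f <- deformation_field(matrix(rnorm(3 * nrow(sph$vertices), sd = 0.2),
                                ncol = 3))
  dc <- demo_channels(shifts = rep(0, 6))
  adapted <- adapt_field(f, sph, dc$states, dc$geom)
  expect_identical(reconstruct(sph, adapted)$vertices,
                   apply_field(sph, f)$vertices)
})
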