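# Synthetic heart/thorax generators and ground-truth deformations.

test_that("generate_heart is deterministic and volumetrically sane", {
  hp <- heart_phantom_params(semi_axes = c(1, 1, 1), lobe_amplitudes = rep(0, 4))
  h1 <- generate_heart(hp)
  expect_silent(validate_surface_mesh(h1))
  expect_equal(mesh_volume(h1), 4 / 3 * pi, tolerance = 0.10)
  expect_identical(generate_heart(hp)$vertices, h1$vertices)

  hp_r <- heart_phantom_params(roughness = 0.1, seed = 3L)
  expect_identical(generate_heart(hp_r)$vertices, generate_heart(hp_r)$vertices)
  expect_false(identical(
    generate_heart(hp_r)$vertices,
    generate_heart(heart_phantom_params(roughness = 0.1, seed = 4L))$vertices))
})

test_that("lobe amplitude strictly increases enclosed volume", {
  vols <- vapply(c(0, 0.5, 1.0), function(a) {
    hp <- heart_phantom_params(semi_axes = c(2, 2, 2),
                               lobe_amplitudes = c(a, 0, 0, 0))
    # voxel-count oracle, independent of the divergence-theorem volume
    mask_volume(mesh_to_mask(generate_heart(hp), spacing = rep(0.1, 3)))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("heart parameter validation", {
  expect_error(heart_phantom_params(semi_axes = c(-1, 1, 1)), "positive")
  expect_error(heart_phantom_params(lobe_amplitudes = c(-0.1, 0, 0, 0)),
               "non-negative")
})

test_that("thorax CT encodes W1/W2 on the grid and carries metadata", {
  ph <- std_phantom()
  # construction-by-placement oracle: the DRR measurement returns the
  # parameters the grid was built from, to one voxel
  tm <- measure_thorax(ph$drr)
  expect_equal(tm$W1, ph$thorax$W1, tolerance = 0.2001)
  expect_equal(tm$W2, ph$thorax$W2, tolerance = 0.2001)
  expect_equal(tm$L, ph$thorax$L)
  expect_s3_class(attr(ph$ct, "heart_mask"), "binary_mask")
  expect_named(attr(ph$ct, "landmarks"),
               c("sternal_notch", "T6_spinous", "T8_spinous"))
})

test_that("thorax CT is deterministic unless noise is requested", {
  thorax <- thorax_phantom_params(seed = 1L)
  thorax2 <- thorax_phantom_params(seed = 2L)
  heart <- generate_heart(heart_phantom_params(center = c(0, 7, -2)))
  ct1 <- generate_thorax_ct(thorax, heart, spacing = rep(0.4, 3))
  ct2 <- generate_thorax_ct(thorax2, heart, spacing = rep(0.4, 3))
  expect_identical(ct1$grid, ct2$grid) # seed only gates noise

  noisy <- thorax_phantom_params(noise_sd = 0.05, seed = 9L)
  n1 <- generate_thorax_ct(noisy, heart, spacing = rep(0.4, 3))
  n2 <- generate_thorax_ct(noisy, heart, spacing = rep(0.4, 3))
  expect_identical(n1$grid, n2$grid) # same seed, same noise
  expect_false(identical(n1$grid, ct1$grid))
})

test_that("zero-contrast heart yields a clean no-edge failure downstream", {
  thorax <- suppressWarnings(
    thorax_phantom_params(heart_attenuation = 1, soft_tissue_attenuation = 1))
  heart <- generate_heart(heart_phantom_params(center = c(0, 7, -2)))
  ct <- generate_thorax_ct(thorax, heart, spacing = rep(0.2, 3))
  drr <- render_drr(ct)
  # silhouette comes from the mask, so channels can still be placed; the
  # intensity profile, however, carries no heart edge
  nc <- navigator_channel("NC5", drr$heart_contour[which.min(drr$heart_contour[, 2]), ])
  expect_error(detect_poi(extract_profile(drr, nc)), "no edge")
})

test_that("oversized hearts are rejected", {
  thorax <- thorax_phantom_params()
  big <- generate_heart(heart_phantom_params(semi_axes = c(12, 6, 4),
                                             center = c(0, 7, -2)))
  expect_error(generate_thorax_ct(thorax, big, spacing = rep(0.4, 3)),
               "does not fit")
})

test_that("generate_deformed_pair produces exact ground truth", {
  hp <- heart_phantom_params(seed = 2L)

  tr <- generate_deformed_pair(hp, deformation_spec("translate",
                                                    offset = c(0, 1, 0)))
  expect_equal(tr$true_field$displacements,
               matrix(rep(c(0, 1, 0), each = nrow(tr$reference$vertices)),
                      ncol = 3))

  sc <- generate_deformed_pair(hp, deformation_spec("scale", factors = 1.1))
  ctr <- colMeans(sc$reference$vertices)
  expect_equal(sc$true_field$displacements,
               0.1 * sweep(sc$reference$vertices, 2, ctr, `-`),
               tolerance = 1e-12)

  id <- generate_deformed_pair(hp, deformation_spec("scale", factors = 1))
  expect_equal(dice(id$reference, id$test, com_align = FALSE)$dice_pct, 100)

  # true_field applied to reference reproduces test to machine precision
  comp <- generate_deformed_pair(hp, deformation_spec("composite", specs = list(
    deformation_spec("scale", factors = c(1.1, 0.9, 1)),
    deformation_spec("bend", amplitude = 0.4, wavelength = 20))))
  rebuilt <- apply_field(comp$reference, comp$true_field)
  expect_lt(max(abs(rebuilt$vertices - comp$test$vertices)), 1e-12)
})

test_that("deformation specs enforce bijectivity", {
  expect_error(deformation_spec("scale", factors = c(0, 1, 1)), "positive")
  expect_error(deformation_spec("bend", amplitude = 10, wavelength = 10),
               "bijection")
})
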