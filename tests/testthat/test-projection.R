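# DRR projection, magnification scaling, rigid 2D alignment.

test_that("render_drr is an exact column-sum projector", {
  # uniform attenuation a over depth D -> constant image a*D
  g <- array(2, c(4, 5, 6))
  ct <- ct_volume(g, spacing = c(0.1, 0.1, 0.3))
  drr <- render_drr(ct)
  expect_true(all(abs(drr$pixels - 2 * 6 * 0.3) < 1e-12))
  expect_equal(dim(drr$pixels), c(5L, 4L)) # rows = y, cols = x

  # single bright voxel -> single bright pixel at (col = i, row = j)
  g <- array(0, c(7, 6, 5)); g[3, 4, 2] <- 10
  drr <- render_drr(ct_volume(g, spacing = c(0.1, 0.1, 0.3)))
  expect_equal(drr$pixels[4, 3], 10 * 0.3)
  expect_equal(sum(drr$pixels != 0), 1L)

  # brute-force column-sum oracle on a phantom slab
  set.seed(12)
  g <- array(runif(6 * 7 * 8), c(6, 7, 8))
  ct <- ct_volume(g, spacing = c(0.2, 0.2, 0.2))
  drr <- render_drr(ct)
  for (i in 1:6) for (j in 1:7) {
    expect_equal(drr$pixels[j, i], sum(g[i, j, ]) * 0.2, tolerance = 1e-9)
  }
})

test_that("render_drr is linear in the volume", {
  set.seed(3)
  g1 <- array(runif(5 * 5 * 5), c(5, 5, 5))
  g2 <- array(runif(5 * 5 * 5), c(5, 5, 5))
  sp <- c(0.1, 0.1, 0.3)
  lin <- render_drr(ct_volume(2 * g1 + 3 * g2, spacing = sp))$pixels
  sep <- 2 * render_drr(ct_volume(g1, spacing = sp))$pixels +
    3 * render_drr(ct_volume(g2, spacing = sp))$pixels
  expect_equal(lin, sep, tolerance = 1e-12)
})

test_that("render_drr attaches silhouette contour and rejects empties", {
  ph <- std_phantom()
  expect_false(is.null(ph$drr$heart_contour))
  # silhouette bbox matches the heart mesh bbox in the image plane (~1 px)
  hb <- apply(ph$heart$vertices[, 1:2], 2, range)
  cb <- apply(ph$drr$heart_contour, 2, range)
  expect_lt(max(abs(hb - cb)), 0.3)
  expect_error(render_drr(ct_volume(array(1, c(2, 2, 2)),
                                    spacing = c(1, 1, 1))[c()]), "")
})

test_that("scale_to_reference rescales calibration only", {
  px <- matrix(runif(100), 10, 10)
  ref <- drr_image(px, c(0.1, 0.1))
  test <- drr_image(px, c(0.1, 0.1),
                    landmarks = list(a = c(0.2, 0.2), b = c(0.6, 0.8)))
  out <- scale_to_reference(test, ref, rbind(c(0, 0), c(10, 0)),
                            rbind(c(0, 0), c(5, 0)))
  expect_equal(attr(out, "scale"), 2.0)
  expect_equal(out$pixel_spacing, c(0.2, 0.2))
  expect_identical(out$pixels, test$pixels)
  # annotated distances are preserved in the reference frame
  d_before <- sqrt(sum((test$landmarks$a - test$landmarks$b)^2))
  d_after <- sqrt(sum((out$landmarks$a - out$landmarks$b)^2))
  expect_equal(d_after, 2 * d_before, tolerance = 1e-9)

  idm <- scale_to_reference(test, ref, rbind(c(0, 0), c(10, 0)),
                            rbind(c(0, 0), c(10, 0)))
  expect_equal(idm$pixel_spacing, test$pixel_spacing)

  # random separations match the direct distance-ratio oracle
  set.seed(8)
  for (i in 1:5) {
    rp <- matrix(rnorm(4, sd = 5), 2); tp <- matrix(rnorm(4, sd = 5), 2)
    s_oracle <- sqrt(sum((rp[1, ] - rp[2, ])^2)) / sqrt(sum((tp[1, ] - tp[2, ])^2))
    out <- scale_to_reference(test, ref, rp, tp)
    expect_equal(attr(out, "scale"), s_oracle, tolerance = 1e-12)
  }

  expect_error(scale_to_reference(test, ref, rbind(c(0, 0), c(0, 0)),
                                  rbind(c(0, 0), c(1, 0))), "degenerate")
})

test_that("rigid_align_2d recovers landmark translations", {
  px <- matrix(0, 8, 8)
  lms <- list(sternal_notch = c(0.5, 0.2), T6_spinous = c(0.5, 0.5),
              T8_spinous = c(0.55, 0.7))
  ref <- drr_image(px, c(0.1, 0.1), landmarks = lms)
  shifted <- lapply(lms, function(p) p + c(-1.5, 2.0))
  test <- drr_image(px, c(0.1, 0.1), landmarks = shifted)
  r <- rigid_align_2d(ref, test)
  expect_equal(r$translation, c(1.5, -2.0), tolerance = 1e-12)
  expect_equal(rigid_align_2d(ref, ref)$translation, c(0, 0))

  # jittered landmarks: translation equals the centroid difference
  # (closed-form least-squares oracle)
  set.seed(21)
  jit <- lapply(lms, function(p) p + rnorm(2, sd = 0.3))
  test2 <- drr_image(px, c(0.1, 0.1), landmarks = jit)
  r2 <- rigid_align_2d(ref, test2)
  oracle <- colMeans(do.call(rbind, lms)) - colMeans(do.call(rbind, jit))
  expect_equal(unname(r2$translation), unname(oracle), tolerance = 1e-12)

  test3 <- drr_image(px, c(0.1, 0.1), landmarks = lms[1:2])
  expect_error(rigid_align_2d(ref, test3), "T8_spinous")
})

test_that("apply_rigid_2d shifts calibration and annotations together", {
  ph <- std_phantom()
  r <- structure(list(translation = c(0.7, -0.3), rotation = 0),
                 class = "rigid_2d")
  moved <- apply_rigid_2d(ph$drr, r)
  expect_equal(moved$origin2d, ph$drr$origin2d + c(0.7, -0.3))
  expect_equal(moved$heart_contour[1, ], ph$drr$heart_contour[1, ] + c(0.7, -0.3))
  expect_equal(moved$landmarks$T6_spinous,
               ph$drr$landmarks$T6_spinous + c(0.7, -0.3))
})
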