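# Channel placement, intensity profiles, POI detection, edge shifts.

test_that("place_channels builds role-appropriate rectangles on anchors", {
  ph <- std_phantom()
  anchors <- suggest_anchors(ph$drr)
  chs <- place_channels(ph$drr, anchors)
  expect_length(chs, 6L)
  expect_equal(vapply(chs, `[[`, character(1), "role"), paste0("NC", 1:6))
  expect_equal(chs[[1]]$size, c(2.0, 0.5)) # horizontal default
  expect_equal(chs[[5]]$size, c(0.5, 4.0)) # vertical default
  expect_equal(chs[[2]]$center, unname(anchors[2, ]))

  # NC5/NC6 anchored at the extreme contour rows straddle them
  ct <- ph$drr$heart_contour
  expect_equal(chs[[5]]$center[2], min(ct[, 2]))
  expect_equal(chs[[6]]$center[2], max(ct[, 2]))

  # each channel rectangle contains at least one contour point
  # (polygon-rectangle intersection oracle on the dense contour)
  for (nc in chs) {
    inside <- ct[, 1] >= nc$center[1] - nc$size[1] / 2 &
      ct[, 1] <= nc$center[1] + nc$size[1] / 2 &
      ct[, 2] >= nc$center[2] - nc$size[2] / 2 &
      ct[, 2] <= nc$center[2] + nc$size[2] / 2
    expect_true(any(inside), info = nc$role)
  }

  expect_error(place_channels(ph$drr, anchors[1:5, ]), "6 anchors")
  far <- anchors; far[3, ] <- far[3, ] + c(15, 0)
  expect_error(place_channels(ph$drr, far), "NC3 anchor")
})

test_that("extract_profile equals a brute-force pixel-averaging oracle", {
  set.seed(5)
  px <- matrix(runif(40 * 50), 40, 50)
  drr <- drr_image(px, c(0.1, 0.1))
  nc_h <- navigator_channel("NC1", c(2.0, 1.5))
  pr <- extract_profile(drr, nc_h)
  # oracle: double loop over pixel centers inside the rectangle
  xc <- (seq_len(50) - 0.5) * 0.1
  yc <- (seq_len(40) - 0.5) * 0.1
  cols <- which(xc >= 1.0 & xc <= 3.0)
  rows <- which(yc >= 1.25 & yc <= 1.75)
  oracle <- vapply(cols, function(cl) mean(px[rows, cl]), numeric(1))
  expect_equal(pr$samples, oracle, tolerance = 1e-12)
  expect_equal(pr$sample_spacing, 0.1)
  expect_equal(pr$axis_origin, xc[cols[1]])

  nc_v <- navigator_channel("NC5", c(2.0, 2.0))
  pv <- extract_profile(drr, nc_v)
  rows_v <- which(yc >= 0 & yc <= 4.0)
  cols_v <- which(xc >= 1.75 & xc <= 2.25)
  expect_equal(pv$samples,
               vapply(rows_v, function(rw) mean(px[rw, cols_v]), numeric(1)),
               tolerance = 1e-12)

  # constant image -> constant profile
  flat <- drr_image(matrix(3, 40, 50), c(0.1, 0.1))
  expect_true(all(extract_profile(flat, nc_h)$samples == 3))

  expect_error(extract_profile(drr, navigator_channel("NC1", c(100, 1))),
               "outside")
})

test_that("a half-plane edge produces a step profile with a located POI", {
  px <- matrix(0, 30, 60)
  px[, 31:60] <- 10 # vertical edge at x = 3.0 cm (0.1 cm pixels)
  drr <- drr_image(px, c(0.1, 0.1))
  nc <- navigator_channel("NC2", c(3.0, 1.5))
  pr <- extract_profile(drr, nc)
  expect_true(all(pr$samples %in% c(0, 10)))
  poi <- detect_poi(pr)
  expect_equal(poi, 3.0, tolerance = 0.1) # step between samples -> inside gap
})

test_that("detect_poi finds the inflection of an analytic sigmoid", {
  x <- seq(0, 4, by = 0.1)
  pr <- intensity_profile(1 / (1 + exp(-(x - 2.0) / 0.2)), 0.1, 0)
  expect_equal(detect_poi(pr), 2.0, tolerance = 0.05)
  # brute-force derivative-scan oracle: the raw maximum-slope sample
  d <- diff(pr$samples)
  expect_equal(detect_poi(pr), (which.max(d) - 0.5) * 0.1, tolerance = 0.1)
})

test_that("detect_poi rejects ramps and noise, tolerates affine rescaling", {
  ramp <- intensity_profile(seq(0, 5, length.out = 30), 0.1, 0)
  expect_error(detect_poi(ramp), "no edge")

  set.seed(9)
  noise <- intensity_profile(rnorm(30), 0.1, 0)
  expect_error(detect_poi(noise), "no edge")

  x <- seq(0, 4, by = 0.1)
  pr <- intensity_profile(1 / (1 + exp(-(x - 1.7) / 0.15)), 0.1, 0)
  poi <- detect_poi(pr)
  for (ab in list(c(10, 0), c(0.01, 5), c(3, -200))) {
    scaled <- intensity_profile(ab[1] * pr$samples + ab[2], 0.1, 0)
    expect_equal(detect_poi(scaled), poi, tolerance = 1e-9)
  }
})

test_that("compute_shift recovers imposed translations and flags nonsense", {
  x <- seq(0, 4, by = 0.1)
  shape <- function(c0) 1 / (1 + exp(-(x - c0) / 0.2))
  ref <- intensity_profile(shape(2.0), 0.1, 0, role = "NC5")

  s <- compute_shift(ref, intensity_profile(shape(2.3), 0.1, 0, role = "NC5"))
  expect_equal(s$shift, 0.3, tolerance = 0.05) # half sample = 0.05

  s0 <- compute_shift(ref, ref)
  expect_equal(s0$shift, 0)
  expect_s3_class(s0, "edge_shift")

  s_neg <- compute_shift(ref, intensity_profile(shape(1.6), 0.1, 0, role = "NC5"))
  expect_equal(s_neg$shift, -0.4, tolerance = 0.05)

  flat <- intensity_profile(rep(1, length(x)), 0.1, 0, role = "NC5")
  expect_error(compute_shift(ref, flat), "\\[NC5, test\\]")
})

test_that("shift estimation is equivariant on phantom DRRs (all channels)", {
  drr <- fine_phantom_drr() # 0.1 cm pixels
  chs <- place_channels(drr, suggest_anchors(drr))
  for (k in c(-3L, 2L)) {
    delta <- k * 0.1
    for (nc in chs) {
      axis <- if (nc$orientation == "horizontal") "x" else "y"
      rolled <- roll_drr(drr, k, axis)
      s <- compute_shift(extract_profile(drr, nc), extract_profile(rolled, nc))
      expect_equal(s$shift, delta, tolerance = 0.05,
                   info = sprintf("%s k=%d", nc$role, k))
    }
  }
})

test_that("channel and profile constructors validate", {
  expect_error(navigator_channel("NC9", c(0, 0)))
  expect_error(navigator_channel("NC1", c(0, 0), size = c(-1, 1)), "positive")
  expect_error(intensity_profile(1:5, 0.1, 0), "8 samples")
  expect_error(intensity_profile(1:20, 0, 0), "positive")
})
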