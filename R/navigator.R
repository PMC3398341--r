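# Navigator channels: rectangular regions of interest placed on matching
# edges of two radiographs. Each channel reduces its rectangle to a 1D mean
# intensity profile along its long axis; the organ edge is the point of
# inflection (POI) of that profile - the zero crossing of the smoothed
# second derivative nearest the maximum rate of intensity change - and the
# per-channel edge shift is the difference of the two POIs.
#
# Roles: NC1/NC2 lower-region right/left circumflexes, NC3/NC4 upper-region
# right/left circumflexes (horizontal, 2.0 x 0.5 cm), NC5/NC6 the
# superior/inferior heart edges (vertical, 0.5 x 4.0 cm). Which of NC5/NC6
# is superior is configuration (`role_map`), defaulting to NC5 = superior.

NC_ROLES <- paste0("NC", 1:6)

#' Construct a navigator channel
#'
#' @param role One of `"NC1"`..`"NC6"`.
#' @param center 2D point (cm, reference-image world frame).
#' @param size Length-2 `(w, h)` cm; defaults 2.0 x 0.5 for horizontal
#'   channels (NC1-NC4) and 0.5 x 4.0 for vertical channels (NC5, NC6).
#' @return An object of class `navigator_channel` with fields `role`,
#'   `center`, `size`, `orientation` (`"horizontal"` channels measure along
#'   x, `"vertical"` along y).
#' @export
navigator_channel <- function(role, center, size = NULL) {
  role <- match.arg(role, NC_ROLES)
  orientation <- if (role %in% c("NC5", "NC6")) "vertical" else "horizontal"
  if (is.null(size)) {
    size <- if (orientation == "vertical") c(0.5, 4.0) else c(2.0, 0.5)
  }
  size <- as.numeric(size)
  if (length(size) != 2L || any(size <= 0)) {
    stop("`size` must be 2 positive numbers (cm)", call. = FALSE)
  }
  structure(list(role = role, center = as.numeric(center), size = size,
                 orientation = orientation),
            class = "navigator_channel")
}

#' @export
print.navigator_channel <- function(x, ...) {
  cat(sprintf("<navigator_channel> %s (%s) at (%.2f, %.2f), %.1f x %.1f cm\n",
              x$role, x$orientation, x$center[1], x$center[2],
              x$size[1], x$size[2]))
  invisible(x)
}

nc_long_axis_length <- function(nc) {
  if (nc$orientation == "vertical") nc$size[2] else nc$size[1]
}

nc_rect <- function(nc) {
  c(x0 = nc$center[1] - nc$size[1] / 2, x1 = nc$center[1] + nc$size[1] / 2,
    y0 = nc$center[2] - nc$size[2] / 2, y1 = nc$center[2] + nc$size[2] / 2)
}

#' Place the six navigator channels on a Reference image
#'
#' Centers role-appropriate default-size channels on six user-supplied
#' anchor points (ordered NC1..NC6, reference world frame). The identical
#' geometry is reused verbatim on the rigidly aligned Test image - spatial
#' correspondence comes from [rigid_align_2d()], not from re-anchoring.
#' Anchors are validated against the image's heart contour: an anchor
#' farther than half the channel's long axis from the contour cannot
#' straddle the edge it is meant to track.
#'
#' @param ref A [drr_image()] carrying a `heart_contour`.
#' @param anchors 6 x 2 matrix of 2D anchor points (cm), rows NC1..NC6.
#' @return List of six [navigator_channel()] objects.
#' @export
place_channels <- function(ref, anchors) {
  stopifnot(inherits(ref, "drr_image"))
  if (is.null(ref$heart_contour)) {
    stop("reference image has no heart contour", call. = FALSE)
  }
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 6L || ncol(anchors) != 2L) {
    stop(sprintf("exactly 6 anchors required (got %d)", nrow(anchors)),
         call. = FALSE)
  }
  channels <- lapply(seq_len(6L), function(i) {
    navigator_channel(NC_ROLES[i], anchors[i, ])
  })
  for (nc in channels) {
    d <- min(sqrt((ref$heart_contour[, 1] - nc$center[1])^2 +
                    (ref$heart_contour[, 2] - nc$center[2])^2))
    if (d > nc_long_axis_length(nc) / 2) {
      stop(sprintf("%s anchor is %.2f cm from the heart contour (> half the channel long axis %.2f cm)",
                   nc$role, d, nc_long_axis_length(nc) / 2), call. = FALSE)
    }
  }
  channels
}

#' Construct a 1D intensity profile
#'
#' @param samples Numeric vector of mean intensities (>= 8 samples).
#' @param sample_spacing Spacing between samples (cm).
#' @param axis_origin World coordinate (cm) of sample 1 along the long axis.
#' @param role Optional channel role carried for provenance.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(samples, sample_spacing, axis_origin, role = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 8L) {
    stop("profile needs at least 8 samples", call. = FALSE)
  }
  if (sample_spacing <= 0) stop("sample spacing must be positive", call. = FALSE)
  structure(list(samples = samples, sample_spacing = sample_spacing,
                 axis_origin = axis_origin, role = role),
            class = "intensity_profile")
}

#' Extract a channel's intensity profile from a radiograph
#'
#' Averages pixel intensities across the channel's short axis and samples
#' along the long axis at pixel pitch. Pixels belong to the rectangle when
#' their centers fall inside it.
#'
#' @param drr A [drr_image()].
#' @param nc A [navigator_channel()] (reference-frame geometry; pass the
#'   *aligned* test image to sample the corresponding test region).
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(drr, nc) {
  stopifnot(inherits(drr, "drr_image"), inherits(nc, "navigator_channel"))
  r <- nc_rect(nc)
  ctr <- drr_px_centers(drr)
  cols <- which(ctr$x >= r["x0"] & ctr$x <= r["x1"])
  rows <- which(ctr$y >= r["y0"] & ctr$y <= r["y1"])
  if (!length(cols) || !length(rows) ||
      r["x0"] < min(ctr$x) - drr$pixel_spacing[1] ||
      r["x1"] > max(ctr$x) + drr$pixel_spacing[1] ||
      r["y0"] < min(ctr$y) - drr$pixel_spacing[2] ||
      r["y1"] > max(ctr$y) + drr$pixel_spacing[2]) {
    stop(sprintf("%s rectangle falls outside the image bounds", nc$role),
         call. = FALSE)
  }
  block <- drr$pixels[rows, cols, drop = FALSE]
  if (nc$orientation == "horizontal") {
    intensity_profile(colMeans(block), drr$pixel_spacing[1], ctr$x[cols[1]],
                      role = nc$role)
  } else {
    intensity_profile(rowMeans(block), drr$pixel_spacing[2], ctr$y[rows[1]],
                      role = nc$role)
  }
}

# Gaussian smoothing; sigma in samples. The kernel is truncated and
# renormalized at the window ends (normalized convolution) rather than
# padded: mirror or extrapolation padding fabricates data and with it
# spurious curvature near the ends, which biases POIs of edges that sit
# off-center after a large shift.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  n <- length(x)
  xp <- c(rep(0, rad), x, rep(0, rad))
  mp <- c(rep(0, rad), rep(1, length(x)), rep(0, rad))
  num <- as.numeric(stats::filter(xp, k, sides = 2))[(rad + 1L):(rad + n)]
  den <- as.numeric(stats::filter(mp, k, sides = 2))[(rad + 1L):(rad + n)]
  num / den
}

#' Detect the point of inflection (organ edge) of a profile
#'
#' Smooths the profile with a Gaussian (raw second differences are
#' noise-dominated on 8-bit-like images; the source method does not mention
#' smoothing, so sigma is an explicit knob), then returns the zero crossing
#' of the second derivative nearest the global maximum of the absolute
#' first derivative, with sub-sample linear interpolation of the crossing.
#' Remaining ties go to the crossing nearest the profile center.
#'
#' The edge gate is scale-free (invariant to affine intensity rescaling
#' `a*I + b`, `a > 0`): an organ edge must dominate the window, so the net
#' intensity change across the profile must account for at least
#' `edge_frac` of its total variation (a flat or noise-only profile fails),
#' and the curvature must be significant relative to the intensity range (a
#' linear ramp - constant slope, no inflection - fails).
#'
#' @param profile An [intensity_profile()].
#' @param smoothing_sigma Gaussian sigma in samples (default 1; wide
#'   kernels bias POIs of off-center edges in the short 2.0 cm channels).
#' @param edge_frac Required ratio of net change to total variation of the
#'   smoothed profile (default 0.5).
#' @return POI position in cm along the channel's long axis.
#' @export
detect_poi <- function(profile, smoothing_sigma = 1, edge_frac = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"))
  raw <- profile$samples
  n <- length(raw)
  # edge gates on the raw profile (exact under translation; smoothing-end
  # effects must not decide whether an edge exists)
  rng <- diff(range(raw))
  tv <- sum(abs(diff(raw)))
  if (rng <= 0 || tv <= 0 || abs(raw[n] - raw[1]) < edge_frac * tv) {
    stop("no edge detected: profile has no dominant intensity gradient",
         call. = FALSE)
  }
  d2raw <- raw[c(2:n, n)] - 2 * raw + raw[c(1, 1:(n - 1))]
  if (max(abs(d2raw[2:(n - 1)])) < 1e-8 * rng) {
    stop("no edge detected: profile has no significant curvature (linear ramp?)",
         call. = FALSE)
  }
  s <- gauss_smooth(raw, smoothing_sigma)
  d1 <- (s[c(2:n, n)] - s[c(1, 1:(n - 1))]) / 2 # central differences
  d2 <- s[c(2:n, n)] - 2 * s + s[c(1, 1:(n - 1))]
  peak <- which.max(abs(d1))
  # zero crossings of d2, zero-run aware (a symmetric edge can put an exact
  # zero on a sample); one-sided boundary stencils excluded
  sg <- sign(d2[2:(n - 1)])
  r <- rle(sg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- numeric(0)
  for (j in seq_along(r$values)) {
    if (r$values[j] == 0) { # zero run flanked by opposite signs
      if (j > 1L && j < length(r$values) &&
          r$values[j - 1L] * r$values[j + 1L] < 0) {
        pos <- c(pos, (starts[j] + ends[j]) / 2) # run middle, 0-based in sg+1
      }
    } else if (j < length(r$values) && r$values[j + 1L] != 0 &&
               r$values[j] * r$values[j + 1L] < 0) {
      i <- ends[j] + 1L # index into d2 (sg offset by 1)
      frac <- d2[i] / (d2[i] - d2[i + 1L])
      pos <- c(pos, i - 1 + frac) # 0-based sample coordinate
    }
  }
  if (!length(pos)) {
    stop("no edge detected: second derivative has no zero crossing",
         call. = FALSE)
  }
  d_peak <- abs(pos - (peak - 1))
  d_center <- abs(pos - (n - 1) / 2)
  best <- order(d_peak, d_center)[1L]
  profile$axis_origin + pos[best] * profile$sample_spacing
}

#' Compute the edge shift between matching Reference and Test profiles
#'
#' `shift = POI(test) - POI(ref)` in cm along the channel's long axis,
#' signed in the +axis direction (+x = patient left for horizontal
#' channels, +y = patient inferior for vertical ones).
#'
#' @param ref_profile,test_profile [intensity_profile()] objects from the
#'   same channel geometry.
#' @param smoothing_sigma,edge_frac Passed to [detect_poi()].
#' @param max_shift Plausibility bound (cm); defaults to the channel long
#'   axis implied by the profile length.
#' @return An object of class `edge_shift` with fields `role`, `poi_ref`,
#'   `poi_test`, `shift`.
#' @export
compute_shift <- function(ref_profile, test_profile, smoothing_sigma = 1,
                          edge_frac = 0.5, max_shift = NULL) {
  poi_r <- tryCatch(detect_poi(ref_profile, smoothing_sigma, edge_frac),
                    error = function(e) {
                      stop(sprintf("[%s, reference] %s",
                                   ref_profile$role %||% "NC?",
                                   conditionMessage(e)), call. = FALSE)
                    })
  poi_t <- tryCatch(detect_poi(test_profile, smoothing_sigma, edge_frac),
                    error = function(e) {
                      stop(sprintf("[%s, test] %s",
                                   test_profile$role %||% "NC?",
                                   conditionMessage(e)), call. = FALSE)
                    })
  shift <- poi_t - poi_r
  if (is.null(max_shift)) {
    max_shift <- length(ref_profile$samples) * ref_profile$sample_spacing
  }
  if (abs(shift) > max_shift) {
    stop(sprintf("[%s] implausible edge shift %.2f cm (> channel length %.2f cm)",
                 ref_profile$role %||% "NC?", shift, max_shift), call. = FALSE)
  }
  structure(list(role = ref_profile$role, poi_ref = poi_r, poi_test = poi_t,
                 shift = shift),
            class = "edge_shift")
}

#' @export
print.edge_shift <- function(x, ...) {
  cat(sprintf("<edge_shift> %s: POI %.3f -> %.3f cm (shift %+.3f cm)\n",
              x$role %||% "NC?", x$poi_ref, x$poi_test, x$shift))
  invisible(x)
}

#' Suggest channel anchors from a heart contour
#'
#' Convenience for phantom studies and the fixtures command: derives the six
#' anchor points a user would click from the supplied heart contour -
#' extremal lateral points of the inferior/superior halves for NC1-NC4 and
#' the inferior-most/superior-most contour points for NC6/NC5. This is not
#' anatomy detection: the contour itself is user-supplied input.
#'
#' @param drr A [drr_image()] with a `heart_contour`.
#' @return 6 x 2 matrix of anchors (rows NC1..NC6).
#' @export
suggest_anchors <- function(drr) {
  stopifnot(inherits(drr, "drr_image"))
  ct <- drr$heart_contour
  if (is.null(ct)) stop("image has no heart contour", call. = FALSE)
  ymid <- mean(range(ct[, 2]))
  lower <- ct[ct[, 2] >= ymid, , drop = FALSE] # inferior half (+y inferior)
  upper <- ct[ct[, 2] < ymid, , drop = FALSE]
  rbind(
    NC1 = lower[which.min(lower[, 1]), ], # lower right (patient right = -x)
    NC2 = lower[which.max(lower[, 1]), ], # lower left
    NC3 = upper[which.min(upper[, 1]), ], # upper right
    NC4 = upper[which.max(upper[, 1]), ], # upper left
    NC5 = ct[which.min(ct[, 2]), ],       # superior edge
    NC6 = ct[which.max(ct[, 2]), ])       # inferior edge
}
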