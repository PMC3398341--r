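# DRR projection and 2D image alignment.
#
# Projection is parallel (anterior view, integration along +z): both images
# of a pair are normalized to the same magnification before any measurement,
# so only relative geometry matters. The source-to-axis distance of a
# divergent geometry is retained as metadata only.

#' Construct a CT attenuation volume
#'
#' @param grid 3D numeric array of relative linear attenuation.
#' @param spacing Voxel spacing (cm), default the planning-CT grid
#'   `c(0.1, 0.1, 0.3)`.
#' @param origin World position (cm) of the grid corner.
#' @param sad Source-to-axis distance metadata (cm, default 100; not used by
#'   the parallel projector).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(grid, spacing = c(0.1, 0.1, 0.3), origin = c(0, 0, 0),
                      sad = 100) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  if (any(!is.finite(grid))) stop("CT grid must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin),
                 sad = sad),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels @ %s cm\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Construct a 2D projected radiograph (DRR) image
#'
#' Rows run along +y (patient inferior), columns along +x (patient left).
#' World mapping: the center of pixel `(row r, col c)` sits at
#' `origin2d + (c - 1/2, r - 1/2) * pixel_spacing`.
#'
#' @param pixels Numeric matrix (rows = y, cols = x).
#' @param pixel_spacing Length-2 positive numeric `(px, py)` in cm.
#' @param origin2d World (x, y) of the image corner (cm).
#' @param isocenter_px Optional `(col, row)` isocenter pixel.
#' @param heart_contour Optional simple closed polygon, K x 2 matrix (cm).
#' @param landmarks Optional named list of 2D points (cm) such as
#'   `sternal_notch`, `T6_spinous`, `T8_spinous`.
#' @param subject_id,group_label Optional cohort metadata.
#' @param sad Magnification metadata (cm).
#' @return An object of class `drr_image`.
#' @export
drr_image <- function(pixels, pixel_spacing, origin2d = c(0, 0),
                      isocenter_px = NULL, heart_contour = NULL,
                      landmarks = list(), subject_id = NULL,
                      group_label = NULL, sad = 100) {
  pixels <- as.matrix(pixels)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    stop("`pixel_spacing` must be 2 positive numbers (cm)", call. = FALSE)
  }
  if (!is.null(heart_contour)) {
    heart_contour <- as.matrix(heart_contour)
    if (ncol(heart_contour) != 2L || nrow(heart_contour) < 3L) {
      stop("`heart_contour` must be a K x 2 polygon with K >= 3", call. = FALSE)
    }
  }
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 origin2d = as.numeric(origin2d), isocenter_px = isocenter_px,
                 heart_contour = heart_contour, landmarks = landmarks,
                 subject_id = subject_id, group_label = group_label, sad = sad),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image> %d x %d px @ %s cm%s%s\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(format(x$pixel_spacing), collapse = "x"),
              if (!is.null(x$heart_contour)) ", heart contour" else "",
              if (length(x$landmarks)) sprintf(", %d landmarks", length(x$landmarks)) else ""))
  invisible(x)
}

# World (x, y) centers of DRR pixel columns / rows.
drr_px_centers <- function(drr) {
  list(x = drr$origin2d[1] + (seq_len(ncol(drr$pixels)) - 0.5) * drr$pixel_spacing[1],
       y = drr$origin2d[2] + (seq_len(nrow(drr$pixels)) - 0.5) * drr$pixel_spacing[2])
}

#' Render an anterior DRR from a CT volume
#'
#' Parallel projection: `pixel(r, c) = sum_k grid[c, r, k] * sz`, i.e. the
#' attenuation line integral along the anterior-posterior (+z) column. If a
#' heart mask is supplied (or present as an attribute of a phantom CT), the
#' silhouette boundary of its z-projection is attached as `heart_contour`;
#' landmark and row-height attributes of phantom CTs are carried across.
#'
#' @param ct A [ct_volume()].
#' @param heart_mask Optional [binary_mask()] on the CT grid.
#' @param subject_id,group_label Optional metadata copied onto the image.
#' @param isocenter Optional world (x, y) isocenter; stored as a pixel
#'   coordinate (the crosshair linkage between the 2D image and the 3D map).
#' @return A [drr_image()].
#' @export
render_drr <- function(ct, heart_mask = attr(ct, "heart_mask"),
                       subject_id = NULL,
                       group_label = attr(ct, "group_label"),
                       isocenter = NULL) {
  stopifnot(inherits(ct, "ct_volume"))
  if (length(ct$grid) == 0L || all(dim(ct$grid) == 0L)) {
    stop("empty CT volume", call. = FALSE)
  }
  sums <- rowSums(ct$grid, dims = 2L) * ct$spacing[3] # x-by-y matrix
  pixels <- t(sums) # rows = y, cols = x
  contour <- NULL
  if (!is.null(heart_mask)) {
    stopifnot(inherits(heart_mask, "binary_mask"))
    if (!identical(dim(heart_mask$grid)[1:2], dim(ct$grid)[1:2])) {
      stop("heart mask grid does not match the CT grid", call. = FALSE)
    }
    sil <- rowSums(heart_mask$grid, dims = 2L) > 0 # x-by-y silhouette
    xs <- heart_mask$origin[1] + (seq_len(dim(sil)[1]) - 0.5) * heart_mask$spacing[1]
    ys <- heart_mask$origin[2] + (seq_len(dim(sil)[2]) - 0.5) * heart_mask$spacing[2]
    cl <- grDevices::contourLines(xs, ys, sil * 1, levels = 0.5)
    if (length(cl)) {
      best <- which.max(vapply(cl, function(l) length(l$x), numeric(1)))
      contour <- cbind(cl[[best]]$x, cl[[best]]$y)
    }
  }
  lm <- attr(ct, "landmarks") %||% list()
  iso_px <- NULL
  if (!is.null(isocenter)) {
    iso_px <- c((isocenter[1] - ct$origin[1]) / ct$spacing[1] + 0.5,
                (isocenter[2] - ct$origin[2]) / ct$spacing[2] + 0.5)
  }
  drr <- drr_image(pixels, pixel_spacing = ct$spacing[1:2],
                   origin2d = ct$origin[1:2], isocenter_px = iso_px,
                   heart_contour = contour, landmarks = lm,
                   subject_id = subject_id, group_label = group_label,
                   sad = ct$sad)
  attr(drr, "upper_row_y") <- attr(ct, "upper_row_y")
  attr(drr, "lower_row_y") <- attr(ct, "lower_row_y")
  drr
}

#' Scale a Test image's calibration to the Reference magnification
#'
#' Mirrors the graticule step: the user marks two points a known common
#' distance apart on each image; the Test image's physical calibration is
#' multiplied by `s = dist(ref_pts) / dist(test_pts)` so that 1 cm on the
#' Test image corresponds to 1 cm on the Reference image. Pixel content is
#' untouched; annotation coordinates are re-derived under the new
#' calibration.
#'
#' @param test,ref [drr_image()] objects.
#' @param ref_pts,test_pts 2 x 2 matrices (two 2D points each, cm).
#' @return The recalibrated Test [drr_image()], with attribute `scale`.
#' @export
scale_to_reference <- function(test, ref, ref_pts, test_pts) {
  stopifnot(inherits(test, "drr_image"), inherits(ref, "drr_image"))
  ref_pts <- as.matrix(ref_pts); test_pts <- as.matrix(test_pts)
  d_ref <- sqrt(sum((ref_pts[1, ] - ref_pts[2, ])^2))
  d_test <- sqrt(sum((test_pts[1, ] - test_pts[2, ])^2))
  if (d_ref <= max(ref$pixel_spacing) || d_test <= max(test$pixel_spacing)) {
    stop("degenerate calibration: graticule points closer than one pixel",
         call. = FALSE)
  }
  s <- d_ref / d_test
  to_px <- function(p) cbind((p[, 1] - test$origin2d[1]) / test$pixel_spacing[1],
                             (p[, 2] - test$origin2d[2]) / test$pixel_spacing[2])
  out <- test
  out$pixel_spacing <- test$pixel_spacing * s
  from_px <- function(px) cbind(out$origin2d[1] + px[, 1] * out$pixel_spacing[1],
                                out$origin2d[2] + px[, 2] * out$pixel_spacing[2])
  if (!is.null(test$heart_contour)) {
    out$heart_contour <- from_px(to_px(test$heart_contour))
  }
  if (length(test$landmarks)) {
    out$landmarks <- lapply(test$landmarks, function(p) {
      drop(from_px(to_px(matrix(p, 1))))
    })
  }
  attr(out, "scale") <- s
  out
}

#' Landmark names used for rigid 2D alignment
#' @return Character vector of the three default bony landmark names.
#' @export
alignment_landmarks <- function() c("sternal_notch", "T6_spinous", "T8_spinous")

#' Rigid (translation-only) 2D alignment of a Test image to a Reference
#'
#' Least-squares translation matching the named bony landmarks (mid sternal
#' notch and the T6/T8 spinous processes): `translation = mean(ref) -
#' mean(test)`, the closed-form minimizer of the summed squared landmark
#' residual over translations. Rotation is fixed at zero: the three
#' landmarks are nearly collinear along the midline, which makes a fitted
#' rotation ill-conditioned (documented limitation).
#'
#' @param ref,test [drr_image()] objects carrying the named landmarks.
#' @param names Landmark names to use (default [alignment_landmarks()]).
#' @return An object of class `rigid_2d`: list with `translation` (cm).
#' @export
rigid_align_2d <- function(ref, test, names = alignment_landmarks()) {
  get_pts <- function(img, who) {
    missing <- setdiff(names, names(img$landmarks))
    if (length(missing)) {
      stop(sprintf("%s image is missing landmark(s): %s", who,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    do.call(rbind, img$landmarks[names])
  }
  pr <- get_pts(ref, "reference")
  pt <- get_pts(test, "test")
  structure(list(translation = colMeans(pr) - colMeans(pt), rotation = 0),
            class = "rigid_2d")
}

#' Apply a rigid 2D transform to a DRR
#'
#' Shifts the image's world calibration (origin) and all annotations by the
#' translation; pixel content is untouched.
#'
#' @param drr A [drr_image()].
#' @param rigid A `rigid_2d` from [rigid_align_2d()].
#' @return The transformed [drr_image()].
#' @export
apply_rigid_2d <- function(drr, rigid) {
  stopifnot(inherits(drr, "drr_image"), inherits(rigid, "rigid_2d"))
  tr <- rigid$translation
  drr$origin2d <- drr$origin2d + tr
  if (!is.null(drr$heart_contour)) {
    drr$heart_contour <- sweep(drr$heart_contour, 2, tr, `+`)
  }
  if (length(drr$landmarks)) {
    drr$landmarks <- lapply(drr$landmarks, function(p) p + tr)
  }
  drr
}
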