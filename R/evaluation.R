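# Reconstruction accuracy: Dice volume overlap and cohort statistics.

#' Dice volume overlap of two heart volumes
#'
#' `dice_pct = 2 |A .and. B| / (|A| + |B|) * 100` on voxel counts. Mesh
#' inputs are voxelized onto a shared grid covering both; with
#' `com_align = TRUE` (the default, matching how reconstructed models are
#' compared to ground truth) the first input is first rigidly translated so
#' the two centers of mass coincide - exact volume centroids for meshes,
#' nearest-voxel COM shift for masks on a common grid. Turn it off for
#' free-breathing-style inhale/exhale comparisons, where the positional
#' difference is part of what is being measured.
#'
#' @param a,b [binary_mask()] objects on identical grids, or closed
#'   [surface_mesh()] objects.
#' @param com_align Align centers of mass first (default TRUE).
#' @param spacing Evaluation grid spacing for mesh inputs (cm, default
#'   0.2 isotropic; pass `c(0.1, 0.1, 0.3)` for the planning-CT grid).
#' @return An object of class `dice_result`: `dice_pct`, `volume1`,
#'   `volume2`, `intersection` (cm^3), `grid_spacing`.
#' @export
dice <- function(a, b, com_align = TRUE, spacing = c(0.2, 0.2, 0.2)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (inherits(a, "surface_mesh") && inherits(b, "surface_mesh")) {
    if (com_align) {
      tr <- mesh_centroid(b) - mesh_centroid(a)
      a <- surface_mesh(sweep(a$vertices, 2, tr, `+`), a$triangles,
                        validate = FALSE)
    }
    lo <- pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min)) - spacing
    hi <- pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max)) + spacing
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
    ga <- voxelize_on_grid(a, dims, spacing, lo)$grid
    gb <- voxelize_on_grid(b, dims, spacing, lo)$grid
  } else if (inherits(a, "binary_mask") && inherits(b, "binary_mask")) {
    if (!identical(dim(a$grid), dim(b$grid)) ||
        !isTRUE(all.equal(a$spacing, b$spacing))) {
      stop("mask inputs must share one grid", call. = FALSE)
    }
    spacing <- a$spacing
    ga <- a$grid; gb <- b$grid
    if (com_align && any(ga) && any(gb)) {
      shift <- round(mask_com_vox(gb) - mask_com_vox(ga))
      ga <- shift_grid(ga, as.integer(shift))
    }
  } else {
    stop("`a` and `b` must both be binary masks or both surface meshes",
         call. = FALSE)
  }
  na <- sum(ga); nb <- sum(gb)
  if (na + nb == 0L) stop("Dice undefined: both volumes are empty", call. = FALSE)
  ni <- sum(ga & gb)
  vox <- prod(spacing)
  structure(list(dice_pct = 2 * ni / (na + nb) * 100,
                 volume1 = na * vox, volume2 = nb * vox,
                 intersection = ni * vox, grid_spacing = spacing),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> %.1f%% (V1 %.1f, V2 %.1f, V1^V2 %.1f cm^3)\n",
              x$dice_pct, x$volume1, x$volume2, x$intersection))
  invisible(x)
}

# Exact volume centroid of a closed mesh (divergence theorem over the
# origin-apex tetrahedron decomposition).
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 2], , drop = FALSE]
  cc <- v[mesh$triangles[, 3], , drop = FALSE]
  vol6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
    a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  ctr <- (a + b + cc) / 4 # tetra centroid (apex at origin contributes 0)
  colSums(ctr * vol6) / sum(vol6)
}

mask_com_vox <- function(g) {
  idx <- which(g, arr.ind = TRUE)
  colMeans(idx)
}

shift_grid <- function(g, shift) {
  d <- dim(g)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - shift[ax]
    i[i >= 1L & i <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] + shift[ax])
  if (any(lengths(src) == 0L)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- g[src[[1]], src[[2]], src[[3]]]
  out
}

#' Paired Student t-test (textbook form)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, with a
#' two-sided p from the t distribution on `n - 1` degrees of freedom.
#' Implemented directly so it can be cross-checked against `stats::t.test`
#' as an independent oracle.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0))
    stop("degenerate paired test: differences have zero variance", call. = FALSE)
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       mean_diff = mean(d))
}

#' Summarize a cohort of Dice results
#'
#' @param cohort Numeric vector of Dice percentages, or a list of
#'   [dice()] results.
#' @return An object of class `cohort_summary`: `values`, `avg`, `min`,
#'   `max`, `sd` (sample SD, n-1; 0 by convention for a single value).
#' @export
summarize_cohort <- function(cohort) {
  if (is.list(cohort)) {
    cohort <- vapply(cohort, function(x) {
      if (inherits(x, "dice_result")) x$dice_pct else as.numeric(x)
    }, numeric(1))
  }
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  structure(list(values = cohort, avg = mean(cohort), min = min(cohort),
                 max = max(cohort),
                 sd = if (length(cohort) > 1L) stats::sd(cohort) else 0),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n=%d avg %.1f min %.1f max %.1f sd %.1f\n",
              length(x$values), x$avg, x$min, x$max, x$sd))
  invisible(x)
}
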