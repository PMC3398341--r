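# Deterministic synthetic thorax/heart phantoms.
#
# The generators state a small world in which every downstream stage is
# testable with known ground truth: a heart is a superellipsoid with four
# Gaussian radial bulges at the lateral circumflex positions (where the four
# horizontal navigator channels sit), embedded in an elliptical-cylinder
# thorax with rib arcs at two vertebral-analog rows, a posterior spine
# column, and relative linear attenuations (bone 3, heart 1.5, soft tissue
# 1, air 0). All generators are pure functions of their parameter records.

#' Parameters of a synthetic heart
#'
#' @param semi_axes Length-3 positive numeric, base ellipsoid semi-axes
#'   (a, b, c) in cm along (x, y, z).
#' @param lobe_amplitudes Length-4 non-negative numeric (cm): radial bulge
#'   amplitudes at the four lateral chamber positions, ordered
#'   (lower-right, lower-left, upper-right, upper-left) to mirror channels
#'   NC1-NC4.
#' @param center Length-3 numeric, heart center (cm, patient frame).
#' @param roughness Amplitude (cm) of a smooth seeded random radial
#'   perturbation (default 0: fully deterministic regardless of seed).
#' @param seed Integer seed; same parameters imply a bit-identical mesh.
#' @param n_theta,n_phi Mesh resolution (latitude rings, longitude segments).
#' @return An object of class `heart_phantom_params`.
#' @export
heart_phantom_params <- function(semi_axes = c(5.0, 6.0, 4.2),
                                 lobe_amplitudes = c(0.8, 1.0, 0.5, 0.6),
                                 center = c(0, 0, 0),
                                 roughness = 0,
                                 seed = 1L,
                                 n_theta = 24L, n_phi = 32L) {
  semi_axes <- as.numeric(semi_axes)
  lobe_amplitudes <- as.numeric(lobe_amplitudes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("`semi_axes` must be 3 positive numbers (cm)", call. = FALSE)
  }
  if (length(lobe_amplitudes) != 4L || any(lobe_amplitudes < 0)) {
    stop("`lobe_amplitudes` must be 4 non-negative numbers (cm)", call. = FALSE)
  }
  structure(list(semi_axes = semi_axes, lobe_amplitudes = lobe_amplitudes,
                 center = as.numeric(center), roughness = roughness,
                 seed = as.integer(seed),
                 n_theta = as.integer(n_theta), n_phi = as.integer(n_phi)),
            class = "heart_phantom_params")
}

# Unit directions of the four circumflex bulges (patient frame: +x left,
# +y inferior): lower-right, lower-left, upper-right, upper-left.
.lobe_dirs <- local({
  d <- rbind(c(-1, 0.6, 0), c(1, 0.6, 0), c(-1, -0.6, 0), c(1, -0.6, 0))
  d / sqrt(rowSums(d^2))
})

#' Generate a synthetic heart surface mesh
#'
#' Closed UV-sphere-parameterized surface: an ellipsoid whose radius is
#' modulated by four Gaussian angular bulges (one per chamber circumflex) and
#' an optional smooth seeded roughness field. With all lobe amplitudes at 0
#' the enclosed volume is within 10% of the analytic ellipsoid volume
#' `4/3*pi*a*b*c` (the discretization underestimates slightly).
#'
#' @param params A [heart_phantom_params()].
#' @return A closed [surface_mesh()].
#' @export
generate_heart <- function(params) {
  stopifnot(inherits(params, "heart_phantom_params"))
  nt <- params$n_theta; np <- params$n_phi
  theta <- seq(0, pi, length.out = nt + 1L)[2:nt] # interior rings
  phi <- seq(0, 2 * pi, length.out = np + 1L)[seq_len(np)]
  th <- rep(theta, each = np)
  ph <- rep(phi, times = nt - 1L)
  # theta measured from the superior pole (-y)
  u <- cbind(sin(th) * cos(ph), -cos(th), sin(th) * sin(ph))
  scale <- rep(1, length(th))
  for (i in 1:4) {
    ang <- acos(pmin(1, pmax(-1, u %*% .lobe_dirs[i, ])))
    scale <- scale + (params$lobe_amplitudes[i] / max(params$semi_axes)) *
      exp(-ang^2 / (2 * 0.45^2))
  }
  if (params$roughness > 0) {
    set.seed(params$seed)
    # smooth random field: low-order trigonometric series in (theta, phi)
    co <- matrix(stats::rnorm(12, sd = params$roughness), 4, 3)
    r <- rep(0, length(th))
    for (m in 1:4) {
      r <- r + co[m, 1] * sin(m * th) +
        co[m, 2] * sin(m * ph) * sin(th) + co[m, 3] * cos(m * ph) * sin(th)
    }
    scale <- scale + r / max(params$semi_axes)
  }
  ring_v <- sweep(u, 2, params$semi_axes, `*`) * scale
  pole_s <- c(1, 1) # poles unaffected by lateral lobes (exp(-ang^2) ~ 0)
  v_sup <- c(0, -params$semi_axes[2], 0) * pole_s[1]
  v_inf <- c(0, params$semi_axes[2], 0) * pole_s[2]
  verts <- rbind(v_sup, ring_v, v_inf)
  verts <- sweep(verts, 2, params$center, `+`)
  rownames(verts) <- NULL
  idx <- function(i, j) 1L + (i - 1L) * np + ((j - 1L) %% np) + 1L # ring i, seg j
  n_inf <- nrow(verts)
  tris <- vector("list", 3L)
  j <- seq_len(np)
  tris[[1]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L)) # superior fan
  if (nt > 2L) {
    strips <- lapply(seq_len(nt - 2L), function(i) {
      rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
            cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    })
    tris[[2]] <- do.call(rbind, strips)
  }
  tris[[3]] <- cbind(n_inf, idx(nt - 1L, j + 1L), idx(nt - 1L, j)) # inferior fan
  mesh <- surface_mesh(verts, do.call(rbind, tris), validate = FALSE)
  if (mesh_volume(mesh) < 0) { # enforce outward orientation
    mesh$triangles <- mesh$triangles[, c(1L, 3L, 2L)]
  }
  mesh
}

#' Parameters of a synthetic thorax CT
#'
#' `W1`/`W2` are the inner-rib horizontal gaps at the upper (T2/T3 analog)
#' and lower (T9/T10 analog) rows; `L` is the vertical distance between the
#' rows. Attenuations are unitless relative linear attenuation (no beam
#' physics): the defaults give bony edges and a visible heart edge on the
#' projected radiograph.
#'
#' @param W1,W2,L Thorax measurements in cm (all > 0).
#' @param rib_attenuation,soft_tissue_attenuation,heart_attenuation Relative
#'   attenuations; `heart_attenuation` must exceed the soft-tissue background
#'   for a heart edge to exist on the DRR.
#' @param group_label Categorical cohort label (e.g. "M"/"F").
#' @param noise_sd Additive Gaussian CT noise (default 0 = off).
#' @param seed Integer seed (only consumed when `noise_sd > 0`).
#' @param depth Anteroposterior body depth (cm).
#' @param rib_thickness Lateral rib thickness (cm).
#' @return An object of class `thorax_phantom_params`.
#' @export
thorax_phantom_params <- function(W1 = 15.0, W2 = 24.8, L = 14.3,
                                  rib_attenuation = 3,
                                  soft_tissue_attenuation = 1,
                                  heart_attenuation = 1.5,
                                  group_label = "M",
                                  noise_sd = 0, seed = 1L,
                                  depth = 15, rib_thickness = 1.2) {
  if (any(c(W1, W2, L) <= 0)) stop("W1, W2, L must be positive", call. = FALSE)
  if (any(c(rib_attenuation, soft_tissue_attenuation, heart_attenuation) < 0)) {
    stop("attenuations must be non-negative", call. = FALSE)
  }
  if (heart_attenuation <= soft_tissue_attenuation) {
    warning("heart_attenuation <= soft tissue: no heart edge will exist on the DRR")
  }
  structure(list(W1 = W1, W2 = W2, L = L,
                 rib_attenuation = rib_attenuation,
                 soft_tissue_attenuation = soft_tissue_attenuation,
                 heart_attenuation = heart_attenuation,
                 group_label = group_label, noise_sd = noise_sd,
                 seed = as.integer(seed), depth = depth,
                 rib_thickness = rib_thickness),
            class = "thorax_phantom_params")
}

#' Generate a synthetic thorax CT volume around a heart mesh
#'
#' Builds, on a regular grid: an elliptical-cylinder soft-tissue body whose
#' half-width interpolates linearly between the two rib rows, lateral rib
#' blocks at the upper/lower rows with inner borders at `+/- W1/2` and
#' `+/- W2/2` (snapped to the voxel lattice, so the constructed inner gap is
#' exact to one voxel), a posterior spine column, and the voxelized heart.
#' Landmark points for rigid 2D alignment (sternal notch, T6/T8 spinous
#' analogs) and the two row heights are attached as attributes, along with
#' the heart [binary_mask()].
#'
#' @param thorax A [thorax_phantom_params()].
#' @param heart A closed [surface_mesh()]; must fit inside the body outline
#'   with margin.
#' @param spacing CT voxel spacing in cm (default the planning-CT grid
#'   `c(0.1, 0.1, 0.3)`; tests use coarser grids for speed).
#' @return A [ct_volume()] with attributes `upper_row_y`, `lower_row_y`,
#'   `heart_mask`, `landmarks`, `group_label`.
#' @export
generate_thorax_ct <- function(thorax, heart, spacing = c(0.1, 0.1, 0.3)) {
  stopifnot(inherits(thorax, "thorax_phantom_params"),
            inherits(heart, "surface_mesh"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  rib_t <- thorax$rib_thickness
  soft_margin <- 1.5
  a1 <- thorax$W1 / 2 + rib_t + soft_margin
  a2 <- thorax$W2 / 2 + rib_t + soft_margin
  half_x <- max(a1, a2) + 1
  y_margin <- 4
  y_upper <- 0
  y_lower <- thorax$L
  y_lo <- y_upper - y_margin
  y_hi <- y_lower + y_margin
  half_z <- thorax$depth / 2
  origin <- c(-half_x, y_lo, -half_z - 0.5)
  dims <- as.integer(ceiling(c(2 * half_x, y_hi - y_lo, thorax$depth + 1) / spacing))
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  # body half-width a(y): linear between rows, clamped beyond
  ay <- a1 + (a2 - a1) * pmin(1, pmax(0, (yc - y_upper) / (y_lower - y_upper)))
  bz <- half_z
  grid <- array(0, dims)
  # (x / a(y))^2 as an x-by-y matrix
  xa2 <- outer(xc, ay, function(x, a) (x / a)^2)
  for (k in seq_len(dims[3])) {
    body <- xa2 + (zc[k] / bz)^2 <= 1
    grid[, , k] <- body * thorax$soft_tissue_attenuation
  }
  # rib blocks: inner border exactly at +/- W/2 (voxel centers beyond it)
  rib_rows <- list(list(y = y_upper, W = thorax$W1),
                   list(y = y_lower, W = thorax$W2))
  rib_halfheight <- 0.5
  rib_z <- abs(zc) <= 0.8 * half_z
  for (rr in rib_rows) {
    ysel <- abs(yc - rr$y) <= rib_halfheight
    xsel <- abs(xc) >= rr$W / 2 & abs(xc) <= rr$W / 2 + rib_t
    if (any(ysel) && any(xsel)) {
      sub <- grid[xsel, ysel, rib_z, drop = FALSE]
      sub[sub > 0] <- thorax$rib_attenuation # bone only inside the body
      grid[xsel, ysel, rib_z] <- sub
    }
  }
  # spine column: posterior midline bone
  spx <- abs(xc) <= 1.4
  spz <- zc >= 0.35 * half_z & zc <= 0.35 * half_z + 2.5
  grid[spx, , spz] <- thorax$rib_attenuation
  # heart: voxelized on the CT grid, replacing soft tissue only
  hb_lo <- apply(heart$vertices, 2, min)
  hb_hi <- apply(heart$vertices, 2, max)
  amin <- min(a1, a2)
  if (hb_lo[1] < -amin + rib_t + 0.2 || hb_hi[1] > amin - rib_t - 0.2 ||
      hb_lo[2] < y_lo + 1 || hb_hi[2] > y_hi - 1 ||
      hb_lo[3] < -bz + 0.2 || hb_hi[3] > 0.35 * half_z) {
    stop("heart does not fit inside the thorax with margin", call. = FALSE)
  }
  hmask <- voxelize_on_grid(heart, dims, spacing, origin)
  hsel <- hmask$grid & grid > 0 & grid < thorax$rib_attenuation
  grid[hsel] <- thorax$heart_attenuation
  if (thorax$noise_sd > 0) {
    set.seed(thorax$seed)
    grid <- grid + array(stats::rnorm(length(grid), sd = thorax$noise_sd), dims)
  }
  ct <- ct_volume(grid, spacing, origin)
  attr(ct, "upper_row_y") <- y_upper
  attr(ct, "lower_row_y") <- y_lower
  attr(ct, "heart_mask") <- hmask
  attr(ct, "landmarks") <- list(
    sternal_notch = c(0, y_upper + 0.2 * thorax$L),
    T6_spinous = c(0, y_upper + 0.45 * thorax$L),
    T8_spinous = c(0, y_upper + 0.65 * thorax$L))
  attr(ct, "group_label") <- thorax$group_label
  ct
}

#' Ground-truth deformation specification
#'
#' A smooth bijective map of 3D space used to derive a Test heart from a
#' Reference heart with an exactly known per-node displacement field.
#' Types: `"scale"` (about the mesh centroid; `factors`, length 1 or 3),
#' `"translate"` (`offset`, length 3, cm), `"bend"` (lateral shear
#' `x' = x + amplitude * sin(pi * (y - y0) / wavelength)`), and
#' `"composite"` (ordered list of specs).
#'
#' @param type One of `"scale"`, `"translate"`, `"bend"`, `"composite"`.
#' @param ... Per-type parameters (see Details above): `factors`, `offset`,
#'   `amplitude`/`wavelength`, or `specs`.
#' @param seed Integer seed recorded for provenance (the map itself is
#'   deterministic).
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(type = c("scale", "translate", "bend", "composite"),
                             ..., seed = 1L) {
  type <- match.arg(type)
  p <- list(...)
  if (type == "scale") {
    f <- p$factors %||% 1
    if (length(f) == 1L) f <- rep(f, 3L)
    if (any(f <= 0)) stop("scale factors must be positive (bijectivity)", call. = FALSE)
    p$factors <- f
  } else if (type == "translate") {
    p$offset <- as.numeric(p$offset %||% c(0, 0, 0))
    stopifnot(length(p$offset) == 3L)
  } else if (type == "bend") {
    p$amplitude <- p$amplitude %||% 0.5
    p$wavelength <- p$wavelength %||% 20
    if (abs(p$amplitude) * pi / p$wavelength >= 1) {
      stop("bend gradient >= 1: map would not be a bijection on the bbox",
           call. = FALSE)
    }
    p$y0 <- p$y0 %||% 0
  } else {
    if (!length(p$specs)) stop("composite spec needs `specs`", call. = FALSE)
    lapply(p$specs, function(s) stopifnot(inherits(s, "deformation_spec")))
  }
  structure(list(type = type, parameters = p, seed = as.integer(seed)),
            class = "deformation_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a deformation spec at a set of points
#'
#' @param points N x 3 matrix (cm).
#' @param spec A [deformation_spec()].
#' @param center Centroid used by `"scale"` (default the point centroid).
#' @return N x 3 matrix of mapped points.
#' @export
apply_deformation_spec <- function(points, spec, center = NULL) {
  stopifnot(inherits(spec, "deformation_spec"))
  points <- as.matrix(points)
  if (is.null(center)) center <- colMeans(points)
  p <- spec$parameters
  switch(spec$type,
    scale = sweep(sweep(sweep(points, 2, center, `-`), 2, p$factors, `*`),
                  2, center, `+`),
    translate = sweep(points, 2, p$offset, `+`),
    bend = {
      out <- points
      out[, 1] <- out[, 1] +
        p$amplitude * sin(pi * (points[, 2] - p$y0) / p$wavelength)
      out
    },
    composite = {
      out <- points
      for (s in p$specs) out <- apply_deformation_spec(out, s, center = center)
      out
    })
}

#' Generate a matched Reference/Test heart pair with exact ground truth
#'
#' The Test mesh is the Reference mesh mapped through `spec`; the returned
#' field is exactly `test - reference` per node, so
#' `apply_field(reference, true_field)` reproduces the Test mesh to machine
#' precision.
#'
#' @param heart_params A [heart_phantom_params()] for the Reference heart.
#' @param spec A [deformation_spec()].
#' @return List with `reference`, `test` ([surface_mesh()]) and `true_field`
#'   (a [deformation_field()]).
#' @export
generate_deformed_pair <- function(heart_params, spec) {
  reference <- generate_heart(heart_params)
  mapped <- apply_deformation_spec(reference$vertices, spec)
  test <- surface_mesh(mapped, reference$triangles, validate = FALSE)
  list(reference = reference, test = test,
       true_field = deformation_field(mapped - reference$vertices,
                                      source = "reference"))
}
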