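# Voxel-grid and mesh primitives shared by every pipeline stage.
#
# World coordinates are centimetres in a fixed patient frame:
#   +x = patient left, +y = patient inferior, +z = patient posterior.
# Voxel indexing is 0-based in the maths below (1-based in R arrays); the
# world position of the CENTER of voxel (i, j, k) is
#   origin + (i + 1/2, j + 1/2, k + 1/2) * spacing.

#' Fixed patient coordinate frame
#'
#' All world coordinates in the package use one axis convention:
#' `+x` = patient left, `+y` = patient inferior, `+z` = patient posterior,
#' units centimetres. Encoding the frame as a constant makes statements such
#' as "0 is most superior and 1 is most inferior" testable: superior is
#' always the smallest `y`.
#'
#' @return A named list with elements `x`, `y`, `z` (axis meanings) and
#'   `units`.
#' @export
patient_frame <- function() {
  list(x = "patient-left", y = "patient-inferior", z = "patient-posterior",
       units = "cm")
}

#' Construct a 3D binary organ mask
#'
#' A binary mask is the volumetric representation of an organ: a 3D logical
#' voxel grid with physical spacing and a world-space origin (the corner of
#' voxel (0,0,0), in cm).
#'
#' @param grid 3D logical (or coercible) array.
#' @param spacing Numeric length-3, voxel edge lengths in cm (default the
#'   planning-CT grid `c(0.1, 0.1, 0.3)`).
#' @param origin Numeric length-3, world position (cm) of the grid corner.
#' @return An object of class `binary_mask` with fields `grid`, `spacing`,
#'   `origin`.
#' @seealso [mask_volume()], [mask_union()], [mask_to_mesh()]
#' @export
binary_mask <- function(grid, spacing = c(0.1, 0.1, 0.3), origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  if (any(dim(grid) < 1L)) stop("`grid` must be non-empty", call. = FALSE)
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) stop("`grid` must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (cm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (cm)", call. = FALSE)
  }
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels @ %s cm, %d true (%.3f cm^3)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$grid), mask_volume(x)))
  invisible(x)
}

#' Physical volume of a binary mask
#'
#' @param mask A [binary_mask()].
#' @return Volume in cm^3: `count(true) * sx * sy * sz`.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$grid) * prod(mask$spacing)
}

#' Construct a closed triangulated surface mesh
#'
#' Surface meshes carry the "nodes" of all deformation fields: `vertices` are
#' N x 3 world coordinates (cm) and `triangles` are M x 3 1-based vertex
#' indices with consistent outward orientation.
#'
#' @param vertices Numeric N x 3 matrix (cm).
#' @param triangles Integer M x 3 matrix of 1-based vertex indices.
#' @param validate Check closedness/orientation invariants (default TRUE;
#'   internal constructors that build provably closed meshes skip it).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L || ncol(triangles) != 3L) {
    stop("`vertices` and `triangles` must have 3 columns", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle index out of range", call. = FALSE)
  }
  m <- structure(list(vertices = vertices, triangles = triangles),
                 class = "surface_mesh")
  if (validate) validate_surface_mesh(m)
  m
}

#' Validate surface-mesh invariants
#'
#' Checks that every vertex is referenced, every edge is shared by exactly
#' two triangles (watertightness), and no triangle has (near-)zero area.
#'
#' @param mesh A [surface_mesh()].
#' @return `mesh`, invisibly; errors describe the violated invariant.
#' @export
validate_surface_mesh <- function(mesh) {
  tr <- mesh$triangles
  if (!all(seq_len(nrow(mesh$vertices)) %in% tr)) {
    stop("mesh has unreferenced vertices", call. = FALSE)
  }
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) {
    stop(sprintf("mesh is not closed: %d edge(s) not shared by exactly 2 triangles",
                 sum(cnt != 2L)), call. = FALSE)
  }
  # Consistent orientation: each undirected edge must appear once per direction
  dkey <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dkey)) {
    stop("mesh orientation inconsistent: repeated directed edge", call. = FALSE)
  }
  a <- tri_areas(mesh)
  if (any(a <= 1e-14)) stop("mesh contains zero-area triangle(s)", call. = FALSE)
  invisible(mesh)
}

tri_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  u <- v[mesh$triangles[, 2], , drop = FALSE] - t1
  w <- v[mesh$triangles[, 3], , drop = FALSE] - t1
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, volume %.3f cm^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' Signed sum of tetrahedron volumes against the origin; positive for the
#' package's outward orientation convention.
#'
#' @param mesh A [surface_mesh()].
#' @return Enclosed volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 2], , drop = FALSE]
  cc <- v[mesh$triangles[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Construct a per-node deformation field
#'
#' Displacement vectors (cm), index-aligned with the vertices of a source
#' mesh. This is the container for both the population-to-reference map and
#' the adapted population-to-test map.
#'
#' @param displacements Numeric N x 3 matrix (cm).
#' @param source Optional name of the source mesh (provenance only).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, source = NULL) {
  displacements <- as.matrix(displacements)
  storage.mode(displacements) <- "double"
  dimnames(displacements) <- NULL
  if (ncol(displacements) != 3L) stop("displacements must be N x 3", call. = FALSE)
  if (any(!is.finite(displacements))) stop("non-finite displacement", call. = FALSE)
  structure(list(displacements = displacements, source = source),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("<deformation_field> %d nodes, |d| mean %.3f max %.3f cm\n",
              nrow(x$displacements), mean(mag), max(mag)))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Union of binary masks (logical OR)
#'
#' Combines co-registered organ masks voxelwise; this is how the population
#' heart model's volumetric support is built from several patients' masks.
#'
#' @param masks List of [binary_mask()] objects on identical grids.
#' @return A [binary_mask()]: voxel true iff true in any input.
#' @export
mask_union <- function(masks) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  if (length(masks) < 1L) stop("need at least one mask", call. = FALSE)
  ref <- masks[[1L]]
  for (m in masks) {
    stopifnot(inherits(m, "binary_mask"))
    if (!identical(dim(m$grid), dim(ref$grid)) ||
        !isTRUE(all.equal(m$spacing, ref$spacing)) ||
        !isTRUE(all.equal(m$origin, ref$origin))) {
      stop("mask grids are incompatible (shape/spacing/origin mismatch)",
           call. = FALSE)
    }
  }
  g <- Reduce(`|`, lapply(masks, `[[`, "grid"))
  binary_mask(g, ref$spacing, ref$origin)
}

# Face tables for the cuberille extractor. For each of the 6 outward
# directions: the 4 corner offsets (in corner-lattice units, added to the
# voxel's base corner) of the boundary quad, ordered so the two triangles
# (1,2,3) and (1,3,4) have outward normals.
.face_corners <- list(
  xm = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
  xp = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
  ym = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
  yp = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
  zm = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)),
  zp = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
)

#' Extract a closed surface mesh from a binary mask
#'
#' Watertight boundary-face ("cuberille") extraction: every face between a
#' true voxel and a false/outside voxel contributes two consistently
#' oriented triangles. With `smoothing_iters = 0` the enclosed volume equals
#' the mask volume exactly; light Laplacian smoothing rounds the staircase at
#' the cost of a small, documented shrink.
#'
#' @param mask A [binary_mask()] with at least one true voxel forming a
#'   single face-connected component.
#' @param smoothing_iters Number of Laplacian smoothing passes (default 0).
#' @param lambda Smoothing step in (0, 1] (default 0.5).
#' @return A closed, outward-oriented [surface_mesh()].
#' @export
mask_to_mesh <- function(mask, smoothing_iters = 0L, lambda = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  if (!any(g)) stop("mask is empty: no surface to extract", call. = FALSE)
  g <- resolve_checkerboards(g)
  ncomp <- count_components(g)
  if (ncomp > 1L) {
    stop(sprintf("mask has %d connected components; expected exactly 1", ncomp),
         call. = FALSE)
  }
  d <- dim(g)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- g
  idx <- which(g, arr.ind = TRUE) # 1-based voxel indices
  pidx <- idx + 1L
  nbr <- function(off) pad[cbind(pidx[, 1] + off[1], pidx[, 2] + off[2],
                                 pidx[, 3] + off[3])]
  offs <- list(xm = c(-1L, 0L, 0L), xp = c(1L, 0L, 0L),
               ym = c(0L, -1L, 0L), yp = c(0L, 1L, 0L),
               zm = c(0L, 0L, -1L), zp = c(0L, 0L, 1L))
  corner_dim <- d + 1L
  tri_keys <- vector("list", 6L)
  for (f in seq_along(offs)) {
    face <- names(offs)[f]
    open <- !nbr(offs[[face]])
    if (!any(open)) next
    base <- idx[open, , drop = FALSE] - 1L # 0-based voxel corner
    fc <- .face_corners[[face]]
    # corner-lattice linear key for each of the 4 quad corners
    keys <- sapply(1:4, function(q) {
      ci <- base[, 1] + fc[q, 1]; cj <- base[, 2] + fc[q, 2]
      ck <- base[, 3] + fc[q, 3]
      ci + corner_dim[1] * (cj + corner_dim[2] * ck)
    })
    if (is.null(dim(keys))) keys <- matrix(keys, nrow = 1L)
    tri_keys[[f]] <- rbind(cbind(keys[, 1], keys[, 2], keys[, 3]),
                           cbind(keys[, 1], keys[, 3], keys[, 4]))
  }
  tri_key <- do.call(rbind, tri_keys)
  ukeys <- sort(unique(as.vector(tri_key)))
  tri <- matrix(match(as.vector(tri_key), ukeys), ncol = 3L)
  ci <- ukeys %% corner_dim[1]
  rest <- ukeys %/% corner_dim[1]
  cj <- rest %% corner_dim[2]
  ck <- rest %/% corner_dim[2]
  verts <- cbind(mask$origin[1] + ci * mask$spacing[1],
                 mask$origin[2] + cj * mask$spacing[2],
                 mask$origin[3] + ck * mask$spacing[3])
  mesh <- surface_mesh(verts, tri, validate = FALSE)
  if (smoothing_iters > 0L) mesh <- smooth_mesh(mesh, smoothing_iters, lambda)
  mesh
}

# Two voxels sharing only an edge (a 2D checkerboard in any axis plane)
# would make that lattice edge borders of four boundary faces - a
# non-manifold, non-closed surface. Fill one voxel of each such pair
# (adding material, which preserves the encompassing property of union
# models) until the configuration is gone.
resolve_checkerboards <- function(g) {
  for (pass in 1:10) {
    changed <- FALSE
    for (perm in list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))) {
      h <- aperm(g, perm)
      d <- dim(h)
      if (d[1] < 2L || d[2] < 2L) next
      A <- h[-d[1], -d[2], , drop = FALSE] # (i,   j)
      B <- h[-1L, -1L, , drop = FALSE]     # (i+1, j+1)
      C <- h[-1L, -d[2], , drop = FALSE]   # (i+1, j)
      D <- h[-d[1], -1L, , drop = FALSE]   # (i,   j+1)
      f1 <- A & B & !C & !D
      f2 <- C & D & !A & !B
      if (any(f1) || any(f2)) {
        changed <- TRUE
        C[f1] <- TRUE
        h[-1L, -d[2], ] <- C
        A2 <- h[-d[1], -d[2], , drop = FALSE]
        A2[f2] <- TRUE
        h[-d[1], -d[2], ] <- A2
        g <- aperm(h, order(perm))
      }
    }
    if (!changed) break
  }
  g
}

# Laplacian smoothing toward the neighbour average (umbrella operator).
smooth_mesh <- function(mesh, iters, lambda = 0.5) {
  nb <- vertex_neighbors(mesh)
  v <- mesh$vertices
  for (it in seq_len(iters)) {
    avg <- rowsum(v[nb$to, , drop = FALSE], nb$from) / nb$deg
    v <- (1 - lambda) * v + lambda * avg
  }
  surface_mesh(v, mesh$triangles, validate = FALSE)
}

# Undirected neighbour lists as flat from/to index vectors.
vertex_neighbors <- function(mesh) {
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3], tr[, 1])
  to <- c(tr[, 2], tr[, 1], tr[, 3], tr[, 2], tr[, 1], tr[, 3])
  key <- paste(from, to)
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  o <- order(from)
  from <- from[o]; to <- to[o]
  list(from = from, to = to, deg = as.vector(table(from)))
}

# Face-connected (6-neighbour) component count via flood fill.
count_components <- function(g) {
  d <- dim(g)
  lin <- which(g)
  if (!length(lin)) return(0L)
  seen <- logical(length(g))
  comps <- 0L
  nx <- d[1]; nxy <- d[1] * d[2]
  for (s in lin) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ar <- arrayInd(cur, d)
      for (off in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                       c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        n <- sweep(ar, 2, off, `+`)
        ok <- n[, 1] >= 1 & n[, 1] <= d[1] & n[, 2] >= 1 & n[, 2] <= d[2] &
          n[, 3] >= 1 & n[, 3] <= d[3]
        if (!any(ok)) next
        nl <- n[ok, 1] + (n[ok, 2] - 1L) * nx + (n[ok, 3] - 1L) * nxy
        nl <- nl[g[nl] & !seen[nl]]
        if (length(nl)) {
          nl <- unique(nl)
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
  }
  comps
}

#' Voxelize a closed mesh into a binary mask
#'
#' Inside/outside decided by ray-casting parity along +x from each voxel
#' center; rays that graze a triangle edge are deterministically offset by
#' `half-voxel * 1e-3` and recast, so counts are reproducible.
#'
#' @param mesh A closed [surface_mesh()].
#' @param spacing Voxel spacing in cm (length 1 or 3).
#' @param padding Margin (cm) added around the mesh bounding box (default one
#'   voxel).
#' @return A [binary_mask()]; the grid is derived from the mesh bounding box
#'   so a valid closed mesh always yields a non-empty mask.
#' @export
mesh_to_mask <- function(mesh, spacing = c(0.2, 0.2, 0.2), padding = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  validate_surface_mesh(mesh)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(padding)) padding <- max(spacing)
  lo <- apply(mesh$vertices, 2, min) - padding
  hi <- apply(mesh$vertices, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  voxelize_on_grid(mesh, dims, spacing, lo)
}

# Voxelize onto an explicit grid (shared-grid Dice needs this).
voxelize_on_grid <- function(mesh, dims, spacing, origin) {
  v <- mesh$vertices
  tr <- mesh$triangles
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  cast <- function(dy, dz) {
    # returns list(ray = j + (k-1)*ny linear ray id, x = crossing, graze = ray ids)
    p1 <- v[tr[, 1], , drop = FALSE]
    p2 <- v[tr[, 2], , drop = FALSE]
    p3 <- v[tr[, 3], , drop = FALSE]
    ray_id <- integer(0); xs <- numeric(0); graze <- integer(0)
    ny <- dims[2]
    for (t in seq_len(nrow(tr))) {
      y1 <- p1[t, 2]; y2 <- p2[t, 2]; y3 <- p3[t, 2]
      z1 <- p1[t, 3]; z2 <- p2[t, 3]; z3 <- p3[t, 3]
      denom <- (y2 - y1) * (z3 - z1) - (y3 - y1) * (z2 - z1)
      if (abs(denom) < 1e-14) next # projects to a line: x-parallel face
      jr <- which(yc + dy >= min(y1, y2, y3) - 1e-12 &
                    yc + dy <= max(y1, y2, y3) + 1e-12)
      kr <- which(zc + dz >= min(z1, z2, z3) - 1e-12 &
                    zc + dz <= max(z1, z2, z3) + 1e-12)
      if (!length(jr) || !length(kr)) next
      gy <- rep(yc[jr] + dy, times = length(kr))
      gz <- rep(zc[kr] + dz, each = length(jr))
      b2 <- ((gy - y1) * (z3 - z1) - (gz - z1) * (y3 - y1)) / denom
      b3 <- ((gz - z1) * (y2 - y1) - (gy - y1) * (z2 - z1)) / denom
      b1 <- 1 - b2 - b3
      inside <- b1 >= 0 & b2 >= 0 & b3 >= 0
      if (!any(inside)) next
      near_edge <- inside & (b1 < 1e-9 | b2 < 1e-9 | b3 < 1e-9)
      rid <- rep(jr, times = length(kr)) + (rep(kr, each = length(jr)) - 1L) * ny
      if (any(near_edge)) graze <- c(graze, rid[near_edge])
      w <- which(inside & !near_edge)
      if (length(w)) {
        ray_id <- c(ray_id, rid[w])
        xs <- c(xs, b1[w] * p1[t, 1] + b2[w] * p2[t, 1] + b3[w] * p3[t, 1])
      }
    }
    list(ray = ray_id, x = xs, graze = unique(graze))
  }
  res <- cast(0, 0)
  # parity failures (odd crossing counts) are grazing symptoms too
  if (length(res$ray)) {
    cnt <- table(res$ray)
    odd <- as.integer(names(cnt)[cnt %% 2L == 1L])
    res$graze <- unique(c(res$graze, odd))
  }
  if (length(res$graze)) {
    # incommensurate y/z offsets so rays also leave the quad diagonals of
    # axis-aligned (cuberille) faces
    res2 <- cast(0.5 * spacing[2] * 1e-3, 0.5 * spacing[3] * 2.31e-3)
    keep <- !(res$ray %in% res$graze)
    take <- res2$ray %in% res$graze
    res <- list(ray = c(res$ray[keep], res2$ray[take]),
                x = c(res$x[keep], res2$x[take]))
  }
  grid <- array(FALSE, dims)
  if (length(res$ray)) {
    sp <- split(res$x, res$ray)
    ny <- dims[2]
    for (nm in names(sp)) {
      rid <- as.integer(nm)
      crossings <- sort(sp[[nm]])
      if (length(crossings) %% 2L == 1L) next # unrecoverable graze: leave outside
      nle <- findInterval(xc, crossings)
      ins <- (length(crossings) - nle) %% 2L == 1L
      if (any(ins)) {
        j <- ((rid - 1L) %% ny) + 1L
        k <- ((rid - 1L) %/% ny) + 1L
        grid[ins, j, k] <- TRUE
      }
    }
  }
  binary_mask(grid, spacing, origin)
}

#' Rigidly align two meshes by center of mass
#'
#' Translates `moving` so its vertex centroid coincides with that of
#' `fixed`; shape is untouched.
#'
#' @param moving,fixed [surface_mesh()] objects.
#' @return List with `translation` (3-vector, cm) and `moved` (the translated
#'   mesh).
#' @export
center_of_mass_align <- function(moving, fixed) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  tr <- colMeans(fixed$vertices) - colMeans(moving$vertices)
  moved <- surface_mesh(sweep(moving$vertices, 2, tr, `+`), moving$triangles,
                        validate = FALSE)
  list(translation = tr, moved = moved)
}

#' Apply a deformation field to a mesh
#'
#' Displaces every vertex by its index-aligned displacement vector;
#' connectivity is unchanged. This is the "apply the interpolated
#' displacements to each nodal point" step of the reconstruction.
#'
#' @param mesh A [surface_mesh()].
#' @param field A [deformation_field()] with one row per mesh vertex.
#' @return The deformed [surface_mesh()].
#' @export
apply_field <- function(mesh, field) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(field, "deformation_field"))
  if (nrow(field$displacements) != nrow(mesh$vertices)) {
    stop(sprintf("field length (%d) does not match mesh vertex count (%d)",
                 nrow(field$displacements), nrow(mesh$vertices)), call. = FALSE)
  }
  surface_mesh(mesh$vertices + field$displacements, mesh$triangles,
               validate = FALSE)
}
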