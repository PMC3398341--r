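# Plain-text persistence for every container.
#
# Meshes round-trip through ASCII VTK legacy PolyData and ASCII PLY; masks
# and CT volumes through a JSON header + run-length-encoded payload;
# deformation fields through CSV (vertex_index, dx, dy, dz) and VTK point
# data; DRRs through ASCII PGM (P2) plus a JSON sidecar carrying the
# physical calibration and annotations. All formats are lossless for the
# package's needs (full double precision in text).

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a surface mesh as ASCII VTK legacy PolyData
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file (conventionally `.vtk`).
#' @return `write_mesh_vtk`: `path` invisibly; `read_mesh_vtk`: the mesh.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "heartnc surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(paste(3L, tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  v <- matrix(scan(text = lines[(ip + 1L):(ip + np)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  raw <- matrix(scan(text = lines[(it + 1L):(it + nt)], quiet = TRUE),
                ncol = 4L, byrow = TRUE)
  surface_mesh(v, raw[, 2:4] + 1L, validate = FALSE)
}

#' Write / read a surface mesh as ASCII PLY
#'
#' @inheritParams write_mesh_vtk
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(v, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(paste(3L, tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  start <- grep("^end_header$", lines)[1]
  v <- matrix(scan(text = lines[(start + 1L):(start + nv)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  raw <- matrix(scan(text = lines[(start + nv + 1L):(start + nv + nf)], quiet = TRUE),
                ncol = 4L, byrow = TRUE)
  surface_mesh(v, raw[, 2:4] + 1L, validate = FALSE)
}

#' Write / read a binary mask (JSON header + run-length payload)
#'
#' The grid is flattened in R's column-major order and run-length encoded;
#' spacing/origin are stored in cm at full precision.
#'
#' @param mask A [binary_mask()].
#' @param path Output file (conventionally `.mask.json`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  r <- rle(as.vector(mask$grid))
  jsonlite::write_json(
    list(container = "binary_mask", dims = dim(mask$grid),
         spacing = mask$spacing, origin = mask$origin,
         rle_lengths = r$lengths, rle_values = as.integer(r$values)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) list())
  if (!identical(j$container, "binary_mask")) {
    stop(sprintf("'%s' is not a binary mask file", path), call. = FALSE)
  }
  g <- array(inverse.rle(structure(list(lengths = j$rle_lengths,
                                        values = as.logical(j$rle_values)),
                                   class = "rle")),
             dim = j$dims)
  binary_mask(g, j$spacing, j$origin)
}

#' Write / read a CT volume (JSON header + quantized run-length payload)
#'
#' Attenuations are stored to 6 decimal places (the phantom scale is O(1),
#' so this is lossless for generated volumes).
#'
#' @param ct A [ct_volume()].
#' @param path Output file (conventionally `.ct.json`).
#' @export
write_ct <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  r <- rle(as.vector(round(ct$grid, 6)))
  jsonlite::write_json(
    list(container = "ct_volume", dims = dim(ct$grid), spacing = ct$spacing,
         origin = ct$origin, sad = ct$sad,
         upper_row_y = attr(ct, "upper_row_y"),
         lower_row_y = attr(ct, "lower_row_y"),
         landmarks = attr(ct, "landmarks"),
         group_label = attr(ct, "group_label"),
         rle_lengths = r$lengths, rle_values = r$values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) list())
  if (!identical(j$container, "ct_volume")) {
    stop(sprintf("'%s' is not a CT volume file", path), call. = FALSE)
  }
  g <- array(inverse.rle(structure(list(lengths = j$rle_lengths,
                                        values = j$rle_values),
                                   class = "rle")),
             dim = j$dims)
  ct <- ct_volume(g, j$spacing, j$origin, sad = j$sad %||% 100)
  attr(ct, "upper_row_y") <- j$upper_row_y
  attr(ct, "lower_row_y") <- j$lower_row_y
  if (!is.null(j$landmarks)) {
    attr(ct, "landmarks") <- lapply(j$landmarks, as.numeric)
  }
  attr(ct, "group_label") <- j$group_label
  ct
}

#' Write / read a deformation field as CSV
#'
#' Columns `vertex_index` (1-based), `dx`, `dy`, `dz` (cm).
#'
#' @param field A [deformation_field()].
#' @param path Output file (conventionally `.csv`).
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  d <- field$displacements
  df <- data.frame(vertex_index = seq_len(nrow(d)),
                   dx = d[, 1], dy = d[, 2], dz = d[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$vertex_index), , drop = FALSE]
  deformation_field(as.matrix(df[, c("dx", "dy", "dz")]))
}

#' Write a deformation field as VTK point data (with its source mesh)
#'
#' Appends a `VECTORS displacement` point-data block to a PolyData file.
#'
#' @param field A [deformation_field()].
#' @param mesh The index-aligned source [surface_mesh()].
#' @param path Output file (conventionally `.vtk`).
#' @export
write_field_vtk <- function(field, mesh, path) {
  stopifnot(nrow(field$displacements) == nrow(mesh$vertices))
  write_mesh_vtk(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(c(sprintf("POINT_DATA %d", nrow(field$displacements)),
               "VECTORS displacement double"), con)
  writeLines(apply(field$displacements, 1,
                   function(p) paste(fmt_num(p), collapse = " ")), con)
  invisible(path)
}

#' Write / read a DRR as ASCII PGM plus a JSON sidecar
#'
#' Pixels are linearly quantized to 16-bit PGM (P2); the sidecar
#' (`<path>.json`) stores the quantization scale/offset, pixel spacing,
#' origin, isocenter, landmarks and contour, so the round trip is lossless
#' to ~5 significant digits of the intensity scale.
#'
#' @param drr A [drr_image()].
#' @param path Output PGM file (conventionally `.pgm`).
#' @export
write_drr <- function(drr, path) {
  stopifnot(inherits(drr, "drr_image"))
  px <- drr$pixels
  lo <- min(px); hi <- max(px)
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  q <- matrix(as.integer(round((px - lo) * scale)), nrow(px), ncol(px))
  con <- file(path, "w")
  writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "65535"), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  close(con)
  side <- list(container = "drr_image", intensity_offset = lo,
               intensity_scale = scale, pixel_spacing = drr$pixel_spacing,
               origin2d = drr$origin2d, isocenter_px = drr$isocenter_px,
               landmarks = drr$landmarks, heart_contour = drr$heart_contour,
               subject_id = drr$subject_id, group_label = drr$group_label,
               sad = drr$sad, upper_row_y = attr(drr, "upper_row_y"),
               lower_row_y = attr(drr, "lower_row_y"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_drr
#' @export
read_drr <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "P2")
  dims <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  vals <- scan(text = lines[-(1:3)], quiet = TRUE)
  q <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- q / j$intensity_scale + j$intensity_offset
  drr <- drr_image(px, j$pixel_spacing, j$origin2d,
                   isocenter_px = j$isocenter_px,
                   heart_contour = j$heart_contour,
                   landmarks = lapply(j$landmarks, as.numeric),
                   subject_id = j$subject_id, group_label = j$group_label,
                   sad = j$sad %||% 100)
  attr(drr, "upper_row_y") <- j$upper_row_y
  attr(drr, "lower_row_y") <- j$lower_row_y
  drr
}

#' Export an intensity profile as CSV for plotting
#'
#' Columns `position_cm` (world coordinate along the channel's long axis)
#' and `intensity`.
#'
#' @param profile An [intensity_profile()].
#' @param path CSV file.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  pos <- profile$axis_origin +
    (seq_along(profile$samples) - 1L) * profile$sample_spacing
  utils::write.csv(data.frame(position_cm = pos, intensity = profile$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Round-trip navigator channel definitions through JSON
#'
#' @param channels List of [navigator_channel()] objects.
#' @param path JSON file.
#' @export
write_channels_json <- function(channels, path) {
  jsonlite::write_json(lapply(channels, function(nc) {
    list(role = nc$role, center = nc$center, size = nc$size)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channels_json
#' @export
read_channels_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i) {
    navigator_channel(j$role[i], unlist(j$center[i]), unlist(j$size[i]))
  })
}

#' Read a 2D contour polygon from CSV
#'
#' Expects columns `x`, `y` (cm); the polygon is closed implicitly.
#'
#' @param path CSV file.
#' @return K x 2 matrix.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x", "y")])
}

#' Write / read thorax measurements as CSV
#'
#' Columns `subject_id`, `group`, `W1`, `W2`, `L`.
#'
#' @param measurements List of [thorax_measurements()].
#' @param path CSV file.
#' @export
write_measurements_csv <- function(measurements, path) {
  df <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(subject_id = m$subject_id, group = m$group_label,
               W1 = m$W1, W2 = m$W2, L = m$L, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    thorax_measurements(df$subject_id[i], df$group[i], df$W1[i], df$W2[i],
                        df$L[i])
  })
}

#' Serialize phantom parameter records to / from JSON
#'
#' @param params A [heart_phantom_params()] or [thorax_phantom_params()].
#' @param path JSON file.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(c(list(container = class(params)[1]), unclass(params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- j$container
  j$container <- NULL
  if (identical(cls, "heart_phantom_params")) {
    do.call(heart_phantom_params, j)
  } else if (identical(cls, "thorax_phantom_params")) {
    do.call(thorax_phantom_params, j)
  } else {
    stop(sprintf("'%s' is not a phantom parameter file", path), call. = FALSE)
  }
}
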