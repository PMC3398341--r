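# Population-to-Reference surface registration.
#
# The biomechanical FEM registration the field uses for this step (linear
# elastic interior, contact surfaces) is out of scope; the documented
# stand-in is iterative closest-point *projection*: every population surface
# node is pulled toward its closest point on the reference surface, the
# displacement field is Laplacian-smoothed over the mesh graph each
# iteration, and a damped step guarantees a non-increasing mean residual.
# Any smooth surface-matching map with logged residuals serves the
# downstream adaptation equally well.

# Closest points on triangles, vectorized over (point, triangle) pairs.
# P, A, B, C: n x 3 matrices. Returns n x 3 closest points. (Ericson,
# "Real-Time Collision Detection", region-by-region.)
closest_point_on_triangles <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, nrow(P), 3L)
  done <- logical(nrow(P))
  set <- function(mask, val) {
    m <- mask & !done
    if (any(m)) {
      out[m, ] <<- val[m, , drop = FALSE]
      done[m] <<- TRUE
    }
  }
  set(d1 <= 0 & d2 <= 0, A)
  set(d3 >= 0 & d4 <= d3, B)
  v_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * v_ab)
  set(d6 >= 0 & d5 <= d6, C)
  w_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * w_ac)
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w_bc)
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  set(rep(TRUE, nrow(P)), A + ab * v + ac * w)
  out
}

# Nearest target vertex for each query point (chunked dense distances).
nearest_vertex <- function(points, verts, chunk = 512L) {
  n <- nrow(points)
  idx <- integer(n)
  v2 <- rowSums(verts^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    p <- points[s:e, , drop = FALSE]
    d <- outer(rowSums(p^2), v2, `+`) - 2 * p %*% t(verts)
    idx[s:e] <- max.col(-d, ties.method = "first")
  }
  idx
}

# Closest point on a mesh surface for each query point, via nearest vertex
# + projection onto that vertex's incident triangles (a local approximation
# that is exact on smooth meshes at the residuals we care about).
closest_point_on_mesh <- function(points, mesh, incidence = NULL) {
  if (is.null(incidence)) incidence <- vertex_triangle_incidence(mesh)
  nv <- nearest_vertex(points, mesh$vertices)
  tri_list <- incidence[nv]
  cnt <- lengths(tri_list)
  pt_idx <- rep.int(seq_len(nrow(points)), cnt)
  tri_idx <- unlist(tri_list, use.names = FALSE)
  tr <- mesh$triangles[tri_idx, , drop = FALSE]
  P <- points[pt_idx, , drop = FALSE]
  cp <- closest_point_on_triangles(P, mesh$vertices[tr[, 1], , drop = FALSE],
                                   mesh$vertices[tr[, 2], , drop = FALSE],
                                   mesh$vertices[tr[, 3], , drop = FALSE])
  d2 <- rowSums((cp - P)^2)
  o <- order(pt_idx, d2)
  first <- o[!duplicated(pt_idx[o])]
  cp[first[order(pt_idx[first])], , drop = FALSE]
}

vertex_triangle_incidence <- function(mesh) {
  tr <- mesh$triangles
  split(rep(seq_len(nrow(tr)), 3L), as.vector(tr))
}

#' Register a population surface onto a reference surface
#'
#' Iterative closest-point projection with per-iteration Laplacian smoothing
#' of the displacement field. The meshes are first rigidly aligned by center
#' of mass (the rigid part is folded into the returned field, so registering
#' translated copies yields fields differing by exactly that translation).
#' Each iteration proposes `field + step * (closest_point - current)`,
#' smooths it, and accepts only if the mean residual does not increase
#' (otherwise the step is halved, up to 5 times); the residual log is
#' therefore non-increasing by construction. Non-convergence yields a
#' warning result carrying the residuals, never an exception.
#'
#' @param population,reference Closed [surface_mesh()] objects.
#' @param iters Maximum iterations (default 30).
#' @param smooth_lambda Laplacian blend weight in `[0, 1)` (default 0.5).
#' @param tol Convergence tolerance on the mean residual (cm).
#' @return An object of class `registration_result`: `field` (a
#'   [deformation_field()], population -> reference), `residual` (list
#'   `mean`, `max`, in cm), `residual_history`, `iterations`, `converged`.
#' @export
register_surface <- function(population, reference, iters = 30L,
                             smooth_lambda = 0.5, tol = 0.01) {
  stopifnot(inherits(population, "surface_mesh"),
            inherits(reference, "surface_mesh"))
  validate_surface_mesh(population)
  validate_surface_mesh(reference)
  inc <- vertex_triangle_incidence(reference)
  nb <- vertex_neighbors(population)
  # solve in a centered canonical frame so the result is rigid-translation
  # equivariant (the COM offset is reattached analytically at the end);
  # centroids are rounded to 1e-9 cm so the centered coordinates - and with
  # them every tie-break in the closest-point search - are bitwise identical
  # across translated copies
  c_pop <- round(colMeans(population$vertices), 9)
  c_ref <- round(colMeans(reference$vertices), 9)
  orig <- sweep(population$vertices, 2, c_pop, `-`)
  reference <- surface_mesh(sweep(reference$vertices, 2, c_ref, `-`),
                            reference$triangles, validate = FALSE)
  field <- matrix(0, nrow(orig), 3L)
  smooth_field <- function(f) {
    if (smooth_lambda <= 0) return(f)
    avg <- rowsum(f[nb$to, , drop = FALSE], nb$from) / nb$deg
    (1 - smooth_lambda) * f + smooth_lambda * avg
  }
  resid_of <- function(f) {
    cur <- orig + f
    cp <- closest_point_on_mesh(cur, reference, inc)
    list(cp = cp, d = sqrt(rowSums((cp - cur)^2)))
  }
  state <- resid_of(field)
  history <- mean(state$d)
  converged <- FALSE
  it <- 0L
  while (it < iters) {
    it <- it + 1L
    step <- 1
    accepted <- FALSE
    for (try in 1:5) {
      cand <- smooth_field(field + step * (state$cp - (orig + field)))
      cand_state <- resid_of(cand)
      if (mean(cand_state$d) <= history[length(history)] + 1e-15) {
        field <- cand
        state <- cand_state
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    history <- c(history, mean(state$d))
    if (history[length(history)] < tol ||
        (length(history) > 1L &&
         abs(diff(utils::tail(history, 2L))) < tol / 10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && mean(state$d) > 10 * tol) {
    warning(sprintf("registration did not converge: mean residual %.4f cm after %d iteration(s)",
                    mean(state$d), it))
  }
  field <- sweep(field, 2, c_ref - c_pop, `+`)
  structure(list(field = deformation_field(field, source = "population"),
                 residual = list(mean = mean(state$d), max = max(state$d)),
                 residual_history = history, iterations = it,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d iteration(s), residual mean %.4f / max %.4f cm%s\n",
              x$iterations, x$residual$mean, x$residual$max,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Sample a deformation field at a navigator channel
#'
#' The predicted population-to-Reference displacement at a channel position
#' (a Delta-NC of the adaptation equations): the mean of the channel-axis
#' component (x for horizontal channels, y for vertical ones) over the nodes
#' whose (x, y) projection falls inside the channel rectangle; if no node
#' projects inside, the node nearest the channel center is used.
#'
#' @param field A [deformation_field()].
#' @param mesh The mesh whose vertex positions locate the nodes - pass the
#'   population mesh *deformed to the Reference* (channels live on the
#'   Reference image).
#' @param nc A [navigator_channel()].
#' @return Delta-NC in cm.
#' @export
field_at_channel <- function(field, mesh, nc) {
  stopifnot(inherits(field, "deformation_field"),
            inherits(mesh, "surface_mesh"),
            inherits(nc, "navigator_channel"))
  if (nrow(mesh$vertices) == 0L) stop("empty mesh", call. = FALSE)
  if (nrow(field$displacements) != nrow(mesh$vertices)) {
    stop("field length does not match mesh vertex count", call. = FALSE)
  }
  r <- nc_rect(nc)
  v <- mesh$vertices
  inside <- v[, 1] >= r["x0"] & v[, 1] <= r["x1"] &
    v[, 2] >= r["y0"] & v[, 2] <= r["y1"]
  comp <- if (nc$orientation == "horizontal") 1L else 2L
  if (any(inside)) {
    mean(field$displacements[inside, comp])
  } else {
    d <- (v[, 1] - nc$center[1])^2 + (v[, 2] - nc$center[2])^2
    field$displacements[which.min(d), comp]
  }
}
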