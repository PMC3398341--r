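# Navigator-channel adaptation of a deformation field.
#
# The population-to-Reference field Delta is converted into a
# population-to-Test field by rescaling each node's displacement with
# ratios (DeltaNC + dNC) / DeltaNC measured at the channels:
#
#   longitudinal (all nodes):   y-ratio blended between the superior and
#                               inferior channels (NC5/NC6) by k_y;
#   lateral, upper region:      x-ratio blended between NC3 and NC4 by k_x;
#   lateral, lower region:      x-ratio blended between NC1 and NC2 by k_x;
#   lateral, middle region:     bilinear blend of all four lateral ratios;
#   anterior-posterior:         z untouched (no lateral film exists).
#
# Weight orientation: each channel's weight is 1 minus its normalized
# distance to the node, so the nearer channel dominates - the superior/right
# channels (at k = 0) carry weight (1 - k), the inferior/left channels
# (at k = 1) carry weight k, and the middle-region bilinear weights are the
# outer product of the two (summing to 1). Source formulas are internally
# inconsistent about this orientation; see the methods vignette. Blends are
# evaluated in lerp form, a + w * (b - a), so that equal ratios collapse
# exactly: with all shifts zero every ratio is 1 and the adapted field is
# bit-for-bit the input field.
#
# Degenerate denominators: when |DeltaNC| < eps the ratio is replaced by the
# additive correction Delta(x0) + dNC, the unique finite limit that
# preserves the zero-shift identity.

#' Construct a channel state (predicted displacement + detected shift)
#'
#' @param role `"NC1"`..`"NC6"`.
#' @param delta Predicted population-to-Reference displacement at the
#'   channel, Delta-NC (cm, from [field_at_channel()]).
#' @param shift Detected Reference-to-Test edge shift, dNC (cm, from
#'   [compute_shift()]).
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(role, delta, shift) {
  role <- match.arg(role, NC_ROLES)
  if (!is.finite(delta) || !is.finite(shift)) {
    stop("channel state values must be finite", call. = FALSE)
  }
  structure(list(role = role, delta = delta, shift = shift),
            class = "channel_state")
}

# Validate a list of six channel states, return named by role.
channel_state_set <- function(states) {
  lapply(states, function(s) stopifnot(inherits(s, "channel_state")))
  roles <- vapply(states, `[[`, character(1), "role")
  missing <- setdiff(NC_ROLES, roles)
  if (length(missing) || anyDuplicated(roles)) {
    stop(sprintf("need each of NC1..NC6 exactly once (missing: %s)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(states, roles)[NC_ROLES]
}

# One channel's adapted term for node displacement `delta_comp`:
# delta_comp * (Delta + d)/Delta, or delta_comp + d when |Delta| < eps.
channel_term <- function(delta_comp, ch, eps) {
  if (abs(ch$delta) < eps) delta_comp + ch$shift
  else delta_comp * ((ch$delta + ch$shift) / ch$delta)
}

#' Normalized node weights within the heart bounding box
#'
#' `k_x = (x - x_right) / (x_left - x_right)` and
#' `k_y = (y - y_sup) / (y_inf - y_sup)`, clamped to `[0, 1]`: 0 is the most
#' right/superior edge of the heart, 1 the most left/inferior. The bounding
#' box comes from the population model deformed to the Reference (the Test
#' anatomy is unknown in deployment).
#'
#' @param vertex Length-3 (or N x 3) node position(s), cm.
#' @param heart_bbox List with `x` and `y` ranges (each length-2, cm) of the
#'   heart in the image plane.
#' @return List with `k_x`, `k_y` (vectors for matrix input).
#' @export
compute_node_weights <- function(vertex, heart_bbox) {
  v <- if (is.matrix(vertex)) vertex else matrix(vertex, ncol = 3L)
  dx <- diff(heart_bbox$x)
  dy <- diff(heart_bbox$y)
  if (dx <= 0 || dy <= 0) {
    stop("degenerate heart bounding box (zero extent)", call. = FALSE)
  }
  list(k_x = pmin(1, pmax(0, (v[, 1] - heart_bbox$x[1]) / dx)),
       k_y = pmin(1, pmax(0, (v[, 2] - heart_bbox$y[1]) / dy)))
}

#' Longitudinal (superior-inferior) adaptation of one node displacement
#'
#' Blends the NC5 and NC6 ratio terms by the node's normalized longitudinal
#' position: the superior channel carries weight `(1 - k_y)`, the inferior
#' channel `k_y` (weights sum to 1).
#'
#' @param delta_y The node's population-to-Reference y-displacement (cm).
#' @param w Node weights from [compute_node_weights()] (uses `k_y`).
#' @param ch5,ch6 [channel_state()] objects for NC5 and NC6.
#' @param role_map Which vertical channel is superior (default NC5, per the
#'   source's body text; configurable because its figure caption says the
#'   opposite).
#' @param eps Denominator guard (cm).
#' @return Adapted y-displacement (cm).
#' @export
adapt_longitudinal <- function(delta_y, w, ch5, ch6,
                               role_map = c(superior = "NC5"), eps = 1e-6) {
  sup <- if (identical(unname(role_map[["superior"]]), "NC6")) ch6 else ch5
  inf <- if (identical(unname(role_map[["superior"]]), "NC6")) ch5 else ch6
  t_sup <- channel_term(delta_y, sup, eps)
  t_inf <- channel_term(delta_y, inf, eps)
  t_sup + w$k_y * (t_inf - t_sup)
}

#' Lateral (left-right) adaptation of one node displacement
#'
#' Upper region: NC3/NC4 blend by `k_x`; lower region: NC1/NC2 blend;
#' middle region: bilinear blend of all four ratio terms with weights
#' `(1-k_x)(1-k_y), k_x(1-k_y), (1-k_x)k_y, k_x k_y` for the
#' (right-upper, left-upper, right-lower, left-lower) channels, summing
#' to 1. In the `k_y -> 1` limit the middle formula equals the lower-region
#' formula; in the `k_y -> 0` limit the upper-region one.
#'
#' @param delta_x The node's population-to-Reference x-displacement (cm).
#' @param w Node weights from [compute_node_weights()].
#' @param region `"upper"`, `"middle"` or `"lower"`.
#' @param channels List of four [channel_state()] objects (NC1..NC4, any
#'   order, matched by role).
#' @param eps Denominator guard (cm).
#' @return Adapted x-displacement (cm).
#' @export
adapt_lateral <- function(delta_x, w, region, channels, eps = 1e-6) {
  region <- match.arg(region, c("upper", "middle", "lower"))
  roles <- vapply(channels, `[[`, character(1), "role")
  ch <- stats::setNames(channels, roles)
  t1 <- channel_term(delta_x, ch$NC1, eps) # lower right
  t2 <- channel_term(delta_x, ch$NC2, eps) # lower left
  t3 <- channel_term(delta_x, ch$NC3, eps) # upper right
  t4 <- channel_term(delta_x, ch$NC4, eps) # upper left
  lower_val <- t1 + w$k_x * (t2 - t1)
  upper_val <- t3 + w$k_x * (t4 - t3)
  switch(region,
         upper = upper_val,
         lower = lower_val,
         middle = upper_val + w$k_y * (lower_val - upper_val))
}

#' Partition mesh nodes into upper/middle/lower regions
#'
#' The four lateral channels divide the heart: nodes superior to the
#' NC3/NC4 row center are `upper`, nodes inferior to the NC1/NC2 row center
#' are `lower`, nodes between are `middle`.
#'
#' @param mesh A [surface_mesh()] (pass the Reference-deformed model).
#' @param channels List of [navigator_channel()] objects including
#'   NC1..NC4.
#' @return An object of class `region_partition`: `labels` (factor per
#'   node), `upper_boundary_y`, `lower_boundary_y` (cm).
#' @export
partition_regions <- function(mesh, channels) {
  stopifnot(inherits(mesh, "surface_mesh"))
  roles <- vapply(channels, `[[`, character(1), "role")
  need <- c("NC1", "NC2", "NC3", "NC4")
  if (!all(need %in% roles)) {
    stop(sprintf("missing lateral channel(s): %s",
                 paste(setdiff(need, roles), collapse = ", ")), call. = FALSE)
  }
  ncs <- stats::setNames(channels, roles)
  y_upper <- mean(c(ncs$NC3$center[2], ncs$NC4$center[2]))
  y_lower <- mean(c(ncs$NC1$center[2], ncs$NC2$center[2]))
  if (!(y_upper < y_lower)) {
    stop("NC3/NC4 row must be superior to the NC1/NC2 row", call. = FALSE)
  }
  y <- mesh$vertices[, 2]
  labels <- factor(ifelse(y < y_upper, "upper",
                          ifelse(y > y_lower, "lower", "middle")),
                   levels = c("upper", "middle", "lower"))
  structure(list(labels = labels, upper_boundary_y = y_upper,
                 lower_boundary_y = y_lower),
            class = "region_partition")
}

#' Adapt a population-to-Reference field into a population-to-Test field
#'
#' Applies [adapt_longitudinal()] to every node's y-displacement and
#' [adapt_lateral()] (per the node's region) to every x-displacement;
#' z-displacements are preserved exactly - no lateral film constrains the
#' anterior-posterior direction. Node weights, regions and the heart
#' bounding box are computed from the Reference-deformed node positions
#' (`mesh` vertices + `field`).
#'
#' @param field The population-to-Reference [deformation_field()].
#' @param mesh The population [surface_mesh()] (same node order as `field`).
#' @param channels List of six [channel_state()] objects.
#' @param nc_geom List of six [navigator_channel()] objects (geometry, for
#'   the region partition).
#' @param role_map,eps See [adapt_longitudinal()].
#' @return The adapted [deformation_field()] (population -> Test).
#' @export
adapt_field <- function(field, mesh, channels, nc_geom,
                        role_map = c(superior = "NC5"), eps = 1e-6) {
  stopifnot(inherits(field, "deformation_field"),
            inherits(mesh, "surface_mesh"))
  if (nrow(field$displacements) != nrow(mesh$vertices)) {
    stop("field length does not match mesh vertex count", call. = FALSE)
  }
  ch <- channel_state_set(channels)
  pos <- mesh$vertices + field$displacements # Reference-deformed nodes
  ref_mesh <- surface_mesh(pos, mesh$triangles, validate = FALSE)
  bbox <- list(x = range(pos[, 1]), y = range(pos[, 2]))
  w <- compute_node_weights(pos, bbox)
  part <- partition_regions(ref_mesh, nc_geom)
  d <- field$displacements
  out <- d
  # --- longitudinal (vectorized lerp, identical algebra to the scalar op)
  sup_role <- if (identical(unname(role_map[["superior"]]), "NC6")) "NC6" else "NC5"
  inf_role <- setdiff(c("NC5", "NC6"), sup_role)
  term <- function(comp, state) {
    if (abs(state$delta) < eps) d[, comp] + state$shift
    else d[, comp] * ((state$delta + state$shift) / state$delta)
  }
  t_sup <- term(2L, ch[[sup_role]])
  t_inf <- term(2L, ch[[inf_role]])
  out[, 2] <- t_sup + w$k_y * (t_inf - t_sup)
  # --- lateral
  t1 <- term(1L, ch$NC1); t2 <- term(1L, ch$NC2)
  t3 <- term(1L, ch$NC3); t4 <- term(1L, ch$NC4)
  lower_val <- t1 + w$k_x * (t2 - t1)
  upper_val <- t3 + w$k_x * (t4 - t3)
  lab <- part$labels
  out[lab == "upper", 1] <- upper_val[lab == "upper"]
  out[lab == "lower", 1] <- lower_val[lab == "lower"]
  mid <- lab == "middle"
  out[mid, 1] <- upper_val[mid] + w$k_y[mid] * (lower_val[mid] - upper_val[mid])
  if (any(!is.finite(out))) stop("adapted field is not finite", call. = FALSE)
  deformation_field(out, source = field$source)
}

#' Reconstruct the Test-specific heart model
#'
#' Applies the adapted population-to-Test field to the population model's
#' nodes. The mesh connectivity is preserved; a heads-up warning (not an
#' error) is raised if the deformation flipped the enclosed volume sign,
#' the cheap proxy for a self-intersecting result.
#'
#' @param population The population [surface_mesh()].
#' @param adapted The adapted [deformation_field()].
#' @return The reconstructed [surface_mesh()].
#' @export
reconstruct <- function(population, adapted) {
  mesh <- apply_field(population, adapted)
  if (mesh_volume(mesh) <= 0) {
    warning("reconstructed mesh has non-positive enclosed volume; the adapted field likely self-intersects")
  }
  mesh
}
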