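# Shared phantom fixtures, built once per test run (all generated in code).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) assign(key, fn(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small closed sphere-ish mesh of radius r.
sphere_mesh <- function(r = 1, center = c(0, 0, 0), n_theta = 20L, n_phi = 28L) {
  generate_heart(heart_phantom_params(semi_axes = rep(r, 3),
                                      lobe_amplitudes = rep(0, 4),
                                      center = center,
                                      n_theta = n_theta, n_phi = n_phi))
}

# Rasterized solid sphere mask (radius cm, spacing cm).
sphere_mask <- function(r = 1, spacing = 0.1) {
  n <- as.integer(ceiling(2 * (r + 2 * spacing) / spacing))
  ctr <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  g <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    g[, , k] <- outer(ctr, ctr, function(x, y) x^2 + y^2) + ctr[k]^2 <= r^2
  }
  binary_mask(g, rep(spacing, 3))
}

# One thorax phantom + heart + CT + DRR at desk-scale spacing, reused by
# projection/matching/navigator tests.
std_phantom <- function() {
  memo("std_phantom", function() {
    thorax <- thorax_phantom_params()
    hp <- heart_phantom_params(center = c(0, thorax$L / 2, -2), seed = 11L)
    heart <- generate_heart(hp)
    ct <- generate_thorax_ct(thorax, heart, spacing = rep(0.2, 3))
    list(thorax = thorax, heart_params = hp, heart = heart, ct = ct,
         drr = render_drr(ct))
  })
}

# Fine-grid (planning-pixel) phantom DRR for sub-pixel shift tests.
fine_phantom_drr <- function() {
  memo("fine_phantom_drr", function() {
    thorax <- thorax_phantom_params()
    hp <- heart_phantom_params(center = c(0, thorax$L / 2, -2), seed = 11L)
    ct <- generate_thorax_ct(thorax, generate_heart(hp),
                             spacing = c(0.1, 0.1, 0.3))
    render_drr(ct)
  })
}

# Shift DRR pixel content by an integer number of pixels along +x (columns)
# or +y (rows), wrapping at the borders (content far from the heart).
roll_drr <- function(drr, k, along = c("x", "y")) {
  along <- match.arg(along)
  m <- drr$pixels
  out <- drr
  if (along == "x") {
    out$pixels <- m[, ((seq_len(ncol(m)) - 1L - k) %% ncol(m)) + 1L]
  } else {
    out$pixels <- m[((seq_len(nrow(m)) - 1L - k) %% nrow(m)) + 1L, ]
  }
  out
}

# Small 3-pair cohort shared by pipeline tests.
small_cohort <- function() {
  memo("small_cohort", function() make_phantom_cohort(n_pairs = 3L, seed = 5L,
                                                      spacing = 0.2))
}

# The bundled matched-pair thorax-measurement cohort (15 pairs, published
# LSD scores).
rtp_cohort <- function() {
  utils::read.csv(system.file("extdata", "rtp_cohort.csv", package = "heartnc"),
                  stringsAsFactors = FALSE)
}

rtp_measurements <- function(df = rtp_cohort()) {
  list(
    refs = lapply(seq_len(nrow(df)), function(i) {
      thorax_measurements(paste0("ref_", df$rtp[i]), substr(df$rtp[i], 1, 1),
                          df$ref_W1[i], df$ref_W2[i], df$ref_L[i])
    }),
    tests = lapply(seq_len(nrow(df)), function(i) {
      thorax_measurements(df$rtp[i], substr(df$rtp[i], 1, 1),
                          df$test_W1[i], df$test_W2[i], df$test_L[i])
    }))
}

# Straight-line re-evaluation of the adaptation equations, one node at a
# time, written independently of adapt_field's vectorized lerp form:
# explicit weighted sums of the per-channel ratio terms.
oracle_adapt <- function(field, mesh, states, nc_geom,
                         superior = "NC5", eps = 1e-6) {
  st <- stats::setNames(states, vapply(states, `[[`, character(1), "role"))
  ncs <- stats::setNames(nc_geom, vapply(nc_geom, `[[`, character(1), "role"))
  d <- field$displacements
  pos <- mesh$vertices + d
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  y_up <- (ncs$NC3$center[2] + ncs$NC4$center[2]) / 2
  y_lo <- (ncs$NC1$center[2] + ncs$NC2$center[2]) / 2
  term <- function(delta_comp, s) {
    if (abs(s$delta) < eps) delta_comp + s$shift
    else delta_comp * (s$delta + s$shift) / s$delta
  }
  out <- d
  inf_role <- setdiff(c("NC5", "NC6"), superior)
  for (i in seq_len(nrow(d))) {
    kx <- min(1, max(0, (pos[i, 1] - xr[1]) / diff(xr)))
    ky <- min(1, max(0, (pos[i, 2] - yr[1]) / diff(yr)))
    out[i, 2] <- (1 - ky) * term(d[i, 2], st[[superior]]) +
      ky * term(d[i, 2], st[[inf_role]])
    t1 <- term(d[i, 1], st$NC1); t2 <- term(d[i, 1], st$NC2)
    t3 <- term(d[i, 1], st$NC3); t4 <- term(d[i, 1], st$NC4)
    out[i, 1] <- if (pos[i, 2] < y_up) {
      (1 - kx) * t3 + kx * t4
    } else if (pos[i, 2] > y_lo) {
      (1 - kx) * t1 + kx * t2
    } else {
      (1 - kx) * (1 - ky) * t3 + kx * (1 - ky) * t4 +
        (1 - kx) * ky * t1 + kx * ky * t2
    }
  }
  out
}

# Six plausible channel states / geometries for adaptation unit tests.
demo_channels <- function(deltas = c(0.5, -0.4, 0.45, -0.5, 0.6, -0.55),
                          shifts = c(0.1, -0.2, 0.15, 0.05, -0.1, 0.2)) {
  states <- lapply(1:6, function(i) {
    channel_state(paste0("NC", i), deltas[i], shifts[i])
  })
  geom <- list(
    navigator_channel("NC1", c(-5, 10)), navigator_channel("NC2", c(5, 10)),
    navigator_channel("NC3", c(-5, 4)), navigator_channel("NC4", c(5, 4)),
    navigator_channel("NC5", c(0, 1)), navigator_channel("NC6", c(0, 13)))
  list(states = states, geom = geom)
}
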