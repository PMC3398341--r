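# End-to-end orchestration: population model -> matching -> channel shifts
# -> adaptation -> reconstruction -> evaluation, plus the seeded phantom
# cohort used to exercise it and a JSON-config command-line driver.

#' Build and validate a run configuration
#'
#' @param x A named list, or path to a JSON file of settings. Recognized
#'   fields (all optional): `out_dir`, `n_pairs`, `seed`, `spacing`
#'   (phantom/evaluation grid, cm), `eval_spacing`, `smoothing_sigma`
#'   (profile smoothing, samples), `edge_frac`, `epsilon` (adaptation
#'   denominator guard, cm), `superior_channel` ("NC5" or "NC6"),
#'   `register_iters`, `smooth_lambda`.
#' @return An object of class `run_config` (a validated list with
#'   defaults filled in).
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  defaults <- list(out_dir = ".", n_pairs = 10L, seed = 1L,
                   spacing = 0.2, eval_spacing = 0.2, smoothing_sigma = 1,
                   edge_frac = 0.5, epsilon = 1e-6, superior_channel = "NC5",
                   register_iters = 30L, smooth_lambda = 0.5)
  cfg <- utils::modifyList(defaults, x[!vapply(x, is.null, logical(1))])
  if (!cfg$superior_channel %in% c("NC5", "NC6")) {
    stop("`superior_channel` must be 'NC5' or 'NC6'", call. = FALSE)
  }
  if (cfg$epsilon <= 0 || cfg$smoothing_sigma < 0 || cfg$spacing <= 0) {
    stop("invalid configuration value", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_pairs <- as.integer(cfg$n_pairs)
  structure(cfg, class = "run_config")
}

#' Build a population heart model from binary masks
#'
#' Union (logical OR) of co-registered organ masks followed by watertight
#' surface extraction: the resulting model encompasses every contributing
#' heart and serves as the common source geometry for all deformations.
#'
#' @param masks List of [binary_mask()] objects on one grid, or a character
#'   vector of mask file paths (see [read_mask()]).
#' @param smoothing_iters Surface smoothing passes (default 2, to soften
#'   the voxel staircase).
#' @param out Optional output path for the model (VTK).
#' @return The population [surface_mesh()].
#' @export
run_build_population <- function(masks, smoothing_iters = 2L, out = NULL) {
  if (is.character(masks)) {
    paths <- masks
    masks <- lapply(paths, function(p) {
      tryCatch(read_mask(p), error = function(e) {
        stop(sprintf("failed reading mask '%s': %s", p, conditionMessage(e)),
             call. = FALSE)
      })
    })
    u <- tryCatch(mask_union(masks), error = function(e) {
      stop(sprintf("%s (files: %s)", conditionMessage(e),
                   paste(basename(paths), collapse = ", ")), call. = FALSE)
    })
  } else {
    u <- mask_union(masks)
  }
  model <- mask_to_mesh(u, smoothing_iters = smoothing_iters)
  if (!is.null(out)) write_mesh_vtk(model, out)
  model
}

#' Generate a seeded phantom Reference/Test cohort
#'
#' The stated world for end-to-end testing: `n_pairs` Reference hearts
#' (varied semi-axes and mild surface roughness) inside a shared-geometry
#' thorax; each Test heart is the Reference mapped through a composite
#' scale + translate + bend deformation emulating inter-patient anatomy
#' differences between thorax-matched patients: lateral/longitudinal scale
#' 0.82-1.18 (sized so the *un-adapted* Reference-vs-Test overlap lands in
#' the mid-80s to low-90s, the clinical baseline regime), heart position
#' offsets up to 0.4 cm (matched patients are landmark-aligned, so residual
#' heart translation relative to the bony thorax is small), bend up to
#' 0.5 cm. The anterior-posterior scale stays 1: no lateral film constrains
#' it, and evaluation is COM-aligned.
#'
#' The population model is built the way the field builds it: the voxel
#' union (logical OR) of several generously sized base hearts, surface
#' extracted. A union model *encompasses* every heart it will be deformed
#' onto, which keeps the population-to-Reference displacement large and
#' inward everywhere - the property that makes the adaptation's
#' `(DeltaNC + dNC) / DeltaNC` ratios well conditioned. Purely a function
#' of `seed`.
#'
#' @param n_pairs Number of Reference/Test pairs (default 15, the cohort
#'   size of the clinical study this emulates).
#' @param seed Integer master seed.
#' @param spacing Phantom CT grid spacing (cm; default 0.2, desk scale).
#' @param n_base Base hearts contributing to the population union
#'   (default 6).
#' @return List with `population` (mesh), `thorax` (params) and `pairs`
#'   (each: `id`, `heart_params`, `spec`, `reference`, `test`,
#'   `true_field`).
#' @export
make_phantom_cohort <- function(n_pairs = 15L, seed = 1L, spacing = 0.2,
                                n_base = 6L) {
  set.seed(seed)
  base_axes <- c(5.0, 6.0, 4.2)
  thorax <- thorax_phantom_params(W1 = 15.0, W2 = 24.8, L = 14.3)
  heart_center <- c(0, thorax$L / 2, -2)
  pairs <- lapply(seq_len(n_pairs), function(i) {
    axes <- base_axes * stats::runif(3, 0.94, 1.06)
    lobes <- stats::runif(4, 0.3, 0.9)
    hp <- heart_phantom_params(semi_axes = axes, lobe_amplitudes = lobes,
                               center = heart_center, roughness = 0.1,
                               seed = seed * 1000L + i)
    spec <- deformation_spec("composite", specs = list(
      deformation_spec("scale",
                       factors = c(stats::runif(1, 0.82, 1.18),
                                   stats::runif(1, 0.82, 1.18), 1)),
      deformation_spec("translate",
                       offset = c(stats::runif(1, -0.4, 0.4),
                                  stats::runif(1, -0.4, 0.4), 0)),
      deformation_spec("bend", amplitude = stats::runif(1, -0.5, 0.5),
                       wavelength = 25, y0 = heart_center[2])))
    pair <- generate_deformed_pair(hp, spec)
    c(list(id = sprintf("pair%02d", i), heart_params = hp, spec = spec), pair)
  })
  # Population model: union of base-heart masks, surface extracted (Step A).
  # Bases are drawn at the generous end of the anatomy range so their union
  # encompasses every cohort heart, as a real multi-patient union does.
  base_masks <- lapply(seq_len(n_base), function(i) {
    bp <- heart_phantom_params(
      semi_axes = base_axes * stats::runif(3, 1.06, 1.20),
      lobe_amplitudes = stats::runif(4, 0.7, 1.0),
      center = heart_center, seed = seed * 100L + i)
    mesh_to_mask_on(generate_heart(bp), heart_center)
  })
  population <- mask_to_mesh(mask_union(base_masks), smoothing_iters = 3L)
  list(population = population, thorax = thorax,
       pairs = pairs, spacing = spacing)
}

# Voxelize a base heart on the fixed population grid (0.35 cm; coarse is
# fine for a population prior, and keeps the union mesh light).
mesh_to_mask_on <- function(mesh, center, half_extent = 9.5, spacing = 0.35) {
  dims <- rep(as.integer(ceiling(2 * half_extent / spacing)), 3L)
  voxelize_on_grid(mesh, dims, rep(spacing, 3L), center - half_extent)
}

#' Reconstruct a Test heart from its 2D image and a Reference registration
#'
#' The core per-pair flow: rigidly align the Test image to the Reference
#' image on the bony landmarks, place the six navigator channels on the
#' Reference image at the supplied anchors, measure the per-channel edge
#' shifts, sample the population-to-Reference field at the channels, adapt
#' the field and apply it to the population model.
#'
#' @param population Population [surface_mesh()].
#' @param registration A [register_surface()] result (population ->
#'   Reference).
#' @param ref_drr,test_drr [drr_image()] objects (Test already scaled to
#'   Reference magnification; see [scale_to_reference()]).
#' @param anchors 6 x 2 anchor matrix (reference frame, cm); default
#'   derived from the Reference heart contour via [suggest_anchors()].
#' @param config A [run_config()].
#' @return List: `mesh` (reconstructed Test model), `adapted` (field),
#'   `reference_model` (population deformed to Reference), `states` (six
#'   [channel_state()]s), `channels`, `shifts`, `rigid`.
#' @export
reconstruct_test_heart <- function(population, registration, ref_drr,
                                   test_drr, anchors = NULL,
                                   config = run_config()) {
  stopifnot(inherits(registration, "registration_result"))
  rigid <- rigid_align_2d(ref_drr, test_drr)
  test_aligned <- apply_rigid_2d(test_drr, rigid)
  if (is.null(anchors)) anchors <- suggest_anchors(ref_drr)
  channels <- place_channels(ref_drr, anchors)
  shifts <- lapply(channels, function(nc) {
    compute_shift(extract_profile(ref_drr, nc),
                  extract_profile(test_aligned, nc),
                  smoothing_sigma = config$smoothing_sigma,
                  edge_frac = config$edge_frac)
  })
  ref_model <- apply_field(population, registration$field)
  states <- lapply(seq_along(channels), function(i) {
    channel_state(channels[[i]]$role,
                  delta = field_at_channel(registration$field, ref_model,
                                           channels[[i]]),
                  shift = shifts[[i]]$shift)
  })
  adapted <- adapt_field(registration$field, population, states, channels,
                         role_map = c(superior = config$superior_channel),
                         eps = config$epsilon)
  list(mesh = reconstruct(population, adapted), adapted = adapted,
       reference_model = ref_model, states = states, channels = channels,
       shifts = shifts, rigid = rigid)
}

# Render the two DRRs of a cohort pair (reference heart and test heart in
# the shared thorax).
render_pair_drrs <- function(cohort, pair) {
  ct_ref <- generate_thorax_ct(cohort$thorax, pair$reference,
                               spacing = rep(cohort$spacing, 3))
  ct_test <- generate_thorax_ct(cohort$thorax, pair$test,
                                spacing = rep(cohort$spacing, 3))
  list(ref = render_drr(ct_ref, subject_id = paste0(pair$id, "_ref")),
       test = render_drr(ct_test, subject_id = paste0(pair$id, "_test")))
}

#' Run the reconstruction pipeline over a phantom cohort
#'
#' For every pair: register the population model to the Reference heart,
#' render both DRRs, reconstruct the Test heart from the Test DRR, and
#' score the reconstruction (Dice against the true Test mesh, COM-aligned)
#' with and without navigator-channel adaptation (the un-adapted comparator
#' is the population-to-Reference model, exactly the "population
#' deformation model" baseline).
#'
#' @param cohort From [make_phantom_cohort()].
#' @param config A [run_config()].
#' @param progress Emit one message per pair (default FALSE).
#' @return Data frame: `pair_id`, `dice_with_nc`, `dice_without_nc`,
#'   `registration_residual`, plus attribute `details` (per-pair results).
#' @export
run_cohort <- function(cohort, config = run_config(), progress = FALSE) {
  details <- vector("list", length(cohort$pairs))
  rows <- vector("list", length(cohort$pairs))
  for (i in seq_along(cohort$pairs)) {
    pair <- cohort$pairs[[i]]
    if (progress) message(sprintf("[%s] registering + reconstructing", pair$id))
    reg <- register_surface(cohort$population, pair$reference,
                            iters = config$register_iters,
                            smooth_lambda = config$smooth_lambda)
    drrs <- render_pair_drrs(cohort, pair)
    rec <- reconstruct_test_heart(cohort$population, reg, drrs$ref,
                                  drrs$test, config = config)
    sp <- rep(config$eval_spacing, 3)
    with_nc <- dice(rec$mesh, pair$test, com_align = TRUE, spacing = sp)
    without_nc <- dice(rec$reference_model, pair$test, com_align = TRUE,
                       spacing = sp)
    rows[[i]] <- data.frame(pair_id = pair$id,
                            dice_with_nc = with_nc$dice_pct,
                            dice_without_nc = without_nc$dice_pct,
                            registration_residual = reg$residual$mean)
    details[[i]] <- list(reconstruction = rec, registration = reg,
                         dice_with = with_nc, dice_without = without_nc)
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}

#' Evaluate a cohort result table
#'
#' @param results Data frame from [run_cohort()] (or read back from its
#'   CSV): needs `dice_with_nc` and `dice_without_nc`.
#' @return List: `with_nc`, `without_nc` ([summarize_cohort()] objects) and
#'   `paired` (the [paired_t()] comparison, NULL when variance degenerates
#'   to zero with identical columns handled as t = 0, p = 1).
#' @export
run_evaluate <- function(results) {
  if (!nrow(results)) stop("empty cohort", call. = FALSE)
  list(with_nc = summarize_cohort(results$dice_with_nc),
       without_nc = summarize_cohort(results$dice_without_nc),
       paired = paired_t(results$dice_with_nc, results$dice_without_nc))
}

# ---------------------------------------------------------------------------
# File-based driver used by the command-line tool.

prov_digest <- function(path) unname(tools::md5sum(path))

#' Write cohort fixtures to a directory
#'
#' Emits the standard small phantom cohort as plain files: the population
#' model (VTK), per-pair reference/test heart meshes, both DRRs (PGM +
#' JSON sidecar) and the parameter records.
#'
#' @param config A [run_config()] (uses `out_dir`, `n_pairs`, `seed`,
#'   `spacing`).
#' @return The cohort, invisibly.
#' @export
run_fixtures <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_phantom_cohort(config$n_pairs, config$seed, config$spacing)
  write_mesh_vtk(cohort$population, file.path(config$out_dir, "population.vtk"))
  write_params_json(cohort$thorax, file.path(config$out_dir, "thorax.json"))
  for (pair in cohort$pairs) {
    pd <- file.path(config$out_dir, pair$id)
    dir.create(pd, showWarnings = FALSE)
    write_mesh_vtk(pair$reference, file.path(pd, "reference.vtk"))
    write_mesh_vtk(pair$test, file.path(pd, "test_truth.vtk"))
    write_params_json(pair$heart_params, file.path(pd, "heart_params.json"))
    drrs <- render_pair_drrs(cohort, pair)
    write_drr(drrs$ref, file.path(pd, "ref_drr.pgm"))
    write_drr(drrs$test, file.path(pd, "test_drr.pgm"))
  }
  invisible(cohort)
}

#' Reconstruct every pair in a fixtures directory
#'
#' File-based counterpart of [run_cohort()]: reads the fixtures written by
#' [run_fixtures()], reconstructs each Test heart, and persists the adapted
#' field, reconstructed mesh and a provenance record (config echo, all six
#' Delta-NC / dNC pairs, registration residuals, md5 digests of inputs and
#' outputs - enough to re-derive the run).
#'
#' @param config A [run_config()]; `out_dir` must hold fixtures.
#' @return Data frame as from [run_cohort()].
#' @export
run_reconstruct <- function(config = run_config()) {
  od <- config$out_dir
  pop_path <- file.path(od, "population.vtk")
  if (!file.exists(pop_path)) {
    stop(sprintf("no population model at '%s' (run fixtures first)", pop_path),
         call. = FALSE)
  }
  population <- read_mesh_vtk(pop_path)
  pair_dirs <- sort(list.dirs(od, recursive = FALSE))
  pair_dirs <- pair_dirs[file.exists(file.path(pair_dirs, "ref_drr.pgm"))]
  if (!length(pair_dirs)) stop("no pair fixtures found", call. = FALSE)
  rows <- vector("list", length(pair_dirs))
  for (i in seq_along(pair_dirs)) {
    pd <- pair_dirs[i]
    id <- basename(pd)
    stage <- "load"
    res <- tryCatch({
      reference <- read_mesh_vtk(file.path(pd, "reference.vtk"))
      truth <- read_mesh_vtk(file.path(pd, "test_truth.vtk"))
      ref_drr <- read_drr(file.path(pd, "ref_drr.pgm"))
      test_drr <- read_drr(file.path(pd, "test_drr.pgm"))
      stage <- "register"
      reg <- register_surface(population, reference,
                              iters = config$register_iters,
                              smooth_lambda = config$smooth_lambda)
      stage <- "reconstruct"
      rec <- reconstruct_test_heart(population, reg, ref_drr, test_drr,
                                    config = config)
      stage <- "evaluate"
      sp <- rep(config$eval_spacing, 3)
      with_nc <- dice(rec$mesh, truth, com_align = TRUE, spacing = sp)
      without_nc <- dice(rec$reference_model, truth, com_align = TRUE,
                         spacing = sp)
      stage <- "persist"
      write_mesh_vtk(rec$mesh, file.path(pd, "reconstructed.vtk"))
      write_field_csv(rec$adapted, file.path(pd, "adapted_field.csv"))
      prov <- list(
        pair = id,
        config = unclass(config),
        channels = lapply(rec$states, function(s) {
          list(role = s$role, delta_nc = s$delta, shift_nc = s$shift)
        }),
        rigid_translation = rec$rigid$translation,
        registration = list(iterations = reg$iterations,
                            residual_mean = reg$residual$mean,
                            residual_max = reg$residual$max),
        dice_with_nc = with_nc$dice_pct,
        dice_without_nc = without_nc$dice_pct,
        inputs = list(
          population_md5 = prov_digest(pop_path),
          reference_md5 = prov_digest(file.path(pd, "reference.vtk")),
          ref_drr_md5 = prov_digest(file.path(pd, "ref_drr.pgm")),
          test_drr_md5 = prov_digest(file.path(pd, "test_drr.pgm"))),
        outputs = list(
          reconstructed_md5 = prov_digest(file.path(pd, "reconstructed.vtk")),
          adapted_field_md5 = prov_digest(file.path(pd, "adapted_field.csv"))))
      jsonlite::write_json(prov, file.path(pd, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      data.frame(pair_id = id, dice_with_nc = with_nc$dice_pct,
                 dice_without_nc = without_nc$dice_pct,
                 registration_residual = reg$residual$mean)
    }, error = function(e) {
      stop(sprintf("[%s, stage %s] %s", id, stage, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(od, "reconstruction_results.csv"),
                   row.names = FALSE, quote = FALSE)
  out
}

#' Evaluate a fixtures directory and write the summary report
#'
#' @param config A [run_config()]; `out_dir` must hold
#'   `reconstruction_results.csv` from [run_reconstruct()].
#' @return The [run_evaluate()] report, invisibly; writes
#'   `evaluation_summary.json`.
#' @export
run_evaluate_dir <- function(config = run_config()) {
  path <- file.path(config$out_dir, "reconstruction_results.csv")
  if (!file.exists(path)) {
    stop("no reconstruction results found (run reconstruct first)",
         call. = FALSE)
  }
  results <- utils::read.csv(path)
  rep <- run_evaluate(results)
  jsonlite::write_json(
    list(with_nc = unclass(rep$with_nc), without_nc = unclass(rep$without_nc),
         paired_t = rep$paired),
    file.path(config$out_dir, "evaluation_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}
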