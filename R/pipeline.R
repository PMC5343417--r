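#' Pipeline configuration
#'
#' One object collecting every knob of the end-to-end analysis.  The input
#' is either a synthetic population (`population` config) or a directory of
#' meshes with a manifest CSV (columns id, gender, side, file).
#'
#' @param population a [population_config()] (used when `mesh_dir` is
#'   `NULL`).
#' @param genders,sides which gender x side cells to generate from the
#'   population config (single-side runs give the side-specific model a
#'   same-side reference, which its mean surface needs).
#' @param mesh_dir,manifest directory of PLY/STL/OBJ meshes plus manifest
#'   CSV path, as an alternative input source.
#' @param align `"none"` (inputs already share the standardized frame, as
#'   generated synthetic bones do) or `"icp"` (rigidly register every
#'   specimen to the reference first).
#' @param reference index or id of the reference specimen (template source
#'   and ICP target).
#' @param n_landmarks template landmark count; `NULL` uses every reference
#'   vertex, which lets mean shapes inherit the reference connectivity.
#' @param gpa_scaling allow scaling in the Procrustes alignment (default
#'   FALSE: size is analysis signal and is retained).
#' @param variance_threshold explained-variance threshold for the mode
#'   count.
#' @param n_trees,n_iterations random-forest size and LOOCV repetitions.
#' @param forest_seed seed for classifier randomness.
#' @param template_seed seed for the farthest-point template start.
#' @param projection_guard maximal allowed template projection distance
#'   (mm); population size spread concentrates at the styloid tip, so this
#'   is larger than the single-specimen default of
#'   [correspond_to_template()].
#' @param classify run the classification stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(population = population_config(),
                            genders = c("F", "M"), sides = c("L", "R"),
                            mesh_dir = NULL, manifest = NULL,
                            align = c("none", "icp"),
                            reference = 1L,
                            n_landmarks = NULL,
                            gpa_scaling = FALSE,
                            variance_threshold = 0.95,
                            n_trees = 50L,
                            n_iterations = 100L,
                            forest_seed = 1L,
                            template_seed = 1L,
                            projection_guard = 40,
                            classify = TRUE) {
  align <- match.arg(align)
  structure(list(population = population, genders = genders, sides = sides,
                 mesh_dir = mesh_dir,
                 manifest = manifest, align = align, reference = reference,
                 n_landmarks = n_landmarks, gpa_scaling = gpa_scaling,
                 variance_threshold = variance_threshold,
                 n_trees = as.integer(n_trees),
                 n_iterations = as.integer(n_iterations),
                 forest_seed = as.integer(forest_seed),
                 template_seed = as.integer(template_seed),
                 projection_guard = projection_guard,
                 classify = classify),
            class = "pipeline_config")
}

load_mesh_population <- function(mesh_dir, manifest) {
  # "F" must stay a gender label, not become FALSE
  mf <- utils::read.csv(manifest, colClasses = "character")
  need <- c("id", "gender", "side", "file")
  if (!all(need %in% names(mf)))
    stop("manifest needs columns id, gender, side, file")
  lapply(seq_len(nrow(mf)), function(i) {
    mesh <- read_mesh(file.path(mesh_dir, mf$file[i]))
    labeled_mesh(mesh, gender = mf$gender[i], side = mf$side[i],
                 truth_landmarks = NULL, params = NULL, id = mf$id[i])
  })
}

#' Run the full shape-analysis pipeline
#'
#' Executes the standard workflow: obtain specimens (generate or load),
#' validate, align, build the dense correspondence, Procrustes-align the
#' landmark sets, fit the overall and the gender-/side-specific Point
#' Distribution Models, count modes at the explained-variance threshold,
#' detect the anatomical landmarks, construct the standardized cut planes,
#' compute per-specimen and mean-shape morphometrics, run the group
#' statistics and (optionally) the LOOCV side/gender classification.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if non-NULL, the result bundle is also written there as
#'   CSV/JSON files (see [write_result_bundle()]).
#' @return an object of class `radius_pipeline`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for '%s': %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }
  population <- if (is.null(config$mesh_dir)) {
    sample_population(config$population, genders = config$genders,
                      sides = config$sides)
  } else {
    load_mesh_population(config$mesh_dir, config$manifest)
  }
  ids <- vapply(population, `[[`, "", "id")
  for (b in population)
    stage("validate", b$id, assert_pipeline_mesh(b$mesh, b$id))

  ref_idx <- if (is.character(config$reference))
    match(config$reference, ids) else as.integer(config$reference)
  if (is.na(ref_idx) || ref_idx < 1 || ref_idx > length(population))
    stop("reference specimen not found")
  reference <- population[[ref_idx]]$mesh

  meshes <- lapply(population, `[[`, "mesh")
  if (config$align == "icp") {
    meshes <- lapply(seq_along(meshes), function(i) {
      if (i == ref_idx) return(meshes[[i]])
      stage("align", ids[i], {
        reg <- rigid_icp(meshes[[i]], reference)
        transform_mesh(meshes[[i]], reg$transform)
      })
    })
  }

  template <- make_template(reference, n = config$n_landmarks,
                            seed = config$template_seed)
  shapes <- lapply(seq_along(meshes), function(i)
    stage("correspond", ids[i],
          correspond_to_template(template, meshes[[i]], id = ids[i],
                                 guard = config$projection_guard)))

  gpa <- stage("gpa", "population",
               generalized_procrustes(shapes,
                                      allow_scaling = config$gpa_scaling))
  aligned <- gpa$aligned

  genders <- vapply(population, `[[`, "", "gender")
  sides <- vapply(population, `[[`, "", "side")
  subsets <- list(overall = rep(TRUE, length(aligned)),
                  F = genders == "F", M = genders == "M",
                  L = sides == "L", R = sides == "R")
  models <- list()
  for (nm in names(subsets)) {
    if (sum(subsets[[nm]]) >= 2L)
      models[[nm]] <- stage("model", nm, pdm(aligned[subsets[[nm]]]))
  }
  mode_counts <- data.frame(
    model = names(models),
    n_specimens = vapply(names(models), function(nm) sum(subsets[[nm]]), 0L),
    n_modes = vapply(models, num_modes,
                     threshold = config$variance_threshold, 0L),
    first_mode_pct = vapply(models, function(m) {
      tot <- sum(m$eigenvalues)
      if (tot > 0) 100 * m$eigenvalues[1] / tot else 0
    }, 0))
  rownames(mode_counts) <- NULL

  morpho <- do.call(rbind, lapply(seq_along(meshes), function(i)
    stage("cutplanes", ids[i],
          specimen_morphometrics(meshes[[i]], id = ids[i],
                                 gender = genders[i], side = sides[i]))))
  rownames(morpho) <- NULL

  # mean-shape sections: only the side-pure model sharing the reference's
  # side has an anatomically interpretable (unblended) mean surface whose
  # template projection is reliable, and only full-vertex templates carry
  # connectivity
  mean_morpho <- NULL
  if (is.null(config$n_landmarks)) {
    for (nm in intersect(sides[ref_idx], names(models))) {
      mm <- tryCatch(
        specimen_morphometrics(mean_mesh(models[[nm]], reference),
                               id = paste0("mean_", nm), gender = NA,
                               side = nm),
        error = function(e) NULL)
      mean_morpho <- rbind(mean_morpho, mm)
    }
  }

  report <- stage("stats", "population",
                  if (length(unique(genders)) == 2L &&
                      length(unique(sides)) == 2L) stats_report(morpho)
                  else group_descriptives(morpho, by = c("gender", "plane")))

  # classification uses the full coefficient vector of the overall model;
  # the 95% truncation defines the reported mode count, but discriminative
  # shape differences (notably side) may sit in later modes
  records <- specimen_records(
    ids, genders, sides,
    coefficients = t(vapply(aligned, function(s)
      project_shape(models$overall, s),
      numeric(ncol(models$overall$modes)))),
    morphometrics = morpho)

  classification <- NULL
  if (config$classify && nlevels(droplevels(factor(sides))) == 2L &&
      nlevels(droplevels(factor(genders))) == 2L) {
    classification <- stage("classify", "population", list(
      side = loocv_random_forest(records, "side", config$n_trees,
                                 config$n_iterations, config$forest_seed),
      gender = loocv_random_forest(records, "gender", config$n_trees,
                                   config$n_iterations, config$forest_seed),
      stepwise = stepwise_side_then_gender(records, config$n_trees,
                                           config$n_iterations,
                                           config$forest_seed)))
  }

  bundle <- structure(list(config = config, ids = ids, genders = genders,
                           sides = sides, template = template,
                           reference_id = ids[ref_idx],
                           shapes = aligned, gpa_mean = gpa$mean,
                           models = models, mode_counts = mode_counts,
                           morphometrics = morpho,
                           mean_shape_morphometrics = mean_morpho,
                           stats = report, records = records,
                           classification = classification),
                      class = "radius_pipeline")
  if (!is.null(out_dir)) write_result_bundle(bundle, out_dir)
  bundle
}

#' @export
print.radius_pipeline <- function(x, ...) {
  cat(sprintf("radius_pipeline: %d specimens (reference %s)\n",
              length(x$ids), x$reference_id))
  cat("mode counts at threshold", x$config$variance_threshold, "\n")
  print(x$mode_counts, row.names = FALSE)
  if (!is.null(x$classification)) {
    for (nm in names(x$classification))
      cat(sprintf("  %s: median LOOCV accuracy %.1f%%\n", nm,
                  100 * x$classification[[nm]]$median))
  }
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' CSV tables (morphometrics, descriptives, mode counts, per-iteration
#' accuracies) and JSON summaries (models, test results, config echo).
#'
#' @param bundle a `radius_pipeline` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$morphometrics,
                   file.path(out_dir, "morphometrics.csv"), row.names = FALSE)
  utils::write.csv(bundle$stats$descriptives,
                   file.path(out_dir, "descriptives.csv"), row.names = FALSE)
  utils::write.csv(bundle$mode_counts,
                   file.path(out_dir, "mode_counts.csv"), row.names = FALSE)
  if (!is.null(bundle$mean_shape_morphometrics))
    utils::write.csv(bundle$mean_shape_morphometrics,
                     file.path(out_dir, "mean_shape_morphometrics.csv"),
                     row.names = FALSE)
  utils::write.csv(rbind(bundle$stats$gender, bundle$stats$side),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  for (nm in names(bundle$models))
    write_pdm_json(bundle$models[[nm]],
                   file.path(out_dir, sprintf("model_%s.json", nm)))
  if (!is.null(bundle$classification)) {
    for (nm in names(bundle$classification))
      write_accuracy(bundle$classification[[nm]],
                     json_path = file.path(out_dir,
                                           sprintf("classify_%s.json", nm)),
                     csv_path = file.path(out_dir,
                                          sprintf("classify_%s.csv", nm)))
  }
  invisible(out_dir)
}
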