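#' Configuration of a synthetic bone population
#'
#' Defines the latent statistical model from which per-specimen
#' [bone_params()] are drawn.  Each specimen gets an isotropic size factor
#' (log-normal, mean-one; males additionally scaled by
#' `gender_width_ratio`) and a set of mean-one log-normal shape factors
#' (width and depth aspect, segment length, taper exponent, tubercle
#' prominence, axial curvature, squareness, styloid height).  The
#' medio-lateral mirror is the only systematic side effect; on left
#' specimens the *shape* factor SDs (not the size factor) are multiplied by
#' `sqrt(side_variance_ratio)`, emulating a population whose left bones
#' vary more in shape while sides do not differ in mean size.
#'
#' The default latent SDs are calibrated from the bundled reference
#' statistics (`calibration`): the size-factor SD plus the width/depth
#' aspect SDs are solved so the pooled (both sides) distal-plane width and
#' depth SDs match their reference values.
#'
#' @param n_per_group specimens per gender x side cell.
#' @param gender_width_ratio male/female mean size factor.
#' @param side_variance_ratio left/right latent shape-variance factor
#'   (>= 0; 1 disables the side effect).
#' @param latent_sds named numeric vector of per-factor SDs on the log
#'   scale (`scale`, `width`, `depth`, `length`, `taper`, `tubercle`,
#'   `curvature`, `squareness`, `styloid`); `width`/`depth`/`scale` default
#'   to the calibrated solution, the rest to realistic mild values.
#' @param vertex_noise_sd per-vertex Gaussian noise SD (mm).
#' @param mesh_resolution target mesh edge length (mm).
#' @param seed integer seed; the same seed yields a byte-identical
#'   population.
#' @param calibration list of distal-plane anchor statistics
#'   (`width_mean`, `width_sd`, `depth_mean`, `depth_sd`), defaulting to
#'   the bundled female reference values.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_per_group = 10L,
                              gender_width_ratio = 33.0 / 29.0,
                              side_variance_ratio = 2,
                              latent_sds = NULL,
                              vertex_noise_sd = 0.05,
                              mesh_resolution = 0.8,
                              seed = 1L,
                              calibration = NULL) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (side_variance_ratio < 0) stop("side_variance_ratio must be >= 0")
  if (vertex_noise_sd < 0) stop("vertex_noise_sd must be >= 0")
  if (is.null(calibration)) {
    tab <- reference_morphometrics()
    calibration <- list(
      width_mean = ref_value(tab, "distal", "width"),
      width_sd = tab$sd[tab$plane == "distal" & tab$parameter == "width" &
                          tab$gender == "F"],
      depth_mean = ref_value(tab, "distal", "depth"),
      depth_sd = tab$sd[tab$plane == "distal" & tab$parameter == "depth" &
                          tab$gender == "F"])
  }
  sds <- c(scale = 0.06, width = NA, depth = NA, length = 0.03,
           taper = 0.25, tubercle = 0.15, curvature = 0.30,
           squareness = 0.04, styloid = 0.12)
  if (!is.null(latent_sds)) {
    if (is.null(names(latent_sds)) || !all(names(latent_sds) %in% names(sds)))
      stop("latent_sds must be named with known factor names")
    sds[names(latent_sds)] <- latent_sds
  }
  # pooled distal CV over both sides: cv^2 = sd_scale^2 + v * sd_aspect^2
  # with v = (1 + side_variance_ratio) / 2
  v <- (1 + side_variance_ratio) / 2
  solve_aspect <- function(cv, have) {
    x2 <- (cv^2 - sds[["scale"]]^2) / v
    if (is.na(have)) {
      if (x2 < 0)
        stop("scale latent SD exceeds the calibrated total width/depth CV")
      sqrt(x2)
    } else have
  }
  sds[["width"]] <- solve_aspect(calibration$width_sd / calibration$width_mean,
                                 sds[["width"]])
  sds[["depth"]] <- solve_aspect(calibration$depth_sd / calibration$depth_mean,
                                 sds[["depth"]])
  if (any(sds < 0)) stop("latent SDs must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 gender_width_ratio = gender_width_ratio,
                 side_variance_ratio = side_variance_ratio,
                 latent_sds = sds,
                 vertex_noise_sd = vertex_noise_sd,
                 mesh_resolution = mesh_resolution,
                 seed = as.integer(seed),
                 calibration = calibration),
            class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf(
    "population_config: %d per gender x side cell (%d total), seed %d\n",
    x$n_per_group, 4L * x$n_per_group, x$seed))
  cat(sprintf("  gender size ratio %.3f, side variance ratio %.2f\n",
              x$gender_width_ratio, x$side_variance_ratio))
  cat("  latent SDs:",
      paste(sprintf("%s=%.3f", names(x$latent_sds), x$latent_sds),
            collapse = " "), "\n")
  invisible(x)
}

# mean-one log-normal factor
lnorm_factor <- function(sd) exp(stats::rnorm(1L, 0, sd) - sd^2 / 2)

#' Draw per-specimen bone parameters from a population configuration
#'
#' @param config a [population_config()].
#' @param gender `"F"` or `"M"`.
#' @param side `"L"` or `"R"`.
#' @return a [bone_params()] object.
#' @keywords internal
draw_bone_params <- function(config, gender, side) {
  sds <- config$latent_sds
  m <- if (side == "L") sqrt(config$side_variance_ratio) else 1
  base <- if (gender == "M") config$gender_width_ratio else 1
  s <- base * lnorm_factor(sds[["scale"]])
  f_w <- lnorm_factor(m * sds[["width"]])
  f_d <- lnorm_factor(m * sds[["depth"]])
  f_L <- lnorm_factor(m * sds[["length"]])
  gamma_t <- 1 + stats::rnorm(1L, 0, m * sds[["taper"]])
  f_tub <- lnorm_factor(m * sds[["tubercle"]])
  f_crv <- lnorm_factor(m * sds[["curvature"]])
  f_sq <- lnorm_factor(m * sds[["squareness"]])
  f_sty <- lnorm_factor(m * sds[["styloid"]])

  sp <- default_station_profiles()
  i_ref <- which.max(sp$half_width)          # distal anchor station
  a_ref <- sp$half_width[i_ref]
  b_ref <- sp$half_depth[i_ref]
  ratio_pow <- function(v, ref, g) ref * (v / ref)^g
  sp$half_width <- f_w * ratio_pow(sp$half_width, a_ref, gamma_t)
  sp$half_depth <- f_d * ratio_pow(sp$half_depth, b_ref, gamma_t)
  sp$squareness <- pmax(1, sp$squareness * f_sq)
  bone_params(axis_length = 70 * f_L,
              axial_curvature = 0.0015 * f_crv,
              station_profiles = sp,
              styloid_height = 6 * f_sty,
              tubercle_prominence = 1.2 * f_d * f_tub,
              side = side,
              global_scale = s)
}

#' Sample a synthetic bone population
#'
#' Draws `n_per_group` specimens for every gender x side cell and generates
#' their surface meshes.  Fully deterministic under the config seed (the
#' caller's RNG state is left untouched).
#'
#' @param config a [population_config()].
#' @param genders,sides which cells to generate (defaults: both genders,
#'   both sides).
#' @param meshes if `FALSE`, skip mesh generation and return only the drawn
#'   parameters (fast path for parameter-level studies).
#' @return list of [labeled_mesh()] objects (or of [bone_params()] when
#'   `meshes = FALSE`, with names giving specimen ids).
#' @export
sample_population <- function(config, genders = c("F", "M"),
                              sides = c("L", "R"), meshes = TRUE) {
  stopifnot(inherits(config, "population_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  out <- list()
  for (g in genders) for (sd in sides) for (i in seq_len(config$n_per_group)) {
    id <- sprintf("%s%s%03d", g, sd, i)
    par <- draw_bone_params(config, g, sd)
    if (meshes) {
      out[[id]] <- generate_bone(par, resolution = config$mesh_resolution,
                                 gender = g, id = id,
                                 vertex_noise_sd = config$vertex_noise_sd)
    } else {
      out[[id]] <- par
      attr(out[[id]], "gender") <- g
    }
  }
  out
}

#' Write a population manifest CSV
#'
#' One row per specimen: id, gender, side, seed and ground-truth landmark
#' coordinates.
#'
#' @param population list of [labeled_mesh()] objects.
#' @param path CSV path.
#' @param seed the generating seed recorded in every row.
#' @return `path`, invisibly.
#' @export
write_population_manifest <- function(population, path, seed = NA_integer_) {
  rows <- do.call(rbind, lapply(population, function(b) {
    data.frame(id = b$id, gender = b$gender, side = b$side, seed = seed,
               styloid_x = b$truth_landmarks$styloid_tip[1],
               styloid_y = b$truth_landmarks$styloid_tip[2],
               styloid_z = b$truth_landmarks$styloid_tip[3],
               tubercle_x = b$truth_landmarks$tubercle_dorsal[1],
               tubercle_y = b$truth_landmarks$tubercle_dorsal[2],
               tubercle_z = b$truth_landmarks$tubercle_dorsal[3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
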