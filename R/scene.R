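#' Generator configuration for synthetic posterior-pole scenes
#'
#' Bundles every tunable parameter of the synthetic eye generator. Distances
#' are in micrometers unless noted, points and radii in millimeters, angles in
#' degrees, thicknesses in micrometers.
#'
#' The defaults encode a cohort in which the architectural (axon-field) disc
#' center sits 4680 um from the fovea on average in both groups, and SIOD eyes
#' additionally carry a Bruch's-membrane-opening (BMO) center displaced toward
#' the fovea by 465 um on average, so that the measured foveo-BMO-center
#' distance averages 4215 um in SIOD eyes. The RNFL field is a 1/r
#' double-wrapped-Gaussian with humps at +/-75 deg from the temporal horizontal
#' of the per-eye foveo-disc axis.
#'
#' @param arch_distance_mean mean fovea to architectural-disc-center distance (um).
#' @param arch_distance_sd_between between-subject SD of that distance (um).
#' @param arch_distance_sd_within within-subject (between-eye) SD (um).
#' @param displacement_mean mean temporal BMO displacement for SIOD eyes (um);
#'   0 produces a null (no-effect) cohort.
#' @param displacement_sd SD of the displacement (um); draws are truncated at 0.
#' @param axis_angle_mean,axis_angle_sd reported foveo-BMO axis angle (deg,
#'   negative = disc superior to the fovea); group-independent.
#' @param bmo_semiaxis_means,bmo_semiaxis_sd BMO ellipse semiaxes (mm).
#' @param baseline RNFL field baseline thickness b at the reference radius (um).
#' @param amp_sup,amp_inf superior/inferior hump amplitudes (um).
#' @param hump_angle hump center angle from the temporal horizontal (deg).
#' @param hump_sigma wrapped-Gaussian hump width (deg).
#' @param reference_radius field reference radius r0 (mm).
#' @param noise_sd additive per-pixel raster noise SD (um).
#' @param subject_effect_sd SD of the per-subject baseline offset shared by
#'   paired eyes (um).
#' @param arcade_halfwidth_mean,arcade_halfwidth_sd half-spread of each venous
#'   arcade at the fovea's vertical line (mm).
#' @param arcade_scale photograph scale for arcade measurements (arbitrary
#'   units per mm); the inter-arcade distance is reported in these units.
#' @param age_mean,age_sd,age_range subject age distribution (years), truncated
#'   to `age_range`.
#' @param axial_length_mean,axial_length_sd axial length distribution (mm).
#' @param p_male probability that a subject is male (group-independent).
#'
#' @return an object of class `scene_params` (a validated list).
#' @export
#' @examples
#' p <- scene_params()
#' p$displacement_mean
scene_params <- function(arch_distance_mean = 4680,
                         arch_distance_sd_between = 200,
                         arch_distance_sd_within = 165,
                         displacement_mean = 465,
                         displacement_sd = 120,
                         axis_angle_mean = -7.5,
                         axis_angle_sd = 3.3,
                         bmo_semiaxis_means = c(0.88, 0.85),
                         bmo_semiaxis_sd = 0.05,
                         baseline = 50,
                         amp_sup = 80,
                         amp_inf = 80,
                         hump_angle = 75,
                         hump_sigma = 25,
                         reference_radius = 1.73,
                         noise_sd = 4,
                         subject_effect_sd = 6,
                         arcade_halfwidth_mean = 2.711,
                         arcade_halfwidth_sd = 0.577,
                         arcade_scale = 333.3,
                         age_mean = 58,
                         age_sd = 14,
                         age_range = c(25, 90),
                         axial_length_mean = 24.25,
                         axial_length_sd = 0.3,
                         p_male = 0.4) {
  p <- as.list(environment())
  if (p$arch_distance_mean <= 0) stop_config("arch_distance_mean must be positive")
  if (p$displacement_mean < 0) stop_config("displacement_mean must be >= 0")
  if (p$displacement_mean >= p$arch_distance_mean) {
    stop_config("displacement_mean must be smaller than arch_distance_mean")
  }
  sds <- c(p$arch_distance_sd_between, p$arch_distance_sd_within,
           p$displacement_sd, p$axis_angle_sd, p$bmo_semiaxis_sd,
           p$noise_sd, p$subject_effect_sd, p$arcade_halfwidth_sd,
           p$age_sd, p$axial_length_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stop_config("all SDs must be finite and >= 0")
  if (length(p$bmo_semiaxis_means) != 2 || any(p$bmo_semiaxis_means <= 0)) {
    stop_config("bmo_semiaxis_means must be two positive semiaxes (mm)")
  }
  if (p$hump_sigma <= 0) stop_config("hump_sigma must be positive")
  if (p$reference_radius <= 0) stop_config("reference_radius must be positive")
  if (p$baseline <= 0) stop_config("baseline thickness must be positive")
  if (p$arcade_halfwidth_mean <= 0 || p$arcade_scale <= 0) {
    stop_config("arcade half-width and scale must be positive")
  }
  if (p$p_male < 0 || p$p_male > 1) stop_config("p_male must be a probability")
  if (length(p$age_range) != 2 || diff(p$age_range) <= 0) {
    stop_config("age_range must be an increasing pair")
  }
  structure(p, class = "scene_params")
}

#' Generate one synthetic posterior-pole scene
#'
#' Draws the landmark geometry and field parameters of a single synthetic eye.
#' Scenes are constructed in the canonical right-eye frame (origin at the
#' fovea, +x nasal toward the disc, +y superior); left-eye scenes are stored
#' mirrored about the vertical axis and flagged by `laterality`.
#'
#' The measured BMO center lies on the segment from the fovea to the
#' architectural disc center, at `displacement` um short of it; control eyes
#' have `displacement == 0` so the two centers coincide.
#'
#' @param params a [scene_params()] object.
#' @param group `"control"` or `"siod"`.
#' @param laterality `"right"` or `"left"`.
#' @param rng_seed integer seed; identical seed and config give an identical
#'   scene. `NULL` continues the current RNG stream (used by [generate_cohort()]).
#' @param eye_id,subject_id identifiers.
#' @param age,axial_length,sex,subject_effect,arch_shift optional subject-level
#'   overrides (used when paired eyes must share subject-level draws).
#' @param arch_distance,displacement optional fixed values (um) overriding the
#'   random draws.
#'
#' @return an object of class `pp_scene`.
#' @export
#' @examples
#' s <- generate_scene(group = "siod", rng_seed = 1,
#'                     arch_distance = 4680, displacement = 465)
#' foveo_bmo_center_distance(s$fovea, s$bmo_center)  # 4215
generate_scene <- function(params = scene_params(),
                           group = c("control", "siod"),
                           laterality = c("right", "left"),
                           rng_seed = NULL,
                           eye_id = NULL, subject_id = NULL,
                           age = NULL, axial_length = NULL, sex = NULL,
                           subject_effect = NULL, arch_shift = NULL,
                           arch_distance = NULL, displacement = NULL) {
  stopifnot(inherits(params, "scene_params"))
  group <- match.arg(group)
  laterality <- match.arg(laterality)
  with_seed(rng_seed, {
    # Fixed draw order: the stream is identical for both lateralities, so a
    # left eye is exactly the mirrored right eye of the same seed.
    age <- age %||% rtruncnorm(1, params$age_mean, params$age_sd,
                               params$age_range[1], params$age_range[2])
    axial_length <- axial_length %||% stats::rnorm(1, params$axial_length_mean,
                                                   params$axial_length_sd)
    sex <- sex %||% if (stats::runif(1) < params$p_male) "male" else "female"
    subject_effect <- subject_effect %||% stats::rnorm(1, 0, params$subject_effect_sd)
    arch_shift <- arch_shift %||% stats::rnorm(1, 0, params$arch_distance_sd_between)
    arch_distance <- arch_distance %||%
      (params$arch_distance_mean + arch_shift +
         stats::rnorm(1, 0, params$arch_distance_sd_within))
    axis_angle <- stats::rnorm(1, params$axis_angle_mean, params$axis_angle_sd)
    if (is.null(displacement)) {
      displacement <- if (group == "siod" && params$displacement_mean > 0) {
        rtruncnorm(1, params$displacement_mean, params$displacement_sd, lower = 0)
      } else 0
    }
    semi <- rtruncnorm(2, params$bmo_semiaxis_means, params$bmo_semiaxis_sd,
                       lower = 0.3)
    h_sup <- rtruncnorm(1, params$arcade_halfwidth_mean,
                        params$arcade_halfwidth_sd, lower = 0.5)
    h_inf <- rtruncnorm(1, params$arcade_halfwidth_mean,
                        params$arcade_halfwidth_sd, lower = 0.5)

    if (arch_distance <= 0) stop_config("drawn arch distance is non-positive")
    if (displacement < 0) stop_config("displacement must be >= 0")
    if (displacement >= arch_distance) {
      stop_config("displacement must be smaller than the arch distance")
    }

    d_mm <- arch_distance / 1000
    # Reported axis angle is the negated math angle of the fovea->disc direction.
    math_ang <- deg2rad(-axis_angle)
    arch_center <- d_mm * c(cos(math_ang), sin(math_ang))
    u <- arch_center / d_mm
    bmo_center <- arch_center - (displacement / 1000) * u

    scene <- structure(list(
      eye_id = eye_id %||% sprintf("EYE_%s_%s", group,
                                   substr(laterality, 1, 1)),
      subject_id = subject_id %||% "SUBJ",
      group = group,
      laterality = laterality,
      age = age,
      axial_length = axial_length,
      sex = sex,
      fovea = c(0, 0),
      arch_center = arch_center,
      bmo_center = bmo_center,
      displacement = displacement,
      bmo_semiaxes = semi,
      field_params = list(baseline = params$baseline,
                          amp_sup = params$amp_sup,
                          amp_inf = params$amp_inf,
                          hump_angle = params$hump_angle,
                          hump_sigma = params$hump_sigma,
                          reference_radius = params$reference_radius),
      arcade_params = list(vertex = arch_center,
                           h_sup = h_sup, h_inf = h_inf,
                           scale = params$arcade_scale,
                           temporal_sign = -1),
      subject_effect = subject_effect,
      noise_sd = params$noise_sd,
      mirrored = FALSE
    ), class = "pp_scene")
    if (laterality == "left") scene <- mirror_scene(scene)
    validate_scene(scene)
    scene
  })
}

#' Mirror a scene about the vertical axis
#'
#' Flips the x coordinate of every landmark and toggles the stored-frame flag.
#' Used to store left eyes in their acquired orientation and to canonicalize
#' them back for measurement.
#'
#' @param scene a `pp_scene`.
#' @return the mirrored `pp_scene`.
#' @export
mirror_scene <- function(scene) {
  stopifnot(inherits(scene, "pp_scene"))
  flip <- function(p) c(-p[1], p[2])
  scene$fovea <- flip(scene$fovea)
  scene$arch_center <- flip(scene$arch_center)
  scene$bmo_center <- flip(scene$bmo_center)
  scene$arcade_params$vertex <- flip(scene$arcade_params$vertex)
  scene$arcade_params$temporal_sign <- -scene$arcade_params$temporal_sign
  scene$mirrored <- !scene$mirrored
  scene
}

#' Canonicalize a scene to the right-eye frame
#'
#' Left eyes are stored mirrored; this returns the geometry in the canonical
#' right-eye frame (+x nasal, +y superior) so that one set of angle and sector
#' conventions applies to every eye. Right eyes are returned unchanged.
#'
#' @param scene a `pp_scene`.
#' @return a `pp_scene` in canonical orientation.
#' @export
canonical_scene <- function(scene) {
  stopifnot(inherits(scene, "pp_scene"))
  if (scene$mirrored) mirror_scene(scene) else scene
}

# TRUE when the scene's stored frame is the canonical right-eye frame.
scene_is_canonical <- function(scene) !isTRUE(scene$mirrored)

#' Validate the invariants of a posterior-pole scene
#'
#' Checks that the BMO center lies on the fovea-to-architectural-center
#' segment at the stated displacement, that the displacement is zero for
#' control eyes, and that landmarks lie within the posterior-pole field.
#'
#' @param scene a `pp_scene`.
#' @return the scene, invisibly; errors on violation.
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "pp_scene"))
  if (!is_point(scene$fovea) || !is_point(scene$arch_center) ||
      !is_point(scene$bmo_center)) {
    stop("scene landmarks must be finite 2-d points", call. = FALSE)
  }
  if (scene$group == "control" && scene$displacement != 0) {
    stop("control scenes must have displacement 0", call. = FALSE)
  }
  if (scene$displacement < 0) stop("displacement must be >= 0", call. = FALSE)
  d_arch <- sqrt(sum((scene$arch_center - scene$fovea)^2))
  d_bmo <- sqrt(sum((scene$bmo_center - scene$fovea)^2))
  expected <- d_arch - scene$displacement / 1000
  if (abs(d_bmo - expected) > 1e-9) {
    stop("bmo_center is not at |fovea-arch| - displacement from the fovea",
         call. = FALSE)
  }
  # collinearity of fovea, bmo_center, arch_center
  v1 <- scene$arch_center - scene$fovea
  v2 <- scene$bmo_center - scene$fovea
  if (abs(v1[1] * v2[2] - v1[2] * v2[1]) > 1e-9) {
    stop("bmo_center does not lie on the fovea-arch_center segment", call. = FALSE)
  }
  pts <- rbind(scene$fovea, scene$arch_center, scene$bmo_center)
  if (any(abs(pts) > 6)) {
    stop("landmarks fall outside the posterior-pole field", call. = FALSE)
  }
  if (any(scene$bmo_semiaxes <= 0)) stop("BMO semiaxes must be positive", call. = FALSE)
  invisible(scene)
}

#' Generate a synthetic case-control cohort
#'
#' SIOD subjects contribute one eye, or both eyes with probability
#' `p_bilateral`; paired eyes share the subject identifier, the subject-level
#' baseline offset, and the subject-level component of the arch distance.
#' Each control subject contributes exactly one eye with random laterality.
#'
#' @param n_siod_subjects number of SIOD subjects (>= 1).
#' @param p_bilateral probability that a SIOD subject contributes both eyes;
#'   the default 7/15 makes 15 subjects yield 22 eyes in expectation.
#' @param n_control_subjects number of control subjects (one eye each).
#' @param params a [scene_params()] object.
#' @param rng_seed integer seed; the whole cohort is reproducible from it.
#'
#' @return a list of `pp_scene` objects (class `pp_cohort`).
#' @export
#' @examples
#' coh <- generate_cohort(4, p_bilateral = 0.5, n_control_subjects = 8,
#'                        rng_seed = 7)
#' scene_table(coh)[, c("eye_id", "group", "laterality")]
generate_cohort <- function(n_siod_subjects, p_bilateral = 7 / 15,
                            n_control_subjects,
                            params = scene_params(), rng_seed = NULL) {
  if (n_siod_subjects < 1) stop_config("n_siod_subjects must be >= 1")
  if (!is.numeric(p_bilateral) || p_bilateral < 0 || p_bilateral > 1) {
    stop_config("p_bilateral must be a probability")
  }
  if (n_control_subjects < 0) stop_config("n_control_subjects must be >= 0")
  with_seed(rng_seed, {
    scenes <- list()
    for (i in seq_len(n_siod_subjects)) {
      sid <- sprintf("SIOD%02d", i)
      age <- rtruncnorm(1, params$age_mean, params$age_sd,
                        params$age_range[1], params$age_range[2])
      al <- stats::rnorm(1, params$axial_length_mean, params$axial_length_sd)
      sex <- if (stats::runif(1) < params$p_male) "male" else "female"
      seff <- stats::rnorm(1, 0, params$subject_effect_sd)
      ashift <- stats::rnorm(1, 0, params$arch_distance_sd_between)
      bilateral <- stats::runif(1) < p_bilateral
      lats <- if (bilateral) c("right", "left") else {
        sample(c("right", "left"), 1)
      }
      for (lat in lats) {
        eid <- sprintf("%s_%s", sid, if (lat == "right") "OD" else "OS")
        scenes[[eid]] <- generate_scene(
          params, group = "siod", laterality = lat,
          eye_id = eid, subject_id = sid,
          age = age, axial_length = al, sex = sex,
          subject_effect = seff, arch_shift = ashift)
      }
    }
    for (i in seq_len(n_control_subjects)) {
      sid <- sprintf("CTRL%03d", i)
      lat <- sample(c("right", "left"), 1)
      eid <- sprintf("%s_%s", sid, if (lat == "right") "OD" else "OS")
      scenes[[eid]] <- generate_scene(
        params, group = "control", laterality = lat,
        eye_id = eid, subject_id = sid)
    }
    structure(scenes, class = c("pp_cohort", "list"))
  })
}

#' Tabulate cohort metadata
#'
#' One row per eye with identifiers, demographics and landmark geometry
#' (stored-frame coordinates).
#'
#' @param scenes a list of `pp_scene` objects.
#' @return a data.frame.
#' @export
scene_table <- function(scenes) {
  rows <- lapply(scenes, function(s) {
    data.frame(eye_id = s$eye_id, subject_id = s$subject_id, group = s$group,
               laterality = s$laterality, age = s$age,
               axial_length = s$axial_length, sex = s$sex,
               fovea_x = s$fovea[1], fovea_y = s$fovea[2],
               arch_x = s$arch_center[1], arch_y = s$arch_center[2],
               bmo_x = s$bmo_center[1], bmo_y = s$bmo_center[2],
               displacement_um = s$displacement,
               bmo_semiaxis_a = s$bmo_semiaxes[1],
               bmo_semiaxis_b = s$bmo_semiaxes[2],
               subject_effect = s$subject_effect,
               noise_sd = s$noise_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pp_scene <- function(x, ...) {
  cat(sprintf("<pp_scene %s: %s %s eye, subject %s>\n", x$eye_id, x$group,
              x$laterality, x$subject_id))
  cat(sprintf("  fovea (%.3f, %.3f) mm; bmo_center (%.3f, %.3f) mm; displacement %.0f um\n",
              x$fovea[1], x$fovea[2], x$bmo_center[1], x$bmo_center[2],
              x$displacement))
  invisible(x)
}

#' @export
print.pp_cohort <- function(x, ...) {
  tb <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<pp_cohort: %d eyes (%s)>\n", length(x),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
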