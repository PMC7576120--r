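# Per-eye posterior-pole measurements: foveo-BMO distances, axis angle, BMO
# area and inter-arcade distance. All operate in the canonical right-eye
# frame; measure_eye() canonicalizes left eyes first.

#' Fovea to BMO-center distance
#'
#' Euclidean distance between the fovea and the BMO center, in micrometers.
#'
#' @param fovea,bmo_center points (mm).
#' @return distance in um.
#' @export
#' @examples
#' foveo_bmo_center_distance(c(0, 0), c(3, 4))  # 5000
foveo_bmo_center_distance <- function(fovea, bmo_center) {
  stopifnot(is_point(fovea), is_point(bmo_center))
  1000 * sqrt(sum((bmo_center - fovea)^2))
}

#' Foveo-BMO axis angle
#'
#' Signed angle of the fovea-to-BMO-center direction against the horizontal
#' in the canonical frame, negated so that a disc superior to the fovea gives
#' a negative angle; range (-180, 180].
#'
#' @param fovea,bmo_center points (mm); must differ.
#' @return angle in degrees.
#' @export
#' @examples
#' foveo_bmo_axis_angle(c(0, 0), c(4.64, 0.61))  # about -7.49
foveo_bmo_axis_angle <- function(fovea, bmo_center) {
  stopifnot(is_point(fovea), is_point(bmo_center))
  d <- bmo_center - fovea
  if (all(d == 0)) stop("axis angle undefined: fovea and BMO center coincide",
                        call. = FALSE)
  a <- -rad2deg(atan2(d[2], d[1]))
  if (a <= -180) a <- a + 360
  a
}

#' Fovea to temporal BMO-margin distance
#'
#' Distance from the fovea to the nearer intersection of the foveo-BMO axis
#' (the ray from the fovea through the BMO center) with the axis-aligned BMO
#' ellipse, in micrometers. Degenerate semiaxes (0, 0) reduce to the center
#' distance.
#'
#' @param fovea,bmo_center points (mm).
#' @param bmo_semiaxes ellipse semiaxes (mm, x then y).
#' @return distance in um.
#' @export
#' @examples
#' foveo_bmo_margin_distance(c(0, 0), c(4.68, 0), c(0.88, 0.88))  # 3800
foveo_bmo_margin_distance <- function(fovea, bmo_center, bmo_semiaxes) {
  stopifnot(is_point(fovea), is_point(bmo_center), length(bmo_semiaxes) == 2)
  if (all(bmo_semiaxes == 0)) return(foveo_bmo_center_distance(fovea, bmo_center))
  if (any(bmo_semiaxes <= 0)) stop("BMO semiaxes must be positive", call. = FALSE)
  d <- bmo_center - fovea
  dist <- sqrt(sum(d^2))
  if (dist == 0) stop("fovea and BMO center coincide", call. = FALSE)
  u <- d / dist
  # Ray f + t u against ((x-cx)/A)^2 + ((y-cy)/B)^2 = 1; f relative to center.
  f <- fovea - bmo_center
  A <- bmo_semiaxes[1]; B <- bmo_semiaxes[2]
  if ((f[1] / A)^2 + (f[2] / B)^2 <= 1) {
    stop("geometry error: fovea lies inside the BMO ellipse", call. = FALSE)
  }
  a <- (u[1] / A)^2 + (u[2] / B)^2
  b <- 2 * (f[1] * u[1] / A^2 + f[2] * u[2] / B^2)
  cc <- (f[1] / A)^2 + (f[2] / B)^2 - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("geometry error: axis ray misses the BMO ellipse", call. = FALSE)
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  t <- min(c(t1, t2)[c(t1, t2) > 0])
  1000 * t
}

#' BMO ellipse area
#'
#' @param bmo_semiaxes semiaxes (mm).
#' @return area in mm^2 (pi a b).
#' @export
bmo_area <- function(bmo_semiaxes) {
  stopifnot(length(bmo_semiaxes) == 2)
  if (any(bmo_semiaxes <= 0)) stop("BMO semiaxes must be positive", call. = FALSE)
  pi * bmo_semiaxes[1] * bmo_semiaxes[2]
}

# Arcade curve evaluation: sideways parabolas through the arcade vertex
# (architectural disc center), parameterized by their half-spread at the
# fovea's vertical line. Defined on the temporal side of the vertex.
arcade_y <- function(arcades, x, side = c("sup", "inf")) {
  side <- match.arg(side)
  v <- arcades$vertex
  s <- arcades$temporal_sign          # -1: temporal is decreasing x (canonical)
  reach <- s * (x - v[1])             # > 0 on the temporal side
  if (any(reach < 0)) {
    stop("arcade curve undefined at the requested x (nasal of the vertex)",
         call. = FALSE)
  }
  h <- if (side == "sup") arcades$h_sup else arcades$h_inf
  # half-spread h is attained where the vertical line through the canonical
  # fovea (x = 0, reach = |vertex_x|) crosses the curve
  p <- h^2 / (4 * abs(v[1]))
  sgn <- if (side == "sup") 1 else -1
  v[2] + sgn * 2 * sqrt(p * reach)
}

#' Vertical inter-arcade distance at the fovea
#'
#' Vertical distance between the crossing points of the superior and inferior
#' venous arcades with the vertical line through the fovea, reported in the
#' arcade curves' native photograph units (arbitrary units, deliberately not
#' converted to um).
#'
#' @param arcades arcade parameter list (a scene's `arcade_params`), or a
#'   `pp_scene`.
#' @param fovea_x x coordinate of the vertical line (mm; default 0, the
#'   canonical fovea).
#' @return distance in arbitrary units.
#' @export
inter_arcade_distance <- function(arcades, fovea_x = 0) {
  if (inherits(arcades, "pp_scene")) arcades <- arcades$arcade_params
  ys <- arcade_y(arcades, fovea_x, "sup")
  yi <- arcade_y(arcades, fovea_x, "inf")
  arcades$scale * abs(ys - yi)
}

#' Measure one eye
#'
#' Computes every per-eye posterior-pole measurement from a scene's
#' landmarks. Left eyes are measured in the canonical mirrored frame so signs
#' and conventions match right eyes.
#'
#' @param scene a `pp_scene`.
#' @return a one-row data.frame: identifiers, demographics,
#'   `foveo_bmo_center_distance` (um), `foveo_bmo_margin_distance` (um),
#'   `foveo_bmo_axis_angle` (deg), `inter_arcade_distance` (arbitrary units),
#'   `bmo_area` (mm^2).
#' @export
#' @examples
#' s <- generate_scene(group = "control", rng_seed = 1, arch_distance = 4680)
#' measure_eye(s)$foveo_bmo_center_distance  # 4680
measure_eye <- function(scene) {
  stopifnot(inherits(scene, "pp_scene"))
  sc <- canonical_scene(scene)
  ctr <- foveo_bmo_center_distance(sc$fovea, sc$bmo_center)
  mrg <- foveo_bmo_margin_distance(sc$fovea, sc$bmo_center, sc$bmo_semiaxes)
  data.frame(eye_id = sc$eye_id, subject_id = sc$subject_id, group = sc$group,
             laterality = scene$laterality, age = sc$age,
             axial_length = sc$axial_length, sex = sc$sex,
             foveo_bmo_center_distance = ctr,
             foveo_bmo_margin_distance = mrg,
             foveo_bmo_axis_angle = foveo_bmo_axis_angle(sc$fovea, sc$bmo_center),
             inter_arcade_distance = inter_arcade_distance(sc),
             bmo_area = bmo_area(sc$bmo_semiaxes),
             stringsAsFactors = FALSE)
}

#' Measure every eye of a cohort
#'
#' @param scenes a list of `pp_scene` objects.
#' @return a data.frame, one row per eye (see [measure_eye()]).
#' @export
measure_cohort <- function(scenes) {
  out <- do.call(rbind, lapply(scenes, measure_eye))
  rownames(out) <- NULL
  out
}
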