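# The noiseless RNFL thickness field and its closed-form circle-profile
# oracle. The field is defined in polar coordinates about the architectural
# disc center: T(r, theta) = (r0 / r) * [B + A_sup g(theta - th) + A_inf
# g(theta + th)] with g a wrapped Gaussian and B the baseline plus the
# subject's shared offset. The 1/r radial decay conserves the circle-integral
# of thickness (axon count), and theta is measured from the per-eye temporal
# direction (the fovea-disc axis), so the double hump is anchored to that
# axis in every eye.

# Wrapped Gaussian on the circle (degrees), unit peak height.
wrapped_gaussian <- function(theta, mu, sigma) {
  out <- 0
  for (k in -2:2) out <- out + exp(-0.5 * ((theta - mu + 360 * k) / sigma)^2)
  out
}

# TSNIT angle (deg in [0,360)) of displacement vectors (wx, wy) in a frame
# whose temporal direction is `u_t`. In a canonical (right-eye) frame the
# temporal->superior->nasal ordering runs math-clockwise; in a mirrored frame
# it runs counterclockwise.
tsnit_angle <- function(wx, wy, u_t, mirrored) {
  cross <- u_t[1] * wy - u_t[2] * wx
  dot <- u_t[1] * wx + u_t[2] * wy
  s <- if (mirrored) 1 else -1
  wrap_deg(s * rad2deg(atan2(cross, dot)))
}

# Points strictly inside the BMO ellipse (axis-aligned, stored frame).
inside_bmo <- function(scene, x, y) {
  ((x - scene$bmo_center[1]) / scene$bmo_semiaxes[1])^2 +
    ((y - scene$bmo_center[2]) / scene$bmo_semiaxes[2])^2 <= 1
}

#' Evaluate the noiseless RNFL thickness field
#'
#' Vectorized over points given in the scene's stored frame. Points inside
#' the BMO ellipse (or at the field singularity r = 0) receive the
#' disc-interior sentinel value 0.
#'
#' @param scene a `pp_scene`.
#' @param x,y point coordinates (mm, stored frame).
#' @param mask_bmo set the BMO interior to 0 (default TRUE).
#' @return thickness values (um).
#' @export
field_thickness <- function(scene, x, y, mask_bmo = TRUE) {
  fp <- scene$field_params
  u_t <- scene$fovea - scene$arch_center
  u_t <- u_t / sqrt(sum(u_t^2))
  wx <- x - scene$arch_center[1]
  wy <- y - scene$arch_center[2]
  r <- sqrt(wx^2 + wy^2)
  theta <- tsnit_angle(wx, wy, u_t, isTRUE(scene$mirrored))
  base <- fp$baseline + scene$subject_effect
  ang <- base +
    fp$amp_sup * wrapped_gaussian(theta, fp$hump_angle, fp$hump_sigma) +
    fp$amp_inf * wrapped_gaussian(theta, -fp$hump_angle, fp$hump_sigma)
  val <- ifelse(r > 0, fp$reference_radius / pmax(r, .Machine$double.eps) * ang, 0)
  val <- pmax(val, 0)
  if (mask_bmo) val[inside_bmo(scene, x, y)] <- 0
  val
}

#' Closed-form circumpapillary profile (test oracle)
#'
#' Evaluates the noiseless field directly at points on a circle, with no
#' rasterization, as the independent oracle for raster resampling and for the
#' scan-circle repositioning analysis. Profile angle 0 deg is temporal and
#' angles follow the temporal-superior-nasal-inferior ordering; `axis_deg`
#' rotates the angular origin (pass the eye's foveo-BMO axis angle to measure
#' relative to the fovea-disc axis, as fovea-to-disc-aligned scans do).
#'
#' @param scene a `pp_scene`.
#' @param center circle center (mm, stored frame); default the BMO center.
#' @param radius circle radius in mm (default the field reference radius).
#' @param angles sample angles in degrees (default 720 samples at 0.5 deg).
#' @param axis_deg angular origin offset in degrees (reported-axis convention).
#' @return an `rnfl_profile` object; samples falling inside the BMO ellipse
#'   are 0 and flagged in `attr(profile, "inside_bmo")` with a warning.
#' @export
#' @examples
#' s <- generate_scene(group = "control", rng_seed = 1)
#' pr <- analytic_circle_profile(s, center = s$arch_center,
#'                               axis_deg = foveo_bmo_axis_angle(s$fovea, s$bmo_center))
#' range(pr$thickness)
analytic_circle_profile <- function(scene, center = scene$bmo_center,
                                    radius = scene$field_params$reference_radius,
                                    angles = profile_angles(720),
                                    axis_deg = 0) {
  stopifnot(inherits(scene, "pp_scene"), is_point(center), radius > 0)
  dirs <- tsnit_dirs(angles + axis_deg, isTRUE(scene$mirrored))
  px <- center[1] + radius * dirs$x
  py <- center[2] + radius * dirs$y
  inside <- inside_bmo(scene, px, py)
  th <- field_thickness(scene, px, py)
  if (any(inside)) {
    warning(sprintf("%d profile samples fall inside the BMO ellipse (sentinel 0)",
                    sum(inside)))
  }
  new_rnfl_profile(center = center, radius = radius, angles = angles,
                   thickness = th, axis_deg = axis_deg,
                   eye_id = scene$eye_id, laterality = scene$laterality,
                   inside_bmo = inside)
}

# Uniform profile angle grid [0, 360) starting temporal.
profile_angles <- function(n_samples) seq(0, 360 - 360 / n_samples,
                                          by = 360 / n_samples)

# Unit direction vectors for TSNIT angles (deg) in the given frame.
tsnit_dirs <- function(psi, mirrored) {
  a <- deg2rad(psi)
  if (mirrored) list(x = cos(a), y = sin(a)) else list(x = -cos(a), y = sin(a))
}

#' Circle-integrated thickness of the noiseless field
#'
#' Numerically integrates thickness times arc length along a circle centered
#' on the architectural disc center. Under the 1/r field this integral (the
#' axon-count analog) is independent of the radius.
#'
#' @param scene a `pp_scene`.
#' @param radius circle radius (mm); must clear the BMO ellipse.
#' @param n_samples angular resolution of the numeric integration.
#' @return the integral (um x mm, per full turn).
#' @export
circle_flux <- function(scene, radius, n_samples = 7200) {
  pr <- analytic_circle_profile(scene, center = scene$arch_center,
                                radius = radius,
                                angles = profile_angles(n_samples))
  2 * pi * radius * mean(pr$thickness)
}
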