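# Circumpapillary circle-scan extraction: bilinear raster resampling at an
# arbitrary center, scan-center repositioning along the foveo-BMO axis,
# clock-hour sector summaries, and double-hump peak localization.

new_rnfl_profile <- function(center, radius, angles, thickness, axis_deg = 0,
                             eye_id = NULL, laterality = "right",
                             inside_bmo = NULL) {
  if (is.unsorted(angles, strictly = TRUE) || any(angles < 0) ||
      any(angles >= 360)) {
    stop("profile angles must be strictly increasing within [0, 360)", call. = FALSE)
  }
  if (any(!is.finite(thickness)) || any(thickness < 0)) {
    stop("profile thickness must be finite and >= 0", call. = FALSE)
  }
  structure(list(center = center, radius = radius, angles = angles,
                 thickness = thickness, n_samples = length(angles),
                 axis_deg = axis_deg, eye_id = eye_id,
                 laterality = laterality),
            inside_bmo = inside_bmo, class = "rnfl_profile")
}

#' @export
print.rnfl_profile <- function(x, ...) {
  cat(sprintf("<rnfl_profile %s: %d samples, r = %.2f mm, center (%.3f, %.3f), axis %.1f deg>\n",
              x$eye_id %||% "?", x$n_samples, x$radius, x$center[1],
              x$center[2], x$axis_deg))
  invisible(x)
}

# Bilinear interpolation of a thickness raster at scene points.
bilinear_sample <- function(map, x, y) {
  idx <- map_index(map, x, y)
  g <- idx$g
  bad <- idx$col < 1 | idx$col > g | idx$row < 1 | idx$row > g
  if (any(bad)) return(list(values = NULL, bad = which(bad)))
  c0 <- pmin(floor(idx$col), g - 1); r0 <- pmin(floor(idx$row), g - 1)
  fc <- idx$col - c0; fr <- idx$row - r0
  v <- map$values
  vals <- (1 - fr) * ((1 - fc) * v[cbind(r0, c0)] + fc * v[cbind(r0, c0 + 1)]) +
    fr * ((1 - fc) * v[cbind(r0 + 1, c0)] + fc * v[cbind(r0 + 1, c0 + 1)])
  list(values = vals, bad = integer(0))
}

#' Resample a circumpapillary circle from a thickness raster
#'
#' Bilinearly interpolates the raster at uniformly spaced angles along a
#' circle, emulating post-acquisition repositioning of the measurement circle
#' on a cube scan. Angle 0 is temporal and angles follow the
#' temporal-superior-nasal-inferior ordering of the raster's frame;
#' `axis_deg` rotates the angular origin to the per-eye foveo-BMO axis.
#'
#' @param map a `thickness_map`.
#' @param center circle center (mm, map frame).
#' @param radius circle radius (mm); default 1.73 (3.46 mm diameter circle).
#' @param n_samples number of samples (default 720, i.e. 0.5 deg spacing).
#' @param axis_deg angular origin offset (deg, reported-axis convention).
#' @return an `rnfl_profile`.
#' @export
#' @examples
#' s <- generate_scene(group = "control", rng_seed = 1)
#' m <- render_thickness_map(s, noise_seed = 2)
#' pr <- resample_circle(m, s$bmo_center)
#' mean(pr$thickness)
resample_circle <- function(map, center, radius = 1.73, n_samples = 720,
                            axis_deg = 0) {
  stopifnot(inherits(map, "thickness_map"), is_point(center), radius > 0)
  angles <- profile_angles(n_samples)
  dirs <- tsnit_dirs(angles + axis_deg, isTRUE(map$mirrored))
  px <- center[1] + radius * dirs$x
  py <- center[2] + radius * dirs$y
  smp <- bilinear_sample(map, px, py)
  if (length(smp$bad)) {
    stop(sprintf("circle leaves the raster, first at angle %.1f deg",
                 angles[smp$bad[1]]), call. = FALSE)
  }
  new_rnfl_profile(center = center, radius = radius, angles = angles,
                   thickness = pmax(smp$values, 0), axis_deg = axis_deg,
                   eye_id = map$eye_id,
                   laterality = if (isTRUE(map$mirrored)) "left" else "right")
}

#' Reposition a scan-circle center along the foveo-BMO axis
#'
#' Moves the center by `shift` micrometers along the unit vector from the
#' fovea toward the BMO center; positive shifts are nasal. Shifting an eye's
#' circle nasally by the group mean foveo-BMO-center distance difference is
#' the normalization manipulation for SIOD profiles.
#'
#' @param bmo_center,fovea points (mm); must differ.
#' @param shift displacement in um (positive = nasal).
#' @return the new center (mm).
#' @export
#' @examples
#' reposition_center(c(4.215, 0), c(0, 0), 465)  # c(4.68, 0)
reposition_center <- function(bmo_center, fovea, shift) {
  stopifnot(is_point(bmo_center), is_point(fovea), is.finite(shift))
  d <- bmo_center - fovea
  len <- sqrt(sum(d^2))
  if (len == 0) stop("fovea and BMO center coincide: axis undefined", call. = FALSE)
  bmo_center + (shift / 1000) * d / len
}

#' Clock-hour sector summary of a profile
#'
#' Averages the profile over twelve 30-degree sectors under the canonical
#' right-eye mapping: hour 9 centered temporal (0 deg), 12 superior (90 deg),
#' 3 nasal (180 deg), 6 inferior (270 deg). Left-eye profiles are mirrored to
#' the canonical frame at extraction ([resample_circle()] and
#' [analytic_circle_profile()] use mirrored direction vectors on mirrored
#' rasters), so profile angles already carry per-eye temporal/nasal semantics
#' and the binning itself is laterality-independent; `laterality` is recorded
#' in the summary.
#'
#' @param profile an `rnfl_profile` with `n_samples` divisible by 12.
#' @param laterality `"right"` or `"left"`; defaults to the profile's tag.
#' @return an object of class `clock_hour_summary` with `sector_means`
#'   (named 1-12, um).
#' @export
clock_hour_summary <- function(profile, laterality = profile$laterality) {
  stopifnot(inherits(profile, "rnfl_profile"))
  laterality <- match.arg(laterality, c("right", "left"))
  n <- profile$n_samples
  if (n %% 12 != 0) stop("n_samples must be divisible by 12", call. = FALSE)
  ang <- profile$angles
  th <- profile$thickness
  hours <- 1:12
  centers <- wrap_deg((hours - 9) * 30)
  means <- vapply(centers, function(ct) {
    inside <- wrap_deg(ang - (ct - 15)) < 30
    if (sum(inside) != n / 12) {
      stop("sector does not contain exactly n_samples/12 samples", call. = FALSE)
    }
    mean(th[inside])
  }, numeric(1))
  structure(list(sector_means = stats::setNames(means, hours),
                 laterality = laterality,
                 convention = "right-eye canonical: 9=temporal, 12=superior, 3=nasal, 6=inferior",
                 n_per_sector = n / 12, eye_id = profile$eye_id),
            class = "clock_hour_summary")
}

#' Locate the superior and inferior RNFL peaks
#'
#' Smooths the profile with a circular moving average (window 15 deg) and
#' returns the argmax over the superior half (0, 180) and inferior half
#' (180, 360). Exact ties are broken toward the temporal side. A flat profile
#' is flagged degenerate with undefined peaks.
#'
#' @param profile an `rnfl_profile` covering the full circle.
#' @param smooth_window smoothing window width in degrees.
#' @return a list with `superior_deg`, `inferior_deg`, `degenerate`.
#' @export
peak_locations <- function(profile, smooth_window = 15) {
  stopifnot(inherits(profile, "rnfl_profile"))
  ang <- profile$angles
  step <- 360 / profile$n_samples
  w <- max(1L, round(smooth_window / step))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(profile$thickness, rep(1 / w, w),
                                 circular = TRUE))
  if (diff(range(sm)) < 1e-9) {
    return(list(superior_deg = NA_real_, inferior_deg = NA_real_,
                degenerate = TRUE))
  }
  pick <- function(idx) {
    v <- sm[idx]
    best <- idx[abs(v - max(v)) < 1e-12]
    # tie-break: closest to temporal (angle 0)
    best[which.min(pmin(ang[best], 360 - ang[best]))]
  }
  sup <- pick(which(ang > 0 & ang < 180))
  inf <- pick(which(ang > 180 & ang < 360))
  list(superior_deg = ang[sup], inferior_deg = ang[inf], degenerate = FALSE)
}
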