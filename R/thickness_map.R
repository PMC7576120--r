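#' Construct a thickness map
#'
#' A rasterized RNFL thickness grid with physical scale, the analog of a
#' disc-centered 200 x 200 cube scan over a 6 x 6 mm field. Row 1 is the
#' superior edge; pixel centers sit at (i - 0.5) * pitch from the field
#' corner.
#'
#' @param values numeric matrix of thicknesses (um), finite and >= 0.
#' @param extent field side length (mm).
#' @param center field center in scene coordinates (mm); the scan is
#'   disc-centered so this is normally the BMO center.
#' @param mirrored logical; TRUE when the raster is in a mirrored (left-eye
#'   stored) frame.
#' @param eye_id optional identifier carried through to writers.
#' @return an object of class `thickness_map`.
#' @export
thickness_map <- function(values, extent = 6, center = c(0, 0),
                          mirrored = FALSE, eye_id = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("thickness grid must be square", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("thickness values must be finite and >= 0", call. = FALSE)
  }
  if (!is_point(center) || extent <= 0) stop("invalid map geometry", call. = FALSE)
  structure(list(values = values, extent = extent, center = center,
                 pixel_pitch = extent / nrow(values),
                 mirrored = mirrored, eye_id = eye_id),
            class = "thickness_map")
}

#' Render a scene to a thickness raster
#'
#' Evaluates the noiseless field at every pixel center of a square raster
#' centered on the BMO center, adds i.i.d. Gaussian pixel noise with the
#' scene's `noise_sd`, clips at 0, and masks the BMO interior to the
#' disc-interior sentinel 0. Deterministic given `noise_seed`.
#'
#' @param scene a `pp_scene`.
#' @param grid samples per side (default 200; must be >= 32).
#' @param extent field side length in mm (default 6).
#' @param noise_seed integer seed for the pixel noise; `NULL` continues the
#'   current RNG stream.
#' @return a `thickness_map`.
#' @export
#' @examples
#' s <- generate_scene(group = "control", rng_seed = 1)
#' m <- render_thickness_map(s, grid = 64, noise_seed = 2)
#' dim(m$values)
render_thickness_map <- function(scene, grid = 200, extent = 6,
                                 noise_seed = NULL) {
  stopifnot(inherits(scene, "pp_scene"))
  if (grid < 32) stop_config("grid must be >= 32")
  r_scan <- scene$field_params$reference_radius
  if (extent / 2 < r_scan) stop_config("extent does not cover the scan circle")
  pitch <- extent / grid
  cx <- scene$bmo_center[1]
  cy <- scene$bmo_center[2]
  xs <- cx - extent / 2 + (seq_len(grid) - 0.5) * pitch        # columns, left to right
  ys <- cy + extent / 2 - (seq_len(grid) - 0.5) * pitch        # rows, superior first
  xg <- matrix(xs, nrow = grid, ncol = grid, byrow = TRUE)
  yg <- matrix(ys, nrow = grid, ncol = grid)
  vals <- matrix(field_thickness(scene, as.vector(xg), as.vector(yg)),
                 nrow = grid)
  if (scene$noise_sd > 0) {
    noise <- with_seed(noise_seed,
                       matrix(stats::rnorm(grid * grid, 0, scene$noise_sd),
                              nrow = grid))
    vals <- vals + noise
  }
  vals <- pmax(vals, 0)
  mask <- matrix(inside_bmo(scene, as.vector(xg), as.vector(yg)), nrow = grid)
  vals[mask] <- 0
  thickness_map(vals, extent = extent, center = scene$bmo_center,
                mirrored = isTRUE(scene$mirrored), eye_id = scene$eye_id)
}

# Fractional (row, col) raster coordinates of scene points; pixel centers at
# integer indices.
map_index <- function(map, x, y) {
  g <- nrow(map$values)
  x0 <- map$center[1] - map$extent / 2
  ytop <- map$center[2] + map$extent / 2
  list(col = (x - x0) / map$pixel_pitch + 0.5,
       row = (ytop - y) / map$pixel_pitch + 0.5,
       g = g)
}

#' Write a thickness map as 16-bit TIFF plus JSON sidecar
#'
#' Thickness is stored in 0.1 um integer units in a single-channel 16-bit
#' TIFF; the sidecar records the physical scale, field center, orientation
#' and eye identifier.
#'
#' @param map a `thickness_map`.
#' @param path TIFF file path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_thickness_map <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  enc <- round(map$values * 10)
  if (any(enc > 65535)) stop("thickness exceeds the 16-bit 0.1 um range", call. = FALSE)
  tiff::writeTIFF(enc / 65535, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(extent_mm = map$extent,
                  pixel_pitch_mm = map$pixel_pitch,
                  center_of_field = map$center,
                  mirrored = map$mirrored,
                  eye_id = map$eye_id,
                  units = "0.1 um per integer step",
                  raster_convention = "row 1 = superior edge; pixel centers at (i-0.5)*pitch from the field corner")
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Read a thickness map written by [write_thickness_map()]
#'
#' @param path TIFF file path (sidecar expected alongside).
#' @return a `thickness_map`.
#' @export
read_thickness_map <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  thickness_map(round(img * 65535) / 10, extent = meta$extent_mm,
                center = as.numeric(meta$center_of_field),
                mirrored = isTRUE(meta$mirrored), eye_id = meta$eye_id)
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map %s: %dx%d px, %.1f mm, center (%.3f, %.3f), pitch %.0f um>\n",
              x$eye_id %||% "?", nrow(x$values), ncol(x$values), x$extent,
              x$center[1], x$center[2], x$pixel_pitch * 1000))
  invisible(x)
}
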