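#' Camera-projector rig configuration
#'
#' Describes the geometry of the structured-light measurement head: a pinhole
#' camera looking down its optical axis at a reference plane, and a stripe
#' projector offset horizontally by the triangulation baseline. All lengths
#' are millimetres, angles radians. The defaults reproduce the desktop rig:
#' 60 mm baseline, 470 mm standard height, 79 x 66 mm field of view with
#' about 15 stripes across it, and a 450--490 mm working range.
#'
#' The coordinate frame is right-handed with origin at the camera centre,
#' +z along the optical axis toward the scene, +x toward the projector and
#' +y up. Heights `h` are reported relative to the reference plane at the
#' standard height, with `h = standard_height_mm - z` (positive = closer to
#' the camera, i.e. protruding).
#'
#' @param ... named overrides for any of the fields listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{baseline_mm}{camera-to-projector horizontal offset (default 60).}
#'   \item{standard_height_mm}{camera-to-reference-plane distance (default 470).}
#'   \item{range_mm}{length-2 numeric, valid (near, far) object distances
#'     (default `c(450, 490)`).}
#'   \item{fov_mm}{length-2 numeric, field of view (width, height) at the
#'     standard height (default `c(79, 66)`).}
#'   \item{image_size_px}{length-2 integer, image (width, height) in pixels
#'     (default `c(790, 660)`, i.e. 0.1 mm/px at the standard height).}
#'   \item{stripes_in_fov}{number of projected stripe periods across the
#'     field-of-view width (default 15).}
#'   \item{n_steps}{number of phase shifts per stack, >= 3 (default 4).}
#'   \item{frequency_ratio}{integer ratio of high to low fringe frequency
#'     used for temporal unwrapping (default 15).}
#'   \item{scan_direction}{"x" (stripes vertical, phase varies along +x) or
#'     "y" (projector assembly rotated 90 degrees, phase varies along +y).}
#' }
#'
#' @return an object of class `rig_config`.
#' @examples
#' rig <- make_default_rig()
#' rig$baseline_mm
#' small <- make_default_rig(image_size_px = c(158, 132))
#' @export
make_default_rig <- function(...) {
  rig <- list(
    baseline_mm        = 60,
    standard_height_mm = 470,
    range_mm           = c(450, 490),
    fov_mm             = c(79, 66),
    image_size_px      = c(790L, 660L),
    stripes_in_fov     = 15,
    n_steps            = 4L,
    frequency_ratio    = 15L,
    scan_direction     = "x"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(rig))
  if (length(unknown) > 0L) {
    stop("unknown rig_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rig[names(overrides)] <- overrides
  rig$image_size_px <- as.integer(rig$image_size_px)
  rig$n_steps <- as.integer(rig$n_steps)
  rig$frequency_ratio <- as.integer(rig$frequency_ratio)
  class(rig) <- "rig_config"
  validate_rig(rig)
  rig
}

validate_rig <- function(rig) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid rig_config field '", field, "': ", msg,
                  call. = FALSE)
  }
  chk(is.numeric(rig$baseline_mm) && rig$baseline_mm > 0,
      "baseline_mm", "must be > 0")
  chk(rig$standard_height_mm > 0, "standard_height_mm", "must be > 0")
  chk(length(rig$range_mm) == 2L &&
        rig$range_mm[1] < rig$standard_height_mm &&
        rig$standard_height_mm < rig$range_mm[2],
      "range_mm", "must bracket standard_height_mm (near < standard < far)")
  chk(length(rig$fov_mm) == 2L && all(rig$fov_mm > 0), "fov_mm",
      "must be two positive lengths")
  chk(length(rig$image_size_px) == 2L && all(rig$image_size_px >= 2L),
      "image_size_px", "must be two integers >= 2")
  chk(rig$stripes_in_fov > 1, "stripes_in_fov", "must be > 1")
  chk(rig$n_steps >= 3L, "n_steps", "must be >= 3")
  chk(rig$frequency_ratio >= 2L, "frequency_ratio", "must be >= 2")
  chk(rig$scan_direction %in% c("x", "y"), "scan_direction",
      "must be \"x\" or \"y\"")
  px_w <- rig$fov_mm[1] / rig$image_size_px[1]
  px_h <- rig$fov_mm[2] / rig$image_size_px[2]
  chk(abs(px_w - px_h) < 1e-9, "image_size_px",
      "pixels must be square (fov width/px width == fov height/px height)")
  invisible(rig)
}

#' @export
print.rig_config <- function(x, ...) {
  cat("<rig_config>\n")
  cat(sprintf("  baseline          %g mm\n", x$baseline_mm))
  cat(sprintf("  standard height   %g mm (range %g-%g mm)\n",
              x$standard_height_mm, x$range_mm[1], x$range_mm[2]))
  cat(sprintf("  field of view     %g x %g mm, %d x %d px (%.4g mm/px)\n",
              x$fov_mm[1], x$fov_mm[2], x$image_size_px[1],
              x$image_size_px[2], pixel_pitch(x)))
  cat(sprintf("  stripes in FOV    %g (N = %d steps, freq ratio %d)\n",
              x$stripes_in_fov, x$n_steps, x$frequency_ratio))
  cat(sprintf("  scan direction    %s\n", x$scan_direction))
  invisible(x)
}

# pixel pitch on the reference plane, mm per pixel
pixel_pitch <- function(rig) rig$fov_mm[1] / rig$image_size_px[1]

# reference-plane fringe frequency, cycles/mm (high), f_high / ratio (low)
fringe_frequency <- function(rig, frequency_id = c("high", "low")) {
  frequency_id <- match.arg(frequency_id)
  f0 <- rig$stripes_in_fov / rig$fov_mm[1]
  if (frequency_id == "low") f0 / rig$frequency_ratio else f0
}

# projector centre in camera coordinates
projector_center <- function(rig) {
  if (rig$scan_direction == "x") c(rig$baseline_mm, 0, 0)
  else c(0, rig$baseline_mm, 0)
}

# lateral reference-plane coordinates (mm) of 0-based pixel coordinates.
# u along image columns maps to +x, v along rows maps to -y (y up).
pixel_to_lateral <- function(rig, u, v) {
  p <- pixel_pitch(rig)
  list(x = (u - rig$image_size_px[1] / 2) * p,
       y = (rig$image_size_px[2] / 2 - v) * p)
}

# full-grid lateral reference coordinates as H x W matrices
lateral_grids <- function(rig) {
  W <- rig$image_size_px[1]; H <- rig$image_size_px[2]
  u <- matrix(rep(0:(W - 1L), each = H), nrow = H)
  v <- matrix(rep(0:(H - 1L), times = W), nrow = H)
  pixel_to_lateral(rig, u, v)
}

#' Back-project a pixel to its viewing ray
#'
#' Returns the camera ray through a pixel as an origin plus unit direction.
#' Pixel coordinates are 0-based, origin at the image top-left, pixel centres
#' at integer coordinates; the ray through the principal pixel is the optical
#' axis, and at the standard height the pixel grid spans the field of view.
#'
#' @param rig a [make_default_rig()] configuration.
#' @param pixel length-2 numeric `(u, v)` pixel coordinates (may be
#'   fractional).
#' @return a list with `origin` (camera centre, mm) and unit `direction`.
#' @examples
#' rig <- make_default_rig()
#' pixel_ray(rig, c(395, 330))$direction  # optical axis
#' @export
pixel_ray <- function(rig, pixel) {
  stopifnot(inherits(rig, "rig_config"), length(pixel) == 2L)
  if (pixel[1] < 0 || pixel[1] > rig$image_size_px[1] - 1L ||
      pixel[2] < 0 || pixel[2] > rig$image_size_px[2] - 1L) {
    stop("pixel (", pixel[1], ", ", pixel[2], ") outside image bounds",
         call. = FALSE)
  }
  lat <- pixel_to_lateral(rig, pixel[1], pixel[2])
  d <- c(lat$x, lat$y, rig$standard_height_mm)
  list(origin = c(0, 0, 0), direction = d / sqrt(sum(d^2)))
}

#' Constant-phase plane of the projected stripe pattern
#'
#' Every unwrapped phase value of the diverging stripe fan corresponds to a
#' plane through the projector centre whose intersection with the reference
#' plane is the straight stripe line carrying that phase. For the high
#' frequency the stripe spacing on the reference plane is
#' `fov width / stripes_in_fov`.
#'
#' @param rig a [make_default_rig()] configuration.
#' @param unwrapped_phase finite phase value, radians.
#' @param frequency_id `"high"` or `"low"`.
#' @return a list with `point` (on the plane, mm), unit `normal`, and
#'   `phase_value`.
#' @export
phase_plane <- function(rig, unwrapped_phase, frequency_id = "high") {
  stopifnot(inherits(rig, "rig_config"), is.finite(unwrapped_phase))
  f <- fringe_frequency(rig, frequency_id)
  L <- rig$standard_height_mm
  d <- rig$baseline_mm
  s_r <- unwrapped_phase / (2 * pi * f)  # stripe trace coordinate on z = L
  if (rig$scan_direction == "x") {
    point <- c(s_r, 0, L)
    n <- c(L, 0, -(s_r - d))
  } else {
    point <- c(0, s_r, L)
    n <- c(0, L, -(s_r - d))
  }
  list(point = point, normal = n / sqrt(sum(n^2)),
       phase_value = unwrapped_phase)
}

# absolute projected phase at 3D points (vectors x, y, z), radians.
# The stripe fan diverges from the projector centre; phase is anchored so
# that phase = 2*pi*f*s on the reference plane z = L, s the coordinate
# along the scan direction.
phase_at_point <- function(rig, x, y, z, frequency_id = "high") {
  f <- fringe_frequency(rig, frequency_id)
  L <- rig$standard_height_mm
  d <- rig$baseline_mm
  s <- if (rig$scan_direction == "x") x else y
  s_r <- d + (s - d) * L / z  # where the projector ray meets z = L
  2 * pi * f * s_r
}

# analytic unwrapped phase of the reference plane per pixel (H x W matrix)
reference_phase <- function(rig, frequency_id = "high") {
  f <- fringe_frequency(rig, frequency_id)
  lat <- lateral_grids(rig)
  s <- if (rig$scan_direction == "x") lat$x else lat$y
  2 * pi * f * s
}

#' Triangulate a single pixel from its unwrapped phase
#'
#' Intersects the pixel's viewing ray with the constant-phase plane of the
#' projector. For small heights at the image centre the result agrees with
#' the classical phase-to-height conversion
#' `h = L * dphi / (dphi + 2 pi f0 d)` where `dphi` is the reference-plane
#' phase minus the measured phase.
#'
#' @inheritParams pixel_ray
#' @param unwrapped_phase absolute (unwrapped) phase at the pixel, radians.
#' @param frequency_id `"high"` or `"low"`.
#' @return length-3 numeric, the 3D point in mm (camera frame).
#' @export
triangulate_pixel <- function(rig, pixel, unwrapped_phase,
                              frequency_id = "high") {
  ray <- pixel_ray(rig, pixel)
  pl <- phase_plane(rig, unwrapped_phase, frequency_id)
  denom <- sum(ray$direction * pl$normal)
  if (abs(denom) < 1e-6) {
    stop("degenerate geometry: pixel ray nearly parallel to phase plane",
         call. = FALSE)
  }
  t <- sum((pl$point - ray$origin) * pl$normal) / denom
  ray$origin + t * ray$direction
}

# vectorised triangulation over the full pixel grid.
# phi: H x W matrix of absolute unwrapped phase. Returns x, y, z matrices
# and a finite/forward validity matrix.
triangulate_grid <- function(rig, phi, frequency_id = "high") {
  f <- fringe_frequency(rig, frequency_id)
  L <- rig$standard_height_mm
  d <- rig$baseline_mm
  lat <- lateral_grids(rig)
  s_r <- phi / (2 * pi * f)
  s_ref <- if (rig$scan_direction == "x") lat$x else lat$y
  denom <- s_ref - s_r + d
  ok <- is.finite(denom) & abs(denom) > 1e-6 * d
  scale <- d / denom          # z = scale * L along each pixel ray
  ok <- ok & is.finite(scale) & scale > 0
  list(x = scale * lat$x, y = scale * lat$y, z = scale * L, ok = ok)
}

#' Serialize / deserialize a rig configuration as JSON
#'
#' Flat JSON with keys exactly matching the `rig_config` field names;
#' lengths in mm.
#'
#' @param rig a `rig_config`.
#' @param path file path.
#' @return `read_rig_config` returns a `rig_config`.
#' @export
write_rig_config <- function(rig, path) {
  stopifnot(inherits(rig, "rig_config"))
  jsonlite::write_json(unclass(rig), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rig_config
#' @export
read_rig_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(make_default_rig, x)
}
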