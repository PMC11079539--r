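#' Render a phase-shifted fringe stack
#'
#' Simulates the camera images of a scene under the projected sinusoidal
#' stripe pattern. For every pixel the surface point along its viewing ray
#' is found (fixed-point iteration on the single-valued depth field), the
#' absolute projected phase is evaluated there, and the N frames are
#' `I_k = albedo * (A + B * cos(phi + delta_k)) + eps` with shift offsets
#' `delta_k = 2 pi k / N` and i.i.d. Gaussian intensity noise
#' `eps ~ N(0, noise_sd)`, seeded and per-frame independent. Defaults
#' A = 128, B = 100 on an arbitrary 8-bit-like intensity scale.
#'
#' Rendering is deterministic given `(rig, scene, frequency_id, noise_sd,
#' seed)` and does not disturb the caller's RNG state.
#'
#' @param rig a [make_default_rig()] configuration.
#' @param scene a `surface_scene`.
#' @param frequency_id `"high"` or `"low"` fringe frequency (the low
#'   frequency is `high / frequency_ratio` and is used for temporal
#'   unwrapping).
#' @param noise_sd additive intensity noise standard deviation.
#' @param seed integer RNG seed for the noise.
#' @param mean_intensity,modulation the pattern's A and B.
#' @return a `fringe_stack`: list of H x W intensity matrices plus metadata.
#' @examples
#' rig <- make_default_rig(image_size_px = c(79, 66))
#' st <- render_fringe_stack(rig, flat_surface(470), "high", 0, 1)
#' length(st$images)
#' @export
render_fringe_stack <- function(rig, scene, frequency_id = c("high", "low"),
                                noise_sd = 0, seed = 1L,
                                mean_intensity = 128, modulation = 100) {
  frequency_id <- match.arg(frequency_id)
  stopifnot(inherits(rig, "rig_config"), inherits(scene, "surface_scene"),
            noise_sd >= 0)
  geo <- intersect_scene(rig, scene)
  clean <- clean_frames(rig, scene, geo, frequency_id,
                        mean_intensity, modulation)
  images <- add_frame_noise(clean, noise_sd, seed)
  new_fringe_stack(images, rig, frequency_id, noise_sd, seed,
                   mean_intensity, modulation)
}

new_fringe_stack <- function(images, rig, frequency_id, noise_sd, seed,
                             mean_intensity, modulation) {
  N <- rig$n_steps
  structure(list(images = images,
                 phase_offsets = 2 * pi * (0:(N - 1L)) / N,
                 frequency_id = frequency_id,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 mean_intensity = mean_intensity, modulation = modulation,
                 rig = rig),
            class = "fringe_stack")
}

#' @export
print.fringe_stack <- function(x, ...) {
  cat(sprintf("<fringe_stack> %d frames %d x %d px, %s frequency, noise_sd %g, seed %d\n",
              length(x$images), ncol(x$images[[1]]), nrow(x$images[[1]]),
              x$frequency_id, x$noise_sd, x$seed))
  invisible(x)
}

# per-pixel ray/surface intersection by fixed-point iteration on z.
# Returns x, y, z matrices (H x W) of surface points in the camera frame.
intersect_scene <- function(rig, scene, tol = 1e-10, max_iter = 80L) {
  lat <- lateral_grids(rig)
  L <- rig$standard_height_mm
  z <- matrix(L, nrow(lat$x), ncol(lat$x))
  for (i in seq_len(max_iter)) {
    x <- lat$x * z / L
    y <- lat$y * z / L
    z_new <- scene$height_fn(x, y)
    dim(z_new) <- dim(z)
    if (max(abs(z_new - z)) < tol) { z <- z_new; break }
    z <- z_new
  }
  x <- lat$x * z / L
  y <- lat$y * z / L
  near <- rig$range_mm[1]; far <- rig$range_mm[2]
  margin <- 0.1 * (far - near)
  out_of_range <- mean(z < near - margin | z > far + margin)
  if (out_of_range > 0.5) {
    stop(sprintf("surface out of measurement range at %.0f%% of pixels",
                 100 * out_of_range), call. = FALSE)
  }
  list(x = x, y = y, z = z)
}

clean_frames <- function(rig, scene, geo, frequency_id,
                         mean_intensity, modulation) {
  phi <- phase_at_point(rig, geo$x, geo$y, geo$z, frequency_id)
  alb <- scene$albedo_fn(geo$x, geo$y)
  dim(alb) <- dim(phi)
  N <- rig$n_steps
  lapply(0:(N - 1L), function(k) {
    alb * (mean_intensity + modulation * cos(phi + 2 * pi * k / N))
  })
}

add_frame_noise <- function(clean, noise_sd, seed) {
  if (noise_sd == 0) return(clean)
  with_local_seed(seed, {
    lapply(clean, function(fr) {
      fr + matrix(stats::rnorm(length(fr), sd = noise_sd),
                  nrow(fr), ncol(fr))
    })
  })
}

# evaluate an expression under a private RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
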