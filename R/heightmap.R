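#' Triangulate a height map from unwrapped phase
#'
#' Every valid pixel's viewing ray is intersected with its constant-phase
#' projector plane, giving a metric 3D point `(x, y, z)`; the height is
#' `h = standard_height - z`, positive toward the camera. Degenerate
#' pixels (near-parallel ray/plane, heights beyond the +/- 30 mm range
#' guard) are flagged invalid, never fatal.
#'
#' @param unwrapped an `unwrapped_phase_map` from [unwrap_phase()].
#' @param rig the rig configuration.
#' @return a `height_map` with matrices `h`, `x`, `y` (true lateral
#'   position per pixel), `valid_mask`, and a `provenance` record.
#' @export
reconstruct_height_map <- function(unwrapped, rig = unwrapped$rig) {
  stopifnot(inherits(unwrapped, "unwrapped_phase_map"))
  if (!any(unwrapped$valid_mask)) stop("no valid pixels", call. = FALSE)
  tri <- triangulate_grid(rig, unwrapped$phase, unwrapped$frequency_id)
  L <- rig$standard_height_mm
  h <- L - tri$z
  valid <- unwrapped$valid_mask & tri$ok & is.finite(h) & abs(h) <= 30
  h[!valid] <- NA_real_
  new_height_map(h, tri$x, tri$y, valid, rig,
                 provenance = list(paste0("triangulated (", unwrapped$method,
                                          " unwrap, ", unwrapped$frequency_id,
                                          " frequency)")))
}

new_height_map <- function(h, x, y, valid, rig, provenance = list()) {
  structure(list(h = h, x = x, y = y, valid_mask = valid, rig = rig,
                 provenance = provenance),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, %.1f%% valid\n",
              ncol(x$h), nrow(x$h), 100 * mean(x$valid_mask)))
  if (any(x$valid_mask)) {
    cat(sprintf("  h range [%.3f, %.3f] mm\n",
                min(x$h[x$valid_mask]), max(x$h[x$valid_mask])))
  }
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' @export
plot.height_map <- function(x, ...) {
  h <- x$h
  h[!x$valid_mask] <- NA
  # image() draws column-major from bottom; transpose and flip rows so the
  # picture matches image orientation (row 1 on top)
  graphics::image(t(h[nrow(h):1, ]), useRaster = TRUE, asp = nrow(h) / ncol(h),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", axes = FALSE, ...)
  invisible(x)
}

#' End-to-end reconstruction from fringe stacks
#'
#' Convenience pipeline: wrapped phase for the high (and low) stacks,
#' temporal or spatial unwrapping, triangulation, optional smoothing.
#'
#' @param stack_high high-frequency `fringe_stack`.
#' @param stack_low low-frequency `fringe_stack` or `NULL`.
#' @param rig rig configuration.
#' @param method unwrapping method, `"temporal"` or `"spatial"`.
#' @param smooth_mm Gaussian smoothing scale in mm (0 = none).
#' @param quality_threshold,min_modulation passed to [wrapped_phase()].
#' @return a `height_map`.
#' @export
reconstruct_surface <- function(stack_high, stack_low = NULL,
                                rig = stack_high$rig,
                                method = c("temporal", "spatial"),
                                smooth_mm = 0,
                                quality_threshold = 0.1,
                                min_modulation = 10) {
  method <- match.arg(method)
  wh <- wrapped_phase(stack_high, quality_threshold, min_modulation)
  wl <- if (!is.null(stack_low)) {
    wrapped_phase(stack_low, quality_threshold, min_modulation)
  }
  uw <- unwrap_phase(wh, wl, rig, method)
  hm <- reconstruct_height_map(uw, rig)
  if (smooth_mm > 0) hm <- smooth_height_map(hm, smooth_mm)
  hm
}

#' Gaussian low-pass smoothing of a height map
#'
#' Masked normalized convolution with a separable Gaussian of standard
#' deviation `scale_mm` (metric units, converted via the pixel pitch):
#' invalid pixels neither contribute to nor receive values. `scale_mm = 0`
#' is the identity.
#'
#' @param hm a `height_map`.
#' @param scale_mm Gaussian standard deviation, mm (>= 0).
#' @export
smooth_height_map <- function(hm, scale_mm = 0.3) {
  stopifnot(inherits(hm, "height_map"))
  if (scale_mm < 0) stop("smoothing scale must be >= 0", call. = FALSE)
  if (scale_mm == 0) return(hm)
  sigma_px <- scale_mm / pixel_pitch(hm$rig)
  r <- max(1L, ceiling(3 * sigma_px))
  kern <- stats::dnorm(-r:r, sd = sigma_px)
  kern <- kern / sum(kern)
  m <- hm$valid_mask * 1
  hz <- hm$h
  hz[!hm$valid_mask] <- 0
  num <- conv_sep(hz * m, kern)
  den <- conv_sep(m, kern)
  h_new <- ifelse(den > 1e-12, num / den, NA_real_)
  h_new[!hm$valid_mask] <- NA_real_
  new_height_map(h_new, hm$x, hm$y, hm$valid_mask, hm$rig,
                 c(hm$provenance,
                   list(sprintf("gaussian smoothing, sigma %g mm", scale_mm))))
}

# separable convolution with zero padding, kernel length 2r+1
conv_sep <- function(M, kern) {
  conv_dim <- function(M, kern, along_rows) {
    r <- (length(kern) - 1L) %/% 2L
    out <- matrix(0, nrow(M), ncol(M))
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      w <- kern[j]
      if (along_rows) {
        # shift across rows (vertical)
        src_rows <- seq_len(nrow(M)) + off
        okr <- src_rows >= 1L & src_rows <= nrow(M)
        out[okr, ] <- out[okr, ] + w * M[src_rows[okr], , drop = FALSE]
      } else {
        src_cols <- seq_len(ncol(M)) + off
        okc <- src_cols >= 1L & src_cols <= ncol(M)
        out[, okc] <- out[, okc] + w * M[, src_cols[okc], drop = FALSE]
      }
    }
    out
  }
  conv_dim(conv_dim(M, kern, TRUE), kern, FALSE)
}

# Map lateral (x, y) mm to fractional 0-based pixel coordinates on a height
# map. The pixel grid is regular in image space, not in lateral space
# (lateral position scales with z/L), so invert iteratively.
lateral_to_pixel <- function(hm, x, y, iters = 4L) {
  rig <- hm$rig
  p <- pixel_pitch(rig)
  W <- rig$image_size_px[1]; H <- rig$image_size_px[2]
  L <- rig$standard_height_mm
  scale <- rep_len(1, length(x))  # z / L
  u <- v <- NULL
  for (i in seq_len(iters)) {
    u <- x / (scale * p) + W / 2
    v <- H / 2 - y / (scale * p)
    ui <- pmin(pmax(round(u), 0), W - 1L)
    vi <- pmin(pmax(round(v), 0), H - 1L)
    hval <- hm$h[cbind(vi + 1L, ui + 1L)]
    hval[is.na(hval)] <- 0
    scale <- (L - hval) / L
  }
  list(u = u, v = v)
}

# Bilinear sample of height at lateral points; NA where any contributing
# pixel is invalid or out of frame. Returns a vector.
sample_height <- function(hm, x, y) {
  rig <- hm$rig
  W <- rig$image_size_px[1]; H <- rig$image_size_px[2]
  px <- lateral_to_pixel(hm, x, y)
  u0 <- floor(px$u); v0 <- floor(px$v)
  fu <- px$u - u0; fv <- px$v - v0
  out <- rep(NA_real_, length(x))
  ok <- u0 >= 0 & u0 <= W - 2L & v0 >= 0 & v0 <= H - 2L &
    is.finite(u0) & is.finite(v0)
  if (!any(ok)) return(out)
  idx <- function(du, dv) cbind(v0[ok] + dv + 1L, u0[ok] + du + 1L)
  vmask <- hm$valid_mask
  all_valid <- vmask[idx(0, 0)] & vmask[idx(1, 0)] &
    vmask[idx(0, 1)] & vmask[idx(1, 1)]
  h00 <- hm$h[idx(0, 0)]; h10 <- hm$h[idx(1, 0)]
  h01 <- hm$h[idx(0, 1)]; h11 <- hm$h[idx(1, 1)]
  val <- (1 - fu[ok]) * (1 - fv[ok]) * h00 + fu[ok] * (1 - fv[ok]) * h10 +
    (1 - fu[ok]) * fv[ok] * h01 + fu[ok] * fv[ok] * h11
  val[!all_valid] <- NA_real_
  out[ok] <- val
  out
}

#' Marker height by two-point averaging
#'
#' Graphite markers are opaque, so the height *at* a marker is read off the
#' surrounding tissue: the mean of the surface height at the two points
#' `p +/- offset_mm * direction` (bilinear interpolation). Odd-symmetric
#' terms of the surface cancel, so on a locally linear surface the average
#' equals the height at `p` itself.
#'
#' @param hm a `height_map`.
#' @param p length-2 numeric lateral marker position, mm.
#' @param offset_mm sampling offset, mm (default 1.5).
#' @param direction length-2 unit vector along which to offset (default
#'   along +y, the half-pipe axis direction).
#' @return the averaged height, or `NA` with a `"reason"` attribute when
#'   either offset point is unmeasurable.
#' @export
marker_height <- function(hm, p, offset_mm = 1.5, direction = c(0, 1)) {
  stopifnot(inherits(hm, "height_map"), length(p) == 2L)
  dirn <- direction / sqrt(sum(direction^2))
  xs <- p[1] + c(-1, 1) * offset_mm * dirn[1]
  ys <- p[2] + c(-1, 1) * offset_mm * dirn[2]
  hs <- sample_height(hm, xs, ys)
  if (anyNA(hs)) {
    out <- NA_real_
    attr(out, "reason") <- "offset point falls on invalid pixels"
    return(out)
  }
  mean(hs)
}

#' Analytic height map of a scene
#'
#' Builds a `height_map` directly from the analytic surface, bypassing
#' rendering and reconstruction: the exact per-pixel ray/surface
#' intersection on the camera grid. Serves as the ground-truth counterpart
#' of a reconstruction and as the entry point for the measurement layer on
#' externally supplied surfaces.
#'
#' @param rig a [make_default_rig()] configuration.
#' @param scene a `surface_scene`.
#' @return a `height_map` with all pixels valid.
#' @export
scene_height_map <- function(rig, scene) {
  geo <- intersect_scene(rig, scene)
  L <- rig$standard_height_mm
  new_height_map(L - geo$z, geo$x, geo$y,
                 matrix(TRUE, nrow(geo$z), ncol(geo$z)), rig,
                 provenance = list("analytic scene height map"))
}
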