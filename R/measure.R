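#' Extract a cross-sectional surface profile
#'
#' Samples the reconstructed surface along the straight lateral segment
#' `pq` at `ceil(|pq| / step) + 1` equally spaced stations (bilinear
#' interpolation). Stations falling on invalid pixels are linearly bridged
#' when the gap is at most 3 stations; longer gaps raise an
#' unmeasurable-section error naming the gap.
#'
#' @param hm a `height_map`.
#' @param p,q length-2 numeric lateral endpoints, mm.
#' @param step_mm sampling step, mm (> 0).
#' @return a `surface_profile`: 3D `points` (n x 3, mm), cumulative
#'   `arc_coordinate`, chord coordinate `s`, and the endpoints.
#' @export
extract_profile <- function(hm, p, q, step_mm = 0.1) {
  stopifnot(inherits(hm, "height_map"), length(p) == 2L, length(q) == 2L,
            step_mm > 0)
  len <- sqrt(sum((q - p)^2))
  if (len == 0) stop("profile endpoints coincide", call. = FALSE)
  n <- ceiling(len / step_mm) + 1L
  s <- seq(0, len, length.out = n)
  xs <- p[1] + s / len * (q[1] - p[1])
  ys <- p[2] + s / len * (q[2] - p[2])
  h <- sample_height(hm, xs, ys)
  if (sum(!is.na(h)) < 2L) {
    stop("profile crosses fewer than 2 valid pixels", call. = FALSE)
  }
  h <- bridge_gaps(h, s, max_gap = 3L)
  L <- hm$rig$standard_height_mm
  pts <- cbind(x = xs, y = ys, z = L - h)
  seg <- sqrt(diff(s)^2 + diff(h)^2)
  structure(list(points = pts, arc_coordinate = c(0, cumsum(seg)), s = s,
                 h = h, endpoints = rbind(p = p, q = q), step_mm = step_mm),
            class = "surface_profile")
}

# linear interpolation over interior NA runs of length <= max_gap; NA runs
# touching the ends or longer than max_gap raise an error naming the gap
bridge_gaps <- function(h, s, max_gap = 3L) {
  if (!anyNA(h)) return(h)
  r <- rle(is.na(h))
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    from <- pos[i]; to <- pos[i] + r$lengths[i] - 1L
    if (i == 1L || i == length(r$values) || r$lengths[i] > max_gap) {
      stop(sprintf(
        "unmeasurable section: %d invalid stations at arc %.2f-%.2f mm",
        r$lengths[i], s[from], s[to]), call. = FALSE)
    }
  }
  filled <- stats::approx(s[!is.na(h)], h[!is.na(h)], xout = s)$y
  ifelse(is.na(h), filled, h)
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("<surface_profile> %d stations, chord %.2f mm, path %.4f mm\n",
              nrow(x$points), max(x$s), max(x$arc_coordinate)))
  invisible(x)
}

#' @export
plot.surface_profile <- function(x, ...) {
  graphics::plot(x$s, x$h, type = "l", xlab = "chord position (mm)",
                 ylab = "height (mm)", ...)
  invisible(x)
}

#' Path length of a profile
#'
#' Total 3D polyline length: the distance measured along the curved
#' surface rather than the straight chord. Always at least the chord
#' length.
#'
#' @param profile a [extract_profile()] result.
#' @return length, mm.
#' @export
path_length <- function(profile) {
  stopifnot(inherits(profile, "surface_profile"))
  if (nrow(profile$points) < 2L) stop("need >= 2 points", call. = FALSE)
  max(profile$arc_coordinate)
}

#' Fit a virtual inferior surface
#'
#' Least-squares bivariate polynomial fit of the height field over an
#' annulus: the region of interest minus a central exclusion zone assumed
#' to contain the lesion. Coordinates are centred and scaled to the ROI
#' for conditioning. The fitted surface stands in for the healthy mucosa
#' underneath the lesion.
#'
#' @param hm a `height_map`.
#' @param roi length-4 numeric `(xmin, xmax, ymin, ymax)` lateral ROI, mm.
#' @param degree total polynomial degree D (default 2); the model has
#'   `(D+1)(D+2)/2` coefficients.
#' @param exclusion_scale the exclusion zone is the ROI shrunk about its
#'   centre by this factor (default 0.6); 0 disables exclusion.
#' @return a `poly_surface` with `coefficients`, `degree`, centring/scaling,
#'   `rms_residual_mm` over the annulus, and the ROI.
#' @export
fit_virtual_surface <- function(hm, roi, degree = 2, exclusion_scale = 0.6) {
  stopifnot(inherits(hm, "height_map"), length(roi) == 4L, degree >= 0)
  cx <- (roi[1] + roi[2]) / 2; cy <- (roi[3] + roi[4]) / 2
  sx <- (roi[2] - roi[1]) / 2; sy <- (roi[4] - roi[3]) / 2
  x <- hm$x; y <- hm$y
  in_roi <- hm$valid_mask & x >= roi[1] & x <= roi[2] &
    y >= roi[3] & y <= roi[4]
  in_excl <- abs(x - cx) <= exclusion_scale * sx &
    abs(y - cy) <= exclusion_scale * sy
  sel <- in_roi & !in_excl
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (sum(sel) < 3 * n_coef) {
    stop("fit annulus contains too few valid pixels (need >= 3x coefficients)",
         call. = FALSE)
  }
  X <- poly_basis((x[sel] - cx) / sx, (y[sel] - cy) / sy, degree)
  fit <- stats::lm.fit(X, hm$h[sel])
  if (fit$rank < n_coef) {
    stop("rank-deficient polynomial design; try a lower degree",
         call. = FALSE)
  }
  structure(list(coefficients = fit$coefficients, degree = degree,
                 center = c(cx, cy), scale = c(sx, sy), roi = roi,
                 exclusion_scale = exclusion_scale,
                 rms_residual_mm = sqrt(mean(fit$residuals^2)),
                 n_pixels = sum(sel)),
            class = "poly_surface")
}

poly_basis <- function(xs, ys, degree) {
  cols <- list()
  for (d in 0:degree) for (i in d:0) {
    cols[[length(cols) + 1L]] <- xs^i * ys^(d - i)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(0:degree, function(d)
    sapply(d:0, function(i) paste0("x", i, "y", d - i))))
  X
}

#' Evaluate a virtual surface
#'
#' @param vs a [fit_virtual_surface()] result.
#' @param x,y lateral coordinates, mm (vectorised).
#' @return predicted heights, mm.
#' @export
predict_surface <- function(vs, x, y) {
  stopifnot(inherits(vs, "poly_surface"))
  X <- poly_basis((x - vs$center[1]) / vs$scale[1],
                  (y - vs$center[2]) / vs$scale[2], vs$degree)
  as.numeric(X %*% vs$coefficients)
}

#' @export
print.poly_surface <- function(x, ...) {
  cat(sprintf("<poly_surface> degree %d, %d coefficients, rms residual %.4f mm over %d px\n",
              x$degree, length(x$coefficients), x$rms_residual_mm,
              x$n_pixels))
  invisible(x)
}

#' Segment the lesion above a virtual surface
#'
#' Thresholds the residual `r = h - virtual_surface(x, y)` at
#' `threshold_mm` and keeps the largest 8-connected component (or the one
#' containing `seed_point`). Set `sign = -1` for depressed lesions
#' (`r < -threshold`). Segmentation is confined to the virtual surface's
#' ROI.
#'
#' @param hm a `height_map`.
#' @param vs a [fit_virtual_surface()] result.
#' @param threshold_mm residual threshold, mm (> 0; default 0.5).
#' @param seed_point optional lateral `(x, y)` inside the wanted component.
#' @param sign `+1` protruded (default), `-1` depressed.
#' @return a `lesion_mask`: logical matrix on the height-map grid plus the
#'   residual field.
#' @export
extract_lesion <- function(hm, vs, threshold_mm = 0.5, seed_point = NULL,
                           sign = 1) {
  stopifnot(inherits(hm, "height_map"), inherits(vs, "poly_surface"),
            threshold_mm > 0, sign %in% c(-1, 1))
  roi <- vs$roi
  r <- matrix(NA_real_, nrow(hm$h), ncol(hm$h))
  sel <- hm$valid_mask & hm$x >= roi[1] & hm$x <= roi[2] &
    hm$y >= roi[3] & hm$y <= roi[4]
  r[sel] <- hm$h[sel] - predict_surface(vs, hm$x[sel], hm$y[sel])
  cand <- !is.na(r) & (sign * r > threshold_mm)
  if (!any(cand)) {
    stop(sprintf("no lesion found: max %s residual %.3f mm below threshold %g mm",
                 if (sign > 0) "positive" else "negative",
                 if (any(sel)) max(sign * r[sel], na.rm = TRUE) else NA,
                 threshold_mm), call. = FALSE)
  }
  lab <- label_components_8(cand)
  if (!is.null(seed_point)) {
    px <- lateral_to_pixel(hm, seed_point[1], seed_point[2])
    ri <- round(px$v) + 1L; ci <- round(px$u) + 1L
    comp <- lab[ri, ci]
    if (is.na(comp) || comp == 0L) {
      stop("seed point does not fall on a supra-threshold component",
           call. = FALSE)
    }
  } else {
    comp <- which.max(tabulate(lab[lab > 0L]))
  }
  structure(list(mask = lab == comp, threshold_mm = threshold_mm,
                 residual = r, sign = sign, connected = TRUE),
            class = "lesion_mask")
}

# 8-connected component labelling by flood fill (queue of linear indices)
label_components_8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  todo <- which(mask)
  next_lab <- 0L
  offsets <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  for (start in todo) {
    if (lab[start] != 0L) next
    next_lab <- next_lab + 1L
    queue <- start
    lab[start] <- next_lab
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      for (i in cur) {
        r0 <- ((i - 1L) %% H) + 1L
        nb <- i + offsets
        keep <- rep(TRUE, 8L)
        if (r0 == 1L) keep[c(1L, 5L, 7L)] <- FALSE
        if (r0 == H) keep[c(2L, 6L, 8L)] <- FALSE
        nb <- nb[keep]
        nb <- nb[nb >= 1L & nb <= H * W]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb) > 0L) {
          lab[nb] <- next_lab
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Major and minor lesion diameters on the curved surface
#'
#' The clinical size descriptors, measured *along the reconstructed
#' surface*, not as straight chords. The footprint centroid is computed on
#' the mask; chords through the centroid are scanned over 180 directions at
#' 1 degree steps; the direction maximizing the masked chord extent defines
#' the major axis (ties toward the smaller angle), the perpendicular the
#' minor axis. Each diameter is the surface path length of the
#' corresponding profile across the mask.
#'
#' @param hm a `height_map`.
#' @param mask a [extract_lesion()] result.
#' @param vs the virtual surface (for the height of the lesion above it).
#' @param step_mm chord sampling step, mm.
#' @return a `lesion_measurement`: `major_diameter_mm`,
#'   `minor_diameter_mm`, `max_height_mm`, `footprint_area_mm2`,
#'   `major_axis_direction`, plus the straight-chord extents.
#' @export
lesion_diameters <- function(hm, mask, vs, step_mm = 0.1) {
  stopifnot(inherits(hm, "height_map"), inherits(mask, "lesion_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty lesion mask", call. = FALSE)
  xs <- hm$x[m]; ys <- hm$y[m]
  ctr <- c(mean(xs), mean(ys))
  # per-pixel lateral footprint area scales with (z/L)^2
  L <- hm$rig$standard_height_mm
  pp <- pixel_pitch(hm$rig)
  area <- sum((pp * (L - hm$h[m]) / L)^2)
  span <- max(sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)) + 2 * step_mm
  ts <- seq(-span, span, by = step_mm)
  angles <- (0:179) * pi / 180
  chord <- numeric(180)
  runs <- vector("list", 180)
  for (a in seq_along(angles)) {
    dirn <- c(cos(angles[a]), sin(angles[a]))
    run <- mask_run(hm, m, ctr, dirn, ts)
    runs[[a]] <- run
    chord[a] <- if (is.null(run)) 0 else run[2] - run[1]
  }
  if (max(chord) < 2 * pp) {
    stop("degenerate lesion: mask thinner than 2 pixels", call. = FALSE)
  }
  best <- which.max(chord)                      # ties -> smaller angle
  perp <- ((best - 1L + 90L) %% 180L) + 1L
  axis_measure <- function(a) {
    run <- runs[[a]]
    if (is.null(run)) return(NULL)
    dirn <- c(cos(angles[a]), sin(angles[a]))
    p <- ctr + run[1] * dirn
    q <- ctr + run[2] * dirn
    list(length = path_length(extract_profile(hm, p, q, step_mm)),
         endpoints = rbind(p = p, q = q), direction = dirn)
  }
  maj <- axis_measure(best)
  min_ <- axis_measure(perp)
  swap <- !is.null(min_) && min_$length > maj$length  # contract: major >= minor
  if (swap) { tmp <- maj; maj <- min_; min_ <- tmp }
  res <- mask$residual[m]
  structure(list(major_diameter_mm = maj$length,
                 minor_diameter_mm = if (is.null(min_)) NA_real_
                                     else min_$length,
                 max_height_mm = max(mask$sign * res, na.rm = TRUE),
                 footprint_area_mm2 = area,
                 major_axis_direction = maj$direction,
                 chord_major_mm = chord[if (swap) perp else best],
                 chord_minor_mm = chord[if (swap) best else perp],
                 major_endpoints = maj$endpoints,
                 minor_endpoints = if (is.null(min_)) NULL
                                   else min_$endpoints,
                 centroid = ctr),
            class = "lesion_measurement")
}

# contiguous masked run containing the centroid along direction dirn;
# returns c(t_min, t_max) or NULL
mask_run <- function(hm, m, ctr, dirn, ts) {
  xs <- ctr[1] + ts * dirn[1]
  ys <- ctr[2] + ts * dirn[2]
  px <- lateral_to_pixel(hm, xs, ys)
  ri <- round(px$v) + 1L; ci <- round(px$u) + 1L
  ok <- ri >= 1L & ri <= nrow(m) & ci >= 1L & ci <= ncol(m)
  inside <- rep(FALSE, length(ts))
  inside[ok] <- m[cbind(ri[ok], ci[ok])]
  i0 <- which.min(abs(ts))
  if (!inside[i0]) return(NULL)
  lo <- i0; while (lo > 1L && inside[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(ts) && inside[hi + 1L]) hi <- hi + 1L
  c(ts[lo], ts[hi])
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat("<lesion_measurement>\n")
  cat(sprintf("  major diameter  %.2f mm (surface path; chord %.2f mm)\n",
              x$major_diameter_mm, x$chord_major_mm))
  cat(sprintf("  minor diameter  %.2f mm (surface path; chord %.2f mm)\n",
              x$minor_diameter_mm, x$chord_minor_mm))
  cat(sprintf("  max height      %.2f mm above the virtual surface\n",
              x$max_height_mm))
  cat(sprintf("  footprint area  %.1f mm^2\n", x$footprint_area_mm2))
  invisible(x)
}

#' Virtual base path under a lesion from flank fitting
#'
#' Estimates the length of the healthy base surface hidden underneath a
#' lesion: a 1-D polynomial is fitted to the profile's flank heights (the
#' stations outside `lesion_span`) and its arc length is integrated across
#' the span. With flat flanks the base path equals the straight span; with
#' curved flanks the polynomial carries the curvature underneath the
#' lesion.
#'
#' @param profile a [extract_profile()] result crossing the lesion with
#'   flank margin on both sides.
#' @param lesion_span length-2 numeric, the lesion's extent in *arc*
#'   coordinates of the profile, mm.
#' @param degree polynomial degree (default 2).
#' @return base path length, mm; attribute `"one_sided"` is `TRUE` when
#'   only one flank had points and the fit extrapolates.
#' @export
base_path_from_flanks <- function(profile, lesion_span, degree = 2) {
  stopifnot(inherits(profile, "surface_profile"), length(lesion_span) == 2L,
            degree >= 0)
  arc <- profile$arc_coordinate
  s <- profile$s
  h <- profile$h
  span_s <- stats::approx(arc, s, xout = sort(lesion_span))$y
  if (anyNA(span_s)) {
    stop("lesion_span outside the profile's arc range", call. = FALSE)
  }
  left <- s < span_s[1]
  right <- s > span_s[2]
  one_sided <- FALSE
  if (sum(left) < degree + 1 || sum(right) < degree + 1) {
    if (sum(left) + sum(right) < degree + 1) {
      stop("insufficient flank points for the polynomial degree",
           call. = FALSE)
    }
    one_sided <- TRUE
    warning("one-sided flank fit; base path extrapolated", call. = FALSE)
  }
  flank <- left | right
  fit <- stats::lm.fit(outer(s[flank], 0:degree, `^`), h[flank])
  cf <- fit$coefficients
  dcf <- cf[-1] * seq_len(degree)          # derivative coefficients
  integrand <- function(ss) {
    slope <- outer(ss, 0:(degree - 1), `^`) %*% dcf
    sqrt(1 + as.numeric(slope)^2)
  }
  out <- if (degree == 0) {
    span_s[2] - span_s[1]
  } else {
    stats::integrate(integrand, span_s[1], span_s[2], rel.tol = 1e-9)$value
  }
  attr(out, "one_sided") <- one_sided
  out
}
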