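#' Analytic test surfaces
#'
#' A `surface_scene` is the simulator's ground truth: a single-valued
#' analytic depth field `z = f(x, y)` (camera frame, mm; larger z = farther
#' from the camera) together with an albedo field in `[0, 1]` and a lateral
#' domain. Scenes are built from the constructors below and modified with
#' [add_lesion()] and [add_markers()]; they are what gets rendered into
#' fringe stacks and what the evaluation harness uses as the reference
#' "measurement microscope".
#'
#' @param distance_mm camera-to-plane distance, mm.
#' @param domain length-4 numeric `(xmin, xmax, ymin, ymax)`, mm.
#' @return a `surface_scene`.
#' @examples
#' sc <- flat_surface(470)
#' surface_height(sc, c(0, 0))
#' @export
flat_surface <- function(distance_mm = 470,
                         domain = c(-39.5, 39.5, -33, 33)) {
  new_scene(
    height_fn = function(x, y) rep_len(distance_mm, length(x)),
    albedo_fn = function(x, y) rep_len(1, length(x)),
    domain = domain,
    descriptor = list(type = "flat", distance_mm = distance_mm,
                      domain = domain)
  )
}

#' Half-pipe jig surface
#'
#' The cylindrical test jig used for height-accuracy evaluation: a half-pipe
#' of given inner radius with its crest (the line nearest the camera) at
#' `crest_distance_mm`, axis along x or y. Across the axis the depth is
#' `z(u) = crest + R - sqrt(R^2 - u^2)` for `|u| <= R`, clamped to
#' `crest + R` outside the pipe walls.
#'
#' @param radius_mm inner radius, mm (> 0); default 21.
#' @param axis direction of the pipe axis, `"x"` or `"y"` (default `"y"`:
#'   curvature runs across x).
#' @param crest_distance_mm camera distance of the crest line, mm.
#' @inheritParams flat_surface
#' @export
half_pipe_surface <- function(radius_mm = 21, axis = c("y", "x"),
                              crest_distance_mm = 455,
                              domain = c(-39.5, 39.5, -33, 33)) {
  axis <- match.arg(axis)
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("radius_mm must be > 0", call. = FALSE)
  }
  R <- radius_mm
  zfun <- function(x, y) {
    u <- if (axis == "y") x else y
    sag <- ifelse(abs(u) <= R, R - sqrt(pmax(R^2 - u^2, 0)), R)
    crest_distance_mm + sag
  }
  new_scene(
    height_fn = zfun,
    albedo_fn = function(x, y) rep_len(1, length(x)),
    domain = domain,
    descriptor = list(type = "half_pipe", radius_mm = radius_mm, axis = axis,
                      crest_distance_mm = crest_distance_mm, domain = domain)
  )
}

new_scene <- function(height_fn, albedo_fn, domain, descriptor) {
  stopifnot(length(domain) == 4L, domain[1] < domain[2], domain[3] < domain[4])
  structure(list(height_fn = height_fn, albedo_fn = albedo_fn,
                 domain = domain, descriptor = descriptor),
            class = "surface_scene")
}

#' @export
print.surface_scene <- function(x, ...) {
  cat("<surface_scene>", x$descriptor$type, "\n")
  cat(sprintf("  domain x [%g, %g] mm, y [%g, %g] mm\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  extras <- setdiff(names(x$descriptor), c("type", "domain"))
  for (nm in extras) {
    v <- x$descriptor[[nm]]
    if (is.list(v)) v <- paste0("<", v$type %||% "list", ">")
    cat(sprintf("  %-18s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a lesion bump
#'
#' Describes a rotationally symmetric lesion to be placed on a base surface:
#' protruded (`height_mm > 0`, toward the camera) or depressed
#' (`height_mm < 0`). The `cosine` profile is the raised-cosine bump
#' `height * (1 + cos(pi * r / Rf)) / 2` for `r <= Rf` (C1-continuous at the
#' rim); `gaussian` is `height * exp(-4 r^2 / Rf^2)` truncated at the rim,
#' with `edge_sharpness` scaling the exponent.
#'
#' @param center length-2 numeric, lateral centre (x, y), mm.
#' @param footprint_diameter_mm footprint diameter `2 * Rf`, mm (> 0).
#' @param height_mm apex height, mm; sign selects protruded/depressed.
#' @param profile `"cosine"` or `"gaussian"`.
#' @param edge_sharpness shape factor for the gaussian profile (default 1).
#' @return a `lesion_spec`.
#' @export
lesion_spec <- function(center = c(0, 0), footprint_diameter_mm = 10,
                        height_mm = 3, profile = c("cosine", "gaussian"),
                        edge_sharpness = 1) {
  profile <- match.arg(profile)
  stopifnot(length(center) == 2L, footprint_diameter_mm > 0,
            is.finite(height_mm), edge_sharpness > 0)
  structure(list(center = as.numeric(center),
                 footprint_diameter_mm = footprint_diameter_mm,
                 height_mm = height_mm, profile = profile,
                 edge_sharpness = edge_sharpness),
            class = "lesion_spec")
}

lesion_bump_height <- function(lesion, r) {
  Rf <- lesion$footprint_diameter_mm / 2
  h <- lesion$height_mm
  inside <- r < Rf
  out <- numeric(length(r))
  if (lesion$profile == "cosine") {
    out[inside] <- h * 0.5 * (1 + cos(pi * r[inside] / Rf))
  } else {
    out[inside] <- h * exp(-4 * lesion$edge_sharpness * (r[inside] / Rf)^2)
  }
  out
}

#' Place a lesion on a scene
#'
#' Subtracts the lesion bump from the depth field (a protrusion moves the
#' surface toward the camera). The footprint must lie inside the scene
#' domain. A zero-height lesion leaves the scene unchanged.
#'
#' @param scene a `surface_scene`.
#' @param lesion a [lesion_spec()].
#' @export
add_lesion <- function(scene, lesion) {
  stopifnot(inherits(scene, "surface_scene"), inherits(lesion, "lesion_spec"))
  Rf <- lesion$footprint_diameter_mm / 2
  c0 <- lesion$center
  d <- scene$domain
  if (c0[1] - Rf < d[1] || c0[1] + Rf > d[2] ||
      c0[2] - Rf < d[3] || c0[2] + Rf > d[4]) {
    stop("lesion footprint extends outside the scene domain", call. = FALSE)
  }
  base_z <- scene$height_fn
  zfun <- function(x, y) {
    r <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
    base_z(x, y) - lesion_bump_height(lesion, r)
  }
  new_scene(zfun, scene$albedo_fn, scene$domain,
            descriptor = c(scene$descriptor,
                           list(lesion = unclass(lesion))))
}

#' Marker grid for accuracy evaluation
#'
#' A rows x cols grid of measurement points at fixed pitch, centred in a
#' stated extent. The default 11 x 8 grid at 5 mm pitch yields the 88
#' evaluation points spanning 50 x 35 mm inside a 50 (vertical) x 45
#' (horizontal) mm extent, emulating graphite dots placed on tissue.
#'
#' @param rows,cols grid dimensions (rows run along y, cols along x).
#' @param pitch_mm grid pitch, mm.
#' @param extent_mm length-2 numeric `(vertical, horizontal)` extent the grid
#'   must fit inside, mm.
#' @return a `marker_grid`: data frame of `(x, y)` points plus attributes.
#' @examples
#' g <- marker_grid()     # 88 points
#' nrow(g$points)
#' @export
marker_grid <- function(rows = 11, cols = 8, pitch_mm = 5,
                        extent_mm = c(50, 45)) {
  stopifnot(rows >= 1, cols >= 1, pitch_mm > 0)
  span_y <- (rows - 1) * pitch_mm
  span_x <- (cols - 1) * pitch_mm
  if (span_y > extent_mm[1] || span_x > extent_mm[2]) {
    stop(sprintf("grid span %g x %g mm exceeds extent %g x %g mm",
                 span_y, span_x, extent_mm[1], extent_mm[2]), call. = FALSE)
  }
  pts <- expand.grid(
    x = seq(-span_x / 2, span_x / 2, length.out = cols),
    y = seq(-span_y / 2, span_y / 2, length.out = rows)
  )
  structure(list(points = pts, pitch_mm = pitch_mm, extent_mm = extent_mm,
                 rows = rows, cols = cols),
            class = "marker_grid")
}

#' Paint markers onto a scene as albedo drops
#'
#' Graphite dots are dark: inside each marker disc the albedo is multiplied
#' by `1 - albedo_drop`. Dark pixels carry almost no fringe modulation, so
#' the reconstruction's quality mask excludes them -- which is why marker
#' heights are read off the surrounding tissue at a +/- offset
#' (see [marker_height()]).
#'
#' @param scene a `surface_scene`.
#' @param grid a [marker_grid()].
#' @param albedo_drop fraction of albedo removed inside markers, in (0, 1].
#' @param diameter_mm marker disc diameter, mm.
#' @export
add_markers <- function(scene, grid, albedo_drop = 0.95, diameter_mm = 1) {
  stopifnot(inherits(scene, "surface_scene"), inherits(grid, "marker_grid"),
            albedo_drop > 0, albedo_drop <= 1, diameter_mm > 0)
  base_a <- scene$albedo_fn
  mx <- grid$points$x
  my <- grid$points$y
  r2 <- (diameter_mm / 2)^2
  afun <- function(x, y) {
    a <- base_a(x, y)
    hit <- rep(FALSE, length(x))
    for (i in seq_along(mx)) {
      hit <- hit | ((x - mx[i])^2 + (y - my[i])^2 <= r2)
    }
    a * ifelse(hit, 1 - albedo_drop, 1)
  }
  new_scene(scene$height_fn, afun, scene$domain,
            descriptor = c(scene$descriptor,
                           list(markers = list(rows = grid$rows,
                                               cols = grid$cols,
                                               pitch_mm = grid$pitch_mm,
                                               extent_mm = grid$extent_mm,
                                               albedo_drop = albedo_drop,
                                               diameter_mm = diameter_mm))))
}

#' Ground-truth height at a lateral point
#'
#' Exact analytic height relative to the reference plane,
#' `h = reference_mm - z(x, y)` (positive = protruding toward the camera).
#' This is the oracle the evaluation harness compares reconstructions
#' against.
#'
#' @param scene a `surface_scene`.
#' @param p length-2 numeric `(x, y)`, mm (or an n x 2 matrix).
#' @param reference_mm reference-plane distance, mm (default 470).
#' @export
surface_height <- function(scene, p, reference_mm = 470) {
  stopifnot(inherits(scene, "surface_scene"))
  p <- matrix(p, ncol = 2)
  d <- scene$domain
  if (any(p[, 1] < d[1] | p[, 1] > d[2] | p[, 2] < d[3] | p[, 2] > d[4])) {
    stop("point outside the scene domain", call. = FALSE)
  }
  as.numeric(reference_mm - scene$height_fn(p[, 1], p[, 2]))
}

#' Exact surface path length between two lateral points
#'
#' Arc length of the surface curve above the straight segment `pq`,
#' computed by adaptive numerical integration of
#' `sqrt(1 + (dz/ds)^2)` with the slope obtained by central differences.
#' This is the high-accuracy ground truth for path-length measurements on
#' curved surfaces.
#'
#' @param scene a `surface_scene`.
#' @param p,q length-2 numeric lateral endpoints, mm.
#' @param rel_tol relative integration tolerance.
#' @return path length, mm.
#' @examples
#' hp <- half_pipe_surface(21)
#' true_path_length(hp, c(-21, 0), c(21, 0))  # pi * 21
#' @export
true_path_length <- function(scene, p, q, rel_tol = 1e-9) {
  stopifnot(inherits(scene, "surface_scene"),
            length(p) == 2L, length(q) == 2L)
  d <- scene$domain
  for (pt in list(p, q)) {
    if (pt[1] < d[1] || pt[1] > d[2] || pt[2] < d[3] || pt[2] > d[4]) {
      stop("segment endpoint outside the scene domain", call. = FALSE)
    }
  }
  len <- sqrt(sum((q - p)^2))
  if (len == 0) return(0)
  dir <- (q - p) / len
  zs <- function(s) scene$height_fn(p[1] + s * dir[1], p[2] + s * dir[2])
  eps <- 1e-5
  integrand <- function(s) {
    slope <- (zs(s + eps) - zs(s - eps)) / (2 * eps)
    sqrt(1 + slope^2)
  }
  out <- tryCatch(
    stats::integrate(integrand, 0, len, rel.tol = rel_tol,
                     subdivisions = 1000L)$value,
    error = function(e) NULL)
  if (!is.null(out)) return(out)
  # adaptive quadrature can reject integrable slope singularities (e.g. the
  # vertical wall of a full-width half-pipe section); fall back to a dense
  # polyline, whose error for a sqrt-type singularity is O(step^1.5)
  n <- 2^17
  s <- seq(0, len, length.out = n + 1L)
  z <- zs(s)
  sum(sqrt(diff(s)^2 + diff(z)^2))
}

#' Rebuild a scene from its JSON descriptor
#'
#' Scenes serialize as JSON descriptors (type + parameters); this inverts
#' [write_scene()].
#'
#' @param desc a descriptor list (as stored in `scene$descriptor`).
#' @export
scene_from_descriptor <- function(desc) {
  sc <- switch(desc$type,
    flat = flat_surface(desc$distance_mm, as.numeric(desc$domain)),
    half_pipe = half_pipe_surface(desc$radius_mm, desc$axis,
                                  desc$crest_distance_mm,
                                  as.numeric(desc$domain)),
    stop("unknown scene type: ", desc$type, call. = FALSE)
  )
  if (!is.null(desc$lesion)) {
    l <- desc$lesion
    sc <- add_lesion(sc, lesion_spec(as.numeric(l$center),
                                     l$footprint_diameter_mm, l$height_mm,
                                     l$profile, l$edge_sharpness))
  }
  if (!is.null(desc$markers)) {
    m <- desc$markers
    sc <- add_markers(sc,
                      marker_grid(m$rows, m$cols, m$pitch_mm,
                                  as.numeric(m$extent_mm)),
                      m$albedo_drop, m$diameter_mm)
  }
  sc
}

#' @rdname scene_from_descriptor
#' @param scene a `surface_scene`.
#' @param path JSON file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "surface_scene"))
  jsonlite::write_json(scene$descriptor, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scene_from_descriptor
#' @export
read_scene <- function(path) {
  scene_from_descriptor(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Default stomach-analog lesion scene
#'
#' The half-pipe base (inner radius 21 mm) carrying a cosine-bump lesion of
#' 10 mm footprint and 3 mm height at the crest: the package's stand-in for
#' a plaster stomach model with a protruded lesion.
#'
#' @param radius_mm half-pipe inner radius, mm.
#' @param footprint_mm,height_mm lesion footprint diameter and apex height.
#' @param crest_distance_mm crest distance from the camera, mm.
#' @export
stomach_lesion_scene <- function(radius_mm = 21, footprint_mm = 10,
                                 height_mm = 3, crest_distance_mm = 455) {
  add_lesion(half_pipe_surface(radius_mm,
                               crest_distance_mm = crest_distance_mm),
             lesion_spec(c(0, 0), footprint_mm, height_mm, "cosine"))
}

#' Analytic surface profile
#'
#' The exact counterpart of [extract_profile()]: samples the analytic
#' surface (not a reconstruction) along segment `pq` at equally spaced
#' stations and returns the same `surface_profile` structure, usable with
#' [path_length()] and [base_path_from_flanks()].
#'
#' @inheritParams true_path_length
#' @param step_mm station spacing, mm.
#' @param reference_mm reference-plane distance for the height convention.
#' @export
true_profile <- function(scene, p, q, step_mm = 0.05, reference_mm = 470) {
  stopifnot(inherits(scene, "surface_scene"), step_mm > 0)
  len <- sqrt(sum((q - p)^2))
  if (len == 0) stop("profile endpoints coincide", call. = FALSE)
  n <- ceiling(len / step_mm) + 1L
  s <- seq(0, len, length.out = n)
  xs <- p[1] + s / len * (q[1] - p[1])
  ys <- p[2] + s / len * (q[2] - p[2])
  z <- scene$height_fn(xs, ys)
  h <- reference_mm - z
  seg <- sqrt(diff(s)^2 + diff(h)^2)
  structure(list(points = cbind(x = xs, y = ys, z = z),
                 arc_coordinate = c(0, cumsum(seg)), s = s, h = h,
                 endpoints = rbind(p = p, q = q), step_mm = step_mm),
            class = "surface_profile")
}
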