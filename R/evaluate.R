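#' Summary statistics for measurement errors
#'
#' Population standard deviation of the errors, its 3-sigma cutoff, and,
#' when paired measured/reference values are supplied, the squared Pearson
#' correlation between them. R-squared is reported as `NA` when the
#' reference is constant.
#'
#' @param errors numeric vector of (measured - true) errors.
#' @param measured,reference optional paired vectors for the correlation.
#' @return list with `sd`, `three_sigma`, `r_squared`.
#' @export
summary_stats <- function(errors, measured = NULL, reference = NULL) {
  errors <- errors[is.finite(errors)]
  if (length(errors) < 2L) stop("need >= 2 error values", call. = FALSE)
  s <- sqrt(mean((errors - mean(errors))^2))   # population SD
  r2 <- NA_real_
  if (!is.null(measured) && !is.null(reference)) {
    ok <- is.finite(measured) & is.finite(reference)
    if (stats::sd(reference[ok]) > 0 && stats::sd(measured[ok]) > 0) {
      r2 <- stats::cor(measured[ok], reference[ok])^2
    }
  }
  list(sd = s, three_sigma = 3 * s, r_squared = r2)
}

#' Marker-grid height-accuracy experiment
#'
#' The digital twin of the half-pipe validation study: porcine-stomach
#' curvature is emulated by the 21 mm half-pipe, the 88 graphite dots by an
#' 11 x 8 marker grid at 5 mm pitch, and the reference microscope by the
#' analytic scene. For each repeat (fresh noise seed derived from the
#' master seed) and each scan direction the scene is rendered, the height
#' map reconstructed, and every marker height read by the +/- 1.5 mm
#' two-point averaging rule, then compared with the exact surface height.
#'
#' @param rig a [make_default_rig()] configuration.
#' @param repeats number of repeat measurements (default 30).
#' @param noise_sd additive intensity noise SD (default 2).
#' @param seed master seed; every repeat/direction seed derives from it.
#' @param directions subset of `c("orthogonal", "parallel")`: stripe phase
#'   running across the half-pipe curvature or along it.
#' @param scene optional `surface_scene` override (markers are added on
#'   top); default is the 21 mm half-pipe.
#' @param grid optional [marker_grid()] override.
#' @param offset_mm marker two-point averaging offset.
#' @return an `evaluation_report` with the per-point error table, pooled
#'   and per-direction SD / 3-sigma / R-squared, a 0.1 mm histogram, and
#'   the configuration snapshot.
#' @export
height_accuracy_experiment <- function(rig = make_default_rig(),
                                       repeats = 30, noise_sd = 2,
                                       seed = 1L,
                                       directions = c("orthogonal",
                                                      "parallel"),
                                       scene = NULL, grid = marker_grid(),
                                       offset_mm = 1.5) {
  stopifnot(repeats >= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.null(scene)) scene <- half_pipe_surface(21)
  scene_m <- add_markers(scene, grid)
  pts <- grid$points
  truth <- surface_height(scene, as.matrix(pts), rig$standard_height_mm)
  seeds <- with_local_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      repeats * length(directions)),
           nrow = repeats))
  rows <- vector("list", repeats * length(directions))
  ri <- 0L
  for (d in seq_along(directions)) {
    # the two scan directions: phase along x runs across the half-pipe
    # curvature (orthogonal), along y runs parallel to its axis
    rig_d <- make_default_rig(utils::modifyList(
      unclass(rig),
      list(scan_direction = if (directions[d] == "orthogonal") "x" else "y")))
    geo <- intersect_scene(rig_d, scene_m)
    clean_hi <- clean_frames(rig_d, scene_m, geo, "high", 128, 100)
    clean_lo <- clean_frames(rig_d, scene_m, geo, "low", 128, 100)
    for (r in seq_len(repeats)) {
      s_r <- seeds[r, d]
      hi <- new_fringe_stack(add_frame_noise(clean_hi, noise_sd, s_r),
                             rig_d, "high", noise_sd, s_r, 128, 100)
      lo <- new_fringe_stack(add_frame_noise(clean_lo, noise_sd, s_r + 1L),
                             rig_d, "low", noise_sd, s_r, 128, 100)
      hm <- reconstruct_surface(hi, lo, rig_d)
      meas <- vapply(seq_len(nrow(pts)), function(i) {
        marker_height(hm, c(pts$x[i], pts$y[i]), offset_mm,
                      direction = c(0, 1))
      }, numeric(1))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(marker = seq_len(nrow(pts)), repeat_id = r,
                               direction = directions[d], measured = meas,
                               true = truth, error = meas - truth)
    }
  }
  tab <- do.call(rbind, rows)
  build_height_report(tab, rig, repeats, noise_sd, seed, directions)
}

build_height_report <- function(tab, rig, repeats, noise_sd, seed,
                                directions) {
  nmiss <- tapply(is.na(tab$error), tab$marker, mean)
  flagged <- as.integer(names(nmiss)[nmiss > 0.1])
  ok <- is.finite(tab$error)
  pooled <- summary_stats(tab$error[ok], tab$measured[ok], tab$true[ok])
  by_dir <- lapply(stats::setNames(nm = directions), function(d) {
    sub <- tab[tab$direction == d & is.finite(tab$error), ]
    summary_stats(sub$error, sub$measured, sub$true)
  })
  err <- tab$error[ok]
  breaks <- seq(floor(min(err) / 0.1) * 0.1 - 0.05,
                ceiling(max(err) / 0.1) * 0.1 + 0.05, by = 0.1)
  hg <- graphics::hist(err, breaks = breaks, plot = FALSE)
  structure(list(per_point_errors = tab,
                 sd_mm = pooled$sd, three_sigma_mm = 3 * pooled$sd,
                 r_squared = pooled$r_squared,
                 r_squared_by_direction = vapply(by_dir, `[[`, numeric(1),
                                                 "r_squared"),
                 sd_by_direction = vapply(by_dir, `[[`, numeric(1), "sd"),
                 histogram = list(breaks = hg$breaks, counts = hg$counts),
                 n_data_points = sum(ok),
                 flagged_markers = flagged,
                 config_snapshot = list(rig = unclass(rig),
                                        repeats = repeats,
                                        noise_sd = noise_sd, seed = seed,
                                        directions = directions)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  n data points   %d\n", x$n_data_points))
  if (!is.null(x$sd_mm)) {
    cat(sprintf("  height error SD %.3f mm (3 sigma %.3f mm)\n",
                x$sd_mm, x$three_sigma_mm))
    for (d in names(x$r_squared_by_direction)) {
      cat(sprintf("  R^2 (%s): %.5f, SD %.3f mm\n", d,
                  x$r_squared_by_direction[[d]], x$sd_by_direction[[d]]))
    }
  }
  if (!is.null(x$length_errors_pct) && nrow(x$length_errors_pct) > 0) {
    cat("  length errors:\n")
    for (i in seq_len(nrow(x$length_errors_pct))) {
      cat(sprintf("    %-12s %.3f%% (measured %.3f mm, true %.3f mm)\n",
                  x$length_errors_pct$case[i],
                  x$length_errors_pct$percent_error[i],
                  x$length_errors_pct$measured_mm[i],
                  x$length_errors_pct$true_mm[i]))
    }
  }
  if (!is.null(x$lateral_max_error_mm)) {
    cat(sprintf("  lateral max error %.4f mm over %d markers\n",
                x$lateral_max_error_mm, x$n_markers_localized))
  }
  invisible(x)
}

#' @export
plot.evaluation_report <- function(x, ...) {
  if (is.null(x$histogram)) {
    stop("report carries no histogram", call. = FALSE)
  }
  graphics::plot(structure(list(breaks = x$histogram$breaks,
                                counts = x$histogram$counts,
                                density = x$histogram$counts,
                                mids = (utils::head(x$histogram$breaks, -1) +
                                          utils::tail(x$histogram$breaks, -1)) / 2,
                                xname = "height error (mm)",
                                equidist = TRUE),
                           class = "histogram"),
                 freq = TRUE, main = "Height measurement error",
                 xlab = "height error (mm)", ...)
  invisible(x)
}

#' Curved-surface length-accuracy experiment
#'
#' The in-silico analog of the plaster-model length study: sections are
#' measured across a protruded lesion on the curved stomach-analog scene
#' (surface path lengths), a base section is estimated from flank
#' polynomial fitting, and each result is compared with the adaptive
#' numerical-integration ground truth. A lateral check reconstructs a flat
#' marker-grid scene and localizes each marker from the modulation deficit,
#' emulating the graph-paper comparison.
#'
#' @param rig a rig configuration.
#' @param cases list of section cases; each a list with `label`, `scene`
#'   (a `surface_scene`), `p`, `q` (profile endpoints), `type`
#'   (`"surface"` or `"base"`), and, for base cases, `lesion_span` (arc mm)
#'   and the lesion-free `base_scene` supplying the truth. `NULL` = the
#'   default three sections (A, B across the default lesion, C base).
#' @param smoothing apply the default 0.3 mm smoothing filter
#'   (`TRUE`/`FALSE`).
#' @param noise_sd intensity noise SD.
#' @param seed master seed.
#' @param lateral_check also run the flat marker-grid lateral accuracy
#'   check.
#' @param step_mm profile sampling step.
#' @return an `evaluation_report` with `length_errors_pct` and, when
#'   enabled, `lateral_max_error_mm`.
#' @export
length_accuracy_experiment <- function(rig = make_default_rig(),
                                       cases = NULL, smoothing = TRUE,
                                       noise_sd = 2, seed = 1L,
                                       lateral_check = TRUE,
                                       step_mm = 0.1) {
  if (is.null(cases)) cases <- default_length_cases()
  seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(cases) + 1L))
  smooth_mm <- if (isTRUE(smoothing)) 0.3 else 0
  res <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    hm <- simulate_and_reconstruct(rig, cs$scene, noise_sd, seeds[i],
                                   smooth_mm = smooth_mm)
    prof <- extract_profile(hm, cs$p, cs$q, step_mm)
    if (cs$type == "surface") {
      meas <- path_length(prof)
      truth <- true_path_length(cs$scene, cs$p, cs$q)
    } else {
      # the lesion span is stated in chord coordinates of the section;
      # base_path_from_flanks wants it in arc coordinates of the profile
      span_s <- sort(cs$lesion_span_s)
      span_arc <- stats::approx(prof$s, prof$arc_coordinate,
                                xout = span_s)$y
      meas <- as.numeric(base_path_from_flanks(prof, span_arc,
                                               degree = cs$degree %||% 2))
      dirn <- (cs$q - cs$p) / sqrt(sum((cs$q - cs$p)^2))
      p1 <- cs$p + span_s[1] * dirn
      p2 <- cs$p + span_s[2] * dirn
      truth <- true_path_length(cs$base_scene, p1, p2)
    }
    data.frame(case = cs$label, measured_mm = meas, true_mm = truth,
               percent_error = 100 * abs(meas - truth) / truth)
  })
  tab <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(case = character(0), measured_mm = numeric(0),
               true_mm = numeric(0), percent_error = numeric(0))
  report <- structure(list(length_errors_pct = tab,
                           n_data_points = nrow(tab),
                           config_snapshot = list(rig = unclass(rig),
                                                  smoothing = smoothing,
                                                  noise_sd = noise_sd,
                                                  seed = seed)),
                      class = "evaluation_report")
  if (isTRUE(lateral_check)) {
    lat <- lateral_accuracy_check(rig, noise_sd,
                                  seeds[length(seeds)])
    report$lateral_max_error_mm <- lat$max_error_mm
    report$lateral_errors <- lat$errors
    report$n_markers_localized <- nrow(lat$errors)
  }
  report
}

# default three sections on the stomach-analog scene: A across the lesion
# (over the curvature), B along the half-pipe axis, C the base underneath
default_length_cases <- function() {
  base <- half_pipe_surface(21)
  lesioned <- add_lesion(base, lesion_spec(c(0, 0), 10, 3, "cosine"))
  list(
    list(label = "A (across)", scene = lesioned, p = c(-7, 0), q = c(7, 0),
         type = "surface"),
    list(label = "B (along)", scene = lesioned, p = c(0, -7), q = c(0, 7),
         type = "surface"),
    list(label = "C (base)", scene = lesioned, p = c(-10.5, 0),
         q = c(10.5, 0), type = "base",
         lesion_span_s = c(5.5, 16.5),  # lesion extent in chord coordinates
         base_scene = base, degree = 2)
  )
}

#' Simulate and reconstruct a scene in one call
#'
#' Renders the high- and low-frequency stacks and runs the default
#' temporal-unwrapping reconstruction.
#'
#' @inheritParams render_fringe_stack
#' @param smooth_mm smoothing scale passed to [smooth_height_map()].
#' @return a `height_map`.
#' @export
simulate_and_reconstruct <- function(rig, scene, noise_sd = 0, seed = 1L,
                                     smooth_mm = 0) {
  geo <- intersect_scene(rig, scene)
  hi <- new_fringe_stack(
    add_frame_noise(clean_frames(rig, scene, geo, "high", 128, 100),
                    noise_sd, seed),
    rig, "high", noise_sd, seed, 128, 100)
  lo <- new_fringe_stack(
    add_frame_noise(clean_frames(rig, scene, geo, "low", 128, 100),
                    noise_sd, seed + 1L),
    rig, "low", noise_sd, seed, 128, 100)
  reconstruct_surface(hi, lo, rig, smooth_mm = smooth_mm)
}

# flat-plane marker grid: reconstruct, localize each marker as the centroid
# of its modulation-deficit blob in reconstructed lateral coordinates, and
# compare with the generating grid
lateral_accuracy_check <- function(rig, noise_sd = 2, seed = 1L,
                                   grid = marker_grid()) {
  scene <- add_markers(flat_surface(rig$standard_height_mm), grid)
  geo <- intersect_scene(rig, scene)
  hi <- new_fringe_stack(
    add_frame_noise(clean_frames(rig, scene, geo, "high", 128, 100),
                    noise_sd, seed),
    rig, "high", noise_sd, seed, 128, 100)
  wp <- wrapped_phase(hi)
  # markers are the low-modulation blobs; label and take centroids
  lab <- label_components_8(!wp$valid_mask)
  lat <- lateral_grids(rig)   # flat scene: lateral position = reference grid
  pts <- grid$points
  errs <- data.frame(marker = seq_len(nrow(pts)), ex = NA_real_,
                     ey = NA_real_)
  sizes <- tabulate(lab[lab > 0])
  for (i in which(sizes >= 3)) {
    sel <- lab == i
    cx <- mean(lat$x[sel]); cy <- mean(lat$y[sel])
    j <- which.min((pts$x - cx)^2 + (pts$y - cy)^2)
    d2 <- (pts$x[j] - cx)^2 + (pts$y[j] - cy)^2
    if (d2 < (grid$pitch_mm / 2)^2) {
      errs$ex[j] <- cx - pts$x[j]
      errs$ey[j] <- cy - pts$y[j]
    }
  }
  errs <- errs[is.finite(errs$ex), ]
  list(errors = errs,
       max_error_mm = max(abs(c(errs$ex, errs$ey))))
}
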